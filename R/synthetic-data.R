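#' Default sampling locales
#'
#' Three archetypal water columns spanning the habitat range of the sampled
#' specimens: a near-isothermal cold Arctic column, a temperate column with a
#' moderate thermocline, and a tropical column with a warm surface layer.
#' Temperature follows a piecewise-exponential decay with depth,
#' `T(z) = T_deep + (T_surf - T_deep) * exp(-z / z_scale)` (see
#' [locale_temperature()]), which reproduces monotone profiles without
#' claiming oceanographic fidelity.
#'
#' @return data frame with columns `name`, `surface_temp` (deg C),
#'   `deep_temp` (deg C), `z_scale` (m), `max_depth` (m).
#' @export
default_locales <- function() {
  data.frame(
    name         = c("arctic", "temperate", "tropical"),
    surface_temp = c(3, 15, 28),
    deep_temp    = c(-1, 2, 4),
    z_scale      = c(100, 150, 120),
    max_depth    = c(3000, 3500, 4000),
    stringsAsFactors = FALSE
  )
}

#' Default compound panel with latent baselines and environmental effects
#'
#' The panel spans every downstream metric: the six major even-chain FAMEs
#' (C14:0, C16:0, C18:0, C18:1, C20:5, C22:6), three odd-chain fatty acids,
#' and one long-chain fatty alcohol. `baseline` is the latent (log-scale)
#' species-mean coordinate; `beta_depth` is the latent effect per km of
#' depth and `beta_temp` the latent effect per deg C. Default effect
#' directions encode deeper = more monounsaturated (C18:1 up, SFAs down) and
#' warmer = longer chains (C18:0 up, C14:0 down), with a C17:0/C17:1
#' temperature exchange and polar enrichment of the C22:1 alcohol.
#'
#' @return data frame with columns `label`, `baseline`, `beta_depth`,
#'   `beta_temp`.
#' @export
default_panel <- function() {
  data.frame(
    label = c("C14:0", "C16:0", "C18:0", "C18:1", "C20:5", "C22:6",
              "C15:0", "C17:0", "C17:1", "C22:1(n-9) alcohol"),
    baseline = log(c(0.06, 0.35, 0.08, 0.09, 0.15, 0.20,
                     0.019, 0.021, 0.0075, 0.02)),
    beta_depth = c(-0.10, -0.05, -0.05, 0.25, 0, 0, 0, 0, 0, -0.15),
    beta_temp  = c(-0.05, 0, 0.04, -0.03, 0, 0, 0, 0.05, -0.04, -0.08),
    stringsAsFactors = FALSE
  )
}

#' Build a simulation configuration
#'
#' Collects all parameters of the synthetic study: tree size, sampling
#' design, habitat structure, the Ornstein-Uhlenbeck (OU) process generating
#' species-level latent composition coordinates, and linear environmental
#' effects on those coordinates.
#'
#' @param n_taxa number of species (>= 2).
#' @param individuals_per_taxon specimens sampled per species.
#' @param locales data frame as returned by [default_locales()].
#' @param panel compound panel as returned by [default_panel()].
#' @param ou_alpha OU selection strength per unit tree height (>= 0).
#' @param ou_sigma stationary SD of the species-level latent traits (>= 0).
#' @param noise_sd individual-level latent SD (>= 0).
#' @param seed integer seed fixing every random draw of the study.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(n_taxa = 20L, individuals_per_taxon = 5L,
                       locales = default_locales(), panel = default_panel(),
                       ou_alpha = 3, ou_sigma = 0.3, noise_sd = 0.15,
                       seed = 1L) {
  if (n_taxa < 2L) stop("n_taxa must be >= 2")
  if (individuals_per_taxon < 1L) stop("individuals_per_taxon must be >= 1")
  if (nrow(locales) == 0L) stop("locale list is empty")
  stopifnot(all(c("name", "surface_temp", "deep_temp", "z_scale", "max_depth")
                %in% names(locales)))
  if (ou_alpha < 0 || ou_sigma < 0 || noise_sd < 0)
    stop("variance/selection parameters must be >= 0")
  if (!all(is.finite(c(ou_alpha, ou_sigma, noise_sd,
                       panel$baseline, panel$beta_depth, panel$beta_temp))))
    stop("non-finite simulation parameters")
  parse_lipid(panel$label) # validates the panel labels
  structure(list(n_taxa = as.integer(n_taxa),
                 individuals_per_taxon = as.integer(individuals_per_taxon),
                 locales = locales, panel = panel,
                 ou_alpha = ou_alpha, ou_sigma = ou_sigma,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sim_config")
}

#' Temperature at depth for an exponential-decay water column
#'
#' @param depth_m depth in meters (>= 0).
#' @param surface_temp,deep_temp,z_scale profile parameters: temperature at
#'   the surface, asymptotic deep temperature, and decay scale in meters.
#' @return temperature in deg C.
#' @export
locale_temperature <- function(depth_m, surface_temp, deep_temp, z_scale) {
  if (any(depth_m < 0)) stop("depth must be >= 0")
  deep_temp + (surface_temp - deep_temp) * exp(-depth_m / z_scale)
}

#' Simulate an ultrametric species phylogeny
#'
#' Draws a random coalescent tree (binary, ultrametric, strictly positive
#' branch lengths) and rescales total height to 1, so that downstream OU
#' selection strengths are expressed per unit tree height.
#'
#' @param n_taxa number of tips (>= 2); labels are `sp01`, `sp02`, ...
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return an [ape::phylo] object of height 1.
#' @export
simulate_tree <- function(n_taxa, seed = NULL) {
  if (n_taxa < 2L) stop("n_taxa must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  phy <- ape::rcoal(n_taxa, tip.label = sprintf("sp%02d", seq_len(n_taxa)))
  h <- max(ape::node.depth.edgelength(phy))
  phy$edge.length <- phy$edge.length / h
  phy
}

#' Simulate specimen collection records
#'
#' Assigns each species to a locale (round-robin) and draws a collection
#' depth for each individual with a shallow-biased quadratic law, then reads
#' temperature off the locale profile. Three strata are guaranteed populated
#' so that both analysis slices (cold, <= 7.5 deg C; shallow, <= 200 m) are
#' non-empty: shallow-warm, shallow-cold and deep-cold records.
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed.
#' @return data frame with columns `sample_id`, `taxon`, `locale`,
#'   `depth_m`, `temp_C`, `method`.
#' @export
simulate_environment <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  loc <- config$locales
  if (nrow(loc) == 0L) stop("locale list is empty")
  taxa <- sprintf("sp%02d", seq_len(config$n_taxa))
  taxon_locale <- loc$name[(seq_along(taxa) - 1L) %% nrow(loc) + 1L]
  rec <- expand.grid(ind = seq_len(config$individuals_per_taxon),
                     taxon = taxa, stringsAsFactors = FALSE)
  rec$locale <- taxon_locale[match(rec$taxon, taxa)]
  li <- match(rec$locale, loc$name)
  rec$depth_m <- loc$max_depth[li] * stats::runif(nrow(rec))^2
  # guarantee the strata both slices need
  warm <- which.max(loc$surface_temp)
  cold <- which.min(loc$surface_temp)
  force_depth <- function(rec, locale_idx, pick, depth) {
    cand <- which(rec$locale == loc$name[locale_idx])
    rec$depth_m[cand[min(pick, length(cand))]] <- depth
    rec
  }
  rec <- force_depth(rec, warm, 1L, 5)
  rec <- force_depth(rec, cold, 1L, 50)
  rec <- force_depth(rec, cold, 2L, min(1500, loc$max_depth[cold]))
  li <- match(rec$locale, loc$name)
  rec$temp_C <- locale_temperature(rec$depth_m, loc$surface_temp[li],
                                   loc$deep_temp[li], loc$z_scale[li])
  rec$method <- ifelse(rec$depth_m <= 30, "SCUBA",
                       ifelse(rec$depth_m <= 1200 & stats::runif(nrow(rec)) < 0.3,
                              "trawl", "ROV"))
  rec$sample_id <- sprintf("%s_%02d", rec$taxon, rec$ind)
  rec[, c("sample_id", "taxon", "locale", "depth_m", "temp_C", "method")]
}

#' Draw stationary Ornstein-Uhlenbeck traits at the tips of a tree
#'
#' Draws `n_traits` independent trait vectors from the stationary OU
#' distribution on a phylogeny: multivariate normal with covariance
#' `sigma^2 * exp(-alpha * d_ij)` where `d_ij` is patristic distance. The
#' draw is exact (eigendecomposition of the stationary covariance), not a
#' path simulation.
#'
#' @param phy an [ape::phylo] tree.
#' @param alpha OU selection strength (>= 0) per unit branch length.
#' @param sigma stationary SD (>= 0).
#' @param n_traits number of independent traits.
#' @return matrix (tips x traits) with row names = tip labels.
#' @export
rou_tips <- function(phy, alpha, sigma, n_traits = 1L) {
  if (alpha < 0 || sigma < 0) stop("alpha and sigma must be >= 0")
  d <- stats::cophenetic(phy)
  n <- nrow(d)
  if (sigma == 0) {
    z <- matrix(0, n, n_traits)
  } else {
    cv <- sigma^2 * exp(-alpha * d)
    e <- eigen(cv, symmetric = TRUE)
    rt <- e$vectors %*% (sqrt(pmax(e$values, 0)) *
                           matrix(stats::rnorm(n * n_traits), n, n_traits))
    z <- rt
  }
  rownames(z) <- rownames(d)
  z
}

#' Simulate compositional profiles on a phylogeny
#'
#' For each compound in the panel, a latent coordinate per individual is
#' built as baseline + species-level OU deviation + `beta_depth * depth_km`
#' + `beta_temp * temp_C` + individual Normal(0, `noise_sd`) noise; the
#' mole-fraction profile is the softmax of the latent coordinates, which
#' guarantees a valid simplex while keeping environmental effects linear on
#' the latent (log-ratio) scale. Ground truth, including per-compound molar
#' ionization coefficients used by [simulate_gcms()], is recorded before any
#' instrument-level noise.
#'
#' @param tree species phylogeny whose tips cover all taxa in `records`.
#' @param records specimen table from [simulate_environment()].
#' @param config a [sim_config()].
#' @param seed optional integer seed.
#' @return list with elements `truth` (tree, `species_baselines`,
#'   `true_betas`, `true_mole_fractions` matrix, `true_ionization`) and
#'   `composition` (long data frame: `sample_id`, `compound`,
#'   `mole_fraction`).
#' @export
simulate_compositions <- function(tree, records, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  unknown <- setdiff(unique(records$taxon), tree$tip.label)
  if (length(unknown))
    stop("taxa absent from tree: ", paste(unknown, collapse = ", "))
  pan <- config$panel
  k <- nrow(pan)
  n <- nrow(records)
  zsp <- rou_tips(tree, config$ou_alpha, config$ou_sigma, n_traits = k)
  colnames(zsp) <- pan$label
  latent <- matrix(pan$baseline, n, k, byrow = TRUE) +
    zsp[records$taxon, , drop = FALSE] +
    outer(records$depth_m / 1000, pan$beta_depth) +
    outer(records$temp_C, pan$beta_temp) +
    matrix(stats::rnorm(n * k, sd = config$noise_sd), n, k)
  ex <- exp(latent)
  x <- ex / rowSums(ex)
  dimnames(x) <- list(records$sample_id, pan$label)
  mass_coef <- exp(stats::rnorm(k, mean = log(1e6), sd = 0.3))
  mm <- lipid_molar_mass(pan$label)
  ionization <- data.frame(compound = pan$label, molar_mass = mm,
                           mass_coefficient = mass_coef,
                           molar_coefficient = mass_coef / mm,
                           stringsAsFactors = FALSE)
  truth <- list(tree = tree,
                species_baselines = sweep(zsp, 2, pan$baseline, "+"),
                true_betas = pan[, c("label", "beta_depth", "beta_temp")],
                true_mole_fractions = x,
                true_ionization = ionization)
  composition <- data.frame(
    sample_id = rep(records$sample_id, each = k),
    compound = rep(pan$label, n),
    mole_fraction = as.vector(t(x)),
    stringsAsFactors = FALSE
  )
  list(truth = truth, composition = composition)
}

#' Build reference electron-impact spectra for a compound panel
#'
#' Synthetic spectra with class-typical base peaks (m/z 74 for saturated
#' FAMEs, 55 for monounsaturates and alcohols, 79 for polyunsaturates), a
#' class secondary ion, and the molecular ion. Compounds listed together in
#' `coelution` share their base peak by construction and additionally carry
#' a small intensity at each partner's molecular ion, so quantitation-ion
#' selection has to fall through base and secondary ions before finding an
#' ion tenfold cleaner than the coeluter.
#'
#' @param labels compound labels.
#' @param coelution list of character vectors, each one group of compounds
#'   that coelute chromatographically.
#' @return data frame `compound`, `mz`, `rel_intensity` (base peak = 1).
#' @export
build_reference_spectra <- function(labels,
                                    coelution = list(c("C20:5", "C22:6"))) {
  sp <- parse_lipid(labels)
  base_mz <- c(SFA = 74L, MUFA = 55L, PUFA = 79L, alcohol = 55L)[sp$class]
  sec_mz <- c(SFA = 87L, MUFA = 69L, PUFA = 91L, alcohol = 83L)[sp$class]
  mol_mz <- as.integer(round(lipid_molar_mass(labels)))
  rows <- lapply(seq_along(labels), function(i) {
    mz <- c(base_mz[i], sec_mz[i], mol_mz[i])
    ri <- c(1, 0.5, 0.3)
    for (grp in coelution) {
      if (labels[i] %in% grp) {
        partners <- setdiff(grp, labels[i])
        pm <- mol_mz[match(partners, labels)]
        mz <- c(mz, pm)
        ri <- c(ri, rep(0.02, length(pm)))
      }
    }
    keep <- !duplicated(mz)
    data.frame(compound = labels[i], mz = mz[keep], rel_intensity = ri[keep],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate GC-MS external standards, sample peaks and reference spectra
#'
#' Standards: one integral per (compound, split ratio), lying on a line
#' through the origin against the on-column fraction `1/(1 + split)`, with
#' slope equal to the compound's mass ionization coefficient (optionally
#' perturbed by relative noise). Sample peaks: single-ion integrals equal to
#' true moles x molar ionization coefficient x a per-sample scale. Spectra:
#' see [build_reference_spectra()]; at least one coeluting pair shares its
#' base peak so quantitation-ion selection is exercised.
#'
#' @param composition long composition table (`sample_id`, `compound`,
#'   `mole_fraction`), e.g. from [simulate_compositions()].
#' @param ionization data frame `compound`, `molar_mass`,
#'   `mass_coefficient`, `molar_coefficient` (all coefficients > 0).
#' @param split_ratios numeric vector of split ratios (>= 2 values;
#'   default: the eight-point calibration series).
#' @param coelution list of coeluting compound groups.
#' @param noise_cv relative (coefficient-of-variation) noise applied to
#'   standard and peak integrals; 0 gives an exact round trip.
#' @param seed optional integer seed.
#' @return list `standards`, `peaks`, `spectra`, with the coelution groups
#'   attached as `attr(, "coelution")`.
#' @export
simulate_gcms <- function(composition, ionization,
                          split_ratios = c(5, 10, 15, 20, 30, 40, 60, 100),
                          coelution = list(c("C20:5", "C22:6")),
                          noise_cv = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(unique(split_ratios)) < 2L)
    stop("at least 2 distinct split ratios are required to define a slope")
  if (any(ionization$mass_coefficient <= 0) ||
      any(ionization$molar_coefficient <= 0))
    stop("ionization coefficients must be > 0")
  labels <- ionization$compound
  coelution <- Filter(function(g) length(intersect(g, labels)) >= 2L, coelution)

  standards <- expand.grid(compound = labels, split_ratio = split_ratios,
                           stringsAsFactors = FALSE)
  i <- match(standards$compound, labels)
  standards$molar_mass_g_mol <- ionization$molar_mass[i]
  standards$integral <- ionization$mass_coefficient[i] *
    on_column_fraction(standards$split_ratio)
  if (noise_cv > 0)
    standards$integral <- standards$integral *
      (1 + stats::rnorm(nrow(standards), sd = noise_cv))
  standards <- standards[order(standards$compound, standards$split_ratio),
                         c("compound", "molar_mass_g_mol", "split_ratio", "integral")]
  rownames(standards) <- NULL

  spectra <- build_reference_spectra(labels, coelution)
  quant_ion <- vapply(labels, function(lab) {
    grp <- Filter(function(g) lab %in% g, coelution)
    partners <- if (length(grp)) setdiff(grp[[1L]], lab) else character()
    select_quant_ion(spectra[spectra$compound == lab, ],
                     lapply(partners, function(p) spectra[spectra$compound == p, ]))
  }, 1)

  samples <- unique(composition$sample_id)
  scale <- exp(stats::rnorm(length(samples), mean = log(5e4), sd = 0.3))
  names(scale) <- samples
  peaks <- composition
  j <- match(peaks$compound, labels)
  if (anyNA(j)) stop("composition contains compounds missing from ionization table")
  peaks$mz <- quant_ion[j]
  peaks$integral <- peaks$mole_fraction * scale[peaks$sample_id] *
    ionization$molar_coefficient[j]
  if (noise_cv > 0)
    peaks$integral <- peaks$integral * (1 + stats::rnorm(nrow(peaks), sd = noise_cv))
  peaks <- peaks[, c("sample_id", "compound", "mz", "integral")]
  rownames(peaks) <- NULL

  out <- list(standards = standards, peaks = peaks, spectra = spectra)
  attr(out, "coelution") <- coelution
  out
}

#' Simulate a complete synthetic study
#'
#' One call producing every input of the analysis pipeline with known ground
#' truth: tree, specimen records, compositions, and GC-MS fixtures. The
#' configuration seed fixes all outputs byte-for-byte.
#'
#' @param config a [sim_config()].
#' @param noise_cv relative instrument noise passed to [simulate_gcms()].
#' @return list `config`, `tree`, `specimens`, `truth`, `composition`,
#'   `standards`, `peaks`, `spectra`, `coelution`.
#' @export
simulate_study <- function(config = sim_config(), noise_cv = 0) {
  set.seed(config$seed)
  tree <- simulate_tree(config$n_taxa)
  specimens <- simulate_environment(config)
  cmp <- simulate_compositions(tree, specimens, config)
  gc <- simulate_gcms(cmp$composition, cmp$truth$true_ionization,
                      noise_cv = noise_cv)
  list(config = config, tree = tree, specimens = specimens,
       truth = cmp$truth, composition = cmp$composition,
       standards = gc$standards, peaks = gc$peaks, spectra = gc$spectra,
       coelution = attr(gc, "coelution"))
}

#' Write a simulated study to disk
#'
#' Writes `tree.nwk`, `specimens.csv`, `composition.csv`, `standards.csv`,
#' `peaks.csv`, `spectra.csv` and `truth.json` into a directory.
#'
#' @param study output of [simulate_study()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ape::write.tree(study$tree, file.path(dir, "tree.nwk"))
  wcsv <- function(df, f) utils::write.csv(df, file.path(dir, f), row.names = FALSE)
  wcsv(study$specimens, "specimens.csv")
  wcsv(study$composition, "composition.csv")
  wcsv(study$standards, "standards.csv")
  wcsv(study$peaks, "peaks.csv")
  wcsv(study$spectra, "spectra.csv")
  tm <- study$truth$true_mole_fractions
  truth <- list(
    seed = study$config$seed,
    ou_alpha = study$config$ou_alpha,
    ou_sigma = study$config$ou_sigma,
    noise_sd = study$config$noise_sd,
    true_betas = study$truth$true_betas,
    true_ionization = study$truth$true_ionization,
    species_baselines = as.data.frame(study$truth$species_baselines),
    true_mole_fractions = data.frame(sample_id = rownames(tm),
                                     as.data.frame(tm, check.names = FALSE))
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", digits = NA)
  invisible(dir)
}
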