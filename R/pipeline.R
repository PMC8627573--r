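#' Analysis configuration for the regression battery
#'
#' Bundles the environmental slicing thresholds, the per-species minimum
#' sample size, the familywise significance level, and the response panels
#' regressed against each environmental predictor. The two slice thresholds
#' are inclusive by default (a specimen at exactly 7.5 deg C enters the
#' depth analysis; one at exactly 200 m enters the temperature analysis);
#' `inclusive = FALSE` switches both to strict inequalities.
#'
#' @param depth_slice_max_temp max body temperature (deg C) for specimens
#'   entering depth regressions.
#' @param temp_slice_max_depth max collection depth (m) for specimens
#'   entering temperature regressions.
#' @param per_species_min_n minimum specimens per species for the
#'   within-species ordinary regressions.
#' @param alpha familywise significance level.
#' @param inclusive logical: compare thresholds with `<=` (default) or `<`.
#' @param summary_responses,major_fames,ocfa_responses response panels; each
#'   (panel x predictor) combination is one Holm family.
#' @param intercorrelation_pairs list of 2-vectors of compound labels, each
#'   regressed one on the other over the full specimen set.
#' @return a list of class `"analysis_config"`.
#' @export
analysis_config <- function(depth_slice_max_temp = 7.5,
                            temp_slice_max_depth = 200,
                            per_species_min_n = 6L,
                            alpha = 0.05,
                            inclusive = TRUE,
                            summary_responses = c("dbi", "chain_length",
                                                  "sfa", "mufa", "pufa"),
                            major_fames = c("C14:0", "C16:0", "C18:0",
                                            "C18:1", "C20:5", "C22:6"),
                            ocfa_responses = c("C17:0", "C17:1"),
                            intercorrelation_pairs = list(
                              c("C20:5", "C22:6"),
                              c("C18:1", "C18:0"),
                              c("C18:1", "C16:0"),
                              c("C18:1", "C14:0"))) {
  if (depth_slice_max_temp <= -2 || temp_slice_max_depth <= 0)
    stop("slice thresholds must be positive / physically sensible")
  if (per_species_min_n < 3L) stop("per_species_min_n must be >= 3")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(depth_slice_max_temp = depth_slice_max_temp,
                 temp_slice_max_depth = temp_slice_max_depth,
                 per_species_min_n = as.integer(per_species_min_n),
                 alpha = alpha, inclusive = inclusive,
                 summary_responses = summary_responses,
                 major_fames = major_fames,
                 ocfa_responses = ocfa_responses,
                 intercorrelation_pairs = intercorrelation_pairs),
            class = "analysis_config")
}

#' Specimens entering the depth analysis (cold slice)
#'
#' Depth regressions are restricted to specimens whose body temperature at
#' collection was at or below the threshold (default 7.5 deg C), limiting
#' covariation between the two environmental predictors.
#'
#' @param records specimen table with columns `depth_m`, `temp_C`.
#' @param config an [analysis_config()].
#' @return the subset of `records`; empty subsets are allowed (a message is
#'   emitted).
#' @export
slice_for_depth <- function(records, config = analysis_config()) {
  keep <- if (config$inclusive) records$temp_C <= config$depth_slice_max_temp
          else records$temp_C < config$depth_slice_max_temp
  out <- records[keep, , drop = FALSE]
  if (nrow(out) == 0L) message("depth slice is empty")
  out
}

#' Specimens entering the temperature analysis (shallow slice)
#'
#' @inheritParams slice_for_depth
#' @return the subset of `records` collected at or above the depth
#'   threshold (default 200 m).
#' @export
slice_for_temperature <- function(records, config = analysis_config()) {
  keep <- if (config$inclusive) records$depth_m <= config$temp_slice_max_depth
          else records$depth_m < config$temp_slice_max_depth
  out <- records[keep, , drop = FALSE]
  if (nrow(out) == 0L) message("temperature slice is empty")
  out
}

#' Join metrics, compositions and specimen records into one response table
#'
#' @param metrics data frame from [compute_metrics()].
#' @param composition long composition table (may be `NULL`).
#' @param records specimen table.
#' @return wide data frame keyed by `sample_id` with specimen covariates
#'   (including `depth_km`), metric columns and one column per compound.
#' @export
build_response_table <- function(metrics, composition = NULL, records) {
  tab <- merge(records, metrics, by = "sample_id", sort = TRUE)
  if (!is.null(composition)) {
    wide <- stats::reshape(composition, idvar = "sample_id",
                           timevar = "compound", direction = "wide")
    names(wide) <- sub("^mole_fraction\\.", "", names(wide))
    tab <- merge(tab, wide, by = "sample_id", sort = TRUE)
  }
  tab$depth_km <- tab$depth_m / 1000
  tab
}

.fit_family <- function(tab, responses, predictor, tree, family, slice,
                        config, ...) {
  missing_resp <- setdiff(responses, names(tab))
  if (length(missing_resp))
    stop("missing response column(s): ", paste(missing_resp, collapse = ", "))
  if (nrow(tab) == 0L) stop("empty slice for family '", family, "'")
  rows <- do.call(rbind, lapply(responses, function(r)
    fit_pgls(tab, r, predictor, tree, slice = slice, ...)))
  rows$family <- family
  rows$p_holm <- holm_adjust(rows$p)
  rows$significant <- rows$p_holm < config$alpha
  rows
}

#' Run the full phylogenetic regression battery
#'
#' Fits OU-PGLS regressions of the lipidome summary metrics, the six major
#' FAMEs and the fatty-alcohol total against depth (within the cold slice)
#' and temperature (within the shallow slice), plus the C17 odd-chain pair
#' against temperature. Holm adjustment is applied within each
#' (panel x predictor) family, and rows are flagged significant at the
#' configured familywise level.
#'
#' @param metrics data frame from [compute_metrics()].
#' @param composition long composition table.
#' @param records specimen table (`sample_id`, `taxon`, `depth_m`,
#'   `temp_C`, ...).
#' @param tree species phylogeny.
#' @param config an [analysis_config()].
#' @param ... further arguments to [fit_pgls()] (e.g. `epsilon`,
#'   `n_grid`).
#' @return data frame of regression rows with `family`, `p_holm` and
#'   `significant` columns.
#' @export
run_battery <- function(metrics, composition, records, tree,
                        config = analysis_config(), ...) {
  tab <- build_response_table(metrics, composition, records)
  dslice <- tab[tab$sample_id %in% slice_for_depth(records, config)$sample_id, ]
  tslice <- tab[tab$sample_id %in% slice_for_temperature(records, config)$sample_id, ]
  alc <- "alcohol"
  fams <- list(
    list(dslice, config$summary_responses, "depth_km", "summary x depth", "cold"),
    list(dslice, config$major_fames,       "depth_km", "major_fames x depth", "cold"),
    list(dslice, alc,                      "depth_km", "alcohol x depth", "cold"),
    list(tslice, config$summary_responses, "temp_C", "summary x temperature", "shallow"),
    list(tslice, config$major_fames,       "temp_C", "major_fames x temperature", "shallow"),
    list(tslice, config$ocfa_responses,    "temp_C", "ocfa x temperature", "shallow"),
    list(tslice, alc,                      "temp_C", "alcohol x temperature", "shallow")
  )
  out <- do.call(rbind, lapply(fams, function(f)
    .fit_family(f[[1L]], f[[2L]], f[[3L]], tree, f[[4L]], f[[5L]], config, ...)))
  rownames(out) <- NULL
  out
}

#' Within-species ordinary regressions
#'
#' For each species with at least `per_species_min_n` specimens inside the
#' relevant slice, fits ordinary least-squares regressions of each summary
#' response on the predictor, with Holm adjustment across responses within
#' the species (one family per species x predictor). Species below the
#' threshold, or with a constant predictor, are skipped with a message.
#'
#' @inheritParams run_battery
#' @return data frame of OLS rows with `taxon`, `family`, `p_holm`,
#'   `significant` columns (zero rows if no species qualifies).
#' @export
per_species_ols <- function(metrics, records, config = analysis_config()) {
  tab <- build_response_table(metrics, NULL, records)
  slices <- list(depth_km = slice_for_depth(records, config)$sample_id,
                 temp_C = slice_for_temperature(records, config)$sample_id)
  out <- list()
  for (predictor in names(slices)) {
    sl <- tab[tab$sample_id %in% slices[[predictor]], ]
    for (taxon in sort(unique(sl$taxon))) {
      d <- sl[sl$taxon == taxon, ]
      if (nrow(d) < config$per_species_min_n) {
        message("skipping ", taxon, " vs ", predictor, ": n = ", nrow(d),
                " < ", config$per_species_min_n)
        next
      }
      if (stats::var(d[[predictor]]) == 0) {
        warning("skipping ", taxon, " vs ", predictor,
                ": constant predictor within species")
        next
      }
      rows <- do.call(rbind, lapply(config$summary_responses, function(r)
        fit_ols(d, r, predictor, slice = taxon)))
      rows$taxon <- taxon
      rows$family <- paste(taxon, predictor, sep = " x ")
      rows$p_holm <- holm_adjust(rows$p)
      rows$significant <- rows$p_holm < config$alpha
      out[[length(out) + 1L]] <- rows
    }
  }
  if (length(out) == 0L) {
    message("no species reached n >= ", config$per_species_min_n)
    return(data.frame())
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Phylogenetic intercorrelations between compound fractions
#'
#' PGLS of one compound's mole fraction on another's over the full specimen
#' set (no environmental slice: intercorrelations use every specimen), with
#' Holm adjustment across the pairs as one family.
#'
#' @param composition long composition table.
#' @param records specimen table.
#' @param tree species phylogeny.
#' @param pairs list of length-2 character vectors `(response, predictor)`;
#'   a pair of identical labels is rejected.
#' @param config an [analysis_config()].
#' @param ... further arguments to [fit_pgls()].
#' @return data frame of regression rows with `p_holm` and `significant`.
#' @export
intercorrelate <- function(composition, records, tree,
                           pairs = analysis_config()$intercorrelation_pairs,
                           config = analysis_config(), ...) {
  have <- unique(composition$compound)
  for (pr in pairs) {
    if (length(pr) != 2L || pr[1L] == pr[2L])
      stop("invalid intercorrelation pair: ", paste(pr, collapse = " ~ "))
    if (!all(pr %in% have))
      stop("unknown compound(s) in pair: ",
           paste(setdiff(pr, have), collapse = ", "))
  }
  metrics0 <- data.frame(sample_id = unique(composition$sample_id))
  tab <- build_response_table(metrics0, composition, records)
  rows <- do.call(rbind, lapply(pairs, function(pr)
    fit_pgls(tab, pr[1L], pr[2L], tree, slice = "all", ...)))
  rows$family <- "intercorrelations"
  rows$p_holm <- holm_adjust(rows$p)
  rows$significant <- rows$p_holm < config$alpha
  rownames(rows) <- NULL
  rows
}

.config_hash <- function(x) {
  # polynomial rolling hash over the deparsed object; fingerprints a run
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a regression report to a TSV file
#'
#' Deterministic column order, with run metadata (seed, configuration
#' fingerprint, package version) embedded as `#` comment header lines.
#'
#' @param results non-empty data frame of regression rows.
#' @param path output path.
#' @param seed seed recorded in the header (optional).
#' @param config configuration object fingerprinted in the header.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, seed = NA, config = NULL) {
  if (is.null(results) || nrow(results) == 0L)
    stop("empty results: nothing to report")
  lead <- c("response", "predictor", "slice", "family", "n")
  cols <- c(intersect(lead, names(results)),
            setdiff(names(results), lead))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot open report path '", path,
                                           "': ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(sprintf("# seed=%s", seed),
               sprintf("# config_hash=%s", .config_hash(config)),
               sprintf("# ctenofa_version=%s",
                       as.character(utils::packageVersion("ctenofa")))), con)
  utils::write.table(format(results[, cols], digits = 15, trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the complete analysis on study inputs
#'
#' Orchestrates quantitation (when raw GC-MS tables are given), metric
#' computation, the phylogenetic regression battery, within-species
#' ordinary regressions, and intercorrelations.
#'
#' @param tree species phylogeny.
#' @param specimens specimen table.
#' @param composition long composition table (used directly when given).
#' @param standards,peaks,spectra,coelution raw GC-MS tables; used via
#'   [quantify_run()] when `composition` is `NULL`.
#' @param config an [analysis_config()].
#' @param basis DBI / chain-length basis (see [double_bond_index()]).
#' @param ... further arguments to [fit_pgls()].
#' @return list `composition`, `metrics`, `battery`, `per_species`,
#'   `intercorrelations`.
#' @export
run_analysis <- function(tree, specimens, composition = NULL,
                         standards = NULL, peaks = NULL, spectra = NULL,
                         coelution = list(), config = analysis_config(),
                         basis = "even_fa", ...) {
  if (is.null(composition)) {
    if (is.null(standards) || is.null(peaks) || is.null(spectra))
      stop("either a composition table or standards+peaks+spectra required")
    composition <- quantify_run(standards, peaks, spectra,
                                coelution = coelution)$composition
  }
  metrics <- compute_metrics(composition, basis = basis)
  list(composition = composition,
       metrics = metrics,
       battery = run_battery(metrics, composition, specimens, tree,
                             config, ...),
       per_species = per_species_ols(metrics, specimens, config),
       intercorrelations = intercorrelate(composition, specimens, tree,
                                          config$intercorrelation_pairs,
                                          config, ...))
}
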