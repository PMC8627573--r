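#' On-column fraction for a GC inlet split ratio
#'
#' The fraction of injected sample reaching the column at split ratio `s` is
#' taken as `1 / (1 + s)`: the calibration signal must vanish as the split
#' diverts everything to waste, which is why the standard curve is
#' regressed through the origin against this axis. The choice of axis is
#' isolated here so an alternative convention is a one-line change.
#'
#' @param split_ratio dimensionless split setting(s), > 0 (0 = splitless).
#' @return on-column fraction in (0, 1].
#' @export
on_column_fraction <- function(split_ratio) {
  if (any(split_ratio < 0)) stop("split ratio must be >= 0")
  1 / (1 + split_ratio)
}

#' Fit an external-standard calibration curve
#'
#' Ordinary least squares of integral against on-column fraction with the
#' intercept fixed at zero. The slope is the compound's mass ionization
#' coefficient (counts per unit split-normalized mass); dividing by the
#' molar mass gives the molar ionization coefficient used for relative
#' quantitation.
#'
#' @param points data frame with columns `split_ratio` and `integral`
#'   (one row per calibration injection; >= 2 distinct split settings).
#' @param molar_mass molar mass of the standard in g/mol (> 0).
#' @param compound compound identifier carried through to the result.
#' @return one-row data frame `compound`, `molar_mass`, `mass_coefficient`,
#'   `molar_coefficient`, `n_points`, `valid` (`FALSE` when the fitted
#'   slope is not strictly positive, e.g. an all-zero standard).
#' @examples
#' pts <- data.frame(split_ratio = c(9, 19, 49), integral = 1000 / (1 + c(9, 19, 49)))
#' fit_standard_curve(pts, molar_mass = 250, compound = "C16:0")
#' @export
fit_standard_curve <- function(points, molar_mass, compound = NA_character_) {
  if (!is.finite(molar_mass) || molar_mass <= 0)
    stop("molar mass must be > 0 (compound ", compound, ")")
  if (any(points$integral < 0)) stop("negative integrals in standard series")
  x <- on_column_fraction(points$split_ratio)
  if (length(unique(x)) < 2L)
    stop("need >= 2 distinct split settings to define a slope (compound ",
         compound, ")")
  slope <- sum(x * points$integral) / sum(x * x)
  data.frame(compound = compound, molar_mass = molar_mass,
             mass_coefficient = slope,
             molar_coefficient = slope / molar_mass,
             n_points = nrow(points), valid = slope > 0,
             stringsAsFactors = FALSE)
}

#' Fit calibration curves for a whole standards table
#'
#' @param standards data frame `compound`, `molar_mass_g_mol`,
#'   `split_ratio`, `integral` (schema written by [simulate_gcms()]).
#' @return data frame of ionization coefficients, one row per compound.
#' @export
fit_standard_curves <- function(standards) {
  out <- lapply(split(standards, standards$compound), function(d) {
    fit_standard_curve(d[, c("split_ratio", "integral")],
                       molar_mass = d$molar_mass_g_mol[1L],
                       compound = d$compound[1L])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.as_spectrum <- function(s) {
  if (is.data.frame(s)) {
    v <- s$rel_intensity
    names(v) <- s$mz
    s <- v
  }
  if (is.null(names(s)) || length(s) == 0L)
    stop("a mass spectrum must be a non-empty named vector or a data frame ",
         "with columns mz and rel_intensity")
  s / max(s)
}

#' Select the quantitation ion for a (possibly coeluting) compound
#'
#' With no coeluters the base peak is used. Against coeluters, the most
#' intense target ion is chosen among those at which the target is at least
#' tenfold more abundant than every coeluting spectrum (`rule = "tenfold"`),
#' or equivalently holds at least a `thres_ortho` share of the summed
#' intensity (`rule = "share"`, target >= 9x coeluter at the default 0.9).
#' Spectra are renormalized to base peak = 1 before comparison; ties are
#' broken toward the lower m/z.
#'
#' @param target spectrum of the compound to quantify: named numeric vector
#'   (names = m/z) or data frame with columns `mz`, `rel_intensity`.
#' @param coeluters list of spectra in the same formats (may be empty).
#' @param thres_ortho minimum target share of summed intensity under
#'   `rule = "share"`.
#' @param rule `"tenfold"` (default) or `"share"`.
#' @return the selected m/z as a number.
#' @examples
#' select_quant_ion(c(`74` = 1, `87` = 0.6, `143` = 0.2),
#'                  list(c(`74` = 0.9, `87` = 0.05)))
#' @export
select_quant_ion <- function(target, coeluters = list(), thres_ortho = 0.9,
                             rule = c("tenfold", "share")) {
  rule <- match.arg(rule)
  tg <- .as_spectrum(target)
  co <- lapply(coeluters, .as_spectrum)
  mz <- as.numeric(names(tg))
  ord <- order(-tg, mz)
  if (length(co) == 0L) return(mz[ord[1L]])
  ok <- function(m, ti) {
    all(vapply(co, function(cs) {
      ci <- if (as.character(m) %in% names(cs)) cs[[as.character(m)]] else 0
      if (rule == "tenfold") ti >= 10 * ci else ti / (ti + ci) >= thres_ortho
    }, TRUE))
  }
  for (i in ord) if (ok(mz[i], tg[[i]])) return(mz[i])
  stop("unresolvable coelution: no ion of the target spectrum is ",
       if (rule == "tenfold") "tenfold more abundant than in"
       else sprintf("above a %.2f share against", thres_ortho),
       " every coeluting spectrum")
}

#' Integrate a single-ion trace between retention-time bounds
#'
#' Trapezoidal area of the extracted-ion trace, with linear interpolation at
#' the bounds when they fall between scans. Empty bounds give zero.
#'
#' @param time,intensity numeric vectors of equal length describing the
#'   trace (time strictly increasing, intensity >= 0).
#' @param bounds numeric length-2, `bounds[1] <= bounds[2]`, within the
#'   trace's time range.
#' @return non-negative area (counts).
#' @export
integrate_peak <- function(time, intensity, bounds = range(time)) {
  if (length(time) != length(intensity) || length(time) < 2L)
    stop("trace needs matched time and intensity vectors of length >= 2")
  if (is.unsorted(time, strictly = TRUE)) stop("time must be strictly increasing")
  if (any(intensity < 0)) stop("intensities must be >= 0")
  if (length(bounds) != 2L || bounds[1L] > bounds[2L])
    stop("unordered integration bounds")
  if (bounds[1L] < time[1L] || bounds[2L] > time[length(time)])
    stop("integration bounds outside the trace")
  if (bounds[1L] == bounds[2L]) return(0)
  inside <- time > bounds[1L] & time < bounds[2L]
  tt <- c(bounds[1L], time[inside], bounds[2L])
  yy <- c(stats::approx(time, intensity, xout = bounds[1L])$y,
          intensity[inside],
          stats::approx(time, intensity, xout = bounds[2L])$y)
  sum(diff(tt) * (yy[-1L] + yy[-length(yy)]) / 2)
}

#' Compute mole fractions for one sample from integrated peaks
#'
#' Divides each single-ion integral by the compound's molar ionization
#' coefficient to obtain relative moles, then closes the composition:
#' `x_i = (A_i / k_i) / sum_j (A_j / k_j)`. Compounds without a valid
#' coefficient are excluded from the closure with a warning (only known,
#' calibrated compounds are quantified).
#'
#' @param peaks data frame with columns `compound` and `integral` for one
#'   sample.
#' @param coefficients data frame from [fit_standard_curves()].
#' @return named numeric vector of mole fractions summing to 1.
#' @export
compute_mole_fractions <- function(peaks, coefficients) {
  coefficients <- coefficients[coefficients$valid &
                                 coefficients$molar_coefficient > 0, ]
  k <- coefficients$molar_coefficient[match(peaks$compound,
                                            coefficients$compound)]
  if (anyNA(k)) {
    warning("excluding compound(s) without a valid ionization coefficient: ",
            paste(unique(peaks$compound[is.na(k)]), collapse = ", "))
    peaks <- peaks[!is.na(k), ]
    k <- k[!is.na(k)]
  }
  if (nrow(peaks) == 0L || all(peaks$integral <= 0))
    stop("no positive peak integrals with known coefficients; ",
         "mole fractions undefined")
  if (any(peaks$integral < 0)) stop("negative peak integral")
  moles <- peaks$integral / k
  x <- moles / sum(moles)
  names(x) <- peaks$compound
  x
}

#' Quantify every sample in a peak table
#'
#' @param peaks data frame `sample_id`, `compound`, `integral`.
#' @param coefficients data frame from [fit_standard_curves()].
#' @return long data frame `sample_id`, `compound`, `mole_fraction`.
#' @export
quantify_samples <- function(peaks, coefficients) {
  out <- lapply(split(peaks, peaks$sample_id), function(d) {
    x <- compute_mole_fractions(d, coefficients)
    data.frame(sample_id = d$sample_id[1L], compound = names(x),
               mole_fraction = unname(x), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Full relative-quantitation workflow for one GC-MS run
#'
#' Fits calibration curves from the standards table, selects a quantitation
#' ion for every compound (base peak, or the coelution-aware choice for
#' compounds sharing a retention window), checks that the peak table was
#' integrated on those ions, and converts integrals to mole fractions.
#'
#' @param standards standards table (see [fit_standard_curves()]).
#' @param peaks peak table `sample_id`, `compound`, `mz`, `integral`.
#' @param spectra reference spectra `compound`, `mz`, `rel_intensity`.
#' @param coelution list of character vectors naming compounds that coelute.
#' @param thres_ortho,rule passed to [select_quant_ion()].
#' @return list with `composition` (long data frame), `coefficients`,
#'   `quant_ions` (named vector).
#' @export
quantify_run <- function(standards, peaks, spectra, coelution = list(),
                         thres_ortho = 0.9, rule = "tenfold") {
  coefficients <- fit_standard_curves(standards)
  labels <- coefficients$compound
  quant_ions <- vapply(labels, function(lab) {
    grp <- Filter(function(g) lab %in% g, coelution)
    partners <- if (length(grp)) setdiff(grp[[1L]], lab) else character()
    select_quant_ion(spectra[spectra$compound == lab, ],
                     lapply(partners, function(p) spectra[spectra$compound == p, ]),
                     thres_ortho = thres_ortho, rule = rule)
  }, 1)
  if ("mz" %in% names(peaks)) {
    expected <- quant_ions[peaks$compound]
    bad <- !is.na(expected) & peaks$mz != expected
    if (any(bad)) {
      warning("dropping ", sum(bad), " peak row(s) not integrated on the ",
              "selected quantitation ion")
      peaks <- peaks[!bad, ]
    }
  }
  list(composition = quantify_samples(peaks, coefficients),
       coefficients = coefficients, quant_ions = quant_ions)
}

#' Test which compounds are detected at statistically significant levels
#'
#' Per compound: a single pass removes observations more than
#' `sigma_cut` standard deviations from the mean, where mean and SD are
#' computed with the observation under test left out (a lone spike inflates
#' the full-sample SD enough that it could never exceed ~sqrt(n) full-sample
#' SDs, so leave-one-out moments are what make a six-sigma rule attainable).
#' A one-tailed one-sample t-test of mean > 0 is then run on the survivors,
#' and p-values are Holm-adjusted across compounds. Compounds with fewer
#' than three surviving observations are excluded with a warning.
#'
#' @param composition long data frame `sample_id`, `compound`,
#'   `mole_fraction` (>= 3 profiles).
#' @param alpha familywise significance level.
#' @param sigma_cut outlier threshold in sample SDs.
#' @return data frame `compound`, `n_used`, `n_outliers_removed`, `t`, `p`,
#'   `p_holm`, `detected`, ordered as in the input.
#' @export
detect_significant_species <- function(composition, alpha = 0.05,
                                       sigma_cut = 6) {
  if (length(unique(composition$sample_id)) < 3L)
    stop("need >= 3 profiles for the detection test")
  labs <- unique(composition$compound)
  rows <- lapply(labs, function(lab) {
    v <- composition$mole_fraction[composition$compound == lab]
    keep <- vapply(seq_along(v), function(i) {
      rest <- v[-i]
      if (length(rest) < 2L) return(TRUE)
      s <- stats::sd(rest)
      dev <- abs(v[i] - mean(rest))
      if (s == 0) dev == 0 else dev <= sigma_cut * s
    }, TRUE)
    u <- v[keep]
    if (length(u) < 3L) {
      warning("compound ", lab, " excluded: fewer than 3 observations ",
              "survive outlier removal")
      return(data.frame(compound = lab, n_used = length(u),
                        n_outliers_removed = sum(!keep),
                        t = NA_real_, p = NA_real_, stringsAsFactors = FALSE))
    }
    if (stats::sd(u) == 0) {
      tt <- if (mean(u) > 0) Inf else 0
      pp <- if (mean(u) > 0) 0 else 1
    } else {
      ht <- stats::t.test(u, mu = 0, alternative = "greater")
      tt <- unname(ht$statistic); pp <- ht$p.value
    }
    data.frame(compound = lab, n_used = length(u),
               n_outliers_removed = sum(!keep), t = tt, p = pp,
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  rep$p_holm <- NA_real_
  ok <- !is.na(rep$p)
  rep$p_holm[ok] <- holm_adjust(rep$p[ok])
  rep$detected <- !is.na(rep$p_holm) & rep$p_holm < alpha
  rep
}
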