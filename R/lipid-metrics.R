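.profile_vec <- function(profile) {
  if (is.data.frame(profile)) {
    v <- profile$mole_fraction
    names(v) <- profile$compound
    profile <- v
  }
  if (is.null(names(profile)) || length(profile) == 0L)
    stop("a composition profile must be a named vector or a data frame ",
         "with columns compound and mole_fraction")
  if (any(profile < 0)) stop("negative mole fractions in profile")
  profile
}

.basis_subset <- function(profile, basis = c("even_fa", "all_fa")) {
  basis <- match.arg(basis)
  sp <- parse_lipid(names(profile))
  keep <- sp$backbone == "fatty-acid"
  if (basis == "even_fa") keep <- keep & !sp$odd_chain
  if (!any(keep) || sum(profile[keep]) <= 0)
    stop("basis '", basis, "' selects an empty (or zero-weight) subset")
  list(x = profile[keep] / sum(profile[keep]), species = sp[keep, ])
}

#' Double bond index of a composition profile
#'
#' Mole-fraction-weighted mean number of double bonds per acyl chain, a
#' standard proxy for membrane unsaturation. By default the basis is the
#' even-chain fatty acid pool (odd-chain acids and fatty alcohols excluded)
#' with the subset renormalized to sum to 1, so the index is a true weighted
#' mean over that pool; `basis = "all_fa"` widens it to all fatty acids.
#'
#' @param profile named mole-fraction vector (names = lipid labels), or a
#'   data frame with columns `compound` and `mole_fraction`.
#' @param basis `"even_fa"` (default) or `"all_fa"`.
#' @return the double bond index (dimensionless, >= 0).
#' @examples
#' double_bond_index(c("C16:0" = 0.5, "C22:6" = 0.5)) # 3
#' @export
double_bond_index <- function(profile, basis = "even_fa") {
  b <- .basis_subset(.profile_vec(profile), basis)
  sum(b$x * b$species$double_bonds)
}

#' Mean acyl chain length of a composition profile
#'
#' Mole-fraction-weighted mean carbon count per chain over the same
#' (renormalized) basis as [double_bond_index()].
#'
#' @inheritParams double_bond_index
#' @return mean carbons per chain.
#' @examples
#' mean_chain_length(c("C14:0" = 0.5, "C18:0" = 0.5)) # 16
#' @export
mean_chain_length <- function(profile, basis = "even_fa") {
  b <- .basis_subset(.profile_vec(profile), basis)
  sum(b$x * b$species$carbons)
}

#' Saturation-class totals of the fatty-acid pool
#'
#' Sums of mole fractions of fatty acids with 0 (SFA), 1 (MUFA) and >= 2
#' (PUFA) double bonds; fatty alcohols are excluded, so the three classes
#' total the fatty-acid fraction of the profile, not necessarily 1.
#'
#' @inheritParams double_bond_index
#' @return named numeric vector `c(sfa, mufa, pufa)`.
#' @export
class_fractions <- function(profile) {
  x <- .profile_vec(profile)
  sp <- parse_lipid(names(x))
  fa <- sp$backbone == "fatty-acid"
  c(sfa  = sum(x[fa & sp$class == "SFA"]),
    mufa = sum(x[fa & sp$class == "MUFA"]),
    pufa = sum(x[fa & sp$class == "PUFA"]))
}

#' Odd-chain fatty acid and fatty-alcohol totals
#'
#' @inheritParams double_bond_index
#' @return named numeric vector `c(ocfa, alcohol)`: total mole fraction of
#'   odd-carbon fatty acids and of fatty-alcohol species.
#' @export
group_totals <- function(profile) {
  x <- .profile_vec(profile)
  sp <- parse_lipid(names(x))
  c(ocfa    = sum(x[sp$backbone == "fatty-acid" & sp$odd_chain]),
    alcohol = sum(x[sp$backbone == "fatty-alcohol"]))
}

#' Per-specimen lipidome summary metrics
#'
#' Computes, for every sample in a long composition table, the regression
#' response variables of the comparative analysis: double bond index, mean
#' chain length (both on the chosen basis), saturation-class totals, OCFA
#' total and fatty-alcohol total.
#'
#' @param composition long data frame `sample_id`, `compound`,
#'   `mole_fraction`.
#' @param basis basis for DBI and chain length (see [double_bond_index()]).
#' @return data frame with one row per sample: `sample_id`, `dbi`,
#'   `chain_length`, `sfa`, `mufa`, `pufa`, `ocfa`, `alcohol`.
#' @export
compute_metrics <- function(composition, basis = "even_fa") {
  out <- lapply(split(composition, composition$sample_id), function(d) {
    x <- .profile_vec(d)
    cf <- class_fractions(x)
    gt <- group_totals(x)
    data.frame(sample_id = d$sample_id[1L],
               dbi = double_bond_index(x, basis),
               chain_length = mean_chain_length(x, basis),
               sfa = cf[["sfa"]], mufa = cf[["mufa"]], pufa = cf[["pufa"]],
               ocfa = gt[["ocfa"]], alcohol = gt[["alcohol"]],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
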