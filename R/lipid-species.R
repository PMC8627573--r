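#' Parse lipid species labels
#'
#' Parses canonical fatty-acid / fatty-alcohol labels of the forms
#' `"C18:1"`, `"C18:1(n-9)"` and `"C22:1(n-9) alcohol"` into their
#' structural components: carbon count, number of double bonds, backbone
#' class, and (when given) the omega position of the first double bond.
#'
#' A label describes an acyl (or alkyl) chain: `C<carbons>:<double bonds>`,
#' optionally followed by an `(n-x)` omega designation and the word
#' `alcohol` for fatty alcohols released from wax esters. Saturation class
#' and odd/even chain parity are derived, never stored.
#'
#' @param labels character vector of species labels.
#' @return A data frame with one row per label and columns `label`,
#'   `carbons`, `double_bonds`, `omega` (NA when unspecified), `backbone`
#'   (`"fatty-acid"` or `"fatty-alcohol"`), `class` (`"SFA"`, `"MUFA"`,
#'   `"PUFA"` for fatty acids, `"alcohol"` otherwise), and logical
#'   `odd_chain`.
#' @examples
#' parse_lipid(c("C16:0", "C22:6", "C22:1(n-9) alcohol"))
#' @export
parse_lipid <- function(labels) {
  if (!is.character(labels) || length(labels) == 0L)
    stop("'labels' must be a non-empty character vector")
  rx <- "^C([0-9]+):([0-9]+)(\\((?:n|ω)-([0-9]+)\\))?( alcohol)?$"
  m <- regmatches(labels, regexec(rx, labels))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad))
    stop("unparseable lipid label(s): ", paste(labels[bad], collapse = ", "))
  carbons <- vapply(m, function(g) as.integer(g[2L]), 1L)
  db      <- vapply(m, function(g) as.integer(g[3L]), 1L)
  omega   <- vapply(m, function(g) if (nzchar(g[5L])) as.integer(g[5L]) else NA_integer_, 1L)
  alcohol <- vapply(m, function(g) nzchar(g[6L]), TRUE)
  if (any(carbons < 4L))
    stop("carbon count below 4 is not a valid acyl chain: ",
         paste(labels[carbons < 4L], collapse = ", "))
  # a methylene-interrupted chain cannot hold more double bonds than this
  too_many <- db > (carbons - 2L) %/% 2L
  if (any(too_many))
    stop("double bond count exceeds floor((carbons - 2)/2) for: ",
         paste(labels[too_many], collapse = ", "))
  cls <- ifelse(alcohol, "alcohol",
                ifelse(db == 0L, "SFA", ifelse(db == 1L, "MUFA", "PUFA")))
  data.frame(
    label        = labels,
    carbons      = carbons,
    double_bonds = db,
    omega        = omega,
    backbone     = ifelse(alcohol, "fatty-alcohol", "fatty-acid"),
    class        = cls,
    odd_chain    = carbons %% 2L == 1L,
    stringsAsFactors = FALSE
  )
}

#' Molar mass of a lipid species as analyzed by GC-MS
#'
#' Fatty acids are quantified as their methyl esters (FAMEs), so the mass
#' returned for a fatty acid CN:d is that of the methyl ester
#' C(N+1)H(2N+2-2d)O2; fatty alcohols run underivatized as CNH(2N+2-2d)O.
#'
#' @param labels character vector of species labels (see [parse_lipid()]).
#' @return numeric vector of molar masses in g/mol.
#' @examples
#' lipid_molar_mass("C16:0") # methyl palmitate, 270.45 g/mol
#' @export
lipid_molar_mass <- function(labels) {
  sp <- parse_lipid(labels)
  mC <- 12.011; mH <- 1.008; mO <- 15.999
  h <- 2L * sp$carbons + 2L - 2L * sp$double_bonds
  ifelse(sp$backbone == "fatty-alcohol",
         mC * sp$carbons + mH * h + mO,
         mC * (sp$carbons + 1L) + mH * h + 2 * mO)
}
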