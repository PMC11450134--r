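# Canonical monoisotopic mass shifts (Da) used throughout.
MASS_ACETYL  <- 42.010565
MASS_PYROGLU <- -17.026549

# 20-letter amino-acid alphabet plus X (unknown residue).
AA20        <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_ALPHABET <- c(AA20, "X")

PROTEASES <- c("trypsin", "gluC", "chymotrypsin")

#' Isotopic labeling chemistry descriptor
#'
#' TAILS-style N-terminomics blocks free alpha- and epsilon-amines in vitro by
#' reductive dimethylation with isotopic formaldehyde. An in-vivo free
#' N-terminus acquires two label methyls (the dimethyl shift); an in-vivo
#' monomethylated N-terminus can only acquire one, producing the diagnostic
#' "hybrid" shift. Two formaldehyde isotopologues are supported:
#'
#' * `CD2_13C` (13C,D2 formaldehyde): dimethyl +34.063117 Da,
#'   hybrid methylation +31.047208 Da.
#' * `D2` (D2 formaldehyde): dimethyl +32.056407 Da,
#'   hybrid methylation +30.043854 Da.
#'
#' @param name Chemistry name, `"CD2_13C"` or `"D2"`.
#' @return A `label_chemistry` object: list with `name`, `dimethyl_shift`
#'   and `hybrid_methyl_shift` (Da).
#' @examples
#' label_chemistry("CD2_13C")$dimethyl_shift
#' @export
label_chemistry <- function(name = c("CD2_13C", "D2")) {
  name <- match.arg(name)
  shifts <- switch(name,
    CD2_13C = c(dimethyl = 34.063117, hybrid = 31.047208),
    D2      = c(dimethyl = 32.056407, hybrid = 30.043854)
  )
  structure(
    list(
      name = name,
      dimethyl_shift = unname(shifts["dimethyl"]),
      hybrid_methyl_shift = unname(shifts["hybrid"])
    ),
    class = "label_chemistry"
  )
}

#' @export
print.label_chemistry <- function(x, ...) {
  cat(sprintf("labeling chemistry %s: dimethyl %+0.6f Da, hybrid methyl %+0.6f Da\n",
              x$name, x$dimethyl_shift, x$hybrid_methyl_shift))
  invisible(x)
}

as_label_chemistry <- function(x) {
  if (inherits(x, "label_chemistry")) return(x)
  if (is.character(x) && length(x) == 1L) return(label_chemistry(x))
  stop("cannot interpret as a labeling chemistry: ", deparse(substitute(x)))
}

#' Protease P1 specificity set
#'
#' Residues accepted on the P1 (preceding) side of a cleavage by each
#' supported protease: trypsin K/R, GluC E/D, chymotrypsin F/Y/W/L/M.
#' Used by the pyroglutamate protease-specificity filter: an N-terminal
#' pyroGlu whose preceding residue matches the protease specificity may be a
#' sample-processing artifact and is not accepted as an in-vivo state.
#'
#' @param protease One of `"trypsin"`, `"gluC"`, `"chymotrypsin"`.
#' @return Character vector of single-letter residues.
#' @export
protease_specificity <- function(protease) {
  sets <- list(
    trypsin      = c("K", "R"),
    gluC         = c("E", "D"),
    chymotrypsin = c("F", "Y", "W", "L", "M")
  )
  if (length(protease) != 1L || !protease %in% names(sets)) {
    stop("unsupported protease: ", paste(protease, collapse = ", "),
         " (supported: ", paste(names(sets), collapse = ", "), ")")
  }
  sets[[protease]]
}
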