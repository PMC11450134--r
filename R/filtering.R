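# Acceptance thresholds and decoy-based FDR.

#' Identification acceptance thresholds
#'
#' Defaults follow the standard Scaffold-style acceptance policy for
#' N-terminomics searches: ProteinProphet probability >= 0.99 with at least
#' one identified peptide, PeptideProphet probability >= 0.95, Mascot ion
#' score >= 40. All bounds are inclusive ("at least").
#'
#' @param min_protein_prob Minimum protein probability (default 0.99).
#' @param min_peptide_prob Minimum peptide probability (default 0.95).
#' @param min_ion_score Minimum ion score (default 40).
#' @param min_peptides_per_protein Minimum distinct peptides per protein
#'   (default 1).
#' @return A `filter_thresholds` list.
#' @export
filter_thresholds <- function(min_protein_prob = 0.99,
                              min_peptide_prob = 0.95,
                              min_ion_score = 40,
                              min_peptides_per_protein = 1L) {
  stopifnot(
    min_protein_prob >= 0, min_protein_prob <= 1,
    min_peptide_prob >= 0, min_peptide_prob <= 1,
    min_ion_score >= 0, min_peptides_per_protein >= 0
  )
  structure(
    list(min_protein_prob = min_protein_prob,
         min_peptide_prob = min_peptide_prob,
         min_ion_score = min_ion_score,
         min_peptides_per_protein = as.integer(min_peptides_per_protein)),
    class = "filter_thresholds"
  )
}

split_accessions <- function(x) strsplit(x, ";", fixed = TRUE)

#' Filter peptide-spectrum matches by acceptance thresholds
#'
#' Retains exactly the rows with `peptide_prob >= min_peptide_prob`,
#' `protein_prob >= min_protein_prob` and `ion_score >= min_ion_score`
#' (inclusive bounds), removes rows mapping only to contaminant accessions,
#' and, when `min_peptides_per_protein > 1`, drops rows none of whose
#' accessions reach that peptide count. Input order is preserved; filtering
#' is idempotent.
#'
#' @param psms PSM data frame (see [read_psm_table()]).
#' @param thresholds A [filter_thresholds()] object.
#' @param contaminant_accessions Accessions of contaminant entries.
#' @return The accepted subset of `psms`.
#' @export
filter_psms <- function(psms, thresholds = filter_thresholds(),
                        contaminant_accessions = character()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  if (!nrow(psms)) return(psms)
  accs <- split_accessions(psms$accessions)
  only_contaminant <- vapply(
    accs, function(a) all(a %in% contaminant_accessions), logical(1)
  )
  keep <- psms$peptide_prob >= thresholds$min_peptide_prob &
    psms$protein_prob >= thresholds$min_protein_prob &
    psms$ion_score >= thresholds$min_ion_score &
    !only_contaminant
  out <- psms[keep, , drop = FALSE]
  if (thresholds$min_peptides_per_protein > 1L && nrow(out)) {
    acc_long <- split_accessions(out$accessions)
    pep_by_acc <- tapply(
      rep(out$peptide, lengths(acc_long)), unlist(acc_long),
      function(p) length(unique(p))
    )
    ok <- vapply(acc_long, function(a) {
      any(pep_by_acc[a] >= thresholds$min_peptides_per_protein)
    }, logical(1))
    out <- out[ok, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

psm_is_decoy <- function(psms, decoy_prefix = "REV_") {
  vapply(split_accessions(psms$accessions),
         function(a) all(startsWith(a, decoy_prefix)), logical(1))
}

#' Decoy-based false discovery rate
#'
#' Counts distinct identifications among accepted rows and estimates the FDR
#' as the simple ratio decoys/targets (Scaffold's reporting convention). A
#' row is a decoy identification iff all of its accessions are decoys. At
#' peptide level, identifications are keyed by peptide sequence plus
#' N-terminal mass shift; at protein level, by the protein group (the sorted
#' accession set), a group being decoy iff every member is.
#'
#' @param accepted Accepted PSM data frame (after [filter_psms()]).
#' @param level `"peptide"` or `"protein"`.
#' @param decoy_prefix Decoy accession prefix.
#' @return An `fdr_report` list: `level`, `n_target`, `n_decoy`, `fdr`,
#'   `degenerate` (TRUE when decoys were seen with zero targets, in which
#'   case `fdr` is reported as 0).
#' @export
compute_decoy_fdr <- function(accepted, level = c("peptide", "protein"),
                              decoy_prefix = "REV_") {
  level <- match.arg(level)
  if (!nrow(accepted)) {
    return(structure(list(level = level, n_target = 0L, n_decoy = 0L,
                          fdr = 0, degenerate = FALSE), class = "fdr_report"))
  }
  decoy <- psm_is_decoy(accepted, decoy_prefix)
  key <- if (level == "peptide") {
    paste(accepted$peptide,
          ifelse(is.na(accepted$nterm_delta), "",
                 sprintf("%.6f", accepted$nterm_delta)),
          sep = "|")
  } else {
    vapply(split_accessions(accepted$accessions),
           function(a) paste(sort(unique(a)), collapse = ";"), character(1))
  }
  n_target <- length(unique(key[!decoy]))
  n_decoy <- length(unique(key[decoy]))
  degenerate <- n_target == 0L && n_decoy > 0L
  fdr <- if (n_target > 0L) n_decoy / n_target else 0
  structure(list(level = level, n_target = n_target, n_decoy = n_decoy,
                 fdr = fdr, degenerate = degenerate), class = "fdr_report")
}

#' @export
print.fdr_report <- function(x, ...) {
  cat(sprintf("%s-level decoy FDR: %d decoys / %d targets = %.4g%%%s\n",
              x$level, x$n_decoy, x$n_target, 100 * x$fdr,
              if (x$degenerate) " (degenerate: no targets)" else ""))
  invisible(x)
}
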