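# Position-frequency matrices of the sequence context around identified
# N-termini (logo inputs).

#' Extract the aligned sequence window around an N-terminus
#'
#' Sequences are aligned at the identified N-terminal residue: the window is
#' the preceding (P1) residue - `"-"` at the protein start - followed by
#' `width` mature residues from the start index, right-padded with `"-"`
#' beyond the protein end.
#'
#' @param protein Protein sequence.
#' @param start_index 1-based start index of the observed N-terminus.
#' @param width Number of mature residues (default 10).
#' @return String of length `width + 1` (P1 first).
#' @export
extract_context <- function(protein, start_index, width = 10L) {
  n <- nchar(protein)
  stopifnot(start_index >= 1L, start_index <= n, width >= 1L)
  p1 <- if (start_index == 1L) "-" else substr(protein, start_index - 1L,
                                               start_index - 1L)
  win <- substr(protein, start_index, min(n, start_index + width - 1L))
  if (nchar(win) < width) {
    win <- paste0(win, strrep("-", width - nchar(win)))
  }
  paste0(p1, win)
}

#' Build a position-frequency matrix of N-terminal sequence contexts
#'
#' Extracts the aligned window for each selected observation, optionally
#' restricts to modification states and/or offset (`dif`) values, removes
#' redundant window strings when `dedupe = TRUE` (non-redundant sequences,
#' the convention for logo inputs), and tallies residues per position. Gap
#' characters (`"-"`, protein start/end) are excluded from column sums;
#' residues outside the 20-letter alphabet count as `X`.
#'
#' @param observations Observation table from [enumerate_observations()].
#' @param proteome Proteome data frame from [read_proteome()].
#' @param state_filter Optional character vector of states to keep.
#' @param dif_filter Optional integer vector of dif values to keep; requires
#'   `offsets`.
#' @param width Number of mature residues in the window (default 10).
#' @param dedupe Remove identical window strings before counting (default
#'   `TRUE`).
#' @param offsets Offset records from [offset_records()], needed for
#'   `dif_filter`.
#' @return A `pfm` object: list with `counts` (residues x positions integer
#'   matrix, positions `P1, +1..+width`), `n` (number of retained windows),
#'   `windows` (the retained window strings).
#' @export
build_pfm <- function(observations, proteome, state_filter = NULL,
                      dif_filter = NULL, width = 10L, dedupe = TRUE,
                      offsets = NULL) {
  sel <- observations
  if (!is.null(state_filter) && nrow(sel)) {
    sel <- sel[sel$state %in% state_filter, , drop = FALSE]
  }
  if (!is.null(dif_filter)) {
    if (is.null(offsets)) {
      stop("dif_filter requires offset records (offsets =)")
    }
    keep_keys <- paste(offsets$accession[offsets$dif %in% dif_filter],
                       offsets$start_index[offsets$dif %in% dif_filter],
                       offsets$state[offsets$dif %in% dif_filter], sep = "\r")
    if (nrow(sel)) {
      sel_keys <- paste(sel$accession, sel$start_index, sel$state, sep = "\r")
      sel <- sel[sel_keys %in% keep_keys, , drop = FALSE]
    }
  }
  positions <- c("P1", paste0("+", seq_len(width)))
  counts <- matrix(0L, nrow = length(AA_ALPHABET), ncol = width + 1L,
                   dimnames = list(AA_ALPHABET, positions))
  if (!nrow(sel)) {
    return(structure(list(counts = counts, n = 0L, windows = character()),
                     class = "pfm"))
  }
  seqs <- stats::setNames(proteome$sequence, proteome$accession)
  windows <- mapply(function(acc, s) extract_context(seqs[[acc]], s, width),
                    sel$accession, sel$start_index, USE.NAMES = FALSE)
  if (dedupe) windows <- unique(windows)
  chars <- matrix(unlist(strsplit(windows, "")), nrow = length(windows),
                  byrow = TRUE)
  for (j in seq_len(ncol(chars))) {
    col <- chars[, j]
    col <- col[col != "-"]
    col[!col %in% AA_ALPHABET] <- "X"
    tab <- table(factor(col, levels = AA_ALPHABET))
    counts[, j] <- as.integer(tab)
  }
  structure(list(counts = counts, n = length(windows), windows = windows),
            class = "pfm")
}

#' Per-column residue frequencies of a PFM
#'
#' @param pfm A `pfm` object from [build_pfm()].
#' @return Numeric matrix of column-normalized frequencies (zero columns
#'   stay zero).
#' @export
pfm_frequencies <- function(pfm) {
  cs <- colSums(pfm$counts)
  cs[cs == 0] <- 1
  sweep(pfm$counts, 2, cs, "/")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("position-frequency matrix: %d sequences, positions %s\n",
              x$n, paste(colnames(x$counts), collapse = " ")))
  modal <- rownames(x$counts)[apply(x$counts, 2, which.max)]
  if (x$n > 0) cat("modal residues:", paste(modal, collapse = " "), "\n")
  invisible(x)
}

#' Write a PFM as a plain matrix TSV
#'
#' Rows are residues, columns positions; consumable by standard logo tools.
#'
#' @param pfm A `pfm` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(pfm, path) {
  df <- data.frame(residue = rownames(pfm$counts), pfm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
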