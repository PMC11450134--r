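# External file dialects: FASTA proteome, PSM TSV, TargetP2-style short text.

PSM_COLUMNS <- c("dataset_id", "peptide", "nterm_delta", "residue_deltas",
                 "accessions", "peptide_prob", "protein_prob", "ion_score",
                 "protease", "preceding_aa")

SIGNAL_CLASSES <- c("noTP", "SP", "mTP", "cTP", "luTP")

#' Read a proteome FASTA with decoy and contaminant flagging
#'
#' Accessions are the first whitespace-delimited token of each FASTA header;
#' the remainder is kept as the description. Decoy entries (reversed
#' sequences appended to the search database) are recognized by an accession
#' prefix; contaminants by membership in a supplied accession list.
#'
#' @param path FASTA file.
#' @param decoy_prefix Accession prefix marking decoy entries (default
#'   `"REV_"`).
#' @param contaminant_accessions Character vector of contaminant accessions.
#' @return `data.frame` with columns `accession`, `sequence`, `is_decoy`,
#'   `is_contaminant`, `description`, in file order.
#' @export
read_proteome <- function(path, decoy_prefix = "REV_",
                          contaminant_accessions = character()) {
  if (!is.character(decoy_prefix) || length(decoy_prefix) != 1L ||
      !nzchar(decoy_prefix)) {
    stop("decoy_prefix must be a non-empty string")
  }
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("empty proteome FASTA: ", path)
  hdr <- names(seqs)
  accession <- sub("\\s.*$", "", hdr)
  description <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  dup <- unique(accession[duplicated(accession)])
  if (length(dup)) {
    stop("duplicate accession(s) in proteome: ", paste(dup, collapse = ", "))
  }
  sq <- toupper(as.character(seqs))
  if (any(!nzchar(sq))) {
    stop("empty sequence for accession(s): ",
         paste(accession[!nzchar(sq)], collapse = ", "))
  }
  data.frame(
    accession = accession,
    sequence = sq,
    is_decoy = startsWith(accession, decoy_prefix),
    is_contaminant = accession %in% contaminant_accessions,
    description = description,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Write a proteome as FASTA
#'
#' @param proteins Data frame as returned by [read_proteome()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_proteome <- function(proteins, path) {
  x <- Biostrings::AAStringSet(proteins$sequence)
  names(x) <- ifelse(nzchar(proteins$description),
                     paste(proteins$accession, proteins$description),
                     proteins$accession)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

.parse_num <- function(x, col, allow_na = FALSE) {
  x <- trimws(x)
  x[!nzchar(x)] <- NA_character_
  v <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(v))
  if (length(bad)) {
    stop(sprintf("malformed %s in PSM table row %d: '%s'", col, bad[1], x[bad[1]]))
  }
  if (!allow_na && anyNA(v)) {
    stop(sprintf("missing %s in PSM table row %d", col, which(is.na(v))[1]))
  }
  v
}

#' Read a peptide identification (PSM) table
#'
#' Tab-separated, UTF-8, `#`-comment lines permitted before the header.
#' Header must be exactly: `dataset_id, peptide, nterm_delta, residue_deltas,
#' accessions, peptide_prob, protein_prob, ion_score, protease,
#' preceding_aa`. `residue_deltas` is a semicolon-joined list of
#' `pos:delta` pairs (1-based position within the peptide); `accessions` is
#' semicolon-joined. An empty `nterm_delta` field means the N-terminal mass
#' shift is absent.
#'
#' @param path TSV file.
#' @return `data.frame` with the dialect columns; `nterm_delta`,
#'   `peptide_prob`, `protein_prob`, `ion_score` numeric (`nterm_delta`
#'   `NA` when absent).
#' @export
read_psm_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty PSM table: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, PSM_COLUMNS)) {
    stop("PSM table header mismatch in ", path, "\n  expected: ",
         paste(PSM_COLUMNS, collapse = ", "), "\n  found:    ",
         paste(header, collapse = ", "))
  }
  if (length(lines) == 1L) {
    return(empty_psm_table())
  }
  cells <- strsplit(lines[-1], "\t", fixed = TRUE)
  ncol_bad <- which(lengths(cells) != length(PSM_COLUMNS))
  if (length(ncol_bad)) {
    stop(sprintf("PSM table row %d has %d fields (expected %d)",
                 ncol_bad[1], lengths(cells)[ncol_bad[1]], length(PSM_COLUMNS)))
  }
  m <- do.call(rbind, cells)
  colnames(m) <- PSM_COLUMNS
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  df$nterm_delta  <- .parse_num(df$nterm_delta, "nterm_delta", allow_na = TRUE)
  df$peptide_prob <- .parse_num(df$peptide_prob, "peptide_prob")
  df$protein_prob <- .parse_num(df$protein_prob, "protein_prob")
  df$ion_score    <- .parse_num(df$ion_score, "ion_score")
  bad_pep <- which(!grepl("^[A-Z]+$", df$peptide))
  if (length(bad_pep)) {
    stop(sprintf("malformed peptide in PSM table row %d: '%s'",
                 bad_pep[1], df$peptide[bad_pep[1]]))
  }
  bad_prot <- which(!df$protease %in% PROTEASES)
  if (length(bad_prot)) {
    stop(sprintf("unknown protease token in PSM table row %d: '%s'",
                 bad_prot[1], df$protease[bad_prot[1]]))
  }
  bad_prob <- which(df$peptide_prob < 0 | df$peptide_prob > 1 |
                    df$protein_prob < 0 | df$protein_prob > 1)
  if (length(bad_prob)) {
    stop(sprintf("probability outside [0,1] in PSM table row %d", bad_prob[1]))
  }
  for (i in seq_len(nrow(df))) {
    rd <- df$residue_deltas[i]
    if (!nzchar(rd)) next
    parts <- strsplit(rd, ";", fixed = TRUE)[[1]]
    ok <- grepl("^[0-9]+:[+-]?[0-9]+(\\.[0-9]+)?$", parts)
    if (!all(ok)) {
      stop(sprintf("malformed residue_deltas in PSM table row %d: '%s'", i, rd))
    }
    pos <- as.integer(sub(":.*$", "", parts))
    if (any(pos < 1L | pos > nchar(df$peptide[i]))) {
      stop(sprintf("residue_deltas position out of peptide range in PSM table row %d", i))
    }
  }
  rownames(df) <- NULL
  df
}

empty_psm_table <- function() {
  df <- data.frame(
    dataset_id = character(), peptide = character(),
    nterm_delta = numeric(), residue_deltas = character(),
    accessions = character(), peptide_prob = numeric(),
    protein_prob = numeric(), ion_score = numeric(),
    protease = character(), preceding_aa = character(),
    stringsAsFactors = FALSE
  )
  df
}

#' Write a PSM table in the package's TSV dialect
#'
#' Mass deltas are written with six decimals; scores and probabilities with
#' full precision. A `# seed:` comment line is prepended when `seed` is
#' given, so simulated tables record their provenance.
#'
#' @param psms PSM data frame (see [read_psm_table()]).
#' @param path Output TSV.
#' @param seed Optional integer recorded as a header comment.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path, seed = NULL) {
  fmt_delta <- function(x) ifelse(is.na(x), "", sprintf("%.6f", x))
  fmt_num <- function(x) sprintf("%.10g", x)
  body <- paste(
    psms$dataset_id, psms$peptide, fmt_delta(psms$nterm_delta),
    psms$residue_deltas, psms$accessions, fmt_num(psms$peptide_prob),
    fmt_num(psms$protein_prob), fmt_num(psms$ion_score),
    psms$protease, psms$preceding_aa,
    sep = "\t"
  )
  lines <- c(
    if (!is.null(seed)) sprintf("# seed: %d", as.integer(seed)),
    paste(PSM_COLUMNS, collapse = "\t"),
    if (nrow(psms)) body
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Parse the residue_deltas field of PSM rows
#'
#' @param x Character vector of semicolon-joined `pos:delta` strings.
#' @return List of data frames with columns `pos` (1-based within peptide)
#'   and `delta` (Da); zero-row frames for empty fields.
#' @export
parse_residue_deltas <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) {
      return(data.frame(pos = integer(), delta = numeric()))
    }
    parts <- strsplit(s, ";", fixed = TRUE)[[1]]
    data.frame(
      pos = as.integer(sub(":.*$", "", parts)),
      delta = as.numeric(sub("^[0-9]+:", "", parts))
    )
  })
}

#' Read TargetP2.0 short-format targeting predictions
#'
#' Lines beginning with `#` are comments. Data lines carry an ID, the
#' predicted class (`noTP`, `SP`, `mTP`, `cTP`, `luTP`), five per-class
#' probabilities (in that order), and, for targeted proteins, a cleavage-site
#' annotation of the form `CS pos: 64-65`. The reported cleavage-site pair is
#' P1-P1', so the first residue of the mature protein (`p1_prime`) is the
#' second integer of the pair.
#'
#' @param path Prediction text file.
#' @param plant_mode Logical; plant-mode output carries the cTP/luTP classes.
#'   Kept for interface clarity, parsing is identical.
#' @return `data.frame` with columns `accession`, `signal_class`,
#'   `p1_prime` (`NA` for `noTP`), `class_probability`.
#' @export
read_targetp_short <- function(path, plant_mode = TRUE) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) stop("no prediction lines in ", path)
  n <- length(lines)
  accession <- character(n); signal_class <- character(n)
  p1_prime <- rep(NA_integer_, n); class_probability <- numeric(n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(tok) < 7L || !tok[2] %in% SIGNAL_CLASSES) {
      stop(sprintf("unparseable prediction line %d in %s", lineno[i], path))
    }
    probs <- suppressWarnings(as.numeric(tok[3:7]))
    if (anyNA(probs)) {
      stop(sprintf("unparseable prediction line %d in %s", lineno[i], path))
    }
    accession[i] <- tok[1]
    signal_class[i] <- tok[2]
    class_probability[i] <- probs[match(tok[2], SIGNAL_CLASSES)]
    if (tok[2] != "noTP") {
      rest <- paste(tok[-(1:7)], collapse = " ")
      m <- regmatches(rest, regexec("CS pos:[ ]*([0-9]+)-([0-9]+)", rest))[[1]]
      if (length(m) != 3L) {
        stop(sprintf("missing CS pos annotation on prediction line %d in %s",
                     lineno[i], path))
      }
      a <- as.integer(m[2]); b <- as.integer(m[3])
      if (b != a + 1L) {
        stop(sprintf("inconsistent CS pos pair %d-%d on prediction line %d in %s",
                     a, b, lineno[i], path))
      }
      p1_prime[i] <- b
    }
  }
  data.frame(accession = accession, signal_class = signal_class,
             p1_prime = p1_prime, class_probability = class_probability,
             stringsAsFactors = FALSE)
}

#' Write targeting predictions in TargetP2.0 short format
#'
#' The predicted class receives `class_probability`; the remainder is spread
#' uniformly over the other classes so rows sum to 1.
#'
#' @param predictions Data frame as returned by [read_targetp_short()].
#' @param path Output file.
#' @param seed Optional integer recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_targetp_short <- function(predictions, path, seed = NULL) {
  n <- nrow(predictions)
  rows <- character(n)
  for (i in seq_len(n)) {
    cls <- predictions$signal_class[i]
    p <- predictions$class_probability[i]
    probs <- rep((1 - p) / 4, 5)
    probs[match(cls, SIGNAL_CLASSES)] <- p
    cs <- if (cls == "noTP" || is.na(predictions$p1_prime[i])) "" else {
      sprintf("CS pos: %d-%d. Pr: %.4f",
              predictions$p1_prime[i] - 1L, predictions$p1_prime[i], p)
    }
    rows[i] <- paste(c(predictions$accession[i], cls,
                       sprintf("%.6f", probs), cs), collapse = "\t")
  }
  lines <- c(
    "# TargetP-2.0 short format (emulated output)",
    if (!is.null(seed)) sprintf("# seed: %d", as.integer(seed)),
    paste("# ID", "Prediction", "noTP", "SP", "mTP", "cTP", "luTP",
          "CS Position", sep = "\t"),
    rows
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a report table as TSV
#'
#' Plain tab-separated output used for every stage report (observation
#' tables, offset records, concordance and breakdown tables).
#'
#' @param x Data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
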