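# Proteoform start-index mapping and N-terminal modification-state
# classification from labeling-chemistry mass shifts.

MOD_STATES <- c("free", "acetyl", "monomethyl", "pyroGlu", "other")

#' Map a peptide to its proteoform start index
#'
#' Returns the 1-based position of the unique occurrence of `peptide` in
#' `protein` (overlapping occurrences count). Start index 1 is the initiator
#' methionine. Isoleucine and leucine are distinct: search engines emit
#' database-resolved sequences.
#'
#' @param protein Protein sequence (string).
#' @param peptide Peptide sequence (string).
#' @return Integer start index.
#' @export
map_peptide_start <- function(protein, peptide) {
  if (!nzchar(protein) || !nzchar(peptide)) {
    stop("protein and peptide must be non-empty")
  }
  hits <- gregexpr(paste0("(?=", peptide, ")"), protein, perl = TRUE)[[1]]
  if (hits[1] == -1L) {
    stop("unmapped: peptide '", peptide, "' not found in protein")
  }
  if (length(hits) > 1L) {
    stop("ambiguous: peptide '", peptide, "' occurs ", length(hits),
         " times in protein")
  }
  as.integer(hits[1])
}

.check_mass_windows <- function(chemistry, tol) {
  masses <- c(acetyl = MASS_ACETYL, free = chemistry$dimethyl_shift,
              monomethyl = chemistry$hybrid_methyl_shift,
              pyroGlu = MASS_PYROGLU)
  if (min(stats::dist(masses)) <= 2 * tol) {
    stop("modification mass windows overlap for chemistry ", chemistry$name,
         " at tolerance ", tol, " Da")
  }
  masses
}

#' Classify the in-vivo N-terminal modification state
#'
#' Interprets the observed N-terminal mass shift under a labeling chemistry:
#' full in-vitro dimethylation means the N-terminus was free in vivo; the
#' hybrid (single label methyl) shift means in-vivo monomethylation;
#' +42.010565 Da is acetylation; -17.026549 Da on an N-terminal Gln is
#' pyroglutamate. pyroGlu is only accepted when the preceding P1 residue
#' does not match the protease specificity (e.g. no K/R preceders for
#' trypsin), since it can also form artifactually after in-vitro proteolysis;
#' rejected pyroGlu and any unmatched shift classify as `"other"`. An absent
#' shift (unlabeled N-terminus) is uninterpretable and also yields
#' `"other"`. The four mass windows are validated non-overlapping at the
#' given tolerance.
#'
#' @param nterm_delta N-terminal mass shift(s) in Da; `NA` for absent.
#' @param first_residue First residue(s) of the peptide.
#' @param preceding_aa Preceding (P1) residue(s), `"-"` at protein start.
#' @param protease Protease name(s); see [protease_specificity()].
#' @param chemistry A [label_chemistry()] object (or its name).
#' @param tol Absolute matching tolerance in Da (default 0.005).
#' @return Character vector of states among
#'   `"free"`, `"acetyl"`, `"monomethyl"`, `"pyroGlu"`, `"other"`.
#' @export
classify_state <- function(nterm_delta, first_residue, preceding_aa,
                           protease = "trypsin",
                           chemistry = label_chemistry("CD2_13C"),
                           tol = 0.005) {
  stopifnot(tol > 0)
  chemistry <- as_label_chemistry(chemistry)
  masses <- .check_mass_windows(chemistry, tol)
  n <- max(length(nterm_delta), length(first_residue), length(preceding_aa),
           length(protease))
  nterm_delta <- rep_len(nterm_delta, n)
  first_residue <- rep_len(first_residue, n)
  preceding_aa <- rep_len(preceding_aa, n)
  protease <- rep_len(protease, n)

  state <- rep("other", n)
  d <- nterm_delta
  hit <- function(mass) !is.na(d) & abs(d - mass) <= tol
  state[hit(masses["acetyl"])] <- "acetyl"
  state[hit(masses["free"])] <- "free"
  state[hit(masses["monomethyl"])] <- "monomethyl"
  pg <- hit(masses["pyroGlu"]) & first_residue == "Q"
  if (any(pg)) {
    ok <- vapply(which(pg), function(i) {
      !(preceding_aa[i] %in% protease_specificity(protease[i]))
    }, logical(1))
    state[which(pg)[ok]] <- "pyroGlu"
  }
  state
}

#' Enumerate proteoform N-terminus observations
#'
#' Maps every accepted N-terminal peptide to its start index in each matched
#' (non-decoy, non-contaminant) protein and aggregates spectra into one
#' observation per distinct proteoform key `(accession, start_index,
#' state)` - so a position identified both acetylated and free yields two
#' proteoform observations (a dual state). Unmapped and ambiguous peptides
#' are dropped; their counts are attached as the `"dropped"` attribute.
#'
#' @param psms Accepted PSM data frame.
#' @param proteome Proteome data frame from [read_proteome()].
#' @param chemistry_by_dataset Named vector/list mapping every `dataset_id`
#'   to a chemistry name (`"CD2_13C"` or `"D2"`).
#' @param tol Mass-matching tolerance in Da.
#' @param decoy_prefix Decoy accession prefix.
#' @return `data.frame` with columns `accession`, `start_index`, `state`,
#'   `preceding_aa` (derived from the protein sequence, `"-"` at position
#'   1), `peptide`, `n_spectra`, `datasets` (semicolon-joined, sorted).
#' @export
enumerate_observations <- function(psms, proteome, chemistry_by_dataset,
                                   tol = 0.005, decoy_prefix = "REV_") {
  datasets <- unique(psms$dataset_id)
  missing_chem <- setdiff(datasets, names(chemistry_by_dataset))
  if (length(missing_chem)) {
    stop("no chemistry assignment for dataset(s): ",
         paste(missing_chem, collapse = ", "))
  }
  empty <- data.frame(
    accession = character(), start_index = integer(), state = character(),
    preceding_aa = character(), peptide = character(),
    n_spectra = integer(), datasets = character(), stringsAsFactors = FALSE
  )
  if (!nrow(psms)) {
    attr(empty, "dropped") <- c(unmapped = 0L, ambiguous = 0L)
    return(empty)
  }
  seqs <- stats::setNames(proteome$sequence, proteome$accession)
  usable <- stats::setNames(!(proteome$is_decoy | proteome$is_contaminant),
                            proteome$accession)

  # classify each PSM row once
  chem_name <- vapply(chemistry_by_dataset[psms$dataset_id], function(x) {
    if (inherits(x, "label_chemistry")) x$name else as.character(x)
  }, character(1))
  state <- rep(NA_character_, nrow(psms))
  for (nm in unique(chem_name)) {
    idx <- which(chem_name == nm)
    state[idx] <- classify_state(
      psms$nterm_delta[idx], substr(psms$peptide[idx], 1, 1),
      psms$preceding_aa[idx], psms$protease[idx],
      label_chemistry(nm), tol
    )
  }

  acc_list <- split_accessions(psms$accessions)
  n_unmapped <- 0L; n_ambiguous <- 0L
  recs <- vector("list", nrow(psms))
  for (i in seq_len(nrow(psms))) {
    for (acc in acc_list[[i]]) {
      if (is.na(usable[acc]) || !usable[acc]) next
      start <- tryCatch(map_peptide_start(seqs[[acc]], psms$peptide[i]),
                        error = function(e) {
                          if (grepl("^ambiguous", conditionMessage(e))) {
                            n_ambiguous <<- n_ambiguous + 1L
                          } else {
                            n_unmapped <<- n_unmapped + 1L
                          }
                          NA_integer_
                        })
      if (is.na(start)) next
      prec <- if (start == 1L) "-" else substr(seqs[[acc]], start - 1L, start - 1L)
      recs[[i]] <- rbind(recs[[i]], data.frame(
        accession = acc, start_index = start, state = state[i],
        preceding_aa = prec, peptide = psms$peptide[i],
        dataset_id = psms$dataset_id[i], stringsAsFactors = FALSE
      ))
    }
  }
  long <- do.call(rbind, recs)
  if (is.null(long) || !nrow(long)) {
    attr(empty, "dropped") <- c(unmapped = n_unmapped, ambiguous = n_ambiguous)
    return(empty)
  }
  key <- paste(long$accession, long$start_index, long$state, sep = "\r")
  agg <- lapply(split(seq_len(nrow(long)), key), function(ii) {
    first <- ii[1]
    data.frame(
      accession = long$accession[first],
      start_index = long$start_index[first],
      state = long$state[first],
      preceding_aa = long$preceding_aa[first],
      peptide = long$peptide[first],
      n_spectra = length(ii),
      datasets = paste(sort(unique(long$dataset_id[ii])), collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$accession, out$start_index, out$state), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- c(unmapped = n_unmapped, ambiguous = n_ambiguous)
  out
}

default_start_bins <- function() {
  list(`1` = c(1, 1), `2` = c(2, 2), `3-100` = c(3, 100), `>100` = c(101, Inf))
}

#' Histogram of proteoform start indices
#'
#' Default bins separate the initiator methionine (index 1), methionine
#' excision (index 2), internal processing (3-100, covering targeting-peptide
#' cleavage), and deep-internal starts (>100).
#'
#' @param observations Observation table from [enumerate_observations()].
#' @param bins Named list of `c(lo, hi)` inclusive ranges.
#' @return `data.frame` with `bin`, `count`, `fraction` (fractions sum to 1
#'   over non-empty input); zero rows for empty input.
#' @export
start_index_histogram <- function(observations, bins = default_start_bins()) {
  if (!nrow(observations)) {
    return(data.frame(bin = character(), count = integer(),
                      fraction = numeric(), stringsAsFactors = FALSE))
  }
  s <- observations$start_index
  count <- vapply(bins, function(r) sum(s >= r[1] & s <= r[2]), integer(1))
  data.frame(bin = names(bins), count = unname(count),
             fraction = unname(count) / length(s), stringsAsFactors = FALSE)
}

#' Number of distinct N-termini per protein
#'
#' Counts distinct proteoform N-termini (the `(start_index, state)` key, so
#' a dual acetyl/free site counts as two) per accession and tabulates how
#' many proteins carry each count.
#'
#' @param observations Observation table from [enumerate_observations()].
#' @return `data.frame` with `n_termini` (>= 1) and `n_proteins`.
#' @export
termini_per_protein <- function(observations) {
  if (!nrow(observations)) {
    return(data.frame(n_termini = integer(), n_proteins = integer()))
  }
  per_acc <- table(observations$accession)
  tab <- table(per_acc)
  data.frame(n_termini = as.integer(names(tab)),
             n_proteins = as.integer(tab))
}
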