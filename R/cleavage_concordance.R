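# Concordance of observed N-termini with predicted targeting-peptide
# cleavage sites within a signed +/-window.

TARGETED_CLASSES <- c("cTP", "mTP", "luTP", "SP")

#' Signed offset between an observed N-terminus and a predicted cleavage site
#'
#' `dif = start_index - p1_prime`: 0 means the observed N-terminal residue is
#' exactly the predicted first mature residue (P1'); positive values mean
#' additional residues were removed beyond the predicted site
#' (post-processing / trimming); negative values mean the observed terminus
#' retains residues of the predicted targeting peptide.
#'
#' @param observation One observation (list or one-row data frame with
#'   `accession`, `start_index`, `state`).
#' @param prediction One targeting prediction (`accession`, `signal_class`,
#'   `p1_prime`).
#' @param window Half-width of the acceptance window (default 5).
#' @return One-row data frame (`accession`, `signal_class`, `dif`, `state`,
#'   `start_index`) or `NULL` when the prediction carries no cleavage site
#'   or the offset falls outside the window.
#' @export
compute_dif <- function(observation, prediction, window = 5L) {
  if (prediction$signal_class == "noTP" || is.na(prediction$p1_prime)) {
    return(NULL)
  }
  dif <- as.integer(observation$start_index) - as.integer(prediction$p1_prime)
  if (abs(dif) > window) return(NULL)
  data.frame(
    accession = observation$accession,
    signal_class = prediction$signal_class,
    dif = dif,
    state = observation$state,
    start_index = as.integer(observation$start_index),
    stringsAsFactors = FALSE
  )
}

#' Offset records for all observation/prediction pairs
#'
#' Joins observations to predictions by accession and keeps the in-window
#' pairs, one record per distinct `(accession, dif, state)` triple.
#'
#' @param observations Observation table from [enumerate_observations()].
#' @param predictions Prediction table from [read_targetp_short()];
#'   must be deduplicated per accession.
#' @param window Half-width of the acceptance window.
#' @return `data.frame` of offset records (`accession`, `signal_class`,
#'   `dif`, `state`, `start_index`).
#' @export
offset_records <- function(observations, predictions, window = 5L) {
  if (anyDuplicated(predictions$accession)) {
    stop("predictions must be deduplicated per accession")
  }
  empty <- data.frame(accession = character(), signal_class = character(),
                      dif = integer(), state = character(),
                      start_index = integer(), stringsAsFactors = FALSE)
  if (!nrow(observations) || !nrow(predictions)) return(empty)
  pred <- predictions[predictions$signal_class != "noTP" &
                        !is.na(predictions$p1_prime), , drop = FALSE]
  m <- merge(observations[, c("accession", "start_index", "state")],
             pred[, c("accession", "signal_class", "p1_prime")],
             by = "accession")
  if (!nrow(m)) return(empty)
  m$dif <- as.integer(m$start_index) - as.integer(m$p1_prime)
  m <- m[abs(m$dif) <= window, , drop = FALSE]
  if (!nrow(m)) return(empty)
  m <- m[!duplicated(paste(m$accession, m$dif, m$state, sep = "\r")), ,
         drop = FALSE]
  out <- m[order(m$accession, m$dif, m$state),
           c("accession", "signal_class", "dif", "state", "start_index")]
  rownames(out) <- NULL
  out
}

#' Concordance table of observed vs predicted cleavage sites
#'
#' For every signal class (and, when stratified, every modification state)
#' tabulates the distinct `(accession, dif, state)` records over the full
#' dif grid `-window..window`, with per-stratum fractions and the cumulative
#' curve over increasing dif. `n_proteins` gives the protein-level tally at
#' each dif alongside the proteoform-level `count`.
#'
#' @inheritParams offset_records
#' @param stratify_by_state Stratify rows by modification state (default
#'   `TRUE`); otherwise a single `"all"` stratum per class.
#' @return `data.frame` with `signal_class`, `stratum`, `dif`, `count`,
#'   `n_proteins`, `fraction`, `cumulative_fraction`.
#' @export
build_concordance <- function(observations, predictions, window = 5L,
                              stratify_by_state = TRUE) {
  rec <- offset_records(observations, predictions, window)
  empty <- data.frame(signal_class = character(), stratum = character(),
                      dif = integer(), count = integer(),
                      n_proteins = integer(), fraction = numeric(),
                      cumulative_fraction = numeric(), stringsAsFactors = FALSE)
  if (!nrow(rec)) return(empty)
  rec$stratum <- if (stratify_by_state) rec$state else "all"
  grid <- seq.int(-window, window)
  groups <- split(rec, paste(rec$signal_class, rec$stratum, sep = "\r"))
  out <- lapply(groups, function(g) {
    count <- vapply(grid, function(d) sum(g$dif == d), integer(1))
    n_prot <- vapply(grid, function(d) length(unique(g$accession[g$dif == d])),
                     integer(1))
    frac <- count / sum(count)
    data.frame(signal_class = g$signal_class[1], stratum = g$stratum[1],
               dif = grid, count = count, n_proteins = n_prot,
               fraction = frac, cumulative_fraction = cumsum(frac),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$signal_class, out$stratum, out$dif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Confirmed targeting-peptide cleavages per signal class
#'
#' A protein's predicted cleavage is confirmed when at least one observed
#' N-terminus lies within the window around the predicted P1'; each protein
#' counts once for its predicted class.
#'
#' @inheritParams offset_records
#' @return `data.frame` with `signal_class`, `n_proteins` (classes with zero
#'   confirmed proteins are omitted).
#' @export
confirmed_cleavages <- function(observations, predictions, window = 5L) {
  rec <- offset_records(observations, predictions, window)
  if (!nrow(rec)) {
    return(data.frame(signal_class = character(), n_proteins = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- tapply(rec$accession, rec$signal_class,
                function(a) length(unique(a)))
  cls <- intersect(TARGETED_CLASSES, names(tab))
  data.frame(signal_class = cls, n_proteins = as.integer(tab[cls]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Modification-state breakdown at confirmed cleavage sites
#'
#' Counts, per signal class, the distinct `(accession, state)` proteoforms
#' among in-window offset records; fractions are relative to the number of
#' confirmed proteins of that class, so dual-state proteins contribute to
#' several states and fractions may sum above 1.
#'
#' @param records Offset records from [offset_records()].
#' @return `data.frame` with `signal_class`, `state`, `n_proteoforms`,
#'   `fraction_of_confirmed`.
#' @export
state_breakdown_at_sites <- function(records) {
  empty <- data.frame(signal_class = character(), state = character(),
                      n_proteoforms = integer(),
                      fraction_of_confirmed = numeric(), stringsAsFactors = FALSE)
  if (!nrow(records)) return(empty)
  out <- lapply(split(records, records$signal_class), function(g) {
    n_confirmed <- length(unique(g$accession))
    key <- unique(paste(g$accession, g$state, sep = "\r"))
    st <- sub("^.*\r", "", key)
    tab <- table(st)
    data.frame(signal_class = g$signal_class[1], state = names(tab),
               n_proteoforms = as.integer(tab),
               fraction_of_confirmed = as.integer(tab) / n_confirmed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$signal_class, out$state), , drop = FALSE]
  rownames(out) <- NULL
  out
}
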