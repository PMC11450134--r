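# Triage of N-terminally acetylated observations at predicted mitochondrial
# presequence cleavage sites: alternative translation initiation, splice
# variant, potential dual targeting, or unclear.

TRIAGE_CATEGORIES <- c("alt_TIS", "splice_variant", "dual_targeting", "unclear")

#' Default plant Kozak position-probability matrix
#'
#' A soft position-probability matrix over a 12-nucleotide window - six
#' upstream positions, the AUG codon, three downstream positions - built
#' from the plant initiation-context consensus (A-rich upstream, G/C
#' immediately downstream). Consensus bases carry most of the probability;
#' the AUG positions are near-deterministic.
#'
#' @return 4 x 12 numeric matrix, rows `A`, `C`, `G`, `U`, columns summing
#'   to 1.
#' @export
default_kozak_pwm <- function() {
  consensus <- c("A", "A", "C", "A", "A", "C", "A", "U", "G", "G", "C", "U")
  bases <- c("A", "C", "G", "U")
  pwm <- matrix(0.15, nrow = 4, ncol = length(consensus),
                dimnames = list(bases, c(paste0("u", 6:1), "A", "U", "G",
                                         paste0("d", 1:3))))
  for (j in seq_along(consensus)) pwm[consensus[j], j] <- 0.55
  for (j in 7:9) {
    pwm[, j] <- 0.01
    pwm[consensus[j], j] <- 0.97
  }
  pwm
}

#' Kozak-context similarity score
#'
#' Scores a nucleotide window against a position-probability matrix as the
#' mean per-position probability normalized by each position's maximum, so
#' the consensus context scores exactly 1 and any context scores in [0, 1].
#' `T` is accepted as `U`.
#'
#' @param context Nucleotide string, same width as the PWM.
#' @param pwm Position-probability matrix (rows `A`, `C`, `G`, `U`); default
#'   [default_kozak_pwm()].
#' @return Similarity score in `[0, 1]`.
#' @export
kozak_similarity <- function(context, pwm = default_kozak_pwm()) {
  ctx <- chartr("T", "U", toupper(context))
  chars <- strsplit(ctx, "")[[1]]
  if (!all(chars %in% rownames(pwm))) {
    stop("context contains non-ACGU/T letters: ", context)
  }
  if (length(chars) != ncol(pwm)) {
    stop("context width ", length(chars), " does not match PWM width ",
         ncol(pwm))
  }
  p <- pwm[cbind(match(chars, rownames(pwm)), seq_along(chars))]
  mean(p / apply(pwm, 2, max))
}

#' Triage input for one acetylated N-terminus at an mTP cleavage site
#'
#' @param accession Protein accession.
#' @param observation List/row with at least `state` (must be `"acetyl"`),
#'   `start_index`, `preceding_aa`.
#' @param prediction List/row with `signal_class`, `p1_prime`.
#' @param protein_sequence Full protein sequence (needed for splice-variant
#'   matching).
#' @param splice_variants List of lists with `accession` and `sequence` for
#'   gene models sharing the gene; may be empty.
#' @param dual_target_call Logical flag consumed from an ambiguous-targeting
#'   predictor (`NA` when unavailable).
#' @param kozak_context Optional nucleotide window centered on the candidate
#'   downstream AUG (`NULL` when unavailable).
#' @return A `triage_input` list.
#' @export
triage_input <- function(accession, observation, prediction,
                         protein_sequence, splice_variants = list(),
                         dual_target_call = NA, kozak_context = NULL) {
  structure(
    list(accession = accession, observation = observation,
         prediction = prediction, protein_sequence = protein_sequence,
         splice_variants = splice_variants,
         dual_target_call = dual_target_call, kozak_context = kozak_context),
    class = "triage_input"
  )
}

# does a splice variant's protein begin at/near (+/-1) the observed residue?
.variant_starts_at <- function(protein_sequence, start_index, variant_seq,
                               k = 10L) {
  for (d in -1:1) {
    pos <- start_index + d
    if (pos < 1L || pos > nchar(protein_sequence)) next
    suffix <- substring(protein_sequence, pos)
    for (cand in unique(c(variant_seq, sub("^M", "", variant_seq)))) {
      m <- min(nchar(cand), nchar(suffix), k)
      if (m >= 5L && substr(cand, 1, m) == substr(suffix, 1, m)) return(TRUE)
    }
  }
  FALSE
}

#' Triage an acetylated N-terminus at a mitochondrial presequence site
#'
#' Applies a total, deterministic decision order:
#' 1. **alt_TIS** - the preceding residue is Met and either the Kozak
#'    similarity of the supplied context reaches `kozak_threshold`, or no
#'    Kozak data are available (the preceding Met itself is the candidate
#'    downstream initiator).
#' 2. **splice_variant** - some splice variant's protein begins at, or
#'    within one residue of, the observed N-terminal residue.
#' 3. **dual_targeting** - an ambiguous-targeting predictor flagged the
#'    protein.
#' 4. **unclear** otherwise.
#'
#' @param input A [triage_input()] object.
#' @param kozak_threshold Minimum Kozak similarity for alt_TIS (default
#'   0.7).
#' @param kozak_pwm PWM passed to [kozak_similarity()].
#' @return A `triage_call` list: `accession`, `category`, `evidence`.
#' @export
triage <- function(input, kozak_threshold = 0.7,
                   kozak_pwm = default_kozak_pwm()) {
  stopifnot(inherits(input, "triage_input"))
  if (!identical(input$observation$state, "acetyl")) {
    stop("triage requires an acetylated observation; got state '",
         input$observation$state, "'")
  }
  evidence <- character()
  pre <- input$observation$preceding_aa
  if (identical(pre, "M")) {
    if (!is.null(input$kozak_context)) {
      score <- kozak_similarity(input$kozak_context, kozak_pwm)
      evidence <- c(evidence, sprintf("preceding Met; Kozak similarity %.3f",
                                      score))
      if (score >= kozak_threshold) {
        return(.triage_call(input$accession, "alt_TIS", c(
          evidence, sprintf("Kozak similarity >= %.2f", kozak_threshold))))
      }
    } else {
      return(.triage_call(input$accession, "alt_TIS",
                          c(evidence, "preceding Met, no Kozak data")))
    }
  }
  for (v in input$splice_variants) {
    if (.variant_starts_at(input$protein_sequence,
                           input$observation$start_index, v$sequence)) {
      return(.triage_call(input$accession, "splice_variant", c(
        evidence,
        sprintf("variant %s starts at/near observed residue %d",
                v$accession, input$observation$start_index))))
    }
  }
  if (isTRUE(input$dual_target_call)) {
    return(.triage_call(input$accession, "dual_targeting",
                        c(evidence, "ambiguous-targeting predictor positive")))
  }
  .triage_call(input$accession, "unclear",
               c(evidence, "no supporting evidence for any category"))
}

.triage_call <- function(accession, category, evidence) {
  structure(list(accession = accession, category = category,
                 evidence = paste(evidence, collapse = "; ")),
            class = "triage_call")
}

#' @export
print.triage_call <- function(x, ...) {
  cat(sprintf("%s -> %s (%s)\n", x$accession, x$category, x$evidence))
  invisible(x)
}

#' Triage a list of inputs into a calls table
#'
#' @param inputs List of [triage_input()] objects.
#' @param ... Passed to [triage()].
#' @return `data.frame` with `accession`, `category`, `evidence`.
#' @export
triage_table <- function(inputs, ...) {
  calls <- lapply(inputs, triage, ...)
  data.frame(
    accession = vapply(calls, `[[`, character(1), "accession"),
    category = vapply(calls, `[[`, character(1), "category"),
    evidence = vapply(calls, `[[`, character(1), "evidence"),
    stringsAsFactors = FALSE
  )
}
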