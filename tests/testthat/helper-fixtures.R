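# In-code fixtures shared across test files.

make_psm <- function(dataset_id = "DS1", peptide = "STKAAGK",
                     nterm_delta = 34.063117, residue_deltas = "",
                     accessions = "P1", peptide_prob = 0.99,
                     protein_prob = 0.999, ion_score = 80,
                     protease = "trypsin", preceding_aa = "R") {
  data.frame(dataset_id = dataset_id, peptide = peptide,
             nterm_delta = nterm_delta, residue_deltas = residue_deltas,
             accessions = accessions, peptide_prob = peptide_prob,
             protein_prob = protein_prob, ion_score = ion_score,
             protease = protease, preceding_aa = preceding_aa,
             stringsAsFactors = FALSE)
}

make_proteome <- function(accession, sequence, is_decoy = FALSE,
                          is_contaminant = FALSE) {
  data.frame(accession = accession, sequence = sequence,
             is_decoy = rep_len(is_decoy, length(accession)),
             is_contaminant = rep_len(is_contaminant, length(accession)),
             description = "", stringsAsFactors = FALSE)
}

make_observations <- function(accession, start_index, state = "free",
                              preceding_aa = "R", peptide = "PEPTIDEK") {
  data.frame(accession = accession, start_index = as.integer(start_index),
             state = rep_len(state, length(accession)),
             preceding_aa = rep_len(preceding_aa, length(accession)),
             peptide = rep_len(peptide, length(accession)),
             n_spectra = rep_len(1L, length(accession)),
             datasets = rep_len("DS1", length(accession)),
             stringsAsFactors = FALSE)
}

make_predictions <- function(accession, signal_class, p1_prime) {
  data.frame(accession = accession, signal_class = signal_class,
             p1_prime = as.integer(p1_prime),
             class_probability = 0.9, stringsAsFactors = FALSE)
}

write_fasta <- function(records, path) {
  writeLines(unlist(lapply(names(records), function(h) {
    c(paste0(">", h), records[[h]])
  })), path)
  path
}

random_protein <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, TRUE),
        collapse = "")
}

# Independent all-pairs oracle for offset records: scans every observation
# against every prediction without any join machinery.
brute_force_offsets <- function(observations, predictions, window = 5L) {
  out <- list()
  for (i in seq_len(nrow(observations))) {
    for (j in seq_len(nrow(predictions))) {
      if (observations$accession[i] != predictions$accession[j]) next
      if (predictions$signal_class[j] == "noTP" ||
          is.na(predictions$p1_prime[j])) next
      dif <- observations$start_index[i] - predictions$p1_prime[j]
      if (abs(dif) > window) next
      out[[length(out) + 1L]] <- data.frame(
        accession = observations$accession[i],
        signal_class = predictions$signal_class[j],
        dif = dif, state = observations$state[i],
        start_index = observations$start_index[i], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(accession = character(), signal_class = character(),
                      dif = integer(), state = character(),
                      start_index = integer(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df <- df[!duplicated(paste(df$accession, df$dif, df$state)), , drop = FALSE]
  df <- df[order(df$accession, df$dif, df$state), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# random observation/prediction fixture over at most n_prot proteins
random_concordance_fixture <- function(n_prot = 50L) {
  accs <- sprintf("P%03d", seq_len(n_prot))
  classes <- sample(c("cTP", "mTP", "luTP", "SP", "noTP"), n_prot, TRUE)
  p1 <- ifelse(classes == "noTP", NA_integer_,
               sample(20:90, n_prot, TRUE))
  preds <- data.frame(accession = accs, signal_class = classes,
                      p1_prime = as.integer(p1), class_probability = 0.9,
                      stringsAsFactors = FALSE)
  n_obs <- n_prot * 2L
  obs <- make_observations(
    accession = sample(accs, n_obs, TRUE),
    start_index = sample(1:100, n_obs, TRUE),
    state = sample(c("free", "acetyl", "monomethyl"), n_obs, TRUE))
  obs <- obs[!duplicated(paste(obs$accession, obs$start_index, obs$state)), ]
  list(observations = obs, predictions = preds)
}

consensus_context <- function(pwm = default_kozak_pwm()) {
  paste(rownames(pwm)[apply(pwm, 2, which.max)], collapse = "")
}

# planted 12-case triage panel covering all four categories and the
# precedence order of the decision rules
triage_panel <- function() {
  prot <- "MKKLSRQATSLLARSTAAGKLVRWWGHK"
  mk <- function(pre, start = 9L, variants = list(), dual = NA, kozak = NULL) {
    triage_input(
      accession = "PpX",
      observation = list(state = "acetyl", start_index = start,
                         preceding_aa = pre),
      prediction = list(signal_class = "mTP", p1_prime = start),
      protein_sequence = prot,
      splice_variants = variants, dual_target_call = dual,
      kozak_context = kozak
    )
  }
  var_at <- function(d, prot_seq = prot, start = 9L) {
    list(accession = "PpX.v2",
         sequence = paste0("M", substring(prot_seq, start + d)))
  }
  good_ctx <- consensus_context()
  bad_ctx <- strrep("U", 12)
  list(
    list(input = mk("M", kozak = good_ctx), want = "alt_TIS"),
    list(input = mk("M"), want = "alt_TIS"),                  # no Kozak data
    list(input = mk("M", kozak = bad_ctx), want = "unclear"),
    list(input = mk("A", variants = list(var_at(0))), want = "splice_variant"),
    list(input = mk("A", variants = list(var_at(1))), want = "splice_variant"),
    list(input = mk("A", variants = list(var_at(-1))), want = "splice_variant"),
    list(input = mk("A", dual = TRUE), want = "dual_targeting"),
    list(input = mk("M", kozak = bad_ctx, variants = list(var_at(0))),
         want = "splice_variant"),
    list(input = mk("M", kozak = good_ctx, variants = list(var_at(0))),
         want = "alt_TIS"),                                   # precedence
    list(input = mk("A", variants = list(var_at(0)), dual = TRUE),
         want = "splice_variant"),                            # precedence
    list(input = mk("A"), want = "unclear"),
    list(input = mk("-", start = 1L, dual = FALSE), want = "unclear")
  )
}
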