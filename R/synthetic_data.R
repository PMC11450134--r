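# Ground-truthed synthetic study generator: proteome with planted targeting
# peptides, TargetP2-style predictions, and PSM tables encoding known
# modification states under both labeling chemistries.

#' Parameters for the synthetic study generator
#'
#' Defaults encode the study conditions the analysis assumes: class mix
#' dominated by untargeted proteins with a substantial plastid fraction,
#' targeting-peptide lengths of 20-80 residues, ragged trimming beyond the
#' cleavage site following a truncated geometric law (0-5 residues), and a
#' modification-state mix of 71% free, 25% acetylated, 3% monomethylated and
#' 1% pyroglutamate.
#'
#' @param n_proteins Number of target proteins.
#' @param class_fractions Named fractions over
#'   `cTP`/`mTP`/`luTP`/`SP`/`noTP`; must sum to 1.
#' @param tp_length_range Inclusive range of targeting-peptide lengths.
#' @param trim_geometric_p Success parameter of the truncated geometric
#'   trimming law on `0..max_trim`.
#' @param max_trim Maximum trimming offset (and the concordance window).
#' @param state_probs Named probabilities over
#'   `free`/`acetyl`/`monomethyl`/`pyroGlu`; must sum to 1.
#' @param mature_aa_bias Relative enrichment factor for Ala/Ser at the
#'   mature N-terminal residue (default 4).
#' @param chemistries Named map dataset_id -> chemistry name; default two
#'   datasets, one per formaldehyde isotopologue.
#' @param protease Protease for all simulated digests.
#' @param p1_jitter Integer jitter half-width applied to emitted predicted
#'   cleavage sites (default 0 = predictions match truth).
#' @param decoy_pass_rate Rate of decoy PSMs passing the acceptance
#'   thresholds (per target protein).
#' @param low_score_rate Rate of extra below-threshold target rows.
#' @param seed Integer seed; all generator output is reproducible from it.
#' @return A `generator_params` list.
#' @export
generator_params <- function(n_proteins = 1000L,
                             class_fractions = c(cTP = 0.2, mTP = 0.1,
                                                 luTP = 0.02, SP = 0.05,
                                                 noTP = 0.63),
                             tp_length_range = c(20L, 80L),
                             trim_geometric_p = 0.5,
                             max_trim = 5L,
                             state_probs = c(free = 0.71, acetyl = 0.25,
                                             monomethyl = 0.03,
                                             pyroGlu = 0.01),
                             mature_aa_bias = 4,
                             chemistries = c(DS1 = "CD2_13C", DS2 = "D2"),
                             protease = "trypsin",
                             p1_jitter = 0L,
                             decoy_pass_rate = 0.002,
                             low_score_rate = 0.05,
                             seed = 1L) {
  if (abs(sum(class_fractions) - 1) > 1e-8) {
    stop("class_fractions must sum to 1")
  }
  if (abs(sum(state_probs) - 1) > 1e-8) {
    stop("state_probs must sum to 1")
  }
  stopifnot(
    n_proteins >= 1L,
    all(sort(names(class_fractions)) == sort(c(TARGETED_CLASSES, "noTP"))),
    all(sort(names(state_probs)) == sort(setdiff(MOD_STATES, "other"))),
    tp_length_range[1] >= 2L, tp_length_range[2] >= tp_length_range[1],
    trim_geometric_p > 0, trim_geometric_p < 1,
    max_trim >= 0L, mature_aa_bias >= 1,
    protease %in% PROTEASES, length(chemistries) >= 1L,
    !is.null(names(chemistries)), p1_jitter >= 0L
  )
  vapply(chemistries, function(x) label_chemistry(x)$name, character(1))
  structure(
    list(n_proteins = as.integer(n_proteins),
         class_fractions = class_fractions,
         tp_length_range = as.integer(tp_length_range),
         trim_geometric_p = trim_geometric_p, max_trim = as.integer(max_trim),
         state_probs = state_probs, mature_aa_bias = mature_aa_bias,
         chemistries = chemistries, protease = protease,
         p1_jitter = as.integer(p1_jitter),
         decoy_pass_rate = decoy_pass_rate, low_score_rate = low_score_rate,
         seed = as.integer(seed)),
    class = "generator_params"
  )
}

# Truncated geometric on 0..max_k: P(k) proportional to p (1-p)^k.
rtrunc_geom <- function(n, p, max_k) {
  probs <- p * (1 - p)^(0:max_k)
  sample(0:max_k, n, replace = TRUE, prob = probs / sum(probs))
}

# Exact partition of n into the named fractions: floor allocation, remainder
# to the largest fractional parts (ties by name order).
allocate_classes <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Generate a ground-truthed synthetic proteome with targeting predictions
#'
#' Builds `n_proteins` random protein sequences. Targeted proteins carry a
#' planted targeting peptide of known length, so the true first mature
#' residue (P1') is known; the observed N-terminal start is P1' plus a
#' truncated-geometric trimming offset. Every protein receives a planted
#' modification state; pyroGlu termini get a Gln first residue and an Ala
#' preceder (never matching a protease specificity); other mature termini
#' are Ala/Ser-enriched. Reversed decoy entries (prefix `REV_`) are
#' appended. The emitted prediction table is exactly the planted truth
#' (optionally jittered).
#'
#' @param params A [generator_params()] object.
#' @return List with `proteins` (targets plus decoys, the
#'   [read_proteome()] layout), `truths` (`accession`, `signal_class`,
#'   `true_p1_prime`, `true_observed_start`, `true_state`, `dataset_id`),
#'   `predictions` (the [read_targetp_short()] layout), and `params`.
#' @export
generate_proteome <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  set.seed(params$seed)
  n <- params$n_proteins
  counts <- allocate_classes(n, params$class_fractions)
  classes <- rep(names(params$class_fractions), counts)
  classes <- sample(classes)  # shuffle class order across accessions

  biased <- rep(1, length(AA20))
  names(biased) <- AA20
  biased[c("A", "S")] <- params$mature_aa_bias
  draw_biased <- function() sample(AA20, 1L, prob = biased)

  accession <- sprintf("SYN%05d", seq_len(n))
  sequences <- character(n)
  p1 <- rep(NA_integer_, n)
  start <- integer(n)
  state <- sample(names(params$state_probs), n, replace = TRUE,
                  prob = params$state_probs)
  dataset <- sample(names(params$chemistries), n, replace = TRUE)

  for (i in seq_len(n)) {
    if (classes[i] != "noTP") {
      tp_len <- sample(params$tp_length_range[1]:params$tp_length_range[2], 1L)
      trim <- rtrunc_geom(1L, params$trim_geometric_p, params$max_trim)
      mature_len <- sample(80:220, 1L)
      len <- tp_len + mature_len
      p1[i] <- tp_len + 1L
      start[i] <- p1[i] + trim
    } else {
      len <- sample(100:300, 1L)
      u <- stats::runif(1)
      start[i] <- if (u < 0.3) 1L else if (u < 0.6) 2L else {
        sample(3:min(100L, len - 40L), 1L)
      }
    }
    sq <- sample(AA20, len, replace = TRUE)
    sq[1] <- "M"
    if (state[i] == "pyroGlu") {
      sq[start[i]] <- "Q"
      if (start[i] > 1L) sq[start[i] - 1L] <- "A"
    } else if (start[i] > 2L) {
      sq[start[i]] <- draw_biased()
    }
    sequences[i] <- paste(sq, collapse = "")
  }

  rev_seq <- vapply(strsplit(sequences, ""), function(x) {
    paste(rev(x), collapse = "")
  }, character(1))
  proteins <- data.frame(
    accession = c(accession, paste0("REV_", accession)),
    sequence = c(sequences, rev_seq),
    is_decoy = rep(c(FALSE, TRUE), each = n),
    is_contaminant = FALSE,
    description = rep(c("synthetic target", "synthetic decoy"), each = n),
    stringsAsFactors = FALSE
  )
  truths <- data.frame(
    accession = accession, signal_class = classes, true_p1_prime = p1,
    true_observed_start = start, true_state = state, dataset_id = dataset,
    stringsAsFactors = FALSE
  )
  pred_p1 <- p1
  if (params$p1_jitter > 0L) {
    jit <- sample(-params$p1_jitter:params$p1_jitter, n, replace = TRUE)
    pred_p1 <- ifelse(is.na(p1), NA_integer_, pmax(2L, p1 + jit))
  }
  predictions <- data.frame(
    accession = accession, signal_class = classes,
    p1_prime = as.integer(pred_p1),
    class_probability = round(stats::runif(n, 0.80, 0.99), 4),
    stringsAsFactors = FALSE
  )
  list(proteins = proteins, truths = truths, predictions = predictions,
       params = params)
}

# C-terminal cleavage residues per protease (same sets as the P1
# specificity used by the pyroGlu filter).
.cleavage_set <- function(protease) protease_specificity(protease)

.state_delta <- function(state, chemistry) {
  switch(state,
    free = chemistry$dimethyl_shift,
    acetyl = MASS_ACETYL,
    monomethyl = chemistry$hybrid_methyl_shift,
    pyroGlu = MASS_PYROGLU,
    stop("no mass shift for state: ", state)
  )
}

# Peptide from `start` to the next protease-specific residue, extended until
# it occurs uniquely in the protein.
.pick_peptide <- function(sq_chars, start, cleav, min_len = 7L,
                          fallback_len = 25L) {
  len <- length(sq_chars)
  cand <- which(sq_chars %in% cleav)
  cand <- cand[cand >= start + min_len - 1L]
  cut <- if (length(cand)) cand[1] else min(start + fallback_len - 1L, len)
  protein <- paste(sq_chars, collapse = "")
  repeat {
    pep <- paste(sq_chars[start:cut], collapse = "")
    n_occ <- length(gregexpr(paste0("(?=", pep, ")"), protein,
                             perl = TRUE)[[1]])
    if (n_occ == 1L || cut >= len) return(pep)
    nxt <- cand[cand > cut]
    cut <- if (length(nxt)) nxt[1] else min(cut + 5L, len)
  }
}

#' Simulate a PSM table from planted truths
#'
#' Each truth yields at least one peptide-spectrum match whose peptide
#' starts at the planted observed start, ends at a protease-specific
#' C-terminal residue, and whose N-terminal mass shift encodes the planted
#' state under that dataset's chemistry. Internal lysines carry the fixed
#' dimethyl side-chain label as residue deltas. Good rows draw scores above
#' the acceptance thresholds; additional below-threshold target rows and
#' decoy rows (both passing and failing) are planted at the configured
#' rates.
#'
#' @param truths Truth table from [generate_proteome()].
#' @param proteins Protein table from [generate_proteome()].
#' @param params The same [generator_params()] object.
#' @return PSM `data.frame` in the [read_psm_table()] dialect.
#' @export
simulate_psm_table <- function(truths, proteins, params) {
  stopifnot(inherits(params, "generator_params"))
  set.seed(params$seed + 1000003L)
  seqs <- stats::setNames(proteins$sequence, proteins$accession)
  cleav <- .cleavage_set(params$protease)
  chems <- lapply(params$chemistries, label_chemistry)

  good_scores <- function(k) {
    data.frame(peptide_prob = stats::runif(k, 0.96, 1),
               protein_prob = stats::runif(k, 0.992, 1),
               ion_score = stats::runif(k, 45, 120))
  }
  bad_scores <- function(k) {
    data.frame(peptide_prob = stats::runif(k, 0.5, 0.949),
               protein_prob = stats::runif(k, 0.992, 1),
               ion_score = stats::runif(k, 10, 39))
  }
  rows <- vector("list", nrow(truths))
  for (i in seq_len(nrow(truths))) {
    acc <- truths$accession[i]
    sq_chars <- strsplit(seqs[[acc]], "")[[1]]
    start <- truths$true_observed_start[i]
    pep <- .pick_peptide(sq_chars, start, cleav)
    chem <- chems[[truths$dataset_id[i]]]
    delta <- .state_delta(truths$true_state[i], chem)
    prec <- if (start == 1L) "-" else sq_chars[start - 1L]
    kpos <- which(strsplit(pep, "")[[1]] == "K")
    rd <- if (length(kpos)) {
      paste(sprintf("%d:%.6f", kpos, chem$dimethyl_shift), collapse = ";")
    } else ""
    n_spec <- 1L + stats::rbinom(1L, 1L, 0.2)
    sc <- good_scores(n_spec)
    rows[[i]] <- data.frame(
      dataset_id = truths$dataset_id[i], peptide = pep, nterm_delta = delta,
      residue_deltas = rd, accessions = acc,
      peptide_prob = sc$peptide_prob, protein_prob = sc$protein_prob,
      ion_score = sc$ion_score, protease = params$protease,
      preceding_aa = prec, stringsAsFactors = FALSE
    )
  }
  psms <- do.call(rbind, rows)

  # below-threshold target rows (should be removed by filtering)
  n_low <- round(params$low_score_rate * nrow(truths))
  if (n_low > 0) {
    pick <- sample(nrow(truths), n_low)
    low <- psms[match(truths$accession[pick], psms$accessions), , drop = FALSE]
    sc <- bad_scores(n_low)
    low$peptide_prob <- sc$peptide_prob
    low$protein_prob <- sc$protein_prob
    low$ion_score <- sc$ion_score
    psms <- rbind(psms, low)
  }

  # decoy rows: a few pass thresholds (drive the empirical FDR), more fail
  decoy_accs <- proteins$accession[proteins$is_decoy]
  make_decoy <- function(k, scores) {
    if (k <= 0) return(NULL)
    acc <- sample(decoy_accs, k, replace = TRUE)
    ds <- sample(names(params$chemistries), k, replace = TRUE)
    pep <- vapply(acc, function(a) {
      s <- sample(2:20, 1L)
      substr(seqs[[a]], s, s + 11L)
    }, character(1))
    data.frame(
      dataset_id = ds, peptide = pep,
      nterm_delta = vapply(ds, function(d) chems[[d]]$dimethyl_shift,
                           numeric(1)),
      residue_deltas = "", accessions = acc,
      peptide_prob = scores$peptide_prob, protein_prob = scores$protein_prob,
      ion_score = scores$ion_score, protease = params$protease,
      preceding_aa = "A", stringsAsFactors = FALSE
    )
  }
  n_pass <- round(params$decoy_pass_rate * nrow(truths))
  psms <- rbind(psms, make_decoy(n_pass, good_scores(n_pass)),
                make_decoy(round(0.01 * nrow(truths)),
                           bad_scores(round(0.01 * nrow(truths)))))
  rownames(psms) <- NULL
  psms
}

#' Write a complete synthetic study to disk
#'
#' Generates the proteome (with decoys), predictions, PSM table and truth
#' table, and writes them in the package's external formats. TSV and
#' prediction files record the seed in a header comment.
#'
#' @param params A [generator_params()] object.
#' @param dir Output directory (created if needed).
#' @return Named list of file paths (`proteome`, `predictions`, `psms`,
#'   `truth`), invisibly; the generated objects are attached as the
#'   `"study"` attribute.
#' @export
write_synthetic_study <- function(params, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  study <- generate_proteome(params)
  psms <- simulate_psm_table(study$truths, study$proteins, study$params)
  paths <- list(
    proteome = file.path(dir, "proteome.fasta"),
    predictions = file.path(dir, "targetp_predictions.txt"),
    psms = file.path(dir, "psms.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_proteome(study$proteins, paths$proteome)
  write_targetp_short(study$predictions, paths$predictions,
                      seed = params$seed)
  write_psm_table(psms, paths$psms, seed = params$seed)
  truth_lines <- c(
    sprintf("# seed: %d", params$seed),
    paste(names(study$truths), collapse = "\t"),
    do.call(paste, c(lapply(study$truths, function(x) {
      ifelse(is.na(x), "", as.character(x))
    }), sep = "\t"))
  )
  writeLines(truth_lines, paths$truth, useBytes = TRUE)
  attr(paths, "study") <- c(study, list(psms = psms))
  invisible(paths)
}

#' Read a synthetic truth table
#'
#' @param path Truth TSV written by [write_synthetic_study()].
#' @return `data.frame` with the truth columns.
#' @export
read_truth_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  df$true_p1_prime <- suppressWarnings(as.integer(df$true_p1_prime))
  df
}

#' Fit the truncated-geometric trimming law
#'
#' Maximum-likelihood estimate of the success parameter `p` of a geometric
#' distribution truncated to `0..max_trim`, from observed trimming offsets
#' (the dif values of in-window records).
#'
#' @param difs Integer offsets in `0..max_trim`.
#' @param max_trim Truncation bound (default 5).
#' @return Estimated `p`.
#' @export
fit_trim_geometric <- function(difs, max_trim = 5L) {
  stopifnot(length(difs) > 0, all(difs >= 0), all(difs <= max_trim))
  n <- length(difs); s <- sum(difs)
  nll <- function(p) {
    -(n * log(p) + s * log(1 - p) - n * log(1 - (1 - p)^(max_trim + 1L)))
  }
  stats::optimize(nll, c(1e-6, 1 - 1e-6))$minimum
}

#' Bootstrap confidence interval for the trimming parameter
#'
#' Percentile bootstrap over the observed offsets.
#'
#' @inheritParams fit_trim_geometric
#' @param B Number of bootstrap replicates (default 200).
#' @param conf Confidence level (default 0.95).
#' @return Named numeric vector `c(lower, estimate, upper)`.
#' @export
bootstrap_trim_ci <- function(difs, max_trim = 5L, B = 200L, conf = 0.95) {
  est <- fit_trim_geometric(difs, max_trim)
  boots <- replicate(B, {
    fit_trim_geometric(sample(difs, replace = TRUE), max_trim)
  })
  a <- (1 - conf) / 2
  q <- stats::quantile(boots, c(a, 1 - a), names = FALSE)
  c(lower = q[1], estimate = est, upper = q[2])
}
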