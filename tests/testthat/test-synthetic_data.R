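test_that("generator parameters validate their distributions", {
  expect_error(generator_params(class_fractions = c(cTP = 0.5, mTP = 0.1,
                                                    luTP = 0.1, SP = 0.1,
                                                    noTP = 0.1)),
               "sum to 1")
  expect_error(generator_params(state_probs = c(free = 0.9, acetyl = 0.2,
                                                monomethyl = 0.03,
                                                pyroGlu = 0.01)),
               "sum to 1")
  expect_error(generator_params(protease = "lysC"))
})

test_that("generation is byte-identical under a fixed seed", {
  p <- generator_params(n_proteins = 60, seed = 123)
  d1 <- tempfile(); d2 <- tempfile()
  f1 <- write_synthetic_study(p, d1)
  f2 <- write_synthetic_study(p, d2)
  for (nm in names(f1)) {
    expect_identical(readLines(f1[[nm]]), readLines(f2[[nm]]), label = nm)
  }
})

test_that("class allocation is an exact partition and TP lengths stay in range", {
  p <- generator_params(n_proteins = 1000, seed = 5)
  study <- generate_proteome(p)
  tab <- table(study$truths$signal_class)
  expect_equal(as.integer(tab[c("cTP", "mTP", "luTP", "SP", "noTP")]),
               c(200L, 100L, 20L, 50L, 630L))
  tp_len <- study$truths$true_p1_prime - 1L
  tp_len <- tp_len[!is.na(tp_len)]
  expect_true(all(tp_len >= 20 & tp_len <= 80))
  # trimming bounded by max_trim for targeted proteins
  targeted <- !is.na(study$truths$true_p1_prime)
  trim <- study$truths$true_observed_start[targeted] -
    study$truths$true_p1_prime[targeted]
  expect_true(all(trim >= 0 & trim <= p$max_trim))
})

test_that("decoys are reversed sequences and predictions carry the planted P1'", {
  p <- generator_params(n_proteins = 30, seed = 9)
  study <- generate_proteome(p)
  targets <- study$proteins[!study$proteins$is_decoy, ]
  decoys <- study$proteins[study$proteins$is_decoy, ]
  expect_equal(decoys$accession, paste0("REV_", targets$accession))
  rev_str <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(decoys$sequence[1], rev_str(targets$sequence[1]))
  targeted <- study$truths$signal_class != "noTP"
  expect_equal(study$predictions$p1_prime[targeted],
               study$truths$true_p1_prime[targeted])
  expect_true(all(is.na(study$predictions$p1_prime[!targeted])))
  # prediction file round-trips: P1' minus one is the planted TP length
  f <- tempfile()
  write_targetp_short(study$predictions, f)
  back <- read_targetp_short(f)
  expect_equal(back$p1_prime[targeted] - 1L,
               study$truths$true_p1_prime[targeted] - 1L)
})

test_that("simulated PSMs encode the planted state under each chemistry", {
  p <- generator_params(n_proteins = 200, seed = 17)
  study <- generate_proteome(p)
  psms <- simulate_psm_table(study$truths, study$proteins, p)
  # first PSM row per truth accession (good rows precede planted noise)
  first <- psms[match(study$truths$accession, psms$accessions), ]
  chem <- lapply(p$chemistries, label_chemistry)
  want <- mapply(function(state, ds) {
    switch(state,
           free = chem[[ds]]$dimethyl_shift,
           acetyl = 42.010565,
           monomethyl = chem[[ds]]$hybrid_methyl_shift,
           pyroGlu = -17.026549)
  }, study$truths$true_state, study$truths$dataset_id)
  expect_equal(first$nterm_delta, unname(want))
  # pyroGlu truths start with Q and are preceded off-specificity
  pg <- first[study$truths$true_state == "pyroGlu", ]
  if (nrow(pg)) {
    expect_true(all(substr(pg$peptide, 1, 1) == "Q"))
    expect_true(all(!pg$preceding_aa %in% c("K", "R")))
  }
  # every good peptide begins at the planted start
  seqs <- setNames(study$proteins$sequence, study$proteins$accession)
  starts <- mapply(function(acc, pep) map_peptide_start(seqs[[acc]], pep),
                   first$accessions, first$peptide)
  expect_equal(unname(starts), study$truths$true_observed_start)
})

test_that("truth tables round-trip through disk", {
  p <- generator_params(n_proteins = 25, seed = 2)
  paths <- write_synthetic_study(p, tempfile())
  truth <- read_truth_table(paths$truth)
  study <- attr(paths, "study")
  expect_equal(truth$accession, study$truths$accession)
  expect_equal(truth$true_observed_start, study$truths$true_observed_start)
  expect_equal(truth$true_p1_prime, study$truths$true_p1_prime)
})

test_that("the truncated-geometric fit recovers p on exact frequencies", {
  # expected counts of a truncated geometric, no sampling noise
  p <- 0.5; m <- 5L
  probs <- p * (1 - p)^(0:m); probs <- probs / sum(probs)
  difs <- rep(0:m, round(probs * 1e5))
  expect_equal(fit_trim_geometric(difs, m), 0.5, tolerance = 1e-3)
  expect_equal(fit_trim_geometric(rep(0L, 50), m) > 0.99, TRUE)
})
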