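test_that("peptide-to-protein mapping returns the unique 1-based start", {
  expect_equal(map_peptide_start("MASTKLVR", "STKLVR"), 3L)
  expect_equal(map_peptide_start("MASTKLVR", "MASTKLVR"), 1L)
  expect_error(map_peptide_start("MASTKLVR", "WWW"), "unmapped")
  expect_error(map_peptide_start("MAXMAX", "MAX"), "ambiguous")
  # overlapping occurrences count as ambiguous too
  expect_error(map_peptide_start("QAAAQ", "AA"), "ambiguous")
  expect_error(map_peptide_start("", "AA"), "non-empty")
})

test_that("modification states are classified from the labeling-chemistry shifts", {
  chem <- label_chemistry("CD2_13C")
  expect_equal(classify_state(42.010565, "A", "V", "trypsin", chem), "acetyl")
  expect_equal(classify_state(31.047208, "S", "F", "trypsin", chem), "monomethyl")
  expect_equal(classify_state(34.063117, "A", "R", "trypsin", chem), "free")
  # pyroGlu accepted only off-specificity and on Gln
  expect_equal(classify_state(-17.026549, "Q", "K", "trypsin", chem), "other")
  expect_equal(classify_state(-17.026549, "Q", "A", "trypsin", chem), "pyroGlu")
  expect_equal(classify_state(-17.026549, "A", "A", "trypsin", chem), "other")
  expect_equal(classify_state(-17.026549, "Q", "E", "gluC", chem), "other")
  expect_equal(classify_state(-17.026549, "Q", "K", "gluC", chem), "pyroGlu")
  # absent delta is uninterpretable
  expect_equal(classify_state(NA, "A", "R", "trypsin", chem), "other")
  # D2 chemistry moves the free/monomethyl windows
  d2 <- label_chemistry("D2")
  expect_equal(classify_state(32.056407, "A", "R", "trypsin", d2), "free")
  expect_equal(classify_state(30.043854, "A", "R", "trypsin", d2), "monomethyl")
  expect_equal(classify_state(34.063117, "A", "R", "trypsin", d2), "other")
})

test_that("tolerance windows behave as closed +/-tol intervals", {
  chem <- label_chemistry("CD2_13C")
  expect_equal(classify_state(42.010565 + 0.0049, "A", "V", "trypsin", chem),
               "acetyl")
  expect_equal(classify_state(42.010565 + 0.0051, "A", "V", "trypsin", chem),
               "other")
  expect_error(classify_state(0, "A", "V", "trypsin", chem, tol = 2),
               "overlap")
})

test_that("observations aggregate spectra by proteoform key with dual states kept apart", {
  proteome <- make_proteome(c("P1", "REV_P1"),
                            c("MASTKLVRGGWQNK", "KNQWGGRVLKTSAM"),
                            is_decoy = c(FALSE, TRUE))
  psms <- rbind(
    make_psm(peptide = "STKLVR", nterm_delta = 34.063117),   # free at 3
    make_psm(dataset_id = "DS2", peptide = "STKLVR",
             nterm_delta = 32.056407),                        # free at 3 (D2)
    make_psm(peptide = "STKLVR", nterm_delta = 42.010565),   # acetyl at 3
    make_psm(peptide = "MASTKLVR", nterm_delta = 42.010565,
             preceding_aa = "-")                              # acetyl at 1
  )
  obs <- enumerate_observations(psms, proteome,
                                c(DS1 = "CD2_13C", DS2 = "D2"))
  expect_equal(nrow(obs), 3L)
  dual <- obs[obs$start_index == 3, ]
  expect_setequal(dual$state, c("free", "acetyl"))
  free3 <- obs[obs$start_index == 3 & obs$state == "free", ]
  expect_equal(free3$n_spectra, 2L)
  expect_equal(free3$datasets, "DS1;DS2")
  expect_equal(obs$preceding_aa[obs$start_index == 1], "-")
  expect_equal(obs$preceding_aa[obs$start_index == 3], c("A", "A"))
  # mapping soundness: protein substring at the mapped interval is the peptide
  for (i in seq_len(nrow(obs))) {
    seqs <- setNames(proteome$sequence, proteome$accession)
    expect_equal(substr(seqs[[obs$accession[i]]], obs$start_index[i],
                        obs$start_index[i] + nchar(obs$peptide[i]) - 1L),
                 obs$peptide[i])
  }
})

test_that("unmapped and ambiguous peptides are dropped with counts logged", {
  proteome <- make_proteome("P1", "MAXTTTMAXTTT")
  psms <- rbind(
    make_psm(peptide = "MAXTT"),   # ambiguous (two occurrences)
    make_psm(peptide = "WWWWW"),   # unmapped
    make_psm(peptide = "TTTMAXTTT")
  )
  obs <- enumerate_observations(psms, proteome, c(DS1 = "CD2_13C"))
  expect_equal(nrow(obs), 1L)
  expect_equal(attr(obs, "dropped"), c(unmapped = 1L, ambiguous = 1L))
})

test_that("missing chemistry assignment for a dataset is an error", {
  proteome <- make_proteome("P1", "MASTKLVR")
  expect_error(
    enumerate_observations(make_psm(dataset_id = "DSX"), proteome,
                           c(DS1 = "CD2_13C")),
    "no chemistry assignment.*DSX")
})

test_that("start-index histogram uses the standard bins and conserves mass", {
  obs <- make_observations("P1", c(1, 1, 2, 5, 50, 120))
  h <- start_index_histogram(obs)
  expect_equal(h$bin, c("1", "2", "3-100", ">100"))
  expect_equal(h$count, c(2L, 1L, 2L, 1L))
  expect_equal(sum(h$fraction), 1)

  all1 <- start_index_histogram(make_observations(c("A", "B"), c(1, 1)))
  expect_equal(all1$fraction[all1$bin == "1"], 1)

  empty <- start_index_histogram(make_observations(character(), integer()))
  expect_equal(nrow(empty), 0L)
})

test_that("termini-per-protein counts dual-state positions as two proteoforms", {
  obs <- rbind(
    make_observations("P1", c(1, 20, 35)),
    make_observations("P2", 10, state = "acetyl"),
    make_observations("P2", 10, state = "free")
  )
  tab <- termini_per_protein(obs)
  expect_equal(tab$n_termini, c(2L, 3L))
  expect_equal(tab$n_proteins, c(1L, 1L))
  expect_equal(nrow(termini_per_protein(obs[0, ])), 0L)
})
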