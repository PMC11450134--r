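test_that("dif is signed start minus P1' and defined exactly on the window", {
  pred <- list(accession = "P1", signal_class = "cTP", p1_prime = 65L)
  obs <- function(s) list(accession = "P1", start_index = s, state = "free")
  expect_equal(compute_dif(obs(65), pred)$dif, 0L)
  expect_equal(compute_dif(obs(70), pred)$dif, 5L)
  expect_null(compute_dif(obs(71), pred))
  expect_equal(compute_dif(obs(60), pred)$dif, -5L)
  expect_null(compute_dif(obs(59), pred))
  # window symmetry over all integer starts
  hits <- vapply(1:130, function(s) !is.null(compute_dif(obs(s), pred)),
                 logical(1))
  expect_equal(which(hits), 60:70)
  expect_null(compute_dif(obs(65), list(accession = "P1",
                                        signal_class = "noTP",
                                        p1_prime = NA)))
})

test_that("offset records match an independent all-pairs oracle on random fixtures", {
  set.seed(99)
  for (rep in 1:5) {
    fx <- random_concordance_fixture(sample(10:50, 1))
    got <- offset_records(fx$observations, fx$predictions)
    want <- brute_force_offsets(fx$observations, fx$predictions)
    expect_equal(got, want)
  }
})

test_that("concordance counts conserve in-window records and fractions sum to 1", {
  set.seed(7)
  fx <- random_concordance_fixture(40)
  rec <- offset_records(fx$observations, fx$predictions)
  tab <- build_concordance(fx$observations, fx$predictions)
  expect_equal(sum(tab$count), nrow(rec))
  for (g in split(tab, paste(tab$signal_class, tab$stratum))) {
    expect_equal(sum(g$fraction), 1)
    expect_true(all(diff(g$cumulative_fraction) >= -1e-12))
    expect_equal(g$cumulative_fraction[nrow(g)], 1)
  }
  # unstratified view pools the same records
  pooled <- build_concordance(fx$observations, fx$predictions,
                              stratify_by_state = FALSE)
  expect_equal(sum(pooled$count), nrow(rec))
})

test_that("exact trimming at P1' concentrates the cTP class at dif 0", {
  accs <- sprintf("C%02d", 1:10)
  preds <- make_predictions(accs, "cTP", 40L)
  obs <- make_observations(accs, 40L)
  tab <- build_concordance(obs, preds)
  expect_equal(tab$fraction[tab$dif == 0], 1)
  expect_true(all(tab$count[tab$dif != 0] == 0))
})

test_that("per-class tables are independent (no cross-class leakage)", {
  preds <- make_predictions(c("A", "B"), c("cTP", "mTP"), c(30L, 50L))
  obs <- rbind(make_observations("A", 31), make_observations("B", 50))
  tab <- build_concordance(obs, preds)
  expect_equal(sum(tab$count[tab$signal_class == "cTP"]), 1L)
  expect_equal(sum(tab$count[tab$signal_class == "mTP"]), 1L)
  expect_equal(tab$count[tab$signal_class == "cTP" & tab$dif == 1], 1L)
  expect_equal(tab$count[tab$signal_class == "mTP" & tab$dif == 0], 1L)
})

test_that("confirmed cleavages count each protein once per class", {
  preds <- make_predictions(c("A", "B", "C"), c("mTP", "mTP", "mTP"),
                            c(30L, 30L, 30L))
  obs <- rbind(
    make_observations("A", c(28, 30, 33)),     # three in-window termini
    make_observations("B", 36),                # dif +6: not confirmed
    make_observations("C", 25)                 # dif -5: confirmed
  )
  conf <- confirmed_cleavages(obs, preds)
  expect_equal(conf$n_proteins[conf$signal_class == "mTP"], 2L)
})

test_that("duplicated predictions per accession are rejected", {
  preds <- rbind(make_predictions("A", "cTP", 30L),
                 make_predictions("A", "mTP", 40L))
  expect_error(offset_records(make_observations("A", 30), preds),
               "deduplicated")
})

test_that("state breakdown uses per-class confirmed denominators", {
  preds <- make_predictions(c("A", "B", "C", "D"), "cTP", 30L)
  obs <- rbind(
    make_observations("A", 30, state = "acetyl"),
    make_observations("A", 31, state = "free"),   # dual-state protein
    make_observations("B", 30, state = "acetyl"),
    make_observations("C", 32, state = "free")
  )
  rec <- offset_records(obs, preds)
  bd <- state_breakdown_at_sites(rec)
  expect_equal(bd$n_proteoforms[bd$state == "acetyl"], 2L)
  expect_equal(bd$n_proteoforms[bd$state == "free"], 2L)
  # 3 confirmed proteins; dual-state A contributes to both states
  expect_equal(bd$fraction_of_confirmed[bd$state == "acetyl"], 2 / 3)
  expect_equal(nrow(state_breakdown_at_sites(rec[0, ])), 0L)
})
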