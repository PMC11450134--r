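test_that("context windows align at the N-terminal residue with gap padding", {
  expect_equal(extract_context("MASTK", 3, width = 3), "ASTK")
  expect_equal(extract_context("MASTK", 1, width = 3), "-MAS")
  expect_equal(extract_context("MAST", 3, width = 4), "AST--")
  expect_equal(nchar(extract_context("MASTKLVR", 2, width = 10)), 11L)
})

test_that("PFM dedupes window strings and excludes gaps from column sums", {
  proteome <- make_proteome(c("P1", "P2", "P3"),
                            c("MASTKL", "MASTKL", "MGLYWW"))
  obs <- make_observations(c("P1", "P2", "P3"), c(2, 2, 2))
  pfm <- build_pfm(obs, proteome, width = 3)
  # P1 and P2 give identical windows -> deduped to 2 sequences
  expect_equal(pfm$n, 2L)
  expect_equal(unname(pfm$counts["A", "+1"]), 1L)
  expect_equal(unname(pfm$counts["G", "+1"]), 1L)
  expect_equal(unname(colSums(pfm$counts)), rep(2L, 4L))

  nodedupe <- build_pfm(obs, proteome, width = 3, dedupe = FALSE)
  expect_equal(nodedupe$n, 3L)

  # idempotence: rebuilding from the same selection gives identical matrices
  expect_identical(pfm$counts, build_pfm(obs, proteome, width = 3)$counts)
})

test_that("column sums equal contributors when no window hits a protein edge", {
  set.seed(5)
  proteome <- make_proteome(sprintf("P%02d", 1:20),
                            replicate(20, random_protein(60)))
  obs <- make_observations(proteome$accession, sample(10:40, 20, TRUE))
  pfm <- build_pfm(obs, proteome, width = 10, dedupe = FALSE)
  expect_true(all(colSums(pfm$counts) == pfm$n))
})

test_that("PFM counts equal an independent brute-force letter tally", {
  set.seed(31)
  proteome <- make_proteome(sprintf("P%03d", 1:100),
                            replicate(100, random_protein(80)))
  obs <- make_observations(proteome$accession, sample(1:60, 100, TRUE))
  width <- 8L
  pfm <- build_pfm(obs, proteome, width = width, dedupe = FALSE)
  # oracle: per-position letter tally over explicitly built windows
  seqs <- setNames(proteome$sequence, proteome$accession)
  wins <- character(0)
  for (i in seq_len(nrow(obs))) {
    s <- obs$start_index[i]; sq <- seqs[[obs$accession[i]]]
    p1 <- if (s == 1) "-" else substr(sq, s - 1, s - 1)
    w <- substr(sq, s, s + width - 1)
    w <- paste0(w, strrep("-", width - nchar(w)))
    wins <- c(wins, paste0(p1, w))
  }
  oracle <- matrix(0L, nrow = nrow(pfm$counts), ncol = width + 1,
                   dimnames = dimnames(pfm$counts))
  for (w in wins) {
    ch <- strsplit(w, "")[[1]]
    for (j in seq_along(ch)) {
      if (ch[j] != "-") oracle[ch[j], j] <- oracle[ch[j], j] + 1L
    }
  }
  expect_identical(pfm$counts, oracle)
})

test_that("state and dif filters select the intended observations", {
  proteome <- make_proteome(c("A", "B"), c("MASTKLVRGG", "MGGYWKLVRG"))
  obs <- rbind(make_observations("A", 3, state = "acetyl"),
               make_observations("B", 5, state = "free"))
  preds <- make_predictions(c("A", "B"), "cTP", c(3L, 3L))
  offs <- offset_records(obs, preds)
  pfm_acetyl <- build_pfm(obs, proteome, state_filter = "acetyl", width = 3)
  expect_equal(pfm_acetyl$n, 1L)
  expect_equal(pfm_acetyl$windows, "ASTK")
  pfm_dif0 <- build_pfm(obs, proteome, dif_filter = 0L, width = 3,
                        offsets = offs)
  expect_equal(pfm_dif0$windows, "ASTK")
  expect_error(build_pfm(obs, proteome, dif_filter = 0L), "offset records")
  empty <- build_pfm(obs, proteome, state_filter = "pyroGlu", width = 3)
  expect_equal(empty$n, 0L)
  expect_true(all(empty$counts == 0L))
})
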