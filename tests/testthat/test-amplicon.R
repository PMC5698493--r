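fwd <- "ACTGGCCTAGCGAATTCGG"
rev <- "TTGCAGGCATCCAATGCAT"

test_that("primer dereplication keeps, trims and orients reads", {
  set.seed(91)
  insert <- random_dna(150, 0.5)
  read_f <- paste0(fwd, insert)
  read_rc <- revcomp(read_f)
  junk <- random_dna(170, 0.5)
  out <- dereplicate_primers(c(a = read_f, b = read_rc, c = junk), fwd, rev)
  expect_identical(out$discarded, 1L)
  expect_identical(names(out$inserts), c("a", "b"))
  # both orientations give the identical oriented insert
  expect_identical(as.character(out$inserts[["a"]]),
                   as.character(out$inserts[["b"]]))
  expect_identical(as.character(out$inserts[["a"]]), insert)
})

test_that("the reverse-primer tail is trimmed when present", {
  set.seed(92)
  insert <- random_dna(120, 0.5)
  read <- paste0(fwd, insert, revcomp(rev))
  out <- dereplicate_primers(c(r = read), fwd, rev)
  expect_identical(as.character(out$inserts[[1L]]), insert)
})

test_that("exact substrings classify as cluster and sub-threshold identity does not", {
  set.seed(93)
  ref <- random_dna(1200, 0.5)
  exact <- substring(ref, 101, 300)
  # 4% of sites substituted: identity ~0.96 over a full-length alignment
  diverged <- strsplit(substring(ref, 401, 600), NULL)[[1L]]
  idx <- seq(5, 200, by = 25)
  for (i in idx) diverged[i] <- setdiff(c("A", "C", "G", "T"), diverged[i])[1L]
  diverged <- paste(diverged, collapse = "")
  cls <- classify_against_cluster(c(hit = exact, miss = diverged), ref)
  expect_identical(cls$reads$label, c("cluster", "other"))
  expect_equal(cls$reads$identity[1L], 1)
  expect_lt(cls$reads$identity[2L], 0.97)
  expect_error(classify_against_cluster(character(0), ref), "empty")
})

test_that("raising the identity threshold never increases the cluster count", {
  set.seed(94)
  ref <- random_dna(800, 0.5)
  asim <- simulate_amplicons(ref, 0.5, 200, error_rate = 0.02,
                             read_length = 150, seed = 94)
  counts <- vapply(c(0.90, 0.95, 0.97, 0.99), function(thr) {
    cls <- classify_against_cluster(asim$reads, ref, min_identity = thr)
    sum(cls$reads$label == "cluster")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("a small mixture is recovered near its simulated fraction", {
  set.seed(95)
  ref <- random_dna(700, 0.5)
  asim <- simulate_amplicons(ref, 0.7, 1000, error_rate = 0.01,
                             read_length = 200, seed = 95)
  cls <- classify_against_cluster(asim$reads, ref)
  se <- sqrt(0.7 * 0.3 / 1000)
  expect_lt(abs(cls$cluster_fraction - 0.7), 3 * se + 0.01)
  expect_gte(cls$cluster_fraction, 0)
  expect_lte(cls$cluster_fraction, 1)
})

test_that("trans-AT flags follow the top-n accession rule", {
  hits <- data.frame(read = c("r1", "r2", "r2", "r3"),
                     accession = c("TAT1", "X1", "TAT2", "Y1"),
                     rank = c(1L, 1L, 501L, 1L))
  flags <- classify_transat(hits, c("TAT1", "TAT2"), top_n = 500,
                            read_ids = c("r1", "r2", "r3", "r4"))
  expect_identical(unname(flags), c(TRUE, FALSE, FALSE, FALSE))
})

test_that("combined labels partition the classified reads", {
  set.seed(96)
  ref <- random_dna(600, 0.5)
  asim <- simulate_amplicons(ref, 0.5, 60, read_length = 150, seed = 96)
  cls <- classify_against_cluster(asim$reads, ref)
  others <- cls$reads$read[cls$reads$label == "other"]
  hits <- data.frame(read = others[1], accession = "TAT1", rank = 1L)
  flags <- classify_transat(hits, "TAT1", read_ids = cls$reads$read)
  cmb <- combine_amplicon_labels(cls, flags)
  expect_true(all(cmb$reads$label %in% c("cluster", "trans-AT-other",
                                         "other")))
  expect_identical(cmb$reads$label[cmb$reads$read == others[1]],
                   "trans-AT-other")
  expect_identical(sum(cmb$reads$label == "cluster"),
                   sum(cls$reads$label == "cluster"))
})
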