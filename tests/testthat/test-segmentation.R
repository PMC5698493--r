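test_that("a uniform profile at baseline yields one single-copy segment", {
  prof <- make_profile(rep(30, 40))
  model <- segment_and_round(prof, 30)
  expect_identical(nrow(model$segments), 1L)
  expect_identical(model$segments$copy, 1L)
})

test_that("step profiles spanning tiers 3x-8x are recovered as integer tiers", {
  set.seed(51)
  tiers <- 3:8
  # window means of 500-bp windows at 30x baseline: a few percent of
  # relative noise, far less than one copy-number step
  depths <- unlist(lapply(tiers, function(t) rnorm(10, t * 30, 3)))
  prof <- make_profile(depths)
  model <- segment_and_round(prof, 30)
  expect_identical(model$segments$copy, tiers)
})

test_that("segmentation of a noisy two-step profile matches exhaustive change-point search", {
  set.seed(52)
  d <- c(rnorm(25, 30, 1.5), rnorm(25, 90, 2.5))
  prof <- make_profile(d)
  model <- segment_and_round(prof, 30)
  expect_identical(nrow(model$segments), 2L)
  cp <- bf_changepoint(d)  # last window of the left segment
  expect_identical(model$segments$end[1L], prof$end[cp])
})

test_that("short noisy segments merge into the closer neighbour", {
  d <- c(rep(30, 20), 75, rep(30, 20))  # lone outlier window
  model <- segment_and_round(make_profile(d), 30)
  expect_identical(nrow(model$segments), 1L)
  expect_identical(model$segments$copy, 1L)
})

test_that("deletion-carrier arithmetic follows the coverage difference", {
  expect_identical(deletion_carriers(5, 7), 2L)
  expect_identical(deletion_carriers(4, 4), 0L)
  expect_identical(deletion_carriers(0, 7), 7L)
  expect_error(deletion_carriers(8, 7), "exceeds")
  expect_error(deletion_carriers(-1, 7), "nonnegative")
})

test_that("expansion with all copies at 1 conserves the assembly length", {
  set.seed(53)
  for (rep in 1:5) {
    n <- sample(2:6, 1)
    bounds <- sort(sample(1:10000, n - 1))
    seg <- data.frame(contig = "c", start = c(1, bounds + 1),
                      end = c(bounds, 10000), copy = 1L)
    expect_equal(expand_genome(seg), 10000)
  }
})

test_that("expansion multiplies segment lengths by copy numbers", {
  seg <- data.frame(contig = "c", start = c(1, 1001), end = c(1000, 1100),
                    copy = c(1L, 7L))
  expect_equal(expand_genome(seg), 1700)
})

test_that("inferred copy number is monotone in the simulated copy number", {
  set.seed(54)
  inferred <- vapply(2:6, function(k) {
    d <- c(rnorm(20, 30, 1), rnorm(20, k * 30, 2), rnorm(20, 30, 1))
    model <- segment_and_round(make_profile(d), 30)
    max(model$segments$copy)
  }, integer(1))
  expect_identical(inferred, 2:6)
  expect_true(all(diff(inferred) >= 0))
})

test_that("copy number, carriers and intact size are recovered across configurations", {
  cases <- data.frame(k = c(3L, 7L, 5L), carriers = c(1L, 2L, 0L))
  ok <- 0L; total <- 0L
  for (ci in seq_len(nrow(cases))) {
    k <- cases$k[ci]; carriers <- cases$carriers[ci]
    dels <- if (carriers > 0L) {
      data.frame(offset = 2001L, length = 2000L, carriers = carriers)
    } else NULL
    for (seed in 1:4) {
      cfg <- sim_config(genome_length = 30000 + k * 6000,
                        cluster_length = 6000, n_copies = k,
                        deletions = dels, baseline_depth = 25, seed = seed)
      sim <- build_genome(cfg)
      aln <- simulate_reads(sim)
      prof <- compute_depth(aln, sim$collapsed)
      bl <- estimate_baseline(prof, c("unique_left", "unique_right"))
      model <- suppressWarnings(segment_and_round(prof, bl))
      cl <- model$segments[model$segments$contig == "cluster", ]
      k_hat <- max(cl$copy)
      car_hat <- if (nrow(cl) > 1L) k_hat - min(cl$copy) else 0L
      total <- total + 1L
      if (k_hat == k && car_hat == carriers &&
          expand_genome(model) == sim$truth$intact_length) ok <- ok + 1L
    }
  }
  expect_gte(ok / total, 0.95)
})
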