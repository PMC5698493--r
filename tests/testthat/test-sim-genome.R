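test_that("a single-copy configuration reproduces the cluster exactly once", {
  cfg <- sim_config(genome_length = 30000, cluster_length = 5000,
                    n_copies = 1, deletions = NULL, seed = 5)
  sim <- build_genome(cfg)
  hits <- Biostrings::countPattern(sim$collapsed[["cluster"]], sim$intact)
  expect_identical(hits, 1L)
  seg <- sim$truth$segments
  expect_true(all(seg$copy[seg$contig == "cluster"] == 1L))
  expect_identical(sim$truth$intact_length, sim$truth$collapsed_length)
})

test_that("with no deletions the truth set has no carriers and no internal junctions", {
  cfg <- sim_config(genome_length = 60000, cluster_length = 5000,
                    n_copies = 3, deletions = NULL, seed = 2)
  sim <- build_genome(cfg)
  expect_identical(nrow(sim$truth$deletion_carriers), 0L)
  # internal breakpoint endpoints carry a coordinate (three-part names)
  ep <- c(sim$truth$junctions$endpoint_a, sim$truth$junctions$endpoint_b)
  expect_false(any(lengths(strsplit(ep, ":")) == 3L))
})

test_that("a seeded 7-copy genome contains an unmutated cluster tag exactly 7 times", {
  sim <- build_genome(sim_config(seed = 42))
  # a 1-kb tag clear of the configured deletion (offset 8001..10000)
  tag <- Biostrings::subseq(sim$collapsed[["cluster"]], 1, 1000)
  expect_identical(Biostrings::countPattern(tag, sim$intact), 7L)
})

test_that("intact length equals collapsed length plus extra-copy contributions", {
  cfg <- sim_config(genome_length = 100000, cluster_length = 10000,
                    n_copies = 4,
                    deletions = data.frame(offset = c(2001, 6001),
                                           length = c(1000, 500),
                                           carriers = c(2, 3)),
                    seed = 8)
  sim <- build_genome(cfg)
  # sum over copies 2..k of (cluster_length - deleted bases in that copy)
  extra <- 0L
  for (i in 2:4) {
    carried <- cfg$deletions$length[i <= 1L + cfg$deletions$carriers]
    extra <- extra + cfg$cluster_length - sum(carried)
  }
  expect_equal(sim$truth$intact_length,
               sim$truth$collapsed_length + extra)
  # segment bookkeeping agrees with the same total
  seg <- sim$truth$segments
  expect_equal(sum((seg$end - seg$start + 1) * seg$copy),
               sim$truth$intact_length)
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- sim_config(genome_length = 40000, cluster_length = 4000,
                    n_copies = 2, deletions = NULL, seed = 99)
  a <- build_genome(cfg)
  b <- build_genome(cfg)
  expect_identical(as.character(a$intact), as.character(b$intact))
  expect_identical(a$truth, b$truth)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(genome_length = 50000, cluster_length = 10000,
                          n_copies = 6, deletions = NULL),
               "configuration error")
  expect_error(sim_config(genome_length = 60000, cluster_length = 5000,
                          n_copies = 2,
                          deletions = data.frame(offset = 1, length = 1000,
                                                 carriers = 2)),
               "n_carrier_copies")
  expect_error(sim_config(genome_length = 60000, cluster_length = 5000,
                          n_copies = 2,
                          deletions = data.frame(offset = 4500, length = 1000,
                                                 carriers = 1)),
               "fit inside")
  expect_error(sim_config(read_length = 200, insert_mean = 300,
                          insert_sd = 10, deletions = NULL),
               "insert")
})

test_that("an inverted copy produces tail-to-tail and head-to-head junctions", {
  cfg <- sim_config(genome_length = 50000, cluster_length = 5000,
                    n_copies = 2, deletions = NULL,
                    inverted_copies = 2L, seed = 4)
  sim <- build_genome(cfg)
  expect_true("tail-to-tail" %in% sim$truth$junctions$orientation)
  expect_true("head-to-head" %in% sim$truth$junctions$orientation)
})
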