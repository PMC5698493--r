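test_that("equal codon usage gives RSCU 1 in every family", {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  cds <- Biostrings::DNAStringSet(c(all = paste(sense, collapse = "")))
  tab <- rscu(cds)
  expect_true(all(abs(tab$rscu - 1) < 1e-12))
  w <- relative_adaptiveness(tab)
  expect_true(all(abs(w$w - 1) < 1e-12))
})

test_that("a 10:0 two-fold family follows the pseudo-count arithmetic", {
  tab <- rscu(Biostrings::DNAStringSet(c(g = strrep("AAA", 10))))
  k <- tab[tab$aa == "K", ]
  expect_equal(k$rscu[k$codon == "AAA"], 10 / (10.5 / 2), tolerance = 1e-12)
  expect_equal(k$rscu[k$codon == "AAG"], 0.5 / (10.5 / 2), tolerance = 1e-12)
  expect_equal(round(k$rscu[k$codon == "AAA"], 3), 1.905)
  expect_equal(round(k$rscu[k$codon == "AAG"], 3), 0.095)
  w <- relative_adaptiveness(tab)
  kw <- w[w$aa == "K", ]
  expect_equal(kw$w[kw$codon == "AAA"], 1)
  expect_equal(round(kw$w[kw$codon == "AAG"], 3), 0.05)
})

test_that("RSCU is invariant to duplicating the input gene", {
  # duplication invariance holds when no pseudo-count fires inside an
  # observed family, so the gene covers its families completely
  gene <- paste0("ATGTGG", "AAAAAG", "GATGAC", "TGTTGC", "CAACAG")
  one <- rscu(Biostrings::DNAStringSet(gene))
  two <- rscu(Biostrings::DNAStringSet(c(gene, gene)))
  expect_equal(one$rscu, two$rscu)
})

test_that("frame errors and internal stops are flagged", {
  expect_error(rscu(Biostrings::DNAStringSet(c(bad = "ATGAA"))), "bad")
  expect_warning(rscu(Biostrings::DNAStringSet(c(g = "ATGTAAATG"))),
                 "internal stop")
})

test_that("CAI closed forms hold", {
  ref <- Biostrings::DNAStringSet(c(r = strrep("GGTGCTCGT", 5)))
  w <- relative_adaptiveness(rscu(ref))
  expect_equal(unname(cai(Biostrings::DNAStringSet(c(g = "GGTGCTCGTGGT")), w)),
               1)
  wv <- c(GGT = 1, GGG = 0.25)
  expect_equal(unname(cai("GGTGGG", wv)), 0.5)
  # ATG, TGG and stops are excluded from the geometric mean
  expect_equal(unname(cai("ATGGGTTGGTAA", w)), 1)
  expect_error(cai("ATGTGG", w), "countable")
})

test_that("genes drawn from the reference usage have higher CAI than uniform genes", {
  cfg <- sim_config(seed = 83)
  ref_cds <- simulate_gene_models(cfg, c(r = 60000), n_genes = 30,
                                  seed = 83)$cds
  w <- relative_adaptiveness(rscu(ref_cds))
  biased <- simulate_gene_models(cfg, c(b = 60000), n_genes = 30, w = w,
                                 seed = 84)$cds
  uniform <- simulate_gene_models(cfg, c(u = 60000), n_genes = 30,
                                  seed = 85)$cds
  expect_gt(mean(cai(biased, w)), mean(cai(uniform, w)))
})

test_that("CAI stays in (0, 1] across random gene sets", {
  cfg <- sim_config(seed = 86)
  gm <- simulate_gene_models(cfg, c(x = 80000), n_genes = 40, seed = 86)
  w <- relative_adaptiveness(rscu(gm$cds))
  vals <- cai(gm$cds, w)
  expect_true(all(vals > 0 & vals <= 1))
})

test_that("two-group comparison reduces to the squared t statistic", {
  set.seed(87)
  x <- c(rnorm(10, 0.5, 0.05), rnorm(12, 0.6, 0.05))
  g <- rep(c("a", "b"), c(10, 12))
  cmp <- compare_cai_categories(x, g)
  tt <- t.test(x ~ g, var.equal = TRUE)
  expect_equal(cmp$anova_f, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(cmp$anova_p, tt$p.value, tolerance = 1e-10)
})

test_that("three-group ANOVA matches the hand-computed mean squares", {
  vals <- list(a = c(0.42, 0.48, 0.45, 0.51), b = c(0.55, 0.60, 0.58),
               c = c(0.70, 0.66, 0.68, 0.72, 0.69))
  x <- unlist(vals, use.names = FALSE)
  g <- rep(names(vals), lengths(vals))
  # manual between/within mean squares
  gm <- mean(x)
  ssb <- sum(lengths(vals) * (vapply(vals, mean, 0) - gm)^2)
  ssw <- sum(unlist(lapply(vals, function(v) (v - mean(v))^2)))
  f_manual <- (ssb / 2) / (ssw / (length(x) - 3))
  cmp <- compare_cai_categories(x, g)
  expect_equal(cmp$anova_f, f_manual, tolerance = 1e-10)
  expect_identical(nrow(cmp$tukey), 3L)
  expect_true(all(cmp$tukey$p_adj >= 0 & cmp$tukey$p_adj <= 1))
})

test_that("identical constant groups give a zero F statistic", {
  cmp <- compare_cai_categories(rep(0.5, 12), rep(c("a", "b", "c"), 4))
  expect_equal(cmp$anova_f, 0)
  expect_error(compare_cai_categories(c(1, 2), c("a", "b")), "two groups")
})
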