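hits3 <- data.frame(
  query = c(rep("g1", 4), rep("g2", 3)),
  subject = c("NR_a", "NR_b", "REF_x", "NR_c", "NR_d", "NR_e", "REF_y"),
  rank = c(1L, 2L, 3L, 4L, 1L, 2L, 101L),
  bitscore = c(400, 390, 380, 370, 300, 290, 50),
  subject_length = c(500, 480, 450, 440, 300, 310, 280),
  stringsAsFactors = FALSE)

test_that("a reference hit within the rank window wins the assignment", {
  asg <- assign_best_homolog(hits3, c("REF_x", "REF_y"), top_k = 100)
  g1 <- asg[asg$gene == "g1", ]
  expect_identical(g1$subject, "REF_x")
  expect_identical(g1$category, "homolog-in-reference")
})

test_that("a reference hit beyond the window falls back to the best overall hit", {
  asg <- assign_best_homolog(hits3, c("REF_x", "REF_y"), top_k = 100)
  g2 <- asg[asg$gene == "g2", ]
  expect_identical(g2$subject, "NR_d")
  expect_identical(g2$category, "hit-in-database")
})

test_that("genes absent from the table are categorised no-hit", {
  asg <- assign_best_homolog(hits3, "REF_x", queries = c("g1", "g2", "g3"))
  expect_identical(asg$category[asg$gene == "g3"], "no-hit")
})

test_that("pseudogene calling is a strict 20% truncation rule", {
  expect_identical(call_pseudogene(700, 1000), TRUE)
  expect_identical(call_pseudogene(800, 1000), FALSE)   # exactly 80%: intact
  expect_identical(call_pseudogene(c(799, 801), c(1000, 1000)),
                   c(TRUE, FALSE))
  expect_error(call_pseudogene(0, 1000), "positive")
  # monotone in the length ratio
  ratios <- seq(0.5, 1.1, by = 0.05)
  calls <- call_pseudogene(ratios * 1000, 1000)
  expect_true(all(diff(as.integer(calls)) <= 0))
})

test_that("calls on a labelled synthetic gene set match the truth exactly", {
  cfg <- sim_config(seed = 73)
  gm <- simulate_gene_models(cfg, c(c1 = 150000, c2 = 150000),
                             n_genes = 100)
  refs <- unique(grep("^REF_", gm$hits$subject, value = TRUE))
  asg <- assign_best_homolog(gm$hits, refs, queries = gm$genes$id)
  with_hit <- asg$category != "no-hit"
  calls <- call_pseudogene(gm$truth$aa_length[with_hit],
                           asg$subject_length[with_hit])
  expect_identical(unname(calls), gm$truth$pseudogene[with_hit])
})

test_that("category table complements merged gene spans into intergenic intervals", {
  genes <- data.frame(id = c("a", "b"), contig = "ctg",
                      start = c(201L, 401L), end = c(500L, 700L),
                      gc = c(0.5, 0.6),
                      category = c("homolog-in-reference", "no-hit"))
  tab <- category_table(genes, c(ctg = 1000))
  inter <- tab[tab$category == "intergenic", ]
  # merged gene span 201-700 leaves gaps 1-200 and 701-1000
  expect_identical(inter$n, 2L)
  expect_equal(inter$avg_length, 250)
  # coding + intergenic = contig length
  gene_span <- 500
  expect_equal(gene_span + inter$n * inter$avg_length, 1000)
  # empty category reports n = 0 with NA means
  hd <- tab[tab$category == "hit-in-database", ]
  expect_identical(hd$n, 0L)
  expect_true(is.na(hd$avg_length))
})

test_that("single-gene contigs give the closed-form intergenic mean", {
  genes <- data.frame(id = "a", contig = "ctg", start = 301L, end = 600L,
                      gc = 0.5, category = "no-hit")
  tab <- category_table(genes, c(ctg = 1000))
  inter <- tab[tab$category == "intergenic", ]
  expect_equal(inter$avg_length, (1000 - 300) / 2)
})

test_that("coding density merges overlapping genes before measuring", {
  genes <- data.frame(contig = "c", start = c(1L, 301L), end = c(400L, 600L))
  cd <- coding_density(data.frame(contig = "c", start = 1L, end = 1000L),
                       genes)
  expect_equal(cd$percent_coding, 60)
  expect_equal(cd$percent_coding * 10,
               bf_union_length(genes$start, genes$end))
  full <- coding_density(data.frame(contig = "c", start = 1L, end = 400L),
                         genes[1, ])
  expect_equal(full$percent_coding, 100)
  none <- coding_density(data.frame(contig = "c", start = 700L, end = 900L),
                         genes)
  expect_equal(none$percent_coding, 0)
  expect_error(
    coding_density(data.frame(contig = "c", start = 1L, end = 2000L),
                   genes, contigs = c(c = 1000)),
    "outside")
})

test_that("category tables round-trip through TSV", {
  genes <- data.frame(id = letters[1:3], contig = "ctg",
                      start = c(101L, 501L, 801L), end = c(300L, 700L, 950L),
                      gc = c(0.5, 0.55, 0.45),
                      category = c("homolog-in-reference", "hit-in-database",
                                   "no-hit"))
  tab <- category_table(genes, c(ctg = 1200))
  tf <- tempfile(fileext = ".tsv")
  write.table(tab, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read.delim(tf, stringsAsFactors = FALSE)
  expect_equal(back$avg_length, tab$avg_length)
  expect_identical(back$n, tab$n)
  expect_identical(back$category, tab$category)
})
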