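#' Simulate gene models, coding sequences and a homolog hit table
#'
#' Emits a gene set with known pseudogene labels for validating the
#' homolog-truncation pseudogene caller and the codon-adaptation
#' analysis. Each gene is conceived as a full-length "homolog" protein
#' of 150-500 aa; a configurable fraction are truncated by a fraction
#' drawn uniformly from `truncation_range` (these are the labelled
#' pseudogenes), while intact genes keep 85-105% of the homolog
#' length. Coding sequences are sampled codon-by-codon, with per-family
#' codon probabilities proportional to a supplied relative-adaptiveness
#' table (uniform within families when none is given). A ranked hit
#' table accompanies the genes: for a configurable fraction the
#' reference-genome subject appears within the rank window (category
#' `homolog-in-reference`), some genes only hit other database subjects
#' and some have no hit at all.
#'
#' @param config A [sim_config()]; `pseudogene_fraction`,
#'   `truncation_range` and `seed` are used.
#' @param contigs Named vector of contig lengths on which to place the
#'   genes (non-overlapping, left to right with short intergenic gaps).
#' @param n_genes Number of genes to attempt to place (placement stops
#'   when a contig runs out of room).
#' @param w Optional `codon_usage` table with a `w` column biasing
#'   codon choice (see [relative_adaptiveness()]).
#' @param ref_fraction Fraction of genes with a reference homolog
#'   (default 0.7); a further `nohit_fraction` (default 0.15) of genes
#'   have no hit at all.
#' @param nohit_fraction Fraction of genes without any database hit.
#' @param seed Integer seed (default derived from the configuration).
#' @return List of class `bgc_genes`: `genes` (id, contig, start, end,
#'   strand, length, gc, category), `cds`
#'   ([Biostrings::DNAStringSet], named by gene id; genes with
#'   category `no-hit` included), `hits` (query, subject, rank,
#'   bitscore, subject_length in aa), `truth` (id, pseudogene,
#'   length_ratio, aa_length, homolog_aa_length).
#' @export
simulate_gene_models <- function(config, contigs, n_genes = 120L,
                                 w = NULL, ref_fraction = 0.7,
                                 nohit_fraction = 0.15,
                                 seed = config$seed + 2L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  lens <- contig_lengths_of(contigs)

  homolog_aa <- sample(150:500, n_genes, replace = TRUE)
  pseudo <- runif(n_genes) < config$pseudogene_fraction
  trunc_frac <- runif(n_genes, config$truncation_range[1L],
                      config$truncation_range[2L])
  ratio <- ifelse(pseudo, 1 - trunc_frac, runif(n_genes, 0.85, 1.05))
  gene_aa <- pmax(30L, as.integer(round(homolog_aa * ratio)))

  cds <- sample_cds(gene_aa, w)

  # place genes left-to-right across the contigs
  placed <- place_genes(gene_aa * 3L, lens)
  n <- nrow(placed)
  if (n < n_genes) {
    warning(sprintf("placed %d of %d genes before running out of contig space",
                    n, n_genes))
    pseudo <- pseudo[seq_len(n)]; ratio <- ratio[seq_len(n)]
    gene_aa <- gene_aa[seq_len(n)]; homolog_aa <- homolog_aa[seq_len(n)]
    cds <- cds[seq_len(n)]
  }
  ids <- sprintf("gene_%04d", seq_len(n))
  names(cds) <- ids

  u <- runif(n)
  category <- ifelse(u < nohit_fraction, "no-hit",
                     ifelse(u < nohit_fraction + (1 - nohit_fraction) *
                              (1 - ref_fraction),
                            "hit-in-database", "homolog-in-reference"))

  genes <- data.frame(id = ids, contig = placed$contig,
                      start = placed$start, end = placed$end,
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      length = gene_aa * 3L,
                      gc = gc_fraction(as.character(cds)),
                      category = category, stringsAsFactors = FALSE)

  hits <- make_hit_table(ids, category, homolog_aa)

  truth <- data.frame(id = ids, pseudogene = pseudo,
                      length_ratio = gene_aa / homolog_aa,
                      aa_length = gene_aa, homolog_aa_length = homolog_aa,
                      stringsAsFactors = FALSE)
  structure(list(genes = genes, cds = cds, hits = hits, truth = truth),
            class = "bgc_genes")
}

# sample in-frame coding sequences codon-by-codon; codon probabilities
# within each synonymous family follow w when supplied
sample_cds <- function(aa_lengths, w = NULL) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  aa_of <- code[sense]
  prob <- rep(1, length(sense))
  names(prob) <- sense
  if (!is.null(w)) {
    stopifnot(is.data.frame(w), "w" %in% names(w))
    prob[w$codon] <- w$w
  }
  aas <- unique(aa_of)
  Biostrings::DNAStringSet(vapply(aa_lengths, function(la) {
    aa_seq <- sample(aas, la, replace = TRUE)
    paste(vapply(aa_seq, function(a) {
      fam <- sense[aa_of == a]
      if (length(fam) == 1L) fam else sample(fam, 1L, prob = prob[fam])
    }, ""), collapse = "")
  }, ""))
}

place_genes <- function(widths, lens) {
  rows <- list()
  ci <- 1L
  pos <- 1L
  ctgs <- names(lens)
  for (i in seq_along(widths)) {
    gap <- sample(50:400, 1L)
    while (ci <= length(ctgs) &&
           pos + gap + widths[i] - 1L > lens[[ctgs[ci]]]) {
      ci <- ci + 1L
      pos <- 1L
    }
    if (ci > length(ctgs)) break
    start <- pos + gap
    rows[[length(rows) + 1L]] <- data.frame(contig = ctgs[ci],
                                            start = start,
                                            end = start + widths[i] - 1L,
                                            stringsAsFactors = FALSE)
    pos <- start + widths[i]
  }
  if (!length(rows)) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0)))
  }
  do.call(rbind, rows)
}

# ranked hit table: reference subject at a random rank within the top-k
# window for homolog-in-reference genes, decoy NR subjects elsewhere
make_hit_table <- function(ids, category, homolog_aa, top_k = 100L) {
  rows <- list()
  for (i in seq_along(ids)) {
    if (category[i] == "no-hit") next
    n_hits <- sample(1:5, 1L)
    ref_rank <- NA_integer_
    if (category[i] == "homolog-in-reference") {
      ref_rank <- sample(seq_len(min(n_hits, 5L)), 1L)
    }
    for (r in seq_len(n_hits)) {
      is_ref <- !is.na(ref_rank) && r == ref_rank
      rows[[length(rows) + 1L]] <- data.frame(
        query = ids[i],
        subject = if (is_ref) sprintf("REF_%s", ids[i])
                  else sprintf("NR_%s_%d", ids[i], r),
        rank = r,
        bitscore = round(500 - 30 * (r - 1L) + runif(1L, -5, 5), 1L),
        subject_length = if (is_ref || r == 1L) homolog_aa[i]
                         else as.integer(round(homolog_aa[i] *
                                                 runif(1L, 0.9, 1.1))),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write a homolog hit table to TSV
#' @param hits Hit table (`query`, `subject`, `rank`, `bitscore`,
#'   `subject_length`).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_hit_table <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a homolog hit table from TSV
#' @param path Path to a TSV written by [write_hit_table()].
#' @return The hit table `data.frame`.
#' @export
read_hit_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
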