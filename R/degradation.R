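#' Assign each gene its best homolog from a ranked hit table
#'
#' For each query gene the hit table (sorted by rank within query) is
#' scanned: the first hit with rank at most `top_k` whose subject
#' belongs to `reference_accessions` wins and the gene is categorised
#' `homolog-in-reference`; otherwise the overall best hit is used
#' (category `hit-in-database`). Ties at the best rank are broken by
#' highest bitscore, then longest subject, then lexicographic subject
#' id. Genes absent from the table receive category `no-hit`.
#'
#' @param hits `data.frame` with columns `query`, `subject`, `rank`,
#'   `bitscore`, `subject_length`. Malformed rows (NA rank or subject)
#'   are skipped with a warning.
#' @param reference_accessions Character vector of subject accessions
#'   belonging to the reference genome.
#' @param top_k Rank window for the reference search (default 100).
#' @param queries Optional character vector of all gene ids, so genes
#'   without any hit appear with category `no-hit`.
#' @return `data.frame` with columns `gene`, `subject`,
#'   `subject_length`, `rank`, `bitscore`, `category`.
#' @export
assign_best_homolog <- function(hits, reference_accessions, top_k = 100L,
                                queries = NULL) {
  bad <- is.na(hits$rank) | is.na(hits$subject) | hits$subject == ""
  if (any(bad)) {
    warning(sprintf("skipping %d malformed hit-table row(s)", sum(bad)))
    hits <- hits[!bad, , drop = FALSE]
  }
  per_query <- split(hits, hits$query)
  rows <- lapply(names(per_query), function(q) {
    h <- per_query[[q]]
    h <- h[order(h$rank, -h$bitscore, -h$subject_length, h$subject), ,
           drop = FALSE]
    ref <- h[h$rank <= top_k & h$subject %in% reference_accessions, ,
             drop = FALSE]
    if (nrow(ref)) {
      pick <- ref[1L, ]; cat_ <- "homolog-in-reference"
    } else {
      pick <- h[1L, ]; cat_ <- "hit-in-database"
    }
    data.frame(gene = q, subject = pick$subject,
               subject_length = pick$subject_length, rank = pick$rank,
               bitscore = pick$bitscore, category = cat_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(queries)) {
    missing <- setdiff(queries, out$gene)
    if (length(missing)) {
      out <- rbind(out, data.frame(gene = missing, subject = NA_character_,
                                   subject_length = NA_real_,
                                   rank = NA_integer_, bitscore = NA_real_,
                                   category = "no-hit",
                                   stringsAsFactors = FALSE))
    }
    out <- out[match(queries, out$gene), ]
  }
  rownames(out) <- NULL
  out
}

#' Call putative pseudogenes from homolog length ratios
#'
#' A gene truncated by strictly more than `1 - min_ratio` (default 20%)
#' relative to its best homolog is a putative pseudogene: the call is
#' `gene_length / homolog_length < min_ratio`, so a ratio of exactly
#' 0.8 is *not* a pseudogene. Lengths must be in the same unit (amino
#' acids for protein-vs-protein hit tables).
#'
#' @param gene_length,homolog_length Positive numeric vectors.
#' @param min_ratio Calling threshold on the length ratio (default 0.8).
#' @return Logical vector: `TRUE` for putative pseudogenes.
#' @examples
#' call_pseudogene(c(700, 800), c(1000, 1000))  # TRUE FALSE
#' @export
call_pseudogene <- function(gene_length, homolog_length, min_ratio = 0.8) {
  if (any(gene_length <= 0, na.rm = TRUE) ||
      any(homolog_length <= 0, na.rm = TRUE)) {
    stop("gene and homolog lengths must be positive")
  }
  gene_length / homolog_length < min_ratio
}

#' Category statistics for genes and intergenic sequence
#'
#' Summarises mean length, mean GC and count per gene category, plus a
#' row for intergenic sequence: the per-contig complement of the merged
#' gene spans (overlapping genes are merged before complementing).
#' Intergenic GC is computed when the genome sequence is supplied.
#'
#' @param genes Gene table with columns `contig`, `start`, `end`,
#'   `category`, and optionally `gc` (fraction).
#' @param contigs Named vector of contig lengths or a
#'   [Biostrings::DNAStringSet] (the latter also enables intergenic GC).
#' @return `data.frame` with columns `category`, `avg_length`,
#'   `gc_percent`, `n`. Empty categories report `n = 0` and `NA` means.
#' @export
category_table <- function(genes, contigs) {
  lens <- contig_lengths_of(contigs)
  cats <- c("homolog-in-reference", "hit-in-database", "no-hit")
  gene_rows <- lapply(cats, function(cc) {
    g <- genes[genes$category == cc, , drop = FALSE]
    data.frame(category = cc,
               avg_length = if (nrow(g)) mean(g$end - g$start + 1) else NA_real_,
               gc_percent = if (nrow(g) && !is.null(g$gc)) 100 * mean(g$gc)
                            else NA_real_,
               n = nrow(g), stringsAsFactors = FALSE)
  })

  inter <- lapply(names(lens), function(ctg) {
    g <- genes[genes$contig == ctg, , drop = FALSE]
    gaps <- IRanges::setdiff(
      IRanges::IRanges(1L, as.integer(lens[[ctg]])),
      IRanges::reduce(IRanges::IRanges(g$start, g$end)))
    data.frame(contig = ctg, start = IRanges::start(gaps),
               end = IRanges::end(gaps), stringsAsFactors = FALSE)
  })
  inter <- do.call(rbind, inter)
  inter_gc <- NA_real_
  if (methods::is(contigs, "DNAStringSet") && nrow(inter)) {
    pieces <- Biostrings::DNAStringSet(vapply(seq_len(nrow(inter)),
      function(i) as.character(Biostrings::subseq(
        contigs[[inter$contig[i]]], inter$start[i], inter$end[i])), ""))
    tot <- Biostrings::letterFrequency(pieces, "GC")
    inter_gc <- 100 * sum(tot) / sum(Biostrings::width(pieces))
  }
  out <- rbind(do.call(rbind, gene_rows),
               data.frame(category = "intergenic",
                          avg_length = if (nrow(inter))
                            mean(inter$end - inter$start + 1) else NA_real_,
                          gc_percent = inter_gc, n = nrow(inter),
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Coding density and mean gene length per region
#'
#' Coding density of a region is the length of the merged union of gene
#' spans intersected with the region, as a percentage of the region
#' length; the mean gene length averages over genes overlapping the
#' region.
#'
#' @param regions `data.frame` with columns `contig`, `start`, `end`
#'   (disjoint intervals).
#' @param genes Gene table with columns `contig`, `start`, `end`.
#' @param contigs Optional named contig lengths; when given, regions
#'   outside contig bounds raise an error.
#' @return `data.frame`: `contig`, `start`, `end`, `percent_coding`,
#'   `mean_gene_length`, `n_genes`.
#' @examples
#' genes <- data.frame(contig = "c", start = c(1, 301), end = c(400, 600))
#' coding_density(data.frame(contig = "c", start = 1, end = 1000), genes)
#' @export
coding_density <- function(regions, genes, contigs = NULL) {
  if (!is.null(contigs)) {
    lens <- contig_lengths_of(contigs)
    for (i in seq_len(nrow(regions))) {
      r <- regions[i, ]
      if (!r$contig %in% names(lens) || r$start < 1L ||
          r$end > lens[[r$contig]]) {
        stop("region outside contig bounds")
      }
    }
  }
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    g <- genes[genes$contig == r$contig & genes$start <= r$end &
                 genes$end >= r$start, , drop = FALSE]
    merged <- IRanges::intersect(
      IRanges::reduce(IRanges::IRanges(g$start, g$end)),
      IRanges::IRanges(r$start, r$end))
    data.frame(contig = r$contig, start = r$start, end = r$end,
               percent_coding = 100 * sum(IRanges::width(merged)) /
                 (r$end - r$start + 1),
               mean_gene_length = if (nrow(g)) mean(g$end - g$start + 1)
                                  else NA_real_,
               n_genes = nrow(g), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
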