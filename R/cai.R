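#' Relative synonymous codon usage (RSCU) of a reference gene set
#'
#' Counts codons over the supplied in-frame coding sequences and, per
#' synonymous family of the standard genetic code, divides each codon's
#' count by the family mean. Following the Sharp-Li convention, codons
#' never observed are assigned a pseudo-count of 0.5 before the family
#' mean is taken, so downstream adaptiveness values stay positive.
#' Stop codons are excluded; single-codon families (ATG, TGG) are kept
#' with RSCU 1.
#'
#' @param cds A [Biostrings::DNAStringSet] (or character vector) of
#'   in-frame coding sequences; every length must be divisible by 3.
#'   An internal stop codon triggers a warning.
#' @return A `data.frame` of class `codon_usage`: `codon`, `aa`,
#'   `count`, `rscu`.
#' @examples
#' tab <- rscu(Biostrings::DNAStringSet(c(g1 = "GGTGGTGGG")))
#' tab[tab$aa == "G", ]
#' @export
rscu <- function(cds) {
  cds <- Biostrings::DNAStringSet(cds)
  bad <- Biostrings::width(cds) %% 3L != 0L
  if (any(bad)) {
    nm <- names(cds)[bad]
    if (is.null(nm)) nm <- which(bad)
    stop("sequence length not divisible by 3: ", paste(nm, collapse = ", "))
  }
  counts <- colSums(Biostrings::trinucleotideFrequency(cds, step = 3L))

  code <- Biostrings::GENETIC_CODE
  internal_stop <- vapply(seq_along(cds), function(i) {
    aa <- strsplit(as.character(Biostrings::translate(
      cds[[i]], if.fuzzy.codon = "X")), NULL)[[1L]]
    any(aa[-length(aa)] == "*")
  }, logical(1L))
  if (any(internal_stop)) {
    warning(sprintf("%d sequence(s) contain internal stop codons",
                    sum(internal_stop)))
  }

  sense <- names(code)[code != "*"]
  adj <- counts[sense]
  adj[adj == 0] <- 0.5
  fam <- split(sense, code[sense])
  rscu_val <- numeric(length(sense))
  names(rscu_val) <- sense
  for (codons in fam) {
    rscu_val[codons] <- adj[codons] / mean(adj[codons])
  }
  out <- data.frame(codon = sense, aa = unname(code[sense]),
                    count = unname(counts[sense]),
                    rscu = unname(rscu_val), stringsAsFactors = FALSE)
  class(out) <- c("codon_usage", "data.frame")
  out
}

#' Relative adaptiveness (w) of each codon
#'
#' Divides each codon's RSCU by the maximum RSCU in its synonymous
#' family, so the preferred codon of every family has w = 1.
#'
#' @param table A `codon_usage` table from [rscu()].
#' @return The table with an added `w` column.
#' @export
relative_adaptiveness <- function(table) {
  stopifnot(all(c("codon", "aa", "rscu") %in% names(table)))
  table$w <- NA_real_
  for (ix in split(seq_len(nrow(table)), table$aa)) {
    table$w[ix] <- table$rscu[ix] / max(table$rscu[ix])
  }
  table
}

#' Codon adaptation index of genes against a reference usage
#'
#' The CAI of a gene is the geometric mean of the relative adaptiveness
#' values of its codons, excluding ATG, TGG (single-codon families) and
#' stop codons, per Sharp and Li.
#'
#' @param cds A [Biostrings::DNAStringSet] (or character vector) of
#'   in-frame genes.
#' @param w Either a `codon_usage` table carrying a `w` column (see
#'   [relative_adaptiveness()]) or a named numeric vector of w values.
#' @return Named numeric vector of CAI values in (0, 1].
#' @examples
#' ref <- Biostrings::DNAStringSet(c(r = "GGTGGTGGTGGG"))
#' w <- relative_adaptiveness(rscu(ref))
#' cai(Biostrings::DNAStringSet(c(g = "GGTGGT")), w)  # 1
#' @export
cai <- function(cds, w) {
  if (is.data.frame(w)) {
    stopifnot("w" %in% names(w))
    wvec <- setNames(w$w, w$codon)
  } else {
    wvec <- w
  }
  code <- Biostrings::GENETIC_CODE
  excluded <- c(names(code)[code %in% c("*", "M", "W")])
  cds <- Biostrings::DNAStringSet(cds)
  bad <- Biostrings::width(cds) %% 3L != 0L
  if (any(bad)) stop("sequence length not divisible by 3")
  vapply(seq_along(cds), function(i) {
    s <- as.character(cds[[i]])
    codons <- substring(s, seq(1L, nchar(s) - 2L, by = 3L),
                        seq(3L, nchar(s), by = 3L))
    codons <- codons[!codons %in% excluded & codons %in% names(wvec)]
    if (!length(codons)) {
      stop("gene with zero countable codons: ",
           if (!is.null(names(cds))) names(cds)[i] else i)
    }
    exp(mean(log(wvec[codons])))
  }, numeric(1L),
  USE.NAMES = FALSE) -> vals
  names(vals) <- names(cds)
  vals
}

#' Compare CAI across gene categories (one-way ANOVA + Tukey HSD)
#'
#' Fits a classical one-way analysis of variance on the untransformed
#' CAI values grouped by category, followed by Tukey's honest
#' significant difference test for all pairwise category contrasts.
#'
#' @param cai_values Numeric vector of per-gene CAI values.
#' @param category Factor (or character) of gene categories, same
#'   length; at least two groups with at least two values each.
#' @return List of class `cai_comparison`: `anova_f`, `anova_p`,
#'   `tukey` (`data.frame` with `comparison`, `diff`, `lwr`, `upr`,
#'   `p_adj`) and the underlying `fit`.
#' @export
compare_cai_categories <- function(cai_values, category) {
  category <- factor(category)
  if (nlevels(category) < 2L || any(table(category) < 2L)) {
    stop("need at least two groups with at least two values each")
  }
  dat <- data.frame(cai = cai_values, category = category)
  fit <- aov(cai ~ category, data = dat)
  s <- summary(fit)[[1L]]
  f_val <- s[["F value"]][1L]
  p_val <- s[["Pr(>F)"]][1L]
  if (stats::var(cai_values) == 0) {
    # degenerate constant input: no group effect by definition
    f_val <- 0; p_val <- 1
  }
  tk <- TukeyHSD(fit)$category
  structure(list(anova_f = f_val,
                 anova_p = p_val,
                 tukey = data.frame(comparison = rownames(tk),
                                    diff = tk[, "diff"],
                                    lwr = tk[, "lwr"], upr = tk[, "upr"],
                                    p_adj = tk[, "p adj"],
                                    row.names = NULL,
                                    stringsAsFactors = FALSE),
                 fit = fit),
            class = "cai_comparison")
}

#' @export
print.cai_comparison <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F = %.4g, p = %.4g\n", x$anova_f, x$anova_p))
  print(x$tukey, ...)
  invisible(x)
}
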