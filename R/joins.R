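#' Mine read-pair evidence for contig and breakpoint adjacencies
#'
#' Under an FR (forward-reverse) paired-end library, a pair spanning a
#' junction leaves one mate pointing off an endpoint on each side: a
#' forward-strand mate advertises the junction beyond the 3' side of
#' its position (a contig tail, or the left flank of an internal
#' breakpoint), a reverse-strand mate the junction before its 5' side
#' (a contig head, or the right flank of a breakpoint). Pairs whose
#' mates map to different contigs, or discordantly to the same contig
#' (wrong order/orientation or an apparent insert beyond
#' `max_insert`), are tallied per endpoint pair and orientation.
#'
#' Orientations follow the strand combination: tail+head joins are
#' `head-to-tail` (colinear), tail+tail `tail-to-tail` and head+head
#' `head-to-head` (inverted adjacencies).
#'
#' @param aln Alignment table with mate information (see
#'   [simulate_reads()] / [read_sam()]).
#' @param contigs Named vector of contig lengths or a
#'   [Biostrings::DNAStringSet].
#' @param max_distance_from_end Maximum distance in bases between a
#'   mate and its endpoint (default 400, about insert mean plus three
#'   standard deviations for a 300 +/- 30 bp library).
#' @param min_mapq Minimum mapping quality for both mates (default 10).
#' @param breakpoints Optional `data.frame` (`contig`, `start`, `end`)
#'   of internal intervals (e.g. deleted segments from a copy-number
#'   model) whose flanks are treated as additional endpoints, named
#'   `"<contig>:<start>:L"` and `"<contig>:<end>:R"`.
#' @param max_insert Largest apparent insert still considered
#'   concordant on one contig (default `max_distance_from_end`).
#' @return `data.frame` of class `join_evidence`: `endpoint_a`,
#'   `endpoint_b`, `orientation`, `support`; the number of records
#'   skipped for missing mate information is in attribute `skipped`.
#' @export
mine_joins <- function(aln, contigs, max_distance_from_end = 400L,
                       min_mapq = 10L, breakpoints = NULL,
                       max_insert = max_distance_from_end) {
  lens <- contig_lengths_of(contigs)
  a <- as.data.frame(aln)
  a$ref_end <- a$pos + cigar_ref_width(a$cigar) - 1L

  # nearest eligible endpoint per read
  n <- nrow(a)
  ep_name <- rep(NA_character_, n)
  ep_side <- rep(NA_character_, n)
  ep_dist <- rep(Inf, n)
  usable <- a$mapped & a$mapq >= min_mapq & !is.na(a$strand)

  plus <- usable & a$strand == "+"
  d <- unname(lens[a$rname]) - a$ref_end
  upd <- plus & !is.na(d) & d >= 0 & d <= max_distance_from_end & d < ep_dist
  ep_name[upd] <- paste0(a$rname[upd], ":tail")
  ep_side[upd] <- "tail"; ep_dist[upd] <- d[upd]

  minus <- usable & a$strand == "-"
  d <- a$pos - 1L
  upd <- minus & !is.na(d) & d >= 0 & d <= max_distance_from_end & d < ep_dist
  ep_name[upd] <- paste0(a$rname[upd], ":head")
  ep_side[upd] <- "head"; ep_dist[upd] <- d[upd]

  if (!is.null(breakpoints) && nrow(breakpoints)) {
    for (i in seq_len(nrow(breakpoints))) {
      bp <- breakpoints[i, ]
      d <- bp$start - 1L - a$ref_end
      upd <- plus & a$rname == bp$contig & !is.na(d) & d >= 0 &
        d <= max_distance_from_end & d < ep_dist
      ep_name[upd] <- sprintf("%s:%d:L", bp$contig, bp$start)
      ep_side[upd] <- "tail"; ep_dist[upd] <- d[upd]
      d <- a$pos - (bp$end + 1L)
      upd <- minus & a$rname == bp$contig & !is.na(d) & d >= 0 &
        d <= max_distance_from_end & d < ep_dist
      ep_name[upd] <- sprintf("%s:%d:R", bp$contig, bp$end)
      ep_side[upd] <- "head"; ep_dist[upd] <- d[upd]
    }
  }

  # pair mates
  m1 <- which(a$mate == 1L)
  key <- paste(a$qname, a$mate)
  m2 <- match(paste(a$qname[m1], 2L), key)
  skipped <- sum(is.na(m2))
  keep <- !is.na(m2)
  m1 <- m1[keep]; m2 <- m2[keep]

  ok <- usable[m1] & usable[m2]
  m1 <- m1[ok]; m2 <- m2[ok]

  same <- a$rname[m1] == a$rname[m2]
  s1 <- a$strand[m1]; s2 <- a$strand[m2]
  fr <- s1 != s2
  pos_plus <- ifelse(s1 == "+", a$pos[m1], a$pos[m2])
  end_minus <- ifelse(s1 == "-", a$ref_end[m1], a$ref_end[m2])
  span <- end_minus - pos_plus + 1L
  concordant <- same & fr & span >= 0L & span <= max_insert
  # a discordant pair may legitimately join an endpoint to itself when
  # both mates point off the same side (inverted self-adjacency of a
  # collapsed repeat); colinear same-endpoint pairs are noise
  self_ok <- ep_side[m1] == ep_side[m2]
  cross <- !concordant & !is.na(ep_name[m1]) & !is.na(ep_name[m2]) &
    (ep_name[m1] != ep_name[m2] | self_ok)

  if (!any(cross)) {
    out <- data.frame(endpoint_a = character(0), endpoint_b = character(0),
                      orientation = character(0), support = integer(0),
                      stringsAsFactors = FALSE)
  } else {
    i1 <- m1[cross]; i2 <- m2[cross]
    ea <- ep_name[i1]; eb <- ep_name[i2]
    ori <- mapply(orientation_label, ep_side[i1], ep_side[i2],
                  USE.NAMES = FALSE)
    swap <- ea > eb
    tmp <- ea[swap]; ea[swap] <- eb[swap]; eb[swap] <- tmp
    tab <- table(paste(ea, eb, ori, sep = "\r"))
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    out <- data.frame(endpoint_a = vapply(parts, `[[`, "", 1L),
                      endpoint_b = vapply(parts, `[[`, "", 2L),
                      orientation = vapply(parts, `[[`, "", 3L),
                      support = as.integer(tab),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$support), ]
    rownames(out) <- NULL
  }
  attr(out, "skipped") <- skipped
  class(out) <- c("join_evidence", "data.frame")
  out
}

#' Build a connection graph from join evidence
#'
#' Nodes are contig ends (`<contig>:head`, `<contig>:tail`) and any
#' internal breakpoint endpoints present in the join list; edges are
#' joins with support at least `min_support`, weighted by support.
#' Backbone edges along each contig (head to tail, through any
#' breakpoint nodes in coordinate order) connect the two ends of a
#' contig, so connected components describe candidate scaffolds. A
#' contig end with no retained join edge is a *loose end*; a fully
#' assembled linear replicon shows exactly two.
#'
#' @param joins A `join_evidence` table from [mine_joins()].
#' @param contigs Named vector of contig lengths or a
#'   [Biostrings::DNAStringSet].
#' @param min_support Minimum read-pair support for an edge (default 3).
#' @return A list of class `connection_graph`: `graph` (an
#'   [igraph::graph]), `edges` (the retained joins), `loose_ends`
#'   (character vector of unconnected contig-end nodes), `n_loose`,
#'   `n_components`.
#' @export
build_graph <- function(joins, contigs, min_support = 3L) {
  lens <- contig_lengths_of(contigs)
  keep <- joins[joins$support >= min_support, , drop = FALSE]

  node_pos <- function(name) {
    parts <- strsplit(name, ":", fixed = TRUE)[[1L]]
    if (length(parts) == 2L) {
      if (parts[2L] == "head") 0 else unname(lens[parts[1L]]) + 1
    } else as.numeric(parts[2L])
  }
  bp_nodes <- setdiff(unique(c(keep$endpoint_a, keep$endpoint_b)),
                      unlist(lapply(names(lens), function(ctg)
                        paste0(ctg, c(":head", ":tail")))))
  nodes <- c(unlist(lapply(names(lens), function(ctg)
    paste0(ctg, c(":head", ":tail")))), bp_nodes)

  backbone <- do.call(rbind, lapply(names(lens), function(ctg) {
    on_ctg <- nodes[startsWith(nodes, paste0(ctg, ":"))]
    on_ctg <- on_ctg[order(vapply(on_ctg, node_pos, numeric(1L)))]
    if (length(on_ctg) < 2L) return(NULL)
    data.frame(from = on_ctg[-length(on_ctg)], to = on_ctg[-1L],
               type = "backbone", support = NA_integer_,
               stringsAsFactors = FALSE)
  }))
  join_edges <- if (nrow(keep)) {
    data.frame(from = keep$endpoint_a, to = keep$endpoint_b,
               type = "join", support = keep$support,
               stringsAsFactors = FALSE)
  } else NULL
  edges <- rbind(backbone, join_edges)

  g <- igraph::graph_from_data_frame(
    if (is.null(edges)) data.frame(from = character(0), to = character(0))
    else edges,
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))

  end_nodes <- unlist(lapply(names(lens), function(ctg)
    paste0(ctg, c(":head", ":tail"))))
  connected <- unique(c(keep$endpoint_a, keep$endpoint_b))
  loose <- setdiff(end_nodes, connected)

  structure(list(graph = g, edges = keep, loose_ends = loose,
                 n_loose = length(loose),
                 n_components = as.integer(igraph::components(g)$no)),
            class = "connection_graph")
}

#' Export a connection graph
#'
#' Writes the retained join edges as a TSV edge list, and optionally
#' the full graph (backbone included) as GraphML.
#'
#' @param cg A `connection_graph` from [build_graph()].
#' @param tsv_path Path for the TSV edge list.
#' @param graphml_path Optional path for a GraphML export.
#' @return Invisibly, `tsv_path`.
#' @export
write_connection_graph <- function(cg, tsv_path, graphml_path = NULL) {
  write.table(cg$edges, tsv_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(graphml_path)) {
    igraph::write_graph(cg$graph, graphml_path, format = "graphml")
  }
  invisible(tsv_path)
}

#' @export
print.connection_graph <- function(x, ...) {
  cat(sprintf("connection_graph: %d join edge(s), %d component(s), %d loose end(s)\n",
              nrow(x$edges), x$n_components, x$n_loose))
  invisible(x)
}
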