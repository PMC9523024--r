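#' Group accessions into haplotypes by encoded protein sequence
#'
#' Accessions sharing an identical translated (amino-acid) sequence form one
#' haplotype; groups smaller than `min_members` are reported as unassigned,
#' matching the convention that a haplotype must be carried by more than two
#' varieties. Synonymous nucleotide differences therefore collapse into the
#' same haplotype. Input sequences must be aligned (equal length). Sequences
#' that cannot be translated (alignment gaps, length not a multiple of
#' three — e.g. explicit deletion alleles) are grouped by their exact
#' nucleotide string instead.
#'
#' @param sequences named character vector of aligned coding sequences (or
#'   arbitrary allele strings when `translate = FALSE`), one per accession.
#' @param min_members minimum group size to call a haplotype (default 3,
#'   i.e. "more than two varieties").
#' @param translate translate nucleotide sequences to amino acids before
#'   grouping (default `TRUE`).
#' @return an object of class `haplotype_set`: list with `haplotypes`
#'   (list of `label`, `sequence` (grouping key), `members`), `unassigned`
#'   (accession IDs in below-threshold groups), and `assignments` (named
#'   vector, `NA` for unassigned). Labels `Hap.1`, `Hap.2`, ... are
#'   assigned by decreasing group size (ties broken by key string order).
#' @export
call_haplotypes <- function(sequences, min_members = 3L, translate = TRUE) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("call_haplotypes: sequences must be uniquely named by accession",
         call. = FALSE)
  if (length(unique(nchar(sequences))) > 1L)
    stop("call_haplotypes: sequences differ in length; align them first",
         call. = FALSE)
  keys <- if (translate) vapply(sequences, translate_or_raw, character(1))
          else toupper(sequences)
  grp <- split(names(sequences), keys)
  sizes <- lengths(grp)
  ord <- order(-sizes, names(grp))
  grp <- grp[ord]; sizes <- sizes[ord]
  is_hap <- sizes >= min_members
  haps <- list()
  for (i in which(is_hap)) {
    haps[[length(haps) + 1L]] <- list(
      label = paste0("Hap.", length(haps) + 1L),
      sequence = names(grp)[i], members = grp[[i]])
  }
  unassigned <- unlist(grp[!is_hap], use.names = FALSE)
  assignments <- stats::setNames(rep(NA_character_, length(sequences)),
                                 names(sequences))
  for (h in haps) assignments[h$members] <- h$label
  structure(list(haplotypes = haps, unassigned = unassigned %||% character(0),
                 assignments = assignments, min_members = min_members),
            class = "haplotype_set")
}

translate_or_raw <- function(s) {
  s <- toupper(s)
  if (nchar(s) %% 3L == 0L && grepl("^[ACGT]+$", s)) {
    as.character(Biostrings::translate(Biostrings::DNAString(s),
                                       if.fuzzy.codon = "X"))
  } else {
    s   # deletion/indel alleles keep their exact string as identity
  }
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: %d haplotypes, %d unassigned accession(s)\n",
              length(x$haplotypes), length(x$unassigned)))
  for (h in x$haplotypes)
    cat(sprintf("  %s: %d member(s)\n", h$label, length(h$members)))
  invisible(x)
}

#' Minimum spanning network of haplotypes
#'
#' Computes pairwise mutation distances between haplotype sequences
#' (Hamming distance for equal-length keys; generalized edit distance, with
#' an indel counted as a single event, otherwise), builds a minimum spanning
#' tree, and augments it with every non-tree edge whose weight equals the
#' maximum edge weight on the tree path between its endpoints (the
#' epsilon = 0 minimum spanning network, whose edge set is independent of
#' how spanning-tree ties are broken). Node sizes carry member counts.
#'
#' @param haps a `haplotype_set`, or a named character vector of one
#'   representative sequence per haplotype.
#' @param epsilon tolerance added to the path-maximum rule; 0 (default)
#'   retains tied alternatives only.
#' @return an object of class `haplo_network`: list with `nodes`
#'   (data.frame `label`, `size`), `edges` (data.frame `from`, `to`,
#'   `weight`, `in_mst`) and `graph` (an igraph object of the network).
#' @export
build_msn <- function(haps, epsilon = 0) {
  if (inherits(haps, "haplotype_set")) {
    labels <- vapply(haps$haplotypes, `[[`, character(1), "label")
    seqs <- vapply(haps$haplotypes, `[[`, character(1), "sequence")
    sizes <- vapply(haps$haplotypes, function(h) length(h$members),
                    integer(1))
  } else {
    labels <- names(haps); seqs <- unname(haps)
    sizes <- rep(1L, length(haps))
    if (is.null(labels))
      stop("build_msn: haplotype sequences must be named", call. = FALSE)
  }
  k <- length(seqs)
  if (k == 0L) stop("build_msn: no haplotypes", call. = FALSE)
  nodes <- data.frame(label = labels, size = sizes, stringsAsFactors = FALSE)
  if (k == 1L) {
    g <- igraph::make_empty_graph(1, directed = FALSE)
    igraph::V(g)$name <- labels
    return(structure(list(nodes = nodes,
                          edges = data.frame(from = character(0),
                                             to = character(0),
                                             weight = numeric(0),
                                             in_mst = logical(0)),
                          graph = g),
                     class = "haplo_network"))
  }
  D <- hap_distances(seqs)
  dimnames(D) <- list(labels, labels)
  full <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                              weighted = TRUE)
  mst <- igraph::mst(full, weights = igraph::E(full)$weight)
  el <- igraph::as_edgelist(full)
  w <- igraph::E(full)$weight
  mst_el <- igraph::as_edgelist(mst)
  mst_key <- paste(pmin(mst_el[, 1], mst_el[, 2]),
                   pmax(mst_el[, 1], mst_el[, 2]))
  key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  in_mst <- key %in% mst_key
  keep <- in_mst
  for (e in which(!in_mst)) {
    path <- igraph::shortest_paths(mst, from = el[e, 1], to = el[e, 2],
                                   output = "epath")$epath[[1]]
    if (w[e] <= max(igraph::E(mst)$weight[as.integer(path)]) + epsilon)
      keep[e] <- TRUE
  }
  edges <- data.frame(from = el[keep, 1], to = el[keep, 2],
                      weight = w[keep], in_mst = in_mst[keep],
                      stringsAsFactors = FALSE)
  ord <- order(edges$from, edges$to)
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "haplo_network")
}

# Hamming distance for equal-length strings, otherwise generalized edit
# distance (adist: an indel counts as one event).
hap_distances <- function(seqs) {
  k <- length(seqs)
  same_len <- length(unique(nchar(seqs))) == 1L
  D <- matrix(0, k, k)
  if (same_len) {
    chars <- strsplit(seqs, "")
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      D[i, j] <- D[j, i] <- sum(chars[[i]] != chars[[j]])
    }
  } else {
    D <- unname(utils::adist(seqs))
  }
  storage.mode(D) <- "double"
  D
}

#' @export
print.haplo_network <- function(x, ...) {
  cat(sprintf("haplo_network: %d nodes, %d edges (%d in MST)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$in_mst)))
  invisible(x)
}

#' Export a haplotype network
#'
#' Writes the network as GraphML (via igraph) and/or an edge-list TSV.
#'
#' @param net a `haplo_network`.
#' @param graphml,edges_tsv output paths (`NULL` to skip either).
#' @export
export_msn <- function(net, graphml = NULL, edges_tsv = NULL) {
  stopifnot(inherits(net, "haplo_network"))
  if (!is.null(graphml))
    igraph::write_graph(net$graph, graphml, format = "graphml")
  if (!is.null(edges_tsv))
    utils::write.table(net$edges, edges_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(net)
}

#' Chi-square test of haplotype-frequency independence
#'
#' Pearson chi-square test (no continuity correction) of independence
#' between haplotype and group (region, subpopulation, era) in a
#' haplotype x group contingency table, with
#' `df = (rows - 1) x (columns - 1)`. A warning is issued when any expected
#' cell count falls below 5.
#'
#' @param table matrix or data.frame of non-negative integer counts,
#'   haplotypes in rows, groups in columns (at least 2 x 2).
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi2_independence <- function(table) {
  x <- as.matrix(table)
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("chi2_independence: need at least a 2 x 2 table", call. = FALSE)
  if (any(x < 0) || any(x != round(x)))
    stop("chi2_independence: counts must be non-negative integers",
         call. = FALSE)
  if (any(rowSums(x) == 0) || any(colSums(x) == 0))
    stop("chi2_independence: all-zero row or column", call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(x, correct = FALSE))
  if (any(res$expected < 5))
    warning("chi2_independence: expected cell count below 5; ",
            "chi-square approximation may be poor", call. = FALSE)
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value), expected = res$expected)
}

#' Haplotype frequency table with percentages
#'
#' Cross-tabulates haplotype assignments against a grouping factor and
#' attaches column percentages, mirroring the frequency-bar presentation of
#' regional haplotype surveys.
#'
#' @param assignments named haplotype labels per accession (NA allowed,
#'   dropped), e.g. the `assignments` field of a `haplotype_set`.
#' @param groups named group labels per accession.
#' @return list with `counts` (haplotype x group matrix) and `percent`
#'   (column percentages).
#' @export
haplotype_freq_table <- function(assignments, groups) {
  ids <- intersect(names(assignments)[!is.na(assignments)], names(groups))
  if (!length(ids))
    stop("haplotype_freq_table: no accession with both assignment and group",
         call. = FALSE)
  counts <- table(haplotype = assignments[ids], group = groups[ids])
  counts <- unclass(counts)
  pct <- sweep(counts, 2L, colSums(counts), "/") * 100
  list(counts = counts, percent = pct)
}
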