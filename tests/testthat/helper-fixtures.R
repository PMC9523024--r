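# Shared fixture builders: everything is generated in code at test time.

# Write a VCF from explicit record rows (list of lists with chrom, pos, id,
# ref, alt (comma string), mq, gt (character vector)).
write_toy_vcf <- function(records, samples, path = tempfile(fileext = ".vcf")) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")), con)
  for (r in records)
    writeLines(paste(c(r$chrom, r$pos, r$id, r$ref, r$alt, ".", ".",
                       sprintf("MQ=%s", r$mq), "GT", r$gt), collapse = "\t"),
               con)
  path
}

toy_samples <- function(n) sprintf("S%02d", seq_len(n))

# Direct (solve-based) multivariate-normal log-likelihood oracles, written
# independently of the package's whitening/profile machinery.
direct_ml_ll <- function(y, X, V) {
  n <- length(y)
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  beta <- solve(XtVi %*% X, XtVi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * (n * log(2 * pi) +
                       determinant(V, logarithm = TRUE)$modulus +
                       t(r) %*% Vi %*% r))
}

direct_reml_ll <- function(y, X, V) {
  n <- length(y); q <- ncol(X)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * ((n - q) * log(2 * pi) +
                       determinant(V, logarithm = TRUE)$modulus +
                       determinant(XtViX, logarithm = TRUE)$modulus -
                       determinant(crossprod(X), logarithm = TRUE)$modulus +
                       t(r) %*% Vi %*% r))
}

# brute-force minimum spanning tree over all spanning trees of a complete
# graph (feasible for <= 6 nodes)
brute_mst_weight <- function(D) {
  k <- nrow(D)
  if (k == 1) return(0)
  edges <- t(utils::combn(k, 2))
  best <- Inf
  for (idx in utils::combn(nrow(edges), k - 1, simplify = FALSE)) {
    sub <- edges[idx, , drop = FALSE]
    g <- igraph::graph_from_edgelist(sub, directed = FALSE)
    if (igraph::vcount(g) == k && igraph::is_connected(g))
      best <- min(best, sum(D[sub]))
  }
  best
}

# split a stacked phenotype table into named per-environment vectors
env_vector <- function(pheno, env) {
  stats::setNames(pheno$value[pheno$environment == env],
                  pheno$variety_id[pheno$environment == env])
}
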