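#' Pairwise linkage disequilibrium (r-squared) matrix
#'
#' Computes r2 as the squared Pearson correlation of the -1/+1 genotype
#' codes over pairwise-complete observations. For a homozygous inbred panel
#' (heterozygotes masked) genotype correlation equals the haplotype-based
#' r2, so no EM haplotype-frequency estimation is needed. Monomorphic
#' markers yield NA rows/columns.
#'
#' @param geno a `geno_matrix` or code matrix.
#' @param chrom,start,end optional window filter (1-based, inclusive) on
#'   the marker metadata; requires a `geno_matrix`.
#' @return an object of class `ld_matrix`: list with `r2` (symmetric matrix
#'   in `[0, 1]`, diagonal 1 for polymorphic markers) and `markers`
#'   (metadata of the retained markers, position-ordered).
#' @export
r2_matrix <- function(geno, chrom = NULL, start = NULL, end = NULL) {
  if (inherits(geno, "geno_matrix")) {
    v <- geno$variants
    keep <- rep(TRUE, nrow(v))
    if (!is.null(chrom)) keep <- keep & v$chrom == chrom
    if (!is.null(start)) keep <- keep & v$pos >= start
    if (!is.null(end)) keep <- keep & v$pos <= end
    ord <- order(v$chrom[keep], v$pos[keep])
    codes <- geno$codes[, keep, drop = FALSE][, ord, drop = FALSE]
    markers <- v[keep, , drop = FALSE][ord, , drop = FALSE]
  } else {
    codes <- geno
    markers <- data.frame(id = colnames(codes) %||%
                            paste0("M", seq_len(ncol(codes))))
  }
  if (ncol(codes) < 2L)
    stop("r2_matrix: need at least two markers", call. = FALSE)
  r2 <- suppressWarnings(
    stats::cor(codes, use = "pairwise.complete.obs"))^2
  mono <- apply(codes, 2L, function(x) stats::var(x, na.rm = TRUE) == 0)
  r2[mono, ] <- NA_real_
  r2[, mono] <- NA_real_
  diag(r2)[!mono] <- 1
  dimnames(r2) <- list(markers$id, markers$id)
  structure(list(r2 = r2, markers = markers), class = "ld_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("ld_matrix: %d markers, mean off-diagonal r2 %.3f\n",
              nrow(x$r2),
              mean(x$r2[upper.tri(x$r2)], na.rm = TRUE)))
  invisible(x)
}

#' Threshold-contiguity LD block annotation
#'
#' Annotates maximal runs of consecutive (position-ordered) markers in which
#' every adjacent pair has r2 at or above the threshold. This is a simple
#' descriptive block rule for inspecting regions around association peaks,
#' not a confidence-interval (Gabriel-type) block caller.
#'
#' @param ld an `ld_matrix`.
#' @param threshold minimum adjacent-pair r2 (default 0.7).
#' @return data.frame with `block`, `first`, `last` (marker indices) and
#'   `n_markers`; blocks of a single marker are omitted.
#' @export
ld_blocks <- function(ld, threshold = 0.7) {
  stopifnot(inherits(ld, "ld_matrix"))
  p <- nrow(ld$r2)
  if (p < 2L) return(data.frame(block = integer(0), first = integer(0),
                                last = integer(0), n_markers = integer(0)))
  adj <- vapply(seq_len(p - 1L),
                function(j) isTRUE(ld$r2[j, j + 1L] >= threshold),
                logical(1))
  blocks <- list()
  j <- 1L
  while (j <= p - 1L) {
    if (adj[j]) {
      k <- j
      while (k <= p - 1L && adj[k]) k <- k + 1L
      blocks[[length(blocks) + 1L]] <- c(j, k)
      j <- k + 1L
    } else j <- j + 1L
  }
  if (!length(blocks))
    return(data.frame(block = integer(0), first = integer(0),
                      last = integer(0), n_markers = integer(0)))
  out <- do.call(rbind, blocks)
  data.frame(block = seq_len(nrow(out)), first = out[, 1], last = out[, 2],
             n_markers = out[, 2] - out[, 1] + 1L)
}
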