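#' Simulation configuration
#'
#' Bundles every parameter of the synthetic germination-panel generator.
#' Defaults emulate a temperate japonica diversity panel phenotyped in two
#' controlled environments (15 degC and 30 degC imbibition): 164 inbred
#' varieties, 1000 genome-wide markers in three weakly differentiated
#' subpopulations, and a polygenic + GxE random-effect architecture with
#' variance components (sigma2_g, sigma2_ge, sigma2_e) = (1, 0.5, 0.5).
#'
#' @param m number of varieties (inbred accessions).
#' @param p number of markers.
#' @param k number of subpopulations.
#' @param fst differentiation parameter of the Balding-Nichols
#'   allele-frequency model, in `[0, 1)`; 0 means no structure.
#' @param maf_range interval within (0, 0.5] from which ancestral minor
#'   allele frequencies are drawn uniformly.
#' @param tri_fraction fraction of markers emitted as tri-allelic records when
#'   writing VCF fixtures (the internal code matrix is always bi-allelic).
#' @param env_means length-2 vector of population-wide trait means, one per
#'   environment, in trait units; names give the environment labels
#'   (default `15C`, `30C`).
#' @param sigma2_g polygenic variance (shared across environments).
#' @param sigma2_ge genotype-by-environment variance (independent between
#'   environments, kinship-structured within an environment).
#' @param sigma2_e residual variance.
#' @param focal_markers `NULL` or a data.frame with columns `marker`
#'   (column index), `zeta1`, `zeta2` (fixed marker effects in environment 1
#'   and 2). A marker with `zeta1 == zeta2` has a common effect only
#'   (no GxE).
#' @param seed integer seed; all generator functions are deterministic given
#'   the configuration.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(m = 164L, p = 1000L, k = 3L, fst = 0.1,
                       maf_range = c(0.05, 0.5), tri_fraction = 0.05,
                       env_means = c("15C" = 40, "30C" = 70),
                       sigma2_g = 1, sigma2_ge = 0.5, sigma2_e = 0.5,
                       focal_markers = NULL, seed = 1L) {
  if (is.null(names(env_means))) names(env_means) <- c("15C", "30C")
  cfg <- list(m = as.integer(m), p = as.integer(p), k = as.integer(k),
              fst = fst, maf_range = maf_range, tri_fraction = tri_fraction,
              env_means = env_means, sigma2_g = sigma2_g,
              sigma2_ge = sigma2_ge, sigma2_e = sigma2_e,
              focal_markers = focal_markers, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$m < 2L) stop("sim_config: m must be >= 2", call. = FALSE)
  if (cfg$p < 1L) stop("sim_config: p must be >= 1", call. = FALSE)
  if (cfg$k < 1L || cfg$k > cfg$m)
    stop("sim_config: k must be in [1, m]", call. = FALSE)
  if (cfg$fst < 0 || cfg$fst >= 1)
    stop("sim_config: fst must be in [0, 1)", call. = FALSE)
  if (length(cfg$maf_range) != 2L || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2])
    stop("sim_config: maf_range must be an interval within (0, 0.5]",
         call. = FALSE)
  if (cfg$tri_fraction < 0 || cfg$tri_fraction > 1)
    stop("sim_config: tri_fraction must be in [0, 1]", call. = FALSE)
  if (length(cfg$env_means) != 2L)
    stop("sim_config: env_means must have length 2", call. = FALSE)
  if (any(c(cfg$sigma2_g, cfg$sigma2_ge, cfg$sigma2_e) < 0))
    stop("sim_config: variance components must be >= 0", call. = FALSE)
  fm <- cfg$focal_markers
  if (!is.null(fm)) {
    if (!is.data.frame(fm) ||
        !all(c("marker", "zeta1", "zeta2") %in% names(fm)))
      stop("sim_config: focal_markers needs columns marker, zeta1, zeta2",
           call. = FALSE)
    if (any(fm$marker < 1L) || any(fm$marker > cfg$p))
      stop("sim_config: focal marker index out of range", call. = FALSE)
  }
  invisible(cfg)
}

#' Simulate a structured homozygous genotype panel
#'
#' Draws subpopulation allele frequencies from a Balding-Nichols model
#' (`Beta(f0 (1-Fst)/Fst, (1-f0)(1-Fst)/Fst)` around an ancestral frequency
#' `f0`) and samples one homozygous diploid genotype per variety and marker,
#' coded -1 (REF/REF) or +1 (ALT/ALT). Heterozygotes are absent by
#' construction, mirroring an inbred panel after heterozygote masking.
#' Marker metadata (chromosome, position, REF/ALT bases, mapping quality
#' spanning both sides of 40) is synthesized alongside.
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed; defaults to `cfg$seed`.
#' @return a `geno_matrix`: list with `codes` (m x p matrix of -1/+1,
#'   dimnames = varieties x marker ids), `variants` (data.frame with chrom,
#'   pos, id, ref, alt, mq), `varieties`, and a `subpop` attribute holding
#'   the simulated subpopulation labels.
#' @export
simulate_genotypes <- function(cfg, seed = cfg$seed) {
  validate_sim_config(cfg)
  set.seed(seed)
  m <- cfg$m; p <- cfg$p; k <- cfg$k
  subpop <- sort(rep_len(seq_len(k), m))
  maf <- stats::runif(p, cfg$maf_range[1], cfg$maf_range[2])
  f0 <- ifelse(stats::runif(p) < 0.5, maf, 1 - maf)   # ancestral ALT freq
  fk <- matrix(0, nrow = k, ncol = p)
  if (cfg$fst < 1e-12) {
    fk[] <- rep(f0, each = k)
  } else {
    a <- (1 - cfg$fst) / cfg$fst
    for (kk in seq_len(k))
      fk[kk, ] <- stats::rbeta(p, f0 * a, (1 - f0) * a)
  }
  # one allele draw per (variety, marker): inbred lines are homozygous
  pr <- fk[subpop, , drop = FALSE]
  codes <- matrix(ifelse(stats::runif(m * p) < pr, 1, -1), nrow = m)
  varieties <- sprintf("VAR%03d", seq_len(m))
  n_chr <- min(12L, p)
  chrom <- sprintf("chr%02d", sort(rep_len(seq_len(n_chr), p)))
  pos <- integer(p)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- cumsum(sample(500:5000, length(idx), replace = TRUE))
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, p, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  mq <- round(stats::runif(p, 30, 60), 1)
  ids <- paste0(chrom, ":", pos)
  variants <- data.frame(chrom = chrom, pos = pos, id = ids, ref = ref,
                         alt = unname(alt), mq = mq,
                         stringsAsFactors = FALSE)
  dimnames(codes) <- list(varieties, ids)
  structure(list(codes = codes, variants = variants, varieties = varieties),
            class = "geno_matrix", subpop = subpop)
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d varieties x %d markers (%d missing calls)\n",
              nrow(x$codes), ncol(x$codes), sum(is.na(x$codes))))
  invisible(x)
}

#' Simulate stacked two-environment phenotypes
#'
#' Forward model for one record of variety i in environment l:
#' `y = t_l + sum_f zeta_{l,f} x_{i,f} + u_G[i] + u_GE[l][i] + e`,
#' with `u_G ~ MVN(0, G sigma2_g)` shared across environments,
#' `u_GE` drawn independently per environment with covariance
#' `G sigma2_ge` within an environment (the Hadamard-product GxE kernel
#' restricted to one environment), and `e ~ N(0, sigma2_e)` iid.
#' When every focal marker has `zeta1 == zeta2` this is exactly the
#' common-effect null model; otherwise the environment-specific alternative.
#'
#' @param geno a `geno_matrix` from [simulate_genotypes()].
#' @param cfg the [sim_config()] used (or a compatible one).
#' @param G optional kinship matrix; defaults to [compute_grm()] of `geno`.
#' @param seed RNG seed; defaults to `cfg$seed + 1`.
#' @return a data.frame (`variety_id`, `environment`, `value`) in
#'   variety-major, environment-minor row order, with attribute `truth`
#'   holding the realized `u_g`, `u_ge` (list of 2) and `eps` draws.
#' @export
simulate_phenotypes <- function(geno, cfg, G = NULL, seed = cfg$seed + 1L) {
  validate_sim_config(cfg)
  stopifnot(inherits(geno, "geno_matrix"))
  m <- nrow(geno$codes)
  if (m != cfg$m || ncol(geno$codes) != cfg$p)
    stop("simulate_phenotypes: geno dimensions do not match cfg", call. = FALSE)
  envs <- names(cfg$env_means)
  set.seed(seed)
  need_g <- cfg$sigma2_g > 0 || cfg$sigma2_ge > 0
  if (need_g && is.null(G)) G <- compute_grm(geno)
  L <- NULL
  if (need_g) {
    Gv <- if (inherits(G, "kinship_matrix")) G$values else G
    L <- chol_psd(Gv)
  }
  u_g <- if (cfg$sigma2_g > 0) drop(L %*% stats::rnorm(m)) * sqrt(cfg$sigma2_g)
         else numeric(m)
  u_ge <- lapply(seq_along(envs), function(l) {
    if (cfg$sigma2_ge > 0) drop(L %*% stats::rnorm(m)) * sqrt(cfg$sigma2_ge)
    else numeric(m)
  })
  eps <- matrix(stats::rnorm(2L * m, sd = sqrt(cfg$sigma2_e)), nrow = m)
  fixed <- matrix(0, nrow = m, ncol = 2L)
  fm <- cfg$focal_markers
  if (!is.null(fm)) {
    for (f in seq_len(nrow(fm))) {
      x <- geno$codes[, fm$marker[f]]
      fixed[, 1L] <- fixed[, 1L] + x * fm$zeta1[f]
      fixed[, 2L] <- fixed[, 2L] + x * fm$zeta2[f]
    }
  }
  vals <- matrix(0, nrow = m, ncol = 2L)
  for (l in 1:2)
    vals[, l] <- cfg$env_means[l] + fixed[, l] + u_g + u_ge[[l]] + eps[, l]
  out <- data.frame(
    variety_id = rep(geno$varieties, each = 2L),
    environment = rep(envs, times = m),
    value = as.vector(t(vals)),
    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(u_g = u_g, u_ge = u_ge, eps = eps)
  out
}

# Upper-triangular factor L' with V = L %*% t(L) for a PSD matrix, tolerating
# tiny negative eigenvalues from finite precision.
chol_psd <- function(V, ridge = 1e-10) {
  ok <- tryCatch(chol(V + diag(ridge * mean(diag(V)), nrow(V))),
                 error = function(e) NULL)
  if (!is.null(ok)) return(t(ok))
  ev <- eigen(V, symmetric = TRUE)
  d <- pmax(ev$values, 0)
  ev$vectors %*% diag(sqrt(d), length(d))
}

#' Write a VCF fixture exercising the preprocessing filters
#'
#' Emits a VCF 4.2 text file for a simulated panel. A `tri_fraction` subset of
#' markers is written as tri-allelic records (two ALT alleles) by recoding a
#' random half of the ALT-homozygous varieties to the second ALT; a small
#' fraction of calls is flipped to heterozygous so the masking step has work
#' to do; per-record `MQ` INFO values come from the marker metadata and span
#' both sides of 40.
#'
#' @param geno a `geno_matrix`.
#' @param cfg the [sim_config()] (supplies `tri_fraction` and the seed).
#' @param path output file path.
#' @param het_rate per-call probability of injecting a heterozygote.
#' @param seed RNG seed; defaults to `cfg$seed + 2`.
#' @return invisibly, a list with `tri_sites` (marker indices written as
#'   tri-allelic), `het` (m x p logical matrix of injected heterozygotes)
#'   and `alt2_hom` (logical matrix of calls recoded to the second ALT).
#' @export
write_vcf_fixture <- function(geno, cfg, path, het_rate = 0.03,
                              seed = cfg$seed + 2L) {
  stopifnot(inherits(geno, "geno_matrix"))
  set.seed(seed)
  m <- nrow(geno$codes); p <- ncol(geno$codes)
  n_tri <- round(cfg$tri_fraction * p)
  tri_sites <- sort(sample.int(p, n_tri))
  het <- matrix(stats::runif(m * p) < het_rate, nrow = m)
  alt2 <- matrix(FALSE, nrow = m, ncol = p)
  bases <- c("A", "C", "G", "T")
  v <- geno$variants
  alt_field <- v$alt
  for (j in tri_sites) {
    third <- sample(setdiff(bases, c(v$ref[j], v$alt[j])), 1L)
    alt_field[j] <- paste(v$alt[j], third, sep = ",")
    carriers <- which(geno$codes[, j] == 1 & !het[, j])
    if (length(carriers) >= 2L)
      alt2[sample(carriers, ceiling(length(carriers) / 2)), j] <- TRUE
  }
  gt <- matrix("0/0", nrow = m, ncol = p)
  gt[geno$codes == 1] <- "1/1"
  gt[alt2] <- "2/2"
  # hets pair the sample's current allele with another allele of the record
  for (j in seq_len(p)) {
    hi <- which(het[, j])
    if (!length(hi)) next
    n_alleles <- if (j %in% tri_sites) 3L else 2L
    for (i in hi) {
      a1 <- switch(gt[i, j], "0/0" = 0L, "1/1" = 1L, "2/2" = 2L)
      a2 <- sample(setdiff(0:(n_alleles - 1L), a1), 1L)
      gt[i, j] <- paste(sort(c(a1, a2)), collapse = "/")
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", geno$varieties), collapse = "\t")),
             con)
  body <- vapply(seq_len(p), function(j) {
    paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], alt_field[j], ".", ".",
            sprintf("MQ=%.1f", v$mq[j]), "GT", gt[, j]), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(list(tri_sites = tri_sites, het = het, alt2_hom = alt2))
}

#' Write a phenotype table as TSV
#'
#' @param pheno data.frame with columns `variety_id`, `environment`, `value`.
#' @param path output path.
#' @export
write_phenotype_tsv <- function(pheno, path) {
  utils::write.table(pheno[, c("variety_id", "environment", "value")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulation configuration as a flat key-value file
#'
#' Scalar fields are written as `key = value` lines; focal markers as
#' `focal_marker = index,zeta1,zeta2` lines (one per marker).
#'
#' @param cfg a [sim_config()].
#' @param path output path.
#' @export
write_sim_config <- function(cfg, path) {
  validate_sim_config(cfg)
  lines <- c(
    sprintf("m = %d", cfg$m), sprintf("p = %d", cfg$p),
    sprintf("k = %d", cfg$k), sprintf("fst = %.10g", cfg$fst),
    sprintf("maf_range = %.10g,%.10g", cfg$maf_range[1], cfg$maf_range[2]),
    sprintf("tri_fraction = %.10g", cfg$tri_fraction),
    sprintf("env_means = %s=%.10g,%s=%.10g",
            names(cfg$env_means)[1], cfg$env_means[1],
            names(cfg$env_means)[2], cfg$env_means[2]),
    sprintf("sigma2_g = %.10g", cfg$sigma2_g),
    sprintf("sigma2_ge = %.10g", cfg$sigma2_ge),
    sprintf("sigma2_e = %.10g", cfg$sigma2_e),
    sprintf("seed = %d", cfg$seed))
  if (!is.null(cfg$focal_markers))
    lines <- c(lines, sprintf("focal_marker = %d,%.10g,%.10g",
                              cfg$focal_markers$marker,
                              cfg$focal_markers$zeta1,
                              cfg$focal_markers$zeta2))
  writeLines(lines, path)
  invisible(path)
}

#' Read a simulation configuration from a flat key-value file
#'
#' @param path a file written by [write_sim_config()].
#' @return a validated [sim_config()].
#' @export
read_sim_config <- function(path) {
  lines <- grep("=", readLines(path), fixed = TRUE, value = TRUE)
  kv <- regmatches(lines, regexpr(" = ", lines), invert = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, `[`, character(1), 2)
  pick <- function(key) vals[keys == key][1]
  em <- strsplit(strsplit(pick("env_means"), ",")[[1]], "=")
  env_means <- stats::setNames(as.numeric(vapply(em, `[`, character(1), 2)),
                               vapply(em, `[`, character(1), 1))
  fm <- NULL
  if (any(keys == "focal_marker")) {
    rows <- do.call(rbind, lapply(strsplit(vals[keys == "focal_marker"], ","),
                                  as.numeric))
    fm <- data.frame(marker = as.integer(rows[, 1]), zeta1 = rows[, 2],
                     zeta2 = rows[, 3])
  }
  sim_config(m = as.integer(pick("m")), p = as.integer(pick("p")),
             k = as.integer(pick("k")), fst = as.numeric(pick("fst")),
             maf_range = as.numeric(strsplit(pick("maf_range"), ",")[[1]]),
             tri_fraction = as.numeric(pick("tri_fraction")),
             env_means = env_means,
             sigma2_g = as.numeric(pick("sigma2_g")),
             sigma2_ge = as.numeric(pick("sigma2_ge")),
             sigma2_e = as.numeric(pick("sigma2_e")),
             focal_markers = fm, seed = as.integer(pick("seed")))
}

#' Read a phenotype table from TSV
#'
#' @param path TSV with columns `variety_id`, `environment`, `value`.
#' @return data.frame with those columns.
#' @export
read_phenotype_tsv <- function(path) {
  ph <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("variety_id", "environment", "value")
  if (!all(need %in% names(ph)))
    stop("phenotype TSV must have columns variety_id, environment, value",
         call. = FALSE)
  ph[, need]
}
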