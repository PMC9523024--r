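#' Normalize germination counts to rates
#'
#' Converts a germinated-seed count into a percentage of the reference count
#' germinated at 30 degC for 48 h (under which all viable seeds are assumed
#' to have germinated). Values above 100 (a seed lot germinating better in
#' the assay than in the reference) are clipped to 100 with a warning.
#'
#' @param germinated non-negative count(s) of germinated seeds.
#' @param reference_30C_48h positive reference count(s).
#' @return germination rate(s) in percent, in `[0, 100]`.
#' @export
normalize_germination <- function(germinated, reference_30C_48h) {
  if (any(reference_30C_48h == 0))
    stop("normalize_germination: reference count of 0 leaves the rate undefined",
         call. = FALSE)
  if (any(germinated < 0) || any(reference_30C_48h < 0))
    stop("normalize_germination: counts must be non-negative", call. = FALSE)
  rate <- 100 * germinated / reference_30C_48h
  if (any(rate > 100)) {
    warning("germination rate(s) above 100% clipped to 100", call. = FALSE)
    rate <- pmin(rate, 100)
  }
  rate
}

#' Stack per-environment phenotypes and build the mixed-model design
#'
#' Assembles the n-vector of phenotypic records together with the incidence
#' matrices of the two-environment mixed model: `T` (n x 2, one-hot over
#' environments, multiplying the environment means t), `Z_G` (n x m, one-hot
#' over varieties, expanding variety-level random effects), `Z_E` (n x 2,
#' content-identical to `T`, used in the Hadamard GxE kernel) and the
#' indicator vectors `pi[[l]]` selecting records from environment l. Rows
#' are ordered variety-major, environment-minor. Unbalanced designs (a
#' variety phenotyped in only one environment) are allowed.
#'
#' @param pheno data.frame with columns `variety_id`, `environment`,
#'   `value`; each (variety, environment) pair at most once.
#' @param varieties optional ordered variety universe; defaults to the
#'   varieties present, in order of first appearance.
#' @param envs optional ordered environment levels (length 2); defaults to
#'   the sorted unique labels.
#' @return a list with `y` (n-vector), `pheno` (re-ordered records),
#'   `T`, `Z_G`, `Z_E`, `pi` (list of 2 indicator vectors), `varieties`,
#'   `envs`.
#' @export
stack_environments <- function(pheno, varieties = NULL, envs = NULL) {
  need <- c("variety_id", "environment", "value")
  if (!all(need %in% names(pheno)))
    stop("stack_environments: pheno needs columns variety_id, environment, value",
         call. = FALSE)
  if (anyDuplicated(pheno[, c("variety_id", "environment")]))
    stop("stack_environments: duplicate (variety, environment) record",
         call. = FALSE)
  if (is.null(varieties)) varieties <- unique(pheno$variety_id)
  if (is.null(envs)) envs <- sort(unique(pheno$environment))
  if (!all(pheno$variety_id %in% varieties))
    stop("stack_environments: record for unknown variety", call. = FALSE)
  if (!all(pheno$environment %in% envs))
    stop("stack_environments: record for unknown environment", call. = FALSE)
  if (length(envs) != 2L)
    stop("stack_environments: exactly two environments expected", call. = FALSE)
  vi <- match(pheno$variety_id, varieties)
  ei <- match(pheno$environment, envs)
  ord <- order(vi, ei)
  pheno <- pheno[ord, , drop = FALSE]
  vi <- vi[ord]; ei <- ei[ord]
  n <- nrow(pheno)
  Tm <- matrix(0, n, 2L, dimnames = list(NULL, envs))
  Tm[cbind(seq_len(n), ei)] <- 1
  Zg <- matrix(0, n, length(varieties), dimnames = list(NULL, varieties))
  Zg[cbind(seq_len(n), vi)] <- 1
  pi_l <- lapply(1:2, function(l) as.numeric(ei == l))
  list(y = pheno$value, pheno = pheno, T = Tm, Z_G = Zg, Z_E = Tm,
       pi = pi_l, varieties = varieties, envs = envs)
}
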