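#' Read a VCF into a list of variant records
#'
#' Thin wrapper around [vcfR::read.vcfR()] that flattens each site into a
#' record holding the alleles, the RMS mapping quality (`MQ` INFO field) and
#' the per-sample diploid allele indices. Multi-allelic records are kept
#' as-is; downstream [split_multiallelic()] expands them.
#'
#' @param path path to a VCF 4.x file (plain or bgzipped).
#' @return an object of class `variant_records`: a list of records, each a
#'   list with `chrom`, `pos`, `id`, `ref`, `alt` (character vector of ALT
#'   alleles), `mq`, and `gt` (sample x 2 integer matrix of allele indices,
#'   `NA` for missing); attribute `samples` carries the sample names.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("read_vcf: no such file: ", path, call. = FALSE)
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e)
                    stop("read_vcf: VCF parse failure in '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt_raw))) gt_raw <- matrix(gt_raw, nrow = 1)
  samples <- colnames(vcf@gt)[-1]
  mq <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "MQ")))
  records <- lapply(seq_len(nrow(fix)), function(r) {
    alt <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
    gt <- parse_gt_strings(gt_raw[r, ])
    id <- fix[r, "ID"]
    if (is.na(id) || id == ".")
      id <- paste0(fix[r, "CHROM"], ":", fix[r, "POS"])
    list(chrom = fix[r, "CHROM"], pos = as.integer(fix[r, "POS"]), id = id,
         ref = fix[r, "REF"], alt = alt, mq = mq[r], gt = gt)
  })
  structure(records, class = "variant_records", samples = samples)
}

# "0/1", "1|2", "./." etc. -> n x 2 integer matrix (NA NA for missing)
parse_gt_strings <- function(x) {
  parts <- strsplit(x, "[/|]")
  gt <- t(vapply(parts, function(a) {
    a <- suppressWarnings(as.integer(a))
    if (length(a) == 1L) a <- c(a, a)   # haploid call treated as homozygous
    a[1:2]
  }, integer(2)))
  gt[is.na(x) | x %in% c(".", "./.", ".|."), ] <- NA_integer_
  gt
}

#' @export
print.variant_records <- function(x, ...) {
  n_alt <- vapply(x, function(r) length(r$alt), integer(1))
  cat(sprintf("variant_records: %d sites, %d samples (%d multi-allelic)\n",
              length(x), length(attr(x, "samples")), sum(n_alt > 1)))
  invisible(x)
}

new_variant_records <- function(records, samples) {
  structure(records, class = "variant_records", samples = samples)
}

#' @export
`[.variant_records` <- function(x, i) {
  new_variant_records(unclass(x)[i], attr(x, "samples"))
}

#' Set heterozygous calls to missing
#'
#' Every genotype whose two allele indices differ is replaced by missing;
#' homozygous calls are untouched. This is the first preprocessing step for
#' an inbred panel, applied before splitting and filtering.
#'
#' @param records a `variant_records` object.
#' @return the records with heterozygotes masked.
#' @export
mask_heterozygotes <- function(records) {
  stopifnot(inherits(records, "variant_records"))
  out <- lapply(records, function(r) {
    het <- !is.na(r$gt[, 1]) & r$gt[, 1] != r$gt[, 2]
    r$gt[het, ] <- NA_integer_
    r
  })
  new_variant_records(out, attr(records, "samples"))
}

#' Expand tri-allelic records into three bi-allelic pseudo-variants
#'
#' A site with alleles (REF, ALT1, ALT2) becomes three bi-allelic records,
#' one per allele pair: (REF, ALT1), (REF, ALT2) and (ALT1, ALT2). Within
#' each derived record, samples carrying the excluded third allele are set
#' missing; all other fields are duplicated from the parent and the derived
#' IDs are suffixed with the allele pair. Bi-allelic records pass through
#' unchanged; records with more than three alleles are dropped with a
#' warning.
#'
#' @param records a `variant_records` object.
#' @return a `variant_records` object in which every record is bi-allelic.
#' @export
split_multiallelic <- function(records) {
  stopifnot(inherits(records, "variant_records"))
  out <- list()
  n_dropped <- 0L
  for (r in records) {
    na <- length(r$alt)
    if (na == 1L) {
      out[[length(out) + 1L]] <- r
    } else if (na == 2L) {
      alleles <- c(r$ref, r$alt)          # indices 0, 1, 2
      pairs <- list(c(0L, 1L), c(0L, 2L), c(1L, 2L))
      for (pr in pairs) {
        d <- r
        d$ref <- alleles[pr[1] + 1L]
        d$alt <- alleles[pr[2] + 1L]
        d$id <- paste0(r$chrom, ":", r$pos, ":", d$ref, "_", d$alt)
        gt <- r$gt
        keep <- is.na(gt[, 1]) | (gt[, 1] %in% pr & gt[, 2] %in% pr)
        gt[!keep, ] <- NA_integer_
        # remap allele indices to 0/1 within the pair
        gt[] <- match(gt, pr) - 1L
        d$gt <- gt
        out[[length(out) + 1L]] <- d
      }
    } else {
      n_dropped <- n_dropped + 1L
    }
  }
  if (n_dropped > 0L)
    warning(n_dropped, " record(s) with >3 alleles dropped", call. = FALSE)
  new_variant_records(out, attr(records, "samples"))
}

#' Filter variants on MAF, mapping quality and call rate
#'
#' Keeps records with minor allele frequency >= `maf_min` (computed on
#' allele counts over non-missing calls), mapping quality >= `mq_min`, and
#' non-missing call fraction >= `call_rate_min`. Intended to run after
#' [mask_heterozygotes()] and [split_multiallelic()], matching the
#' mask -> split -> filter pipeline order. Records with no non-missing call
#' (or a missing MQ annotation) are dropped.
#'
#' @param records a `variant_records` object (bi-allelic).
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param mq_min minimum mapping quality (default 40).
#' @param call_rate_min minimum non-missing call fraction (default 0.40).
#' @return the surviving `variant_records`.
#' @export
filter_variants <- function(records, maf_min = 0.05, mq_min = 40,
                            call_rate_min = 0.40) {
  stopifnot(inherits(records, "variant_records"))
  keep <- vapply(records, function(r) {
    called <- !is.na(r$gt[, 1])
    if (!any(called)) return(FALSE)
    if (is.na(r$mq) || r$mq < mq_min) return(FALSE)
    if (mean(called) < call_rate_min) return(FALSE)
    f_alt <- sum(r$gt[called, ]) / (2 * sum(called))
    min(f_alt, 1 - f_alt) >= maf_min
  }, logical(1))
  new_variant_records(records[keep], attr(records, "samples"))
}

#' Encode bi-allelic records as a -1/+1 genotype matrix
#'
#' Homozygous-reference calls become -1, homozygous-alternate +1, anything
#' else (missing or residual heterozygote) missing, yielding the
#' `{-1, 1} = {REF/REF, ALT/ALT}` coding used by all association models.
#'
#' @param records bi-allelic `variant_records` (heterozygotes masked).
#' @param varieties optional ordered subset of sample IDs; defaults to all
#'   samples in file order.
#' @return a `geno_matrix` (see [simulate_genotypes()] for the layout).
#' @export
encode_genotypes <- function(records, varieties = NULL) {
  stopifnot(inherits(records, "variant_records"))
  samples <- attr(records, "samples")
  if (is.null(varieties)) varieties <- samples
  idx <- match(varieties, samples)
  if (anyNA(idx))
    stop("encode_genotypes: unknown variety ID(s): ",
         paste(varieties[is.na(idx)], collapse = ", "), call. = FALSE)
  if (any(vapply(records, function(r) length(r$alt), integer(1)) > 1L))
    stop("encode_genotypes: multi-allelic record present; run split_multiallelic first",
         call. = FALSE)
  p <- length(records)
  codes <- matrix(NA_real_, nrow = length(varieties), ncol = p)
  for (j in seq_len(p)) {
    gt <- records[[j]]$gt[idx, , drop = FALSE]
    hom_ref <- !is.na(gt[, 1]) & gt[, 1] == 0L & gt[, 2] == 0L
    hom_alt <- !is.na(gt[, 1]) & gt[, 1] == 1L & gt[, 2] == 1L
    codes[hom_ref, j] <- -1
    codes[hom_alt, j] <- 1
  }
  variants <- data.frame(
    chrom = vapply(records, `[[`, character(1), "chrom"),
    pos = vapply(records, `[[`, integer(1), "pos"),
    id = vapply(records, `[[`, character(1), "id"),
    ref = vapply(records, `[[`, character(1), "ref"),
    alt = vapply(records, function(r) r$alt[1], character(1)),
    mq = vapply(records, function(r) as.numeric(r$mq), numeric(1)),
    stringsAsFactors = FALSE)
  dimnames(codes) <- list(varieties, variants$id)
  structure(list(codes = codes, variants = variants, varieties = varieties),
            class = "geno_matrix")
}

#' Write variant records as a VCF file
#'
#' Emits a minimal VCF 4.2 representation of the records (GT-only FORMAT,
#' MQ in INFO), e.g. to persist the post-filtering variant set.
#'
#' @param records a `variant_records` object.
#' @param path output path.
#' @export
write_vcf_records <- function(records, path) {
  stopifnot(inherits(records, "variant_records"))
  samples <- attr(records, "samples")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  for (r in records) {
    gt <- ifelse(is.na(r$gt[, 1]), "./.",
                 paste(r$gt[, 1], r$gt[, 2], sep = "/"))
    writeLines(paste(c(r$chrom, r$pos, r$id, r$ref,
                       paste(r$alt, collapse = ","), ".", ".",
                       sprintf("MQ=%.1f", r$mq), "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a genotype matrix as TSV
#'
#' @param geno a `geno_matrix`.
#' @param path output path; varieties in rows, markers in columns,
#'   codes -1/1/NA.
#' @export
write_genotype_tsv <- function(geno, path) {
  utils::write.table(geno$codes, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
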