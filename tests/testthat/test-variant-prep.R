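samples10 <- toy_samples(10)

test_that("read_vcf preserves record order, multi-allelic sites and 1/2 calls", {
  recs <- c(
    lapply(1:9, function(i)
      list(chrom = "chr1", pos = i * 100, id = ".", ref = "A", alt = "C",
           mq = 50, gt = rep(c("0/0", "1/1"), 5))),
    list(list(chrom = "chr2", pos = 50, id = "tri1", ref = "A", alt = "C,T",
              mq = 50,
              gt = c("0/0", "0/0", "1/1", "2/2", "1/2", "0/0", "1/1", "2/2",
                     "0/0", "./."))))
  path <- write_toy_vcf(recs, samples10)
  rr <- read_vcf(path)
  expect_length(rr, 10)
  expect_identical(vapply(rr, `[[`, integer(1), "pos")[1:9],
                   as.integer(1:9 * 100))
  tri <- rr[[10]]
  expect_length(tri$alt, 2L)
  # "1/2" is a het between ALT1 and ALT2
  expect_identical(tri$gt[5, ], c(1L, 2L))
  expect_true(all(is.na(tri$gt[10, ])))
  expect_error(read_vcf(tempfile()), "no such file")
})

test_that("mask_heterozygotes blanks exactly the heterozygous calls", {
  recs <- list(
    list(chrom = "chr1", pos = 1, id = "hom", ref = "A", alt = "C", mq = 50,
         gt = rep(c("0/0", "1/1"), 5)),
    list(chrom = "chr1", pos = 2, id = "some_het", ref = "A", alt = "C",
         mq = 50,
         gt = c("0/1", "0/0", "1/1", "0/1", "0/0", "1/1", "0/1", "0/0",
                "1/1", "0/0")),
    list(chrom = "chr1", pos = 3, id = "all_het", ref = "A", alt = "C",
         mq = 50, gt = rep("0/1", 10)))
  rr <- read_vcf(write_toy_vcf(recs, samples10))
  mm <- mask_heterozygotes(rr)
  expect_identical(mm[[1]]$gt, rr[[1]]$gt)            # identity on homs
  expect_identical(sum(is.na(mm[[2]]$gt[, 1])), 3L)   # exactly the 3 hets
  expect_true(all(is.na(mm[[3]]$gt)))
})

test_that("tri-allelic records expand to the three allele-pair contrasts", {
  recs <- list(list(chrom = "chr3", pos = 10, id = "tri", ref = "A",
                    alt = "C,T", mq = 55,
                    gt = c(rep("0/0", 4), rep("1/1", 3), rep("2/2", 2),
                           "0/1")))
  rr <- mask_heterozygotes(read_vcf(write_toy_vcf(recs, samples10)))
  sp <- split_multiallelic(rr)
  expect_length(sp, 3L)
  expect_identical(vapply(sp, `[[`, character(1), "ref"), c("A", "A", "C"))
  expect_identical(vapply(sp, function(r) r$alt, character(1)),
                   c("C", "T", "T"))
  # derived (A,C): A/A -> hom-ref, C/C -> hom-alt, T/T -> missing
  enc <- encode_genotypes(sp)
  expect_identical(unname(enc$codes[1:9, 1]),
                   c(-1, -1, -1, -1, 1, 1, 1, NA, NA))
  expect_identical(unname(enc$codes[1:9, 2]),
                   c(-1, -1, -1, -1, NA, NA, NA, 1, 1))
  expect_identical(unname(enc$codes[1:9, 3]),
                   c(NA, NA, NA, NA, -1, -1, -1, 1, 1))
  # masked het stays missing everywhere
  expect_true(all(is.na(enc$codes[10, ])))
  # metadata duplicated from the parent
  expect_true(all(vapply(sp, `[[`, numeric(1), "mq") == 55))
  expect_true(all(vapply(sp, `[[`, integer(1), "pos") == 10L))
  # bi-allelic records pass through unchanged
  bi <- read_vcf(write_toy_vcf(list(
    list(chrom = "chr1", pos = 5, id = "bi", ref = "G", alt = "T", mq = 50,
         gt = rep(c("0/0", "1/1"), 5))), samples10))
  expect_identical(split_multiallelic(bi)[[1]], bi[[1]])
})

test_that("each sample is observed in exactly two of the three derived records", {
  recs <- list(list(chrom = "chr3", pos = 10, id = "tri", ref = "A",
                    alt = "C,T", mq = 55,
                    gt = c(rep("0/0", 3), rep("1/1", 3), rep("2/2", 3),
                           "./.")))
  sp <- split_multiallelic(read_vcf(write_toy_vcf(recs, samples10)))
  observed <- sapply(sp, function(r) !is.na(r$gt[, 1]))
  expect_identical(unname(rowSums(observed)[1:9]), rep(2, 9))
  expect_identical(unname(rowSums(observed)[10]), 0)
})

test_that("variant filters keep exactly the clean records", {
  hom <- function(codes) c("0/0", "1/1")[(codes + 3) / 2]
  clean_gt <- rep(c("0/0", "1/1"), 5)
  recs <- list(
    list(chrom = "chr1", pos = 100, id = "clean1", ref = "A", alt = "C",
         mq = 50, gt = clean_gt),
    list(chrom = "chr1", pos = 200, id = "low_maf", ref = "A", alt = "C",
         mq = 50, gt = rep("0/0", 10)),
    list(chrom = "chr1", pos = 300, id = "low_mq", ref = "A", alt = "C",
         mq = 39, gt = clean_gt),
    list(chrom = "chr1", pos = 400, id = "low_call", ref = "A", alt = "C",
         mq = 50, gt = c("0/0", "1/1", "0/0", rep("./.", 7))),
    list(chrom = "chr1", pos = 500, id = "clean2", ref = "G", alt = "T",
         mq = 40, gt = clean_gt),                      # MQ 40 boundary kept
    list(chrom = "chr1", pos = 600, id = "clean3", ref = "G", alt = "T",
         mq = 60, gt = c(rep("0/0", 7), rep("1/1", 3))))
  rr <- mask_heterozygotes(read_vcf(write_toy_vcf(recs, samples10)))
  kept <- filter_variants(rr)
  expect_identical(vapply(kept, `[[`, character(1), "id"),
                   c("clean1", "clean2", "clean3"))
  # idempotence
  expect_identical(unclass(filter_variants(kept)), unclass(kept))
})

test_that("MAF and call-rate boundaries are inclusive", {
  # 20 samples: one ALT hom among 20 calls -> allele freq exactly 0.05
  s20 <- toy_samples(20)
  recs <- list(
    list(chrom = "chr1", pos = 1, id = "maf05", ref = "A", alt = "C",
         mq = 50, gt = c("1/1", rep("0/0", 19))),
    list(chrom = "chr1", pos = 2, id = "cr40", ref = "A", alt = "C",
         mq = 50, gt = c(rep(c("0/0", "1/1"), 4), rep("./.", 12))))
  rr <- read_vcf(write_toy_vcf(recs, s20))
  kept <- filter_variants(rr)
  expect_identical(vapply(kept, `[[`, character(1), "id"),
                   c("maf05", "cr40"))
})

test_that("mask -> split -> filter keeps a superset of the unsplit bi-allelic survivors", {
  cfg <- sim_config(m = 50, p = 80, tri_fraction = 0.25, seed = 31)
  g <- simulate_genotypes(cfg)
  path <- tempfile(fileext = ".vcf")
  write_vcf_fixture(g, cfg, path)
  masked <- mask_heterozygotes(read_vcf(path))
  with_split <- filter_variants(split_multiallelic(masked))
  bi_only <- masked[vapply(masked, function(r) length(r$alt) == 1L,
                           logical(1))]
  without_split <- filter_variants(bi_only)
  ids_with <- vapply(with_split, `[[`, character(1), "id")
  ids_without <- vapply(without_split, `[[`, character(1), "id")
  expect_true(all(ids_without %in% ids_with))
  expect_gte(length(ids_with), length(ids_without))
})

test_that("encode_genotypes maps homozygote classes and rejects bad input", {
  recs <- list(
    list(chrom = "chr1", pos = 1, id = "a", ref = "A", alt = "C", mq = 50,
         gt = c(rep("0/0", 10))),
    list(chrom = "chr1", pos = 2, id = "b", ref = "A", alt = "C", mq = 50,
         gt = c("0/0", "1/1", "./.", rep("0/0", 7))))
  rr <- read_vcf(write_toy_vcf(recs, samples10))
  enc <- encode_genotypes(rr)
  expect_true(all(enc$codes[, 1] == -1))
  expect_identical(unname(enc$codes[1:3, 2]), c(-1, 1, NA))
  expect_error(encode_genotypes(rr, varieties = c("S01", "NOPE")), "unknown")
  tri <- read_vcf(write_toy_vcf(list(
    list(chrom = "chr1", pos = 9, id = "t", ref = "A", alt = "C,T", mq = 50,
         gt = rep("0/0", 10))), samples10))
  expect_error(encode_genotypes(tri), "multi-allelic")
})

test_that("records with more than three alleles are dropped with a warning", {
  recs <- list(
    list(chrom = "chr1", pos = 1, id = "quad", ref = "A", alt = "C,G,T",
         mq = 50, gt = rep("0/0", 10)),
    list(chrom = "chr1", pos = 2, id = "bi", ref = "A", alt = "C", mq = 50,
         gt = rep(c("0/0", "1/1"), 5)))
  rr <- read_vcf(write_toy_vcf(recs, samples10))
  expect_warning(sp <- split_multiallelic(rr), ">3 alleles")
  expect_identical(vapply(sp, `[[`, character(1), "id"), "bi")
})

test_that("variant records round-trip through write_vcf_records", {
  cfg <- sim_config(m = 15, p = 20, tri_fraction = 0.2, seed = 157)
  g <- simulate_genotypes(cfg)
  p1 <- tempfile(fileext = ".vcf")
  write_vcf_fixture(g, cfg, p1)
  rec <- mask_heterozygotes(read_vcf(p1))
  p2 <- tempfile(fileext = ".vcf")
  write_vcf_records(rec, p2)
  back <- read_vcf(p2)
  expect_identical(lapply(unclass(back), `[[`, "gt"),
                   lapply(unclass(rec), `[[`, "gt"))
  expect_identical(vapply(back, `[[`, character(1), "ref"),
                   vapply(rec, `[[`, character(1), "ref"))
})
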