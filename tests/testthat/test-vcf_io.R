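test_that("VCF parsing recovers additive coding, phase, flags and missing calls", {
  path <- write_toy_vcf(c(
    "1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0|0\t0|1",
    "1\t200\trs1\tC\tT\t.\tPASS\tIMPACT=HIGH\tGT\t0|1\t1|1",
    "1\t300\t.\tG\tG,T\t.\tPASS\t.\tGT\t1|1\t0|2"))
  gm <- read_vcf(path)
  expect_equal(unname(gm$gt["A", ]), c(0L, 1L, 2L))
  expect_equal(unname(gm$gt["B", ]), c(1L, 2L, 1L))
  expect_true(gm$phased)
  expect_equal(gm$variants$multiallelic, c(FALSE, FALSE, TRUE))
  expect_equal(gm$variants$impact, c(NA, "HIGH", NA))
  expect_equal(gm$variants$id, c(NA, "rs1", NA))

  miss <- read_vcf(write_toy_vcf("1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t./.\t0/1"))
  expect_true(is.na(miss$gt["A", 1]))
  expect_equal(unname(miss$gt["B", 1]), 1L)
  expect_false(miss$phased)
})

test_that("write/read round trip is the identity on genotypes, phase and order", {
  for (seed in 1:3) {
    gm <- random_gm(5, 40, seed = seed, miss = 0.15)
    path <- tempfile(fileext = ".vcf")
    write_vcf(gm, path)
    back <- read_vcf(path)
    expect_identical(unname(back$gt), unname(gm$gt))
    expect_identical(back$sample_ids, gm$sample_ids)
    expect_identical(back$variants$pos, gm$variants$pos)
    expect_false(back$phased)

    ph <- random_gm(4, 30, seed = seed + 10, phased = TRUE)
    write_vcf(ph, path)
    back <- read_vcf(path)
    expect_true(back$phased)
    expect_identical(unname(back$haplotypes), unname(ph$haplotypes))
    expect_identical(unname(back$gt), unname(ph$gt))
  }
})

test_that("dosages round trip through the DS field to three decimals", {
  gm <- random_gm(3, 10, seed = 2, miss = 0)
  ds <- matrix(c(1.234, runif(29, 0, 2)), nrow = 3)
  dos <- structure(list(sample_ids = gm$sample_ids, variants = gm$variants,
                        ds = ds, post_var = ds * 0,
                        dr2 = runif(10)),
                   class = "imputed_dosages")
  path <- tempfile(fileext = ".vcf")
  write_vcf(gm, path, dosages = dos)
  back <- read_dosage_vcf(path)
  expect_equal(unname(back$ds), unname(ds), tolerance = 1e-3)
  expect_equal(back$dr2, dos$dr2, tolerance = 1e-4)
})

test_that("an empty matrix writes a valid header-only VCF", {
  gm <- genotype_matrix(matrix(integer(0), nrow = 2, ncol = 0),
                        data.frame(chrom = character(0), pos = integer(0)),
                        sample_ids = c("A", "B"), chrom_order = "1")
  path <- tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  back <- read_vcf(path)
  expect_equal(n_variants(back), 0L)
  expect_equal(back$sample_ids, c("A", "B"))
})

test_that("variant statistics classify transitions, transversions and indels", {
  mk <- function(ref, alt) {
    m <- length(ref)
    genotype_matrix(matrix(0L, 2, m),
                    data.frame(chrom = rep("1", m), pos = seq_len(m) * 10,
                               ref = ref, alt = alt))
  }
  st <- compute_variant_stats(mk(c("A", "C", "A"), c("G", "T", "C")))
  expect_equal(st$ti, 2); expect_equal(st$tv, 1); expect_equal(st$titv, 2.0)

  empty <- compute_variant_stats(mk(character(0), character(0)))
  expect_equal(empty$n_sites, 0)
  expect_true(is.nan(empty$titv))

  mixed <- compute_variant_stats(mk(c("A", "A"), c("G", "AT")))
  expect_equal(mixed$n_snps, 1); expect_equal(mixed$n_indels, 1)

  multi <- compute_variant_stats(mk("G", "G,T"))
  expect_equal(multi$n_multiallelic, 1)
  expect_equal(multi$n_snps, 0)
})

test_that("Ti/Tv matches brute-force pair classification on random SNP sets", {
  set.seed(99)
  for (i in 1:5) {
    m <- 50
    ref <- sample(c("A", "C", "G", "T"), m, TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                  character(1))
    gm <- genotype_matrix(matrix(0L, 2, m),
                          data.frame(chrom = "1", pos = seq_len(m), ref = ref,
                                     alt = alt))
    st <- compute_variant_stats(gm)
    oracle <- titv_brute(ref, alt)
    expect_equal(st$ti, unname(oracle["ti"]))
    expect_equal(st$tv, unname(oracle["tv"]))
  }
})

test_that("marker panels load deduplicated and sorted from TSV and BED", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("1\t100", "1\t100", "1\t50"), tsv)
  p <- load_marker_panel(tsv)
  expect_equal(p$sites$pos, c(50L, 100L))

  bed <- tempfile(fileext = ".bed")
  writeLines("1\t99\t100", bed)
  pb <- load_marker_panel(bed)
  expect_equal(pb$sites$pos, 100L)

  bad <- tempfile()
  writeLines(c("1\tx", "1\ty"), bad)
  expect_error(load_marker_panel(bad), "non-numeric")
})

test_that("masking counts the panel/VCF intersection", {
  gm <- random_gm(3, 10, seed = 5, miss = 0)
  inside <- gm$variants$pos[c(2, 5, 9)]
  p <- marker_panel(rep("chr1", 5), c(inside, 1L, 2L))
  masked <- mask_to_panel(gm, p)
  expect_equal(sum(colSums(!is.na(masked$gt)) > 0), 3)
})

test_that("variants are strictly sorted by chromosome-order and position", {
  v <- data.frame(chrom = c("chr2", "chr1", "chr2", "chr1"),
                  pos = c(5L, 9L, 1L, 3L))
  gm <- genotype_matrix(matrix(0L, 1, 4), v, chrom_order = c("chr2", "chr1"))
  expect_equal(gm$variants$chrom, c("chr2", "chr2", "chr1", "chr1"))
  expect_equal(gm$variants$pos, c(1L, 5L, 3L, 9L))
})
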