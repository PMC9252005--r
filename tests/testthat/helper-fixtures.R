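# Fixtures are generated in code at test time. The heavier simulated
# cohorts are memoised per (label, seed) so several test files can share
# one build within a run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# A small single-chromosome cohort: 40 target-cluster, 10 related,
# 10 distant samples, 2,000 sites on 2 Mb.
small_sim <- function(seed = 7, planted_lethal = NULL) {
  cached(paste0("small_", seed, "_", is.null(planted_lethal)), {
    cfg <- sim_config(
      chrom_lengths = c(chr1 = 2e6), n_variants = 2000,
      breeds = list(breed_group_spec("wb", 1, 0.02, 40),
                    breed_group_spec("ar", 2, 0.10, 10),
                    breed_group_spec("sh", 3, 0.30, 10)),
      panel_sizes = c(medium = 120, high = 1000),
      coverage_gaps = data.frame(chrom = "chr1", start = 5e5, end = 6e5),
      planted_lethal = planted_lethal, seed = seed)
    simulate_dataset(cfg)
  })
}

small_rp <- function(d) {
  tiers <- d$breed_labels$tier
  names(tiers) <- d$breed_labels$sample
  build_reference_panels(tiers)
}

# Random unphased genotype matrix with missingness, for round-trip and
# distance properties.
random_gm <- function(n, m, seed, miss = 0.1, phased = FALSE) {
  set.seed(seed)
  pos <- sort(sample.int(1e6, m))
  v <- data.frame(chrom = "chr1", pos = pos,
                  ref = sample(c("A", "C", "G", "T"), m, TRUE),
                  alt = NA_character_)
  v$alt <- vapply(v$ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                  character(1))
  if (phased) {
    hap <- matrix(rbinom(2 * n * m, 1, 0.4), nrow = 2 * n)
    gt <- hap[seq(1, 2 * n, 2), , drop = FALSE] + hap[seq(2, 2 * n, 2), , drop = FALSE]
    genotype_matrix(gt, v, sample_ids = sprintf("S%02d", 1:n),
                    phased = TRUE, haplotypes = hap)
  } else {
    gt <- matrix(rbinom(n * m, 2, 0.4), nrow = n)
    gt[matrix(runif(n * m) < miss, nrow = n)] <- NA_integer_
    genotype_matrix(gt, v, sample_ids = sprintf("S%02d", 1:n))
  }
}

# Write VCF body lines to a temp file, with a minimal header.
write_toy_vcf <- function(body, samples = c("A", "B")) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body), path)
  path
}
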