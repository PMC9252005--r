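#' Describe one breed group for simulation
#'
#' Breeds are organised in three tiers of genetic distance from the
#' target cluster, mirroring the grouping of a multi-breed cohort by
#' multidimensional scaling: tier 1 is the target cluster itself, tier 2
#' contains related breeds, tier 3 distant ones.
#'
#' @param label breed name.
#' @param tier relationship tier, 1, 2 or 3.
#' @param F Balding-Nichols drift parameter in `[0, 1)`; larger values
#'   mean stronger divergence of the breed's allele frequencies from the
#'   ancestral frequency.
#' @param n number of diploid individuals.
#' @return a `breed_group_spec` list.
#' @export
breed_group_spec <- function(label, tier, F, n) {
  stopifnot(tier %in% 1:3, F >= 0, F < 1, n >= 1)
  structure(list(label = label, tier = as.integer(tier), F = F,
                 n_individuals = as.integer(n)),
            class = "breed_group_spec")
}

#' Simulation configuration
#'
#' Bundles all parameters of the synthetic multi-breed sequence panel.
#' The defaults define a desk-scale cohort of 120 horses-like samples:
#' 65 target-cluster animals (the size of a cross-validation panel of
#' five 13-animal folds), 30 related and 25 distant, on two 10-Mb
#' chromosomes with 20,000 polymorphic sites.
#'
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param n_variants total number of simulated sites.
#' @param ancestral_sfs `c(shape1, shape2)` of the Beta distribution of
#'   ancestral allele frequencies; the default `c(0.5, 0.5)` gives a
#'   U-shaped site-frequency spectrum.
#' @param breeds list of [breed_group_spec()]s. Within a configuration,
#'   tier-1 `F` must not exceed tier-2 `F`, nor tier-2 tier-3.
#' @param recomb_rate recombination rate in cM/Mb (default 1), which sets
#'   the mean mosaic segment length to `1/recomb_rate` Mb.
#' @param panel_sizes `c(medium = ..., high = ...)` requested marker
#'   counts for the two nested arrays; the default keeps the roughly 1:9
#'   medium:high density ratio of commercial 60K vs 670K equine chips.
#' @param coverage_gaps data frame `chrom, start, end` (bp) of intervals
#'   that carry no array markers, emulating assembly regions not covered
#'   by the chips.
#' @param panel_maf_min minimum cohort MAF for a site to be eligible for
#'   an array (default 0.05, as arrays target common variants).
#' @param high_impact_fraction fraction of sites annotated HIGH impact.
#' @param planted_lethal `NULL`, or `list(q = target allele frequency,
#'   tier = carrier tier scope)` for a planted recessive lethal with zero
#'   alt homozygotes.
#' @param n_founders breed-founder haplotypes per breed (default 20).
#' @param mutation_rate per-site allele flip rate on copied haplotypes
#'   (default 0.002).
#' @param seed integer seed; all randomness flows from it through named
#'   substreams so partial reruns are reproducible.
#' @return a `sim_config` list.
#' @export
sim_config <- function(chrom_lengths = c(chr1 = 10e6, chr2 = 10e6),
                       n_variants = 20000,
                       ancestral_sfs = c(0.5, 0.5),
                       breeds = default_breeds(),
                       recomb_rate = 1.0,
                       panel_sizes = c(medium = 600, high = 5400),
                       coverage_gaps = data.frame(chrom = "chr1",
                                                  start = 5e6, end = 6e6),
                       panel_maf_min = 0.05,
                       high_impact_fraction = 0.01,
                       planted_lethal = NULL,
                       n_founders = 20,
                       mutation_rate = 0.002,
                       seed = 1) {
  stopifnot(all(chrom_lengths > 0), n_variants >= 1,
            length(ancestral_sfs) == 2, all(ancestral_sfs > 0),
            recomb_rate > 0, n_founders >= 2,
            mutation_rate >= 0, mutation_rate <= 1,
            high_impact_fraction >= 0, high_impact_fraction <= 1,
            panel_maf_min >= 0, panel_maf_min <= 0.5)
  if (!all(c("medium", "high") %in% names(panel_sizes))) {
    stop("panel_sizes must name 'medium' and 'high'")
  }
  if (!(panel_sizes["medium"] <= panel_sizes["high"] &&
        panel_sizes["high"] <= n_variants)) {
    stop("need panel_sizes['medium'] <= panel_sizes['high'] <= n_variants")
  }
  tiers <- vapply(breeds, `[[`, integer(1), "tier")
  Fs <- vapply(breeds, `[[`, numeric(1), "F")
  for (t in 1:2) {
    if (any(tiers == t) && any(tiers == t + 1) &&
        max(Fs[tiers == t]) > min(Fs[tiers == t + 1])) {
      stop("tier-", t, " F must not exceed tier-", t + 1, " F")
    }
  }
  if (!is.null(planted_lethal)) {
    stopifnot(planted_lethal$q > 0, planted_lethal$q <= 0.5)
    if (is.null(planted_lethal$tier)) planted_lethal$tier <- 1:3
  }
  structure(list(chrom_lengths = chrom_lengths, n_variants = n_variants,
                 ancestral_sfs = ancestral_sfs, breeds = breeds,
                 recomb_rate = recomb_rate, panel_sizes = panel_sizes,
                 coverage_gaps = coverage_gaps, panel_maf_min = panel_maf_min,
                 high_impact_fraction = high_impact_fraction,
                 planted_lethal = planted_lethal, n_founders = n_founders,
                 mutation_rate = mutation_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_breeds <- function() {
  list(breed_group_spec("warmblood", 1, 0.02, 65),
       breed_group_spec("related_a", 2, 0.10, 15),
       breed_group_spec("related_b", 2, 0.10, 15),
       breed_group_spec("distant_a", 3, 0.30, 13),
       breed_group_spec("distant_b", 3, 0.30, 12))
}

# Named-substream splitter: every operation draws its own seed from the
# master seed, so regenerating one component does not perturb the others.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.integer(seed) * 7919L + as.integer(h %% 104729L)) %% 2147483562L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  expr
}

#' Simulate a structured multi-breed phased dataset
#'
#' Generates a fully phased sequence-level cohort: ancestral allele
#' frequencies from a Beta site-frequency spectrum, breed frequencies
#' via the Balding-Nichols model, per-breed founder haplotype pools, and
#' sample haplotypes as recombinant mosaics of the founders with
#' per-site mutation. Nested medium/high marker panels and HIGH-impact
#' annotations are drawn from the result, and an optional recessive
#' lethal is planted with zero alt homozygotes.
#'
#' @param cfg a [sim_config()].
#' @return a `simulated_dataset` list with elements `gm` (phased truth
#'   [genotype_matrix()]), `panels` (`$medium`, `$high`
#'   [marker_panel()]s), `breed_labels` (data frame `sample`, `breed`,
#'   `tier`) and `truth_info` (planted-lethal bookkeeping or `NULL`).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  chroms <- names(cfg$chrom_lengths)
  m_per <- distribute_counts(cfg$n_variants, cfg$chrom_lengths)
  positions <- with_seed(substream_seed(cfg$seed, "positions"), {
    do.call(rbind, lapply(seq_along(chroms), function(ci) {
      data.frame(chrom = chroms[ci],
                 pos = sort(sample.int(cfg$chrom_lengths[ci], m_per[ci])))
    }))
  })
  m <- nrow(positions)

  p_anc <- with_seed(substream_seed(cfg$seed, "ancestral"),
                     stats::rbeta(m, cfg$ancestral_sfs[1], cfg$ancestral_sfs[2]))

  n_total <- sum(vapply(cfg$breeds, `[[`, integer(1), "n_individuals"))
  hap <- matrix(0L, nrow = 2L * n_total, ncol = m)
  breed_labels <- data.frame(sample = character(n_total),
                             breed = character(n_total),
                             tier = integer(n_total))
  row0 <- 0L
  for (b in cfg$breeds) {
    founders <- with_seed(substream_seed(cfg$seed, paste0("founders_", b$label)),
                          breed_founders(p_anc, b$F, cfg$n_founders))
    nb <- b$n_individuals
    bh <- with_seed(substream_seed(cfg$seed, paste0("mosaic_", b$label)),
                    mosaic_haplotypes(founders, 2L * nb, positions,
                                      cfg$chrom_lengths, cfg$recomb_rate,
                                      cfg$mutation_rate))
    hap[row0 * 2L + seq_len(2L * nb), ] <- bh
    idx <- row0 + seq_len(nb)
    breed_labels$sample[idx] <- sprintf("%s_%02d", b$label, seq_len(nb))
    breed_labels$breed[idx] <- b$label
    breed_labels$tier[idx] <- b$tier
    row0 <- row0 + nb
  }

  truth_info <- NULL
  if (!is.null(cfg$planted_lethal)) {
    pl <- cfg$planted_lethal
    scope <- which(breed_labels$tier %in% pl$tier)
    n_carriers <- round(2 * length(scope) * pl$q)
    if (n_carriers > length(scope)) {
      stop("planted lethal infeasible: q = ", pl$q,
           " needs more heterozygous carriers than scoped samples")
    }
    site <- with_seed(substream_seed(cfg$seed, "lethal_site"), {
      s <- sample.int(m, 1)
      carriers <- sample(scope, n_carriers)
      which_hap <- sample(c(0L, 1L), n_carriers, replace = TRUE)
      hap[, s] <- 0L
      hap[2L * carriers - 1L + which_hap, s] <- 1L
      s
    })
    truth_info <- list(lethal_site = site,
                       lethal_chrom = positions$chrom[site],
                       lethal_pos = positions$pos[site],
                       lethal_q = n_carriers / (2 * length(scope)),
                       carrier_tiers = pl$tier)
  }

  gt <- hap[seq(1L, nrow(hap), 2L), , drop = FALSE] +
    hap[seq(2L, nrow(hap), 2L), , drop = FALSE]
  refalt <- with_seed(substream_seed(cfg$seed, "alleles"), random_snp_alleles(m))
  variants <- data.frame(chrom = positions$chrom, pos = positions$pos,
                         id = sprintf("var%06d", seq_len(m)),
                         ref = refalt$ref, alt = refalt$alt,
                         multiallelic = FALSE,
                         impact = NA_character_, dr2 = NA_real_)
  gm <- genotype_matrix(gt, variants, sample_ids = breed_labels$sample,
                        phased = TRUE, haplotypes = hap, chrom_order = chroms)

  panels <- design_marker_panels(gm, cfg)
  lethal_idx <- if (is.null(truth_info)) NULL else {
    match(paste(truth_info$lethal_chrom, truth_info$lethal_pos, sep = ":"),
          variant_keys(gm))
  }
  gm <- annotate_impacts(gm, cfg, lethal_index = lethal_idx)
  if (!is.null(truth_info)) truth_info$lethal_index <- lethal_idx

  structure(list(gm = gm, panels = panels, breed_labels = breed_labels,
                 truth_info = truth_info, config = cfg),
            class = "simulated_dataset")
}

distribute_counts <- function(total, weights) {
  raw <- total * weights / sum(weights)
  out <- floor(raw)
  rem <- total - sum(out)
  if (rem > 0) {
    extra <- order(raw - out, decreasing = TRUE)[seq_len(rem)]
    out[extra] <- out[extra] + 1
  }
  as.integer(out)
}

# Balding-Nichols breed frequencies, realised in a founder pool whose
# allele counts are stochastically rounded (floor + Bernoulli on the
# fraction) so the pool frequency is unbiased for the breed frequency
# without the extra drift that iid Bernoulli founder draws would add.
breed_founders <- function(p_anc, F, K) {
  m <- length(p_anc)
  p_b <- if (F == 0) p_anc else {
    stats::rbeta(m, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
  }
  target <- K * p_b
  counts <- floor(target) + (stats::runif(m) < target - floor(target))
  founders <- matrix(0L, nrow = K, ncol = m)
  ranks <- matrix(stats::runif(K * m), nrow = K, ncol = m)
  thresh <- matrix(counts, nrow = K, ncol = m, byrow = TRUE)
  ord <- apply(ranks, 2, function(col) rank(col, ties.method = "first"))
  founders[ord <= thresh] <- 1L
  founders
}

# Recombinant mosaics of the founder pool: segment lengths are
# exponential with mean 1/recomb_rate Mb, founder choice uniform per
# segment, then per-site mutation flips.
mosaic_haplotypes <- function(founders, n_haps, positions, chrom_lengths,
                              recomb_rate, mutation_rate) {
  K <- nrow(founders)
  m <- ncol(founders)
  out <- matrix(0L, nrow = n_haps, ncol = m)
  rate_bp <- recomb_rate / 1e6
  for (ci in seq_along(chrom_lengths)) {
    cols <- which(positions$chrom == names(chrom_lengths)[ci])
    L <- chrom_lengths[ci]
    pos <- positions$pos[cols]
    for (h in seq_len(n_haps)) {
      n_bp_max <- max(8L, ceiling(3 * L * rate_bp) + 8L)
      brk <- cumsum(stats::rexp(n_bp_max, rate_bp))
      while (sum(brk <= L) == length(brk)) {
        brk <- c(brk, brk[length(brk)] + cumsum(stats::rexp(n_bp_max, rate_bp)))
      }
      brk <- brk[brk <= L]
      seg <- findInterval(pos, brk) + 1L
      donors <- sample.int(K, length(brk) + 1L, replace = TRUE)
      out[h, cols] <- founders[cbind(donors[seg], cols)]
    }
  }
  if (mutation_rate > 0) {
    flips <- which(matrix(stats::runif(length(out)) < mutation_rate,
                          nrow = nrow(out)))
    out[flips] <- 1L - out[flips]
  }
  out
}

random_snp_alleles <- function(m) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  list(ref = ref, alt = unname(alt))
}

#' Design nested medium/high marker panels
#'
#' Draws the high-density panel as a MAF-weighted sample (without
#' replacement) of the eligible sites — cohort MAF at least
#' `cfg$panel_maf_min`, outside any coverage gap — and the medium panel
#' as a nested uniform subsample of the high panel.
#'
#' @param gm sequence-level [genotype_matrix()].
#' @param cfg a [sim_config()].
#' @return list with `marker_panel`s `$medium` and `$high`.
#' @export
design_marker_panels <- function(gm, cfg) {
  maf <- cohort_maf(gm)
  eligible <- !is.na(maf) & maf >= cfg$panel_maf_min & !gm$variants$multiallelic
  gaps <- cfg$coverage_gaps
  if (!is.null(gaps) && nrow(gaps) > 0) {
    for (i in seq_len(nrow(gaps))) {
      eligible <- eligible & !(gm$variants$chrom == gaps$chrom[i] &
                                 gm$variants$pos >= gaps$start[i] &
                                 gm$variants$pos <= gaps$end[i])
    }
  }
  n_high <- as.integer(cfg$panel_sizes["high"])
  n_med <- as.integer(cfg$panel_sizes["medium"])
  if (sum(eligible) < n_high) {
    stop("only ", sum(eligible), " eligible sites for a high panel of ", n_high)
  }
  with_seed(substream_seed(cfg$seed, "panels"), {
    hi <- sample(which(eligible), n_high, prob = maf[eligible])
    med <- sample(hi, n_med)
    list(medium = marker_panel(gm$variants$chrom[med], gm$variants$pos[med],
                               name = "medium", chrom_order = gm$chrom_order),
         high = marker_panel(gm$variants$chrom[hi], gm$variants$pos[hi],
                             name = "high", chrom_order = gm$chrom_order))
  })
}

cohort_maf <- function(gm) {
  ac <- colSums(gm$gt, na.rm = TRUE)
  an <- 2 * colSums(!is.na(gm$gt))
  f <- ifelse(an > 0, ac / an, NA_real_)
  pmin(f, 1 - f)
}

#' Annotate variant impact classes
#'
#' Labels each site HIGH independently with probability
#' `cfg$high_impact_fraction` (all others OTHER); a planted lethal site
#' is always labelled HIGH regardless of the draw.
#'
#' @param gm a [genotype_matrix()].
#' @param cfg a [sim_config()].
#' @param lethal_index optional variant index forced to HIGH.
#' @return `gm` with the `impact` column of its variant table filled.
#' @export
annotate_impacts <- function(gm, cfg, lethal_index = NULL) {
  m <- n_variants(gm)
  high <- with_seed(substream_seed(cfg$seed, "impacts"),
                    stats::runif(m) < cfg$high_impact_fraction)
  if (!is.null(lethal_index)) high[lethal_index] <- TRUE
  gm$variants$impact <- ifelse(high, "HIGH", "OTHER")
  gm
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("simulated_dataset:", n_samples(x$gm), "samples,", n_variants(x$gm),
      "sites,", length(unique(x$breed_labels$breed)), "breeds\n")
  cat("  panels: medium =", nrow(x$panels$medium$sites),
      " high =", nrow(x$panels$high$sites), "\n")
  if (!is.null(x$truth_info)) {
    cat("  planted lethal at", x$truth_info$lethal_chrom, ":",
        x$truth_info$lethal_pos, "(q =",
        signif(x$truth_info$lethal_q, 3), ")\n")
  }
  invisible(x)
}
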