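#' Parameters of the haplotype-copying HMM
#'
#' @param ne effective population size scaling the switch rate
#'   (dimensionless, default 1000, the value commonly used for horse
#'   panels).
#' @param err allele-mismatch emission probability (default 1e-3).
#' @param recomb_rate cM/Mb used to convert bp gaps to Morgans
#'   (default 1).
#' @param min_switch floor on the per-interval switch probability so
#'   zero-length gaps never freeze the chain (default 1e-8).
#' @return an `hmm_params` list.
#' @export
hmm_params <- function(ne = 1000, err = 1e-3, recomb_rate = 1.0,
                       min_switch = 1e-8) {
  stopifnot(ne > 0, err > 0, err < 0.5, recomb_rate > 0, min_switch > 0)
  structure(list(ne = ne, err = err, recomb_rate = recomb_rate,
                 min_switch = min_switch),
            class = "hmm_params")
}

#' Cumulative genetic map from physical positions
#'
#' Constant-rate map: position `p` bp at `rate` cM/Mb lies at
#' `p * rate * 1e-8` Morgans (1 cM/Mb = 1e-8 Morgan/bp).
#'
#' @param positions sorted ascending bp positions.
#' @param rate recombination rate in cM/Mb.
#' @return numeric vector of non-decreasing map positions in Morgans.
#' @export
build_genetic_map <- function(positions, rate = 1.0) {
  if (is.unsorted(positions)) stop("positions must be sorted ascending")
  positions * rate * 1e-8
}

#' Impute one sample on one chromosome
#'
#' Runs the diploid Li-Stephens forward-backward pass for a single
#' target: the hidden state is an ordered pair of reference haplotypes,
#' each copy switching between sites with probability
#' `1 - exp(-4 ne dM / K)` to a uniformly chosen haplotype, and typed
#' genotypes observed through an allele-mismatch error `err`. Returns
#' the posterior expected alt dosage and posterior dosage variance at
#' every sequence site.
#'
#' @param target_gt integer vector of genotypes (0/1/2, `NA` missing)
#'   over all `M` sequence sites of the chromosome; only entries where
#'   `typed` is `TRUE` are used as observations.
#' @param ref_haps `K x M` 0/1 matrix of phased reference haplotypes.
#' @param typed logical mask of typed sites (default: all non-missing).
#' @param map genetic map in Morgans (default: built from `positions`).
#' @param positions bp positions, used when `map` is not given.
#' @param params an [hmm_params()].
#' @return list with numeric vectors `ds` (in `[0, 2]`) and `post_var`.
#' @export
impute_sample <- function(target_gt, ref_haps, typed = NULL, map = NULL,
                          positions = NULL, params = hmm_params()) {
  ref_haps <- as.matrix(ref_haps)
  storage.mode(ref_haps) <- "integer"
  M <- ncol(ref_haps)
  stopifnot(length(target_gt) == M, nrow(ref_haps) >= 1,
            all(ref_haps %in% c(0L, 1L)))
  if (is.null(map)) {
    if (is.null(positions)) stop("supply either map or positions")
    map <- build_genetic_map(positions, params$recomb_rate)
  }
  stopifnot(length(map) == M)
  gt <- as.integer(target_gt)
  if (!is.null(typed)) gt[!typed] <- NA_integer_
  out <- .ls_impute_chrom(gt, ref_haps, as.numeric(map),
                          params$ne, params$err, params$min_switch)
  out$ds <- pmin(pmax(out$ds, 0), 2)
  out
}

#' Impute a set of target samples against a phased reference
#'
#' Masks each target to the typed-site panel and imputes every sequence
#' site chromosome by chromosome. Samples are conditionally independent
#' given the reference, so results do not depend on processing order.
#'
#' @param targets unphased [genotype_matrix()] of the target samples at
#'   all sequence sites (genotypes outside `panel` may already be
#'   missing; any that are not are masked here).
#' @param reference phased [genotype_matrix()] of the reference samples
#'   at the same sites. Every typed site must be present in the
#'   reference.
#' @param panel a [marker_panel()] of typed sites, or `NULL` to use all
#'   non-missing target genotypes.
#' @param params an [hmm_params()].
#' @return an `imputed_dosages` object: `sample_ids`, `variants`, the
#'   samples x variants matrices `ds` and `post_var`, and the
#'   per-variant `dr2` from [compute_dr2()].
#' @export
impute_panel <- function(targets, reference, panel = NULL,
                         params = hmm_params()) {
  stopifnot(reference$phased)
  if (!identical(variant_keys(targets), variant_keys(reference))) {
    stop("imputation requires the reference to cover all target sites")
  }
  if (any(targets$sample_ids %in% reference$sample_ids)) {
    stop("target and reference sample sets overlap")
  }
  typed <- if (is.null(panel)) rep(TRUE, n_variants(targets)) else {
    variant_keys(targets) %in% variant_keys(panel)
  }
  n <- n_samples(targets)
  M <- n_variants(targets)
  ds <- matrix(NA_real_, n, M, dimnames = list(targets$sample_ids, NULL))
  pv <- matrix(NA_real_, n, M)
  for (chr in targets$chrom_order) {
    cols <- which(targets$variants$chrom == chr)
    if (!length(cols)) next
    map <- build_genetic_map(targets$variants$pos[cols], params$recomb_rate)
    H <- reference$haplotypes[, cols, drop = FALSE]
    tmask <- typed[cols]
    for (s in seq_len(n)) {
      g <- targets$gt[s, cols]
      out <- impute_sample(g, H, typed = tmask, map = map, params = params)
      ds[s, cols] <- out$ds
      pv[s, cols] <- out$post_var
    }
  }
  structure(list(sample_ids = targets$sample_ids,
                 variants = targets$variants,
                 ds = ds, post_var = pv,
                 dr2 = compute_dr2(ds, pv)),
            class = "imputed_dosages")
}

#' @export
print.imputed_dosages <- function(x, ...) {
  cat("imputed_dosages:", length(x$sample_ids), "samples x",
      nrow(x$variants), "variants; mean DR2 =",
      format(mean(x$dr2, na.rm = TRUE), digits = 3), "\n")
  invisible(x)
}

#' Per-variant dosage R-squared
#'
#' Estimated squared correlation between imputed and true allele dose,
#' computed from the posterior dosage variance (the Browning-style
#' variance-ratio form):
#' \deqn{DR2_j = \frac{Var_s(ds_{sj})}{Var_s(ds_{sj}) + mean_s(postvar_{sj})}}
#' clamped to `[0, 1]`. A variant with zero dosage variance and zero
#' mean posterior variance is defined to have DR2 = 0.
#'
#' @param ds samples x variants dosage matrix (at least 2 samples).
#' @param post_var matching posterior variance matrix.
#' @return numeric vector of per-variant DR2 in `[0, 1]`.
#' @export
compute_dr2 <- function(ds, post_var) {
  ds <- as.matrix(ds); post_var <- as.matrix(post_var)
  if (nrow(ds) < 2) stop("DR2 needs at least 2 samples")
  v <- apply(ds, 2, stats::var)
  mpv <- colMeans(post_var)
  denom <- v + mpv
  out <- ifelse(denom > 0, v / denom, 0)
  pmin(pmax(out, 0), 1)
}
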