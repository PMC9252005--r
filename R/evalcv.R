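#' Split samples into cross-validation folds
#'
#' Seeded permutation of the ids followed by a split into `k` contiguous
#' blocks whose sizes differ by at most one (the first `n mod k` folds
#' get the extra sample). 65 samples at `k = 5` give five folds of 13.
#'
#' @param ids character vector of sample ids.
#' @param k number of folds (>= 2).
#' @param seed integer seed; the assignment is deterministic given
#'   `(ids, k, seed)`.
#' @return a `fold_assignment` list with `fold_of` (named integer vector
#'   of fold indices 1..k), `k` and `seed`.
#' @export
make_folds <- function(ids, k, seed = 1) {
  stopifnot(k >= 2)
  n <- length(ids)
  if (k > n) stop("more folds (", k, ") than samples (", n, ")")
  perm <- with_seed(seed, sample(ids))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  fold_of <- rep(seq_len(k), times = sizes)
  names(fold_of) <- perm
  fold_of <- fold_of[ids]
  structure(list(fold_of = fold_of, k = as.integer(k), seed = as.integer(seed)),
            class = "fold_assignment")
}

#' Select folds cyclically around a validation fold
#'
#' Returns the `m` folds after (or before) the validation fold in
#' cyclic order, excluding the validation fold itself. With folds
#' labelled (a)..(e) this reproduces the usual worked patterns: the two
#' folds following (c) are (d) and (e); the three following are (d),
#' (e), (a); the two preceding (b) are (e) and (a).
#'
#' @param validation_fold index in 1..k.
#' @param m number of folds to select, `1 <= m <= k - 1`.
#' @param direction `"following"` or `"previous"`.
#' @param k total fold count.
#' @return integer vector of `m` fold indices in cyclic order.
#' @export
select_cyclic_folds <- function(validation_fold, m,
                                direction = c("following", "previous"), k) {
  direction <- match.arg(direction)
  stopifnot(validation_fold >= 1, validation_fold <= k, m >= 1)
  if (m >= k) stop("m must be < k (cannot select the validation fold)")
  v0 <- validation_fold - 1L  # 0-based arithmetic
  off <- if (direction == "following") seq_len(m) else -(m:1)
  ((v0 + off) %% k) + 1L
}

#' Mask genotypes down to a marker panel
#'
#' Sets genotypes at all sites outside the panel to missing while
#' keeping the sites in the matrix (so they remain imputation targets).
#' The result is unphased. Masking is idempotent.
#'
#' @param gm a [genotype_matrix()].
#' @param panel a [marker_panel()].
#' @return the masked, unphased `genotype_matrix`.
#' @export
mask_to_panel <- function(gm, panel) {
  keep <- variant_keys(gm) %in% variant_keys(panel)
  gt <- gm$gt
  gt[, !keep] <- NA_integer_
  genotype_matrix(gt, gm$variants, sample_ids = gm$sample_ids,
                  phased = FALSE, chrom_order = gm$chrom_order)
}

#' Per-variant minor allele frequency from the RP1 sequence data
#'
#' MAF is computed from the sequence-level genotypes of the RP1 animals
#' only: `maf = min(f, 1 - f)` with `f` the alt-allele count over twice
#' the non-missing RP1 genotypes. Variants missing in all RP1 samples
#' get `NA`.
#'
#' @param gm sequence-level [genotype_matrix()].
#' @param rp1_ids RP1 sample ids.
#' @return numeric vector of per-variant MAF in `[0, 0.5]`.
#' @export
reference_maf <- function(gm, rp1_ids) {
  stopifnot(length(rp1_ids) > 0)
  idx <- match(rp1_ids, gm$sample_ids)
  if (anyNA(idx)) stop("unknown RP1 sample id")
  g <- gm$gt[idx, , drop = FALSE]
  ac <- colSums(g, na.rm = TRUE)
  an <- 2 * colSums(!is.na(g))
  f <- ifelse(an > 0, ac / an, NA_real_)
  pmin(f, 1 - f)
}

#' Configure an imputation scenario
#'
#' @param validation_fold fold index used for validation.
#' @param reference_mode `"cyclic"` (reference = `m` folds following the
#'   validation fold), `"rp2"` or `"rp3"` (all `k - 1` other folds plus
#'   the tier-2, resp. tier-2 and tier-3, animals).
#' @param m number of reference folds for `"cyclic"` mode (2, 3 or 4).
#' @param density `"medium"` or `"high"` marker panel for the targets.
#' @param two_step logical; two-step imputation (medium -> high ->
#'   sequence) instead of direct imputation. Requires `density =
#'   "medium"`.
#' @param dr2_threshold optional DR2 cutoff in `[0, 1]` applied to the
#'   step-one output (sites with DR2 >= threshold are kept); only
#'   meaningful with `two_step = TRUE`.
#' @param joint_target impute all RP1 samples at once using only the
#'   tier-2/3 animals as reference (the information-content scenario).
#' @param hmm an [hmm_params()].
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(validation_fold = 1,
                            reference_mode = c("cyclic", "rp2", "rp3"),
                            m = 4, density = c("medium", "high"),
                            two_step = FALSE, dr2_threshold = NULL,
                            joint_target = FALSE, hmm = hmm_params()) {
  reference_mode <- match.arg(reference_mode)
  density <- match.arg(density)
  if (two_step && density != "medium") {
    stop("two-step imputation starts from the medium panel")
  }
  if (!is.null(dr2_threshold)) {
    stopifnot(dr2_threshold >= 0, dr2_threshold <= 1)
    if (!two_step) stop("dr2_threshold applies to two-step imputation only")
  }
  structure(list(validation_fold = as.integer(validation_fold),
                 reference_mode = reference_mode, m = as.integer(m),
                 density = density, two_step = two_step,
                 dr2_threshold = dr2_threshold,
                 joint_target = joint_target, hmm = hmm),
            class = "scenario_config")
}

#' Run one imputation scenario
#'
#' Assembles the reference haplotypes and target samples implied by the
#' scenario, masks the targets to the scenario's marker panel and
#' imputes them to sequence level with the haplotype-copying HMM. For
#' two-step scenarios, step one imputes medium to high density using
#' the two folds preceding the validation fold (masked to the high
#' panel) as reference, optionally drops step-one sites with DR2 below
#' `dr2_threshold`, rounds the step-one dosages to best-guess genotypes,
#' and step two imputes those to sequence level using the two folds
#' following the validation fold as the sequenced reference.
#'
#' @param data a `simulated_dataset` (or any list with elements `gm`,
#'   `panels$medium`, `panels$high`).
#' @param rp a `reference_panel_spec` from [build_reference_panels()].
#' @param folds a `fold_assignment` over the RP1 samples.
#' @param sc a [scenario_config()].
#' @return an `imputed_dosages` object for the validation samples over
#'   all sequence sites, with attribute `"scenario"`.
#' @export
run_scenario <- function(data, rp, folds, sc) {
  gm <- data$gm
  panel <- data$panels[[sc$density]]
  rp1 <- rp$rp1
  fold_of <- folds$fold_of[rp1]

  if (sc$joint_target) {
    target_ids <- rp1
    ref_ids <- setdiff(rp$rp3, rp1)
  } else {
    target_ids <- rp1[fold_of == sc$validation_fold]
    ref_folds <- switch(sc$reference_mode,
      cyclic = select_cyclic_folds(sc$validation_fold, sc$m, "following", folds$k),
      rp2 = ,
      rp3 = select_cyclic_folds(sc$validation_fold, folds$k - 1L, "following", folds$k))
    ref_ids <- rp1[fold_of %in% ref_folds]
    if (sc$reference_mode == "rp2") ref_ids <- c(ref_ids, setdiff(rp$rp2, rp1))
    if (sc$reference_mode == "rp3") ref_ids <- c(ref_ids, setdiff(rp$rp3, rp1))
  }
  if (length(intersect(target_ids, ref_ids))) {
    stop("reference and validation sample sets overlap")
  }

  targets <- mask_to_panel(subset_gm(gm, samples = target_ids), panel)

  if (!sc$two_step) {
    reference <- subset_gm(gm, samples = ref_ids)
    out <- impute_panel(targets, reference, panel = panel, params = sc$hmm)
  } else {
    high <- data$panels$high
    prev <- select_cyclic_folds(sc$validation_fold, 2L, "previous", folds$k)
    nxt <- select_cyclic_folds(sc$validation_fold, 2L, "following", folds$k)
    ref1_ids <- rp1[fold_of %in% prev]
    ref2_ids <- rp1[fold_of %in% nxt]

    hi_cols <- variant_keys(gm) %in% variant_keys(high)
    ref1 <- subset_gm(gm, samples = ref1_ids, sites = hi_cols)
    tg1 <- subset_gm(targets, sites = hi_cols)
    step1 <- impute_panel(tg1, ref1, panel = data$panels$medium, params = sc$hmm)

    keep1 <- if (is.null(sc$dr2_threshold)) rep(TRUE, length(step1$dr2)) else
      dr2_keep_mask(step1$dr2, sc$dr2_threshold)

    # best-guess genotypes from step-one dosages feed step two
    bg <- matrix(pmin(pmax(round(step1$ds), 0L), 2L), nrow = nrow(step1$ds))
    gt2 <- matrix(NA_integer_, nrow = length(target_ids), ncol = n_variants(gm))
    gt2[, which(hi_cols)[keep1]] <- as.integer(bg[, keep1, drop = FALSE])
    tg2 <- genotype_matrix(gt2, gm$variants, sample_ids = target_ids,
                           chrom_order = gm$chrom_order)
    reference <- subset_gm(gm, samples = ref2_ids)
    out <- impute_panel(tg2, reference, panel = NULL, params = sc$hmm)
    attr(out, "step1") <- list(dr2 = step1$dr2, kept = keep1)
  }
  attr(out, "scenario") <- sc
  attr(out, "reference_ids") <- ref_ids
  out
}

#' DR2 quality filter
#'
#' Sites with dosage R-squared greater than or equal to the threshold
#' are kept (a threshold of 0.4 keeps a site with DR2 exactly 0.4).
#'
#' @param dr2 numeric vector of per-variant DR2 values.
#' @param threshold cutoff in `[0, 1]`.
#' @return logical keep mask.
#' @export
dr2_keep_mask <- function(dr2, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  !is.na(dr2) & dr2 >= threshold
}

#' Per-variant imputation accuracy with exclusion rules
#'
#' Accuracy `r` per variant is the Pearson correlation between the true
#' genotypes and the estimated alt-allele dosages over all pooled
#' validation samples. A variant is excluded (with a single reason
#' code) when it is multiallelic, was not imputed, or shows no
#' variation of the observed genotypes or of the dosages within at
#' least one validation fold.
#'
#' @param observed truth [genotype_matrix()] at sequence sites covering
#'   the dosage samples.
#' @param dosages an `imputed_dosages` object (possibly the
#'   concatenation of several folds' outputs, see [combine_dosages()]).
#' @param folds a `fold_assignment` covering the dosage samples.
#' @param maf optional per-variant MAF (from [reference_maf()]) to carry
#'   into the table.
#' @return an `accuracy_table` data frame with columns `chrom`, `pos`,
#'   `maf`, `r`, `included`, `reason` (one of `ok`, `multiallelic`,
#'   `not_imputed`, `no_variation_obs`, `no_variation_dosage`).
#' @export
accuracy_per_variant <- function(observed, dosages, folds, maf = NULL) {
  ids <- dosages$sample_ids
  if (length(ids) < 2) stop("need at least 2 pooled validation samples")
  oidx <- match(ids, observed$sample_ids)
  if (anyNA(oidx)) stop("dosage sample missing from observed matrix")
  truth <- observed$gt[oidx, , drop = FALSE]

  v <- observed$variants
  didx <- match(variant_keys(observed), variant_keys(dosages$variants))
  m <- nrow(v)
  r <- rep(NA_real_, m)
  reason <- rep("ok", m)

  fold_of <- folds$fold_of[ids]
  fold_list <- split(seq_along(ids), fold_of)

  ds <- matrix(NA_real_, nrow = length(ids), ncol = m)
  ok <- !is.na(didx)
  ds[, ok] <- dosages$ds[, didx[ok], drop = FALSE]

  not_imp <- !ok | colSums(!is.na(ds)) < length(ids)
  # per-fold zero-variance exclusions on observed genotypes and dosages
  novar_obs <- rep(FALSE, m); novar_ds <- rep(FALSE, m)
  for (fi in fold_list) {
    tf <- truth[fi, , drop = FALSE]
    df <- ds[fi, , drop = FALSE]
    rng <- function(x) {
      a <- suppressWarnings(apply(x, 2, function(col) {
        cr <- range(col, na.rm = TRUE); cr[2] - cr[1]
      }))
      a[!is.finite(a)] <- 0
      a
    }
    novar_obs <- novar_obs | rng(tf) == 0
    novar_ds <- novar_ds | (!not_imp & rng(df) == 0)
  }

  reason[novar_ds] <- "no_variation_dosage"
  reason[novar_obs] <- "no_variation_obs"
  reason[not_imp] <- "not_imputed"
  reason[v$multiallelic] <- "multiallelic"
  inc <- reason == "ok"

  if (any(inc)) {
    ti <- truth[, inc, drop = FALSE]
    di <- ds[, inc, drop = FALSE]
    r[inc] <- vapply(seq_len(ncol(ti)), function(j) {
      suppressWarnings(stats::cor(ti[, j], di[, j],
                                  use = "pairwise.complete.obs"))
    }, numeric(1))
    # pooled zero variance despite per-fold variation cannot occur, but a
    # degenerate correlation is never reported as included
    degen <- inc
    degen[inc] <- is.na(r[inc])
    reason[degen] <- "no_variation_obs"
    inc <- reason == "ok"
  }

  out <- data.frame(chrom = v$chrom, pos = v$pos,
                    maf = if (is.null(maf)) NA_real_ else maf,
                    r = r, included = inc, reason = reason)
  class(out) <- c("accuracy_table", "data.frame")
  out
}

#' Concatenate per-fold imputation results
#'
#' Stacks the sample rows of several `imputed_dosages` objects over the
#' same variant set (e.g. the five separately imputed validation folds)
#' and recomputes DR2 on the pooled samples.
#'
#' @param ... `imputed_dosages` objects with identical variants.
#' @return a pooled `imputed_dosages` object.
#' @export
combine_dosages <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && is.list(xs[[1]]) && !inherits(xs[[1]], "imputed_dosages")) {
    xs <- xs[[1]]
  }
  keys <- lapply(xs, function(x) variant_keys(x$variants))
  if (!all(vapply(keys, identical, logical(1), keys[[1]]))) {
    stop("variant sets differ between dosage objects")
  }
  ds <- do.call(rbind, lapply(xs, `[[`, "ds"))
  pv <- do.call(rbind, lapply(xs, `[[`, "post_var"))
  structure(list(sample_ids = unlist(lapply(xs, `[[`, "sample_ids")),
                 variants = xs[[1]]$variants, ds = ds, post_var = pv,
                 dr2 = compute_dr2(ds, pv)),
            class = "imputed_dosages")
}

#' Aggregate per-variant accuracies
#'
#' Means of included per-variant `r` overall, per chromosome, per
#' half-open genomic window `[start, start + window_bp)` and per MAF bin
#' `(x, y]` (the bin labelled "x-y" contains variants with
#' `x < MAF <= y`). When a marker panel is supplied, an ordinary
#' least-squares regression of the window mean `r` on the window marker
#' density (markers per Mb) is reported with slope, intercept and
#' adjusted R-squared; windows without included variants are omitted.
#'
#' @param tab an `accuracy_table`.
#' @param window_bp window width in bp (default 1 Mb).
#' @param maf_bins bin edges over `[0, 0.5]`.
#' @param panel optional [marker_panel()] for the density regression.
#' @return an `aggregate_accuracy` list.
#' @export
aggregate_accuracy <- function(tab, window_bp = 1e6,
                               maf_bins = seq(0, 0.5, by = 0.1),
                               panel = NULL) {
  stopifnot(window_bp > 0)
  inc <- tab[tab$included, , drop = FALSE]
  if (nrow(inc) == 0) stop("no included variants to aggregate")

  by_chrom <- stats::aggregate(r ~ chrom, data = inc, FUN = mean)
  by_chrom$n <- as.vector(table(inc$chrom)[by_chrom$chrom])

  win <- floor((inc$pos - 1) / window_bp)
  wkey <- paste(inc$chrom, win, sep = ":")
  wmean <- tapply(inc$r, wkey, mean)
  wn <- tapply(inc$r, wkey, length)
  wchrom <- tapply(inc$chrom, wkey, `[`, 1)
  wstart <- tapply(win, wkey, `[`, 1) * window_bp + 1
  by_window <- data.frame(chrom = as.character(wchrom[names(wmean)]),
                          start = as.numeric(wstart[names(wmean)]),
                          mean_r = as.numeric(wmean),
                          n = as.integer(wn[names(wmean)]))
  rownames(by_window) <- NULL

  bin <- cut(inc$maf, breaks = maf_bins, include.lowest = FALSE)
  by_maf <- data.frame(bin = levels(bin),
                       mean_r = as.numeric(tapply(inc$r, bin, mean)),
                       n = as.integer(table(bin)))

  reg <- NULL
  if (!is.null(panel)) {
    pw <- floor((panel$sites$pos - 1) / window_bp)
    pkey <- paste(panel$sites$chrom, pw, sep = ":")
    dens <- table(pkey) / (window_bp / 1e6)
    wk <- paste(by_window$chrom, floor((by_window$start - 1) / window_bp), sep = ":")
    density <- as.numeric(dens[wk])
    density[is.na(density)] <- 0
    fit <- stats::lm(by_window$mean_r ~ density)
    s <- suppressWarnings(summary(fit))  # exact fits trip summary.lm
    reg <- list(slope = unname(stats::coef(fit)[2]),
                intercept = unname(stats::coef(fit)[1]),
                adj_r_squared = s$adj.r.squared)
  }

  structure(list(overall = mean(inc$r), n_included = nrow(inc),
                 n_excluded = sum(!tab$included),
                 by_chromosome = by_chrom, by_window = by_window,
                 by_maf_bin = by_maf, density_regression = reg,
                 window_bp = window_bp),
            class = "aggregate_accuracy")
}

#' @export
print.aggregate_accuracy <- function(x, ...) {
  cat(sprintf("mean r = %.4f over %d variants (%d excluded)\n",
              x$overall, x$n_included, x$n_excluded))
  invisible(x)
}
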