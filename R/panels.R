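#' Pairwise identity-by-state distance
#'
#' Computes the allele-sharing distance 1 - IBS between all sample
#' pairs over the sites of a marker panel (the same quantity PLINK's
#' MDS operates on). For samples a, b over the M panel sites that are
#' non-missing in both:
#' \deqn{D_{ab} = 1 - \frac{1}{M}\sum_m \frac{2 - |g_{am} - g_{bm}|}{2}}
#' Sites missing in either sample are skipped for that pair.
#'
#' @param gm a [genotype_matrix()].
#' @param panel optional [marker_panel()]; when given, only panel sites
#'   present in `gm` are used.
#' @return a `distance_matrix` list with `sample_ids` and the symmetric
#'   matrix `D` (entries in `[0, 1]`, zero diagonal).
#' @export
ibs_distance <- function(gm, panel = NULL) {
  if (n_samples(gm) < 2) stop("need at least 2 samples")
  g <- gm$gt
  if (!is.null(panel)) {
    keep <- variant_keys(gm) %in% variant_keys(panel)
    if (!any(keep)) stop("no overlap between panel and variants")
    g <- g[, keep, drop = FALSE]
  }
  obs <- !is.na(g)
  G <- g; G[!obs] <- 0L
  I0 <- (G == 0L) & obs; I1 <- (G == 1L) & obs; I2 <- (G == 2L) & obs
  storage.mode(I0) <- storage.mode(I1) <- storage.mode(I2) <- "double"
  # sum over shared sites of |g_a - g_b|
  absdiff <- I0 %*% t(I1) + I1 %*% t(I0) + I1 %*% t(I2) + I2 %*% t(I1) +
    2 * (I0 %*% t(I2) + I2 %*% t(I0))
  n_shared <- (obs * 1) %*% t(obs * 1)
  if (any(n_shared == 0)) {
    bad <- sort(which(n_shared == 0, arr.ind = TRUE)[1, ])
    stop("no overlapping non-missing sites for pair ",
         gm$sample_ids[bad[1]], " / ", gm$sample_ids[bad[2]])
  }
  D <- absdiff / (2 * n_shared)
  diag(D) <- 0
  D <- (D + t(D)) / 2
  dimnames(D) <- list(gm$sample_ids, gm$sample_ids)
  structure(list(sample_ids = gm$sample_ids, D = D),
            class = "distance_matrix")
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix, takes the top-k
#' eigenpairs and scales eigenvectors by the square roots of their
#' eigenvalues. Dimensions with non-positive eigenvalues are truncated
#' to zero width (non-Euclidean IBS matrices are expected and not an
#' error). Implemented via [stats::cmdscale()].
#'
#' @param D a `distance_matrix` (from [ibs_distance()]) or a symmetric
#'   numeric matrix.
#' @param k number of dimensions, `1 <= k < n_samples`.
#' @return an `mds_coordinates` list with `sample_ids`, the
#'   `n x k` matrix `coords` (columns centered) and the non-increasing
#'   `eigenvalues`.
#' @export
classical_mds <- function(D, k = 2) {
  ids <- NULL
  if (inherits(D, "distance_matrix")) { ids <- D$sample_ids; D <- D$D }
  D <- as.matrix(D)
  if (is.null(ids)) ids <- rownames(D)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(D)))
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8))) {
    stop("distance matrix is not symmetric")
  }
  n <- nrow(D)
  stopifnot(k >= 1, k < n)
  fit <- suppressWarnings(stats::cmdscale(D, k = k, eig = TRUE))
  pts <- fit$points
  if (is.null(pts) || ncol(pts) < k) {
    # pad dimensions lost to non-positive eigenvalues with zero width
    pad <- matrix(0, nrow = n, ncol = k - if (is.null(pts)) 0 else ncol(pts))
    pts <- cbind(pts, pad)
  }
  ev <- sort(fit$eig, decreasing = TRUE)[seq_len(k)]
  ev <- pmax(ev, 0)
  rownames(pts) <- ids
  structure(list(sample_ids = ids, coords = pts, eigenvalues = ev),
            class = "mds_coordinates")
}

#' Assign samples to relationship tiers around a target cluster
#'
#' Reproducible replacement for a by-eye grouping of an MDS plot: the
#' centroid of the target samples is computed in the first `dims` MDS
#' dimensions and every sample is assigned by its Euclidean distance to
#' that centroid — tier 1 within `t1` (inclusive), tier 2 within `t2`,
#' tier 3 beyond. Target samples are always tier 1.
#'
#' @param mds an `mds_coordinates` object.
#' @param target_ids sample ids of the target cluster.
#' @param t1,t2 tier radii, `0 < t1 < t2`. Defaults: `t1` is 1.1 times
#'   the largest target-to-centroid distance, `t2 = 3 * t1`.
#' @param dims number of leading MDS dimensions used (default 2).
#' @return named integer vector of tiers (1, 2 or 3) per sample.
#' @export
assign_relationship_groups <- function(mds, target_ids, t1 = NULL, t2 = NULL,
                                       dims = 2) {
  stopifnot(length(target_ids) > 0, dims <= ncol(mds$coords))
  idx <- match(target_ids, mds$sample_ids)
  if (anyNA(idx)) stop("target id not in MDS: ", target_ids[which(is.na(idx))[1]])
  X <- mds$coords[, seq_len(dims), drop = FALSE]
  centroid <- colMeans(X[idx, , drop = FALSE])
  d <- sqrt(colSums((t(X) - centroid)^2))
  if (is.null(t1)) t1 <- 1.1 * max(d[idx])
  if (is.null(t2)) t2 <- 3 * t1
  if (t1 <= 0) t1 <- .Machine$double.eps
  stopifnot(t1 < t2)
  tier <- ifelse(d <= t1, 1L, ifelse(d <= t2, 2L, 3L))
  tier[idx] <- 1L
  names(tier) <- mds$sample_ids
  tier
}

#' Build nested reference panels from tier labels
#'
#' RP1 is the target cluster (tier 1), RP2 adds the related tier-2
#' samples and RP3 all samples, so RP1 is a subset of RP2 is a subset
#' of RP3.
#'
#' @param tiers named integer vector of tiers per sample (names are
#'   sample ids), as from [assign_relationship_groups()].
#' @return a `reference_panel_spec` list with `target_cluster`, `rp1`,
#'   `rp2`, `rp3` (character id vectors) and `group_of` (the input).
#' @export
build_reference_panels <- function(tiers) {
  stopifnot(!is.null(names(tiers)), all(tiers %in% 1:3))
  ids <- names(tiers)
  rp1 <- ids[tiers == 1L]
  if (length(rp1) == 0) stop("empty tier 1: no target cluster")
  structure(list(target_cluster = rp1, rp1 = rp1,
                 rp2 = ids[tiers <= 2L], rp3 = ids,
                 group_of = tiers),
            class = "reference_panel_spec")
}

#' @export
print.reference_panel_spec <- function(x, ...) {
  cat(sprintf("reference_panel_spec: |RP1| = %d  |RP2| = %d  |RP3| = %d\n",
              length(x$rp1), length(x$rp2), length(x$rp3)))
  invisible(x)
}
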