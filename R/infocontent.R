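#' Monte Carlo ANOVA configuration
#'
#' @param window_bp local window width in bp around each focal variant
#'   (default 1 Mb).
#' @param replicates number of Monte Carlo focal draws (default 300).
#' @param seed integer seed; the procedure is deterministic given it.
#' @param max_predictors cap on the number of local predictors; windows
#'   with more sites are screened down to the `max_predictors` most
#'   correlated ones. Defaults to `n_samples - 2`.
#' @return an `mc_anova_config` list.
#' @export
mc_anova_config <- function(window_bp = 1e6, replicates = 300, seed = 1,
                            max_predictors = NULL) {
  stopifnot(window_bp > 0, replicates >= 1)
  structure(list(window_bp = window_bp, replicates = as.integer(replicates),
                 seed = as.integer(seed), max_predictors = max_predictors),
            class = "mc_anova_config")
}

#' Monte Carlo analysis of variance between two marker panels
#'
#' Estimates the proportion of genetic variation in panel `A` that is
#' captured by panel `B`. Each replicate draws a focal variant
#' uniformly from `A`'s polymorphic sites and regresses its centered
#' genotype vector on the centered genotypes of `B`'s sites within half
#' a window of the focal position (ordinary least squares through a
#' rank-revealing QR; if the window holds more than `max_predictors`
#' sites, the most strongly correlated ones are kept). The replicate
#' contributes the adjusted R-squared
#' `1 - (1 - R2) (n - 1) / (n - p - 1)`, floored at 0 and capped at 1;
#' an empty window contributes 0. The report is the mean over
#' replicates with its Monte Carlo standard error.
#'
#' @param A,B [genotype_matrix()] objects over the same samples,
#'   restricted to the two panels' sites.
#' @param cfg an [mc_anova_config()].
#' @param from_label,to_label labels for the report.
#' @return an `explained_variance` list: `from_panel`, `to_panel`,
#'   `proportion`, `mc_se`, `n_replicates`.
#' @export
mc_anova <- function(A, B, cfg = mc_anova_config(),
                     from_label = "A", to_label = "B") {
  if (!identical(A$sample_ids, B$sample_ids)) {
    stop("A and B must cover the same samples in the same order")
  }
  n <- n_samples(A)
  stopifnot(n >= 3)
  ga <- A$gt; gb <- B$gt
  va <- apply(ga, 2, function(x) stats::var(x, na.rm = TRUE))
  poly <- which(!is.na(va) & va > 0)
  if (!length(poly)) stop("no polymorphic site in panel A")
  cap <- if (is.null(cfg$max_predictors)) n - 2L else
    min(cfg$max_predictors, n - 2L)

  vals <- with_seed(cfg$seed, {
    focal <- sample(poly, cfg$replicates, replace = TRUE)
    vapply(focal, function(s) {
      y <- ga[, s]
      y <- y - mean(y)
      w <- which(B$variants$chrom == A$variants$chrom[s] &
                   abs(B$variants$pos - A$variants$pos[s]) <= cfg$window_bp / 2)
      if (!length(w)) return(0)
      X <- gb[, w, drop = FALSE]
      X <- scale(X, center = TRUE, scale = FALSE)
      keep <- which(apply(X, 2, function(x) any(x != 0)))
      if (!length(keep)) return(0)
      X <- X[, keep, drop = FALSE]
      if (ncol(X) > cap) {
        sc <- abs(drop(crossprod(X, y))) /
          sqrt(colSums(X^2))
        X <- X[, order(sc, decreasing = TRUE)[seq_len(cap)], drop = FALSE]
      }
      q <- qr(X)
      p <- q$rank
      fitted <- qr.fitted(q, y)
      tss <- sum(y^2)
      if (tss == 0) return(0)
      r2 <- 1 - sum((y - fitted)^2) / tss
      adj <- if (n - p - 1 > 0) 1 - (1 - r2) * (n - 1) / (n - p - 1) else r2
      min(max(adj, 0), 1)
    }, numeric(1))
  })
  structure(list(from_panel = from_label, to_panel = to_label,
                 proportion = mean(vals),
                 mc_se = stats::sd(vals) / sqrt(length(vals)),
                 n_replicates = length(vals)),
            class = "explained_variance")
}

#' @export
print.explained_variance <- function(x, ...) {
  cat(sprintf("%s explained by %s: %.3f (MC se %.4f, R = %d)\n",
              x$from_panel, x$to_panel, x$proportion, x$mc_se,
              x$n_replicates))
  invisible(x)
}

#' Explained variance for all ordered panel pairs
#'
#' Runs [mc_anova()] for every ordered pair of a named list of panels
#' (e.g. the 60K array data, the imputed panel and the sequence data),
#' producing the full proportion-explained matrix.
#'
#' @param panels named list of at least two [genotype_matrix()] objects
#'   over identical samples.
#' @param cfg an [mc_anova_config()].
#' @return data frame with columns `from`, `to`, `proportion`, `mc_se`.
#' @export
explained_variance_matrix <- function(panels, cfg = mc_anova_config()) {
  stopifnot(length(panels) >= 2, !is.null(names(panels)))
  ids <- lapply(panels, `[[`, "sample_ids")
  if (!all(vapply(ids, identical, logical(1), ids[[1]]))) {
    stop("all panels must cover the same samples")
  }
  pairs <- expand.grid(from = names(panels), to = names(panels),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    ev <- mc_anova(panels[[pairs$from[i]]], panels[[pairs$to[i]]], cfg,
                   from_label = pairs$from[i], to_label = pairs$to[i])
    data.frame(from = ev$from_panel, to = ev$to_panel,
               proportion = ev$proportion, mc_se = ev$mc_se)
  }))
  rownames(out) <- NULL
  out
}
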