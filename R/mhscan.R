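#' One-sided binomial p-value for a homozygote deficit
#'
#' Under Hardy-Weinberg equilibrium an allele at frequency `q` produces
#' homozygotes with probability `q^2`, so the number of homozygotes
#' among `n` diploid individuals is Binomial(n, q^2). The p-value for
#' an observed absence or reduction of homozygotes is the lower tail
#' `P(X <= k)`; for `k = 0` this is exactly `(1 - q^2)^n`.
#'
#' @param k observed homozygote count, `0 <= k <= n`.
#' @param n genotyped diploid individuals.
#' @param q frequency of the tested (less frequent) allele, in
#'   `[0, 0.5]`.
#' @return the one-sided p-value.
#' @export
homozygote_deficit_pvalue <- function(k, n, q) {
  stopifnot(all(k >= 0), all(k <= n), all(q >= 0))
  if (any(q > 0.5)) stop("test the minor allele: q must be <= 0.5")
  stats::pbinom(k, n, q^2)
}

#' Scan HIGH-impact variants for missing homozygosity
#'
#' Tests every biallelic HIGH-impact variant for a significant absence
#' or reduction of homozygotes of its minor allele under HWE, with
#' Bonferroni correction over the number of tested variants. The tested
#' allele frequency is estimated from the same cohort's allele counts.
#' The attribute `"max_q_k0"` reports the largest tested frequency
#' among variants with zero observed homozygotes, a useful diagnostic
#' of how close the cohort comes to a detectable signal.
#'
#' @param gm a [genotype_matrix()] with impact annotations.
#' @param alpha family-wise significance level (default 0.05).
#' @return data frame (sorted by adjusted p-value) with columns
#'   `chrom`, `pos`, `id`, `q`, `n`, `k`, `p_raw`, `m`, `p_bonf`,
#'   `significant`; attribute `max_q_k0`.
#' @export
scan_missing_homozygosity <- function(gm, alpha = 0.05) {
  v <- gm$variants
  if (all(is.na(v$impact))) stop("impact annotations are required")
  test <- which(v$impact == "HIGH" & !v$multiallelic)
  if (!length(test)) {
    warning("no biallelic HIGH-impact variants to test")
    out <- data.frame(chrom = character(0), pos = integer(0),
                      id = character(0), q = numeric(0), n = integer(0),
                      k = integer(0), p_raw = numeric(0), m = integer(0),
                      p_bonf = numeric(0), significant = logical(0))
    attr(out, "max_q_k0") <- NA_real_
    return(out)
  }
  g <- gm$gt[, test, drop = FALSE]
  nn <- colSums(!is.na(g))
  f_alt <- colSums(g, na.rm = TRUE) / (2 * nn)
  minor_is_alt <- f_alt <= 0.5
  q <- ifelse(minor_is_alt, f_alt, 1 - f_alt)
  k <- ifelse(minor_is_alt, colSums(g == 2L, na.rm = TRUE),
              colSums(g == 0L, na.rm = TRUE))
  m <- length(test)
  p_raw <- homozygote_deficit_pvalue(k, nn, q)
  p_bonf <- pmin(1, m * p_raw)
  out <- data.frame(chrom = v$chrom[test], pos = v$pos[test],
                    id = v$id[test], q = q, n = nn, k = as.integer(k),
                    p_raw = p_raw, m = m, p_bonf = p_bonf,
                    significant = p_bonf <= alpha)
  out <- out[order(out$p_bonf, out$p_raw), ]
  rownames(out) <- NULL
  attr(out, "max_q_k0") <- if (any(out$k == 0)) max(out$q[out$k == 0]) else NA_real_
  attr(out, "alpha") <- alpha
  out
}

#' Minimal sample size to prove missing homozygosity
#'
#' Smallest number of diploid individuals `n` such that observing zero
#' homozygotes for an allele at frequency `q` is significant after
#' Bonferroni correction over `m` tests: the smallest integer with
#' `(1 - q^2)^n <= alpha / m`. The boundary is verified both ways
#' (`n` satisfies the inequality, `n - 1` does not).
#'
#' @param q allele frequency, `0 < q <= 0.5`.
#' @param m number of tests (default 1).
#' @param alpha family-wise level (default 0.05).
#' @return the minimal integer `n` (0 when the condition already holds
#'   with no samples, i.e. `alpha / m >= 1`).
#' @export
minimal_sample_size <- function(q, m = 1, alpha = 0.05) {
  stopifnot(m >= 1, alpha > 0)
  if (q <= 0) stop("q = 0 expects no homozygotes: no finite n exists")
  if (q > 0.5) stop("q must be <= 0.5")
  a <- alpha / m
  if (a >= 1) return(0L)
  lp <- log1p(-q^2)  # log per-sample survival, < 0
  la <- log(a)
  # tiny relative slack so a q returned by minimal_maf (which satisfies
  # the equality exactly in real arithmetic) round-trips to the same n
  eps <- 1e-9 * abs(la)
  n <- as.integer(ceiling(la / lp))
  # verify the boundary in both directions (guards float edge cases)
  while (n * lp > la + eps) n <- n + 1L
  while (n > 0L && (n - 1L) * lp <= la + eps) n <- n - 1L
  n
}

#' Minimal allele frequency to prove missing homozygosity
#'
#' Smallest frequency `q` at which complete absence of homozygotes
#' among `n` individuals is significant after Bonferroni correction
#' over `m` tests, from the closed form
#' `q* = sqrt(1 - (alpha / m)^(1 / n))`, which satisfies
#' `(1 - q*^2)^n = alpha / m` exactly.
#'
#' @param n diploid sample size (>= 1).
#' @param m number of tests (default 1).
#' @param alpha family-wise level (default 0.05).
#' @return the minimal frequency `q*` (0 when `alpha / m >= 1`).
#' @export
minimal_maf <- function(n, m = 1, alpha = 0.05) {
  stopifnot(n >= 1, m >= 1, alpha > 0)
  a <- alpha / m
  if (a >= 1) return(0)
  sqrt(1 - exp(log(a) / n))
}
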