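# Independent oracles used to check the package implementations. These
# deliberately use the most direct (brute-force) formulation of each
# quantity and share no code with the package internals.

# Exhaustive path-sum oracle for the diploid copying HMM: enumerate all
# K^M single-copy paths, weight ordered pairs by prior x emission, and
# sum. Feasible for K <= 4, M <= 6.
brute_force_dosage <- function(gt, H, map, ne, err, min_switch) {
  K <- nrow(H); M <- ncol(H)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), M)))[, M:1, drop = FALSE]
  np <- nrow(paths)
  logw <- rep(log(1 / K), np)
  if (M > 1) {
    for (m in 2:M) {
      theta <- max(1 - exp(-4 * ne * (map[m] - map[m - 1]) / K), min_switch)
      same <- paths[, m] == paths[, m - 1]
      logw <- logw + log((1 - theta) * same + theta / K)
    }
  }
  A <- matrix(H[cbind(as.vector(paths), rep(seq_len(M), each = np))], nrow = np)
  w <- exp(logw)
  E <- matrix(1, np, np)
  for (m in seq_len(M)) {
    g <- gt[m]
    if (is.na(g)) next
    mism <- abs(g - outer(A[, m], A[, m], "+"))
    E <- E * (1 - err)^(2 - mism) * err^mism
  }
  Ew <- E %*% w
  Z <- sum(w * Ew)
  ds <- numeric(M); pv <- numeric(M)
  for (m in seq_len(M)) {
    d1 <- 2 * sum((w * A[, m]) * Ew) / Z
    cross <- as.numeric(t(w * A[, m]) %*% E %*% (w * A[, m])) / Z
    e2 <- d1 + 2 * cross
    ds[m] <- d1; pv[m] <- e2 - d1^2
  }
  list(ds = ds, post_var = pv)
}

# Hudson FST (ratio-of-averages form with finite-sample correction).
hudson_fst <- function(g1, g2) {
  p1 <- colMeans(g1) / 2; p2 <- colMeans(g2) / 2
  n1 <- 2 * nrow(g1); n2 <- 2 * nrow(g2)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ok <- den > 0
  sum(num[ok]) / sum(den[ok])
}

# Direct binomial lower-tail mass summation.
binom_tail_sum <- function(k, n, p) {
  sum(vapply(0:k, function(j) choose(n, j) * p^j * (1 - p)^(n - j), numeric(1)))
}

# Pairwise Ti/Tv classification from first principles.
titv_brute <- function(ref, alt) {
  stopifnot(all(nchar(ref) == 1), all(nchar(alt) == 1), all(ref != alt))
  purine <- c("A", "G")
  ti <- sum((ref %in% purine) == (alt %in% purine))
  c(ti = ti, tv = length(ref) - ti)
}
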