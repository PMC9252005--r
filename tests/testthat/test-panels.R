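test_that("IBS distance matches hand-computed values", {
  mk <- function(...) {
    g <- rbind(...)
    genotype_matrix(g, data.frame(chrom = "1", pos = seq_len(ncol(g))),
                    sample_ids = paste0("s", seq_len(nrow(g))))
  }
  expect_equal(unname(ibs_distance(mk(c(0, 1, 2), c(0, 1, 2)))$D[1, 2]), 0)
  expect_equal(unname(ibs_distance(mk(c(0, 0, 0), c(2, 2, 2)))$D[1, 2]), 1)
  # 1 - (2 + 1 + 2) / (3 * 2) = 1/6
  expect_equal(unname(ibs_distance(mk(c(0, 1, 2), c(0, 2, 2)))$D[1, 2]), 1 / 6)
})

test_that("IBS distance is symmetric, bounded and missing-aware", {
  for (seed in 1:3) {
    gm <- random_gm(8, 60, seed = seed, miss = 0.35)
    D <- ibs_distance(gm)$D
    expect_equal(D, t(D))
    expect_true(all(diag(D) == 0))
    expect_true(all(D >= 0 & D <= 1))
    # spot-check one pair against a direct loop over shared sites
    a <- gm$gt[2, ]; b <- gm$gt[5, ]
    ok <- !is.na(a) & !is.na(b)
    expect_equal(unname(D[2, 5]),
                 1 - mean((2 - abs(a[ok] - b[ok])) / 2))
  }
})

test_that("a pair with no shared sites raises an informative error", {
  gt <- rbind(c(0L, NA), c(NA, 1L))
  gm <- genotype_matrix(gt, data.frame(chrom = "1", pos = 1:2),
                        sample_ids = c("x", "y"))
  expect_error(ibs_distance(gm), "x / y")
})

test_that("classical MDS reproduces known configurations", {
  D0 <- matrix(0, 4, 4)
  m0 <- classical_mds(structure(list(sample_ids = letters[1:4], D = D0),
                                class = "distance_matrix"), k = 2)
  expect_true(all(abs(m0$coords) < 1e-12))

  # three collinear points at distances 1, 1, 2 embed as -1, 0, 1
  D <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  m <- classical_mds(structure(list(sample_ids = c("p", "q", "r"), D = D),
                               class = "distance_matrix"), k = 1)
  x <- m$coords[, 1]
  expect_equal(unname(sort(x)), c(-1, 0, 1), tolerance = 1e-9)
  expect_true(all(diff(m$eigenvalues) <= 1e-9))
  expect_lt(abs(mean(m$coords[, 1])), 1e-9)
})

test_that("full-rank MDS of a Euclidean distance matrix reproduces it", {
  set.seed(3)
  for (i in 1:3) {
    pts <- matrix(rnorm(15), 5, 3)
    D <- as.matrix(dist(pts))
    m <- classical_mds(D, k = 4)
    Dhat <- as.matrix(dist(m$coords))
    expect_equal(unname(Dhat), unname(D), tolerance = 1e-8)
  }
})

test_that("MDS separates simulated distant tiers on the first dimension", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 3e6), n_variants = 3000,
                    breeds = list(breed_group_spec("t1", 1, 0.05, 20),
                                  breed_group_spec("t3", 3, 0.30, 20)),
                    panel_sizes = c(medium = 150, high = 600),
                    coverage_gaps = NULL, seed = 21)
  d <- simulate_dataset(cfg)
  m <- classical_mds(ibs_distance(d$gm, d$panels$medium), k = 2)
  x1 <- m$coords[d$breed_labels$tier == 1, 1]
  x3 <- m$coords[d$breed_labels$tier == 3, 1]
  expect_true(max(min(x1), min(x3)) > min(max(x1), max(x3)) ||
                min(x1) > max(x3) || min(x3) > max(x1))
})

test_that("tier assignment follows centroid radii with inclusive boundaries", {
  coords <- rbind(c(0, 0), c(1, 0), c(0, 1), c(5, 0), c(30, 0))
  mds <- structure(list(sample_ids = paste0("s", 1:5), coords = coords,
                        eigenvalues = c(2, 1)),
                   class = "mds_coordinates")
  tiers <- assign_relationship_groups(mds, c("s1", "s2"), t1 = 1, t2 = 10)
  # centroid (0.5, 0); s3 at distance sqrt(1.25) > 1 -> tier 2;
  # s4 at 4.5 -> tier 2; s5 at 29.5 -> tier 3
  expect_equal(unname(tiers), c(1L, 1L, 2L, 2L, 3L))
  # boundary exactly t1 is tier 1
  mds$coords[3, ] <- c(1.5, 0)
  tiers <- assign_relationship_groups(mds, c("s1", "s2"), t1 = 1, t2 = 10)
  expect_equal(unname(tiers[3]), 1L)
  # all samples targeted -> all tier 1
  all1 <- assign_relationship_groups(mds, paste0("s", 1:5), t1 = 1, t2 = 10)
  expect_true(all(all1 == 1L))
  expect_error(assign_relationship_groups(mds, "nope"), "nope")
})

test_that("tier assignments are invariant to sample order", {
  d <- small_sim()
  m <- classical_mds(ibs_distance(d$gm, d$panels$medium), k = 2)
  targets <- d$breed_labels$sample[d$breed_labels$tier == 1]
  t_fwd <- assign_relationship_groups(m, targets, t1 = 0.05, t2 = 0.15)
  perm <- rev(seq_along(m$sample_ids))
  m2 <- structure(list(sample_ids = m$sample_ids[perm],
                       coords = m$coords[perm, , drop = FALSE],
                       eigenvalues = m$eigenvalues),
                  class = "mds_coordinates")
  t_rev <- assign_relationship_groups(m2, targets, t1 = 0.05, t2 = 0.15)
  expect_equal(t_fwd[names(t_rev)], t_rev)
})

test_that("reference panels nest RP1 within RP2 within RP3", {
  tiers <- c(rep(1L, 10), rep(2L, 20), rep(3L, 30))
  names(tiers) <- sprintf("s%02d", seq_along(tiers))
  rp <- build_reference_panels(tiers)
  expect_equal(lengths(rp[c("rp1", "rp2", "rp3")]), c(rp1 = 10L, rp2 = 30L, rp3 = 60L))
  expect_true(all(rp$rp1 %in% rp$rp2), all(rp$rp2 %in% rp$rp3))
  expect_identical(rp$target_cluster, rp$rp1)

  one <- c(a = 1L, b = 2L, c = 3L)
  rp1 <- build_reference_panels(one)
  expect_equal(lengths(rp1[c("rp1", "rp2", "rp3")]), c(rp1 = 1L, rp2 = 2L, rp3 = 3L))

  all1 <- build_reference_panels(c(a = 1L, b = 1L))
  expect_identical(all1$rp1, all1$rp3)

  expect_error(build_reference_panels(c(a = 2L, b = 3L)), "empty tier 1")
})
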