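test_that("folds split evenly: 65 samples give five folds of 13", {
  ids <- sprintf("h%02d", 1:65)
  f <- make_folds(ids, 5, seed = 42)
  expect_equal(as.integer(table(f$fold_of)), rep(13L, 5))
  expect_identical(f$fold_of, make_folds(ids, 5, seed = 42)$fold_of)
  f2 <- make_folds(letters[1:7], 3, seed = 1)
  expect_equal(sort(as.integer(table(f2$fold_of)), decreasing = TRUE), c(3L, 2L, 2L))
  expect_error(make_folds(letters[1:3], 5), "folds")
})

test_that("cyclic fold selection reproduces the worked (a)-(e) patterns", {
  # validation (c): the following two are (d), (e); three are (d), (e), (a)
  expect_equal(select_cyclic_folds(3, 2, "following", k = 5), c(4L, 5L))
  expect_equal(select_cyclic_folds(3, 3, "following", k = 5), c(4L, 5L, 1L))
  # validation (b): the previous two are (e), (a)
  expect_equal(select_cyclic_folds(2, 2, "previous", k = 5), c(5L, 1L))
  expect_error(select_cyclic_folds(1, 5, "following", k = 5), "m must be")
})

test_that("masking to a panel blanks everything else and is idempotent", {
  gm <- random_gm(4, 10, seed = 8, miss = 0)
  panel <- marker_panel(rep("chr1", 3), gm$variants$pos[c(1, 4, 7)])
  m1 <- mask_to_panel(gm, panel)
  expect_equal(sum(colSums(is.na(m1$gt)) == 4), 7)
  expect_equal(n_variants(m1), 10)
  m2 <- mask_to_panel(m1, panel)
  expect_identical(m1$gt, m2$gt)
  empty <- mask_to_panel(gm, marker_panel(character(0), integer(0)))
  expect_true(all(is.na(empty$gt)))
})

test_that("reference MAF uses RP1 samples only", {
  gt <- rbind(rep(1L, 3), rep(1L, 3), c(0L, 0L, 0L))
  gm <- genotype_matrix(gt, data.frame(chrom = "1", pos = 1:3),
                        sample_ids = c("r1", "r2", "x"))
  expect_equal(reference_maf(gm, c("r1", "r2")), c(0.5, 0.5, 0.5))
  gm$gt["x", ] <- c(2L, 2L, 2L)
  expect_equal(reference_maf(gm, c("r1", "r2")), c(0.5, 0.5, 0.5))
  # 13 alt alleles over 130: maf 0.1
  gt65 <- matrix(0L, 65, 1)
  gt65[1:13, 1] <- 1L
  gm65 <- genotype_matrix(gt65, data.frame(chrom = "1", pos = 1),
                          sample_ids = sprintf("h%02d", 1:65))
  expect_equal(reference_maf(gm65, gm65$sample_ids), 0.1)
})

test_that("the DR2 filter keeps exactly the sites meeting the bound", {
  expect_equal(dr2_keep_mask(c(0.39, 0.40, 0.80), 0.4), c(FALSE, TRUE, TRUE))
  expect_equal(dr2_keep_mask(c(0, NA, 1), 0.4), c(FALSE, FALSE, TRUE))
})

make_acc_fixture <- function(truth, ds, k = 2) {
  n <- nrow(truth); m <- ncol(truth)
  ids <- sprintf("v%02d", 1:n)
  v <- data.frame(chrom = "1", pos = seq_len(m) * 100)
  obs <- genotype_matrix(truth, v, sample_ids = ids)
  dos <- structure(list(sample_ids = ids, variants = obs$variants, ds = ds,
                        post_var = ds * 0, dr2 = rep(1, m)),
                   class = "imputed_dosages")
  folds <- list(fold_of = stats::setNames(rep(seq_len(k), length.out = n), ids),
                k = k, seed = 0L)
  class(folds) <- "fold_assignment"
  list(obs = obs, dos = dos, folds = folds)
}

test_that("per-variant accuracy is the pooled Pearson correlation", {
  truth <- cbind(c(0L, 0L, 1L, 2L), c(0L, 1L, 1L, 2L))
  fx <- make_acc_fixture(truth, ds = truth + 0)
  tab <- accuracy_per_variant(fx$obs, fx$dos, fx$folds)
  expect_true(all(tab$included))
  expect_equal(tab$r, c(1, 1))

  # hand-checked correlation: truth (0,0,1,2) vs ds (0.2,0.1,0.9,1.7)
  fx2 <- make_acc_fixture(truth, ds = cbind(c(0.2, 0.1, 0.9, 1.7),
                                            c(0, 1, 1, 2)))
  tab2 <- accuracy_per_variant(fx2$obs, fx2$dos, fx2$folds)
  expect_equal(tab2$r[1], 0.998343226806, tolerance = 1e-9)
})

test_that("no-variation exclusions are applied per validation fold", {
  # variant 1: truth constant within fold 2 (samples 2 and 4) only
  truth <- cbind(c(0L, 1L, 2L, 1L), c(0L, 1L, 2L, 0L))
  fx <- make_acc_fixture(truth, ds = truth + c(0.1, -0.1))
  tab <- accuracy_per_variant(fx$obs, fx$dos, fx$folds)
  expect_false(tab$included[1])
  expect_equal(tab$reason[1], "no_variation_obs")
  expect_true(tab$included[2])

  # constant dosage in one fold (truth varies in every fold here)
  truth2 <- cbind(c(0L, 1L, 2L, 0L), c(0L, 1L, 2L, 0L))
  ds <- cbind(c(0.5, 0.5, 0.5, 0.5), c(0, 1, 2, 0.2))
  fx2 <- make_acc_fixture(truth2, ds = ds)
  tab2 <- accuracy_per_variant(fx2$obs, fx2$dos, fx2$folds)
  expect_equal(tab2$reason[1], "no_variation_dosage")

  # multiallelic wins over other reasons
  fx3 <- make_acc_fixture(truth2, ds = ds)
  fx3$obs$variants$multiallelic[1] <- TRUE
  tab3 <- accuracy_per_variant(fx3$obs, fx3$dos, fx3$folds)
  expect_equal(tab3$reason[1], "multiallelic")
})

test_that("exclusion reasons match a brute-force recomputation on a CV run", {
  d <- small_sim()
  rp <- small_rp(d)
  folds <- make_folds(rp$rp1, 5, seed = 3)
  per_fold <- lapply(1:5, function(v) {
    run_scenario(d, rp, folds,
                 scenario_config(v, "cyclic", m = 2, density = "medium"))
  })
  pooled <- combine_dosages(per_fold)
  obs <- subset_gm(d$gm, samples = pooled$sample_ids)
  tab <- accuracy_per_variant(obs, pooled, folds,
                              maf = reference_maf(d$gm, rp$rp1))

  # brute force: recompute the exclusion mask from the raw matrices
  fold_of <- folds$fold_of[pooled$sample_ids]
  set.seed(17)
  for (j in sample(n_variants(obs), 200)) {
    want <- "ok"
    for (v in 1:5) {
      rows <- which(fold_of == v)
      if (length(unique(pooled$ds[rows, j])) == 1) want <- "no_variation_dosage"
    }
    for (v in 1:5) {
      rows <- which(fold_of == v)
      if (length(unique(obs$gt[rows, j])) == 1) want <- "no_variation_obs"
    }
    if (obs$variants$multiallelic[j]) want <- "multiallelic"
    expect_equal(tab$reason[j], want)
  }
  expect_true(all(tab$r[tab$included] >= -1 & tab$r[tab$included] <= 1))
})

test_that("scenario reference compositions have the expected sizes", {
  d <- small_sim()
  rp <- small_rp(d)
  folds <- make_folds(rp$rp1, 5, seed = 3)
  n1 <- length(rp$rp1)
  per_fold <- as.integer(table(folds$fold_of))

  dos <- run_scenario(d, rp, folds, scenario_config(1, "rp3", density = "medium"))
  expect_equal(length(dos$sample_ids), per_fold[1])
  # rp3 mode: the 4 non-validation folds of RP1 plus all tier-2/3 animals
  expect_equal(length(attr(dos, "reference_ids")),
               sum(per_fold[-1]) + length(setdiff(rp$rp3, rp$rp1)))
  expect_length(intersect(attr(dos, "reference_ids"), dos$sample_ids), 0)

  dos2 <- run_scenario(d, rp, folds, scenario_config(2, "cyclic", m = 3))
  expect_equal(length(attr(dos2, "reference_ids")), sum(per_fold[c(3, 4, 5)]))

  expect_error(
    run_scenario(d, rp, list(fold_of = stats::setNames(rep(1L, n1), rp$rp1),
                             k = 1L, seed = 0L),
                 scenario_config(1, "cyclic", m = 2)),
    "m must be|overlap")
})

test_that("two-step imputation runs and honours the DR2 hand-off filter", {
  d <- small_sim()
  rp <- small_rp(d)
  folds <- make_folds(rp$rp1, 5, seed = 3)
  sc <- scenario_config(2, "cyclic", m = 2, density = "medium",
                        two_step = TRUE, dr2_threshold = 0.4)
  dos <- run_scenario(d, rp, folds, sc)
  s1 <- attr(dos, "step1")
  expect_equal(s1$kept, s1$dr2 >= 0.4)
  expect_true(any(s1$kept))
  expect_true(all(dos$ds >= 0 & dos$ds <= 2))
  # two-step from the high panel is rejected
  expect_error(scenario_config(1, density = "high", two_step = TRUE), "medium")
})

test_that("aggregation means, MAF bin convention and density regression", {
  tab <- data.frame(chrom = "1", pos = c(5e5, 15e5, 25e5),
                    maf = c(0.2, 0.05, 0.42),
                    r = c(0.7, 0.5, 0.9),
                    included = c(TRUE, FALSE, TRUE),
                    reason = c("ok", "no_variation_obs", "ok"))
  agg <- aggregate_accuracy(tab)
  expect_equal(agg$overall, 0.8)
  expect_equal(agg$by_window$mean_r, c(0.7, 0.9))
  # maf exactly 0.2 falls into (0.1, 0.2]
  expect_equal(agg$by_maf_bin$mean_r[agg$by_maf_bin$bin == "(0.1,0.2]"], 0.7)
  expect_equal(agg$by_maf_bin$mean_r[agg$by_maf_bin$bin == "(0.4,0.5]"], 0.9)

  # exact linear fixture: mean window r = 0.1 + 0.02 * density
  dens <- c(3, 7, 11, 19)
  pos <- unlist(lapply(seq_along(dens), function(w) {
    (w - 1) * 1e6 + seq_len(dens[w]) * 1000
  }))
  panel <- marker_panel(rep("1", length(pos)), pos)
  tab2 <- data.frame(chrom = "1",
                     pos = (seq_along(dens) - 1) * 1e6 + 5e5,
                     maf = 0.3, r = 0.1 + 0.02 * dens,
                     included = TRUE, reason = "ok")
  agg2 <- aggregate_accuracy(tab2, panel = panel)
  expect_equal(agg2$density_regression$slope, 0.02, tolerance = 1e-9)
  expect_equal(agg2$density_regression$intercept, 0.1, tolerance = 1e-9)
  expect_equal(agg2$density_regression$adj_r_squared, 1, tolerance = 1e-9)

  expect_error(aggregate_accuracy(tab[0, ]), "no included")
})
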