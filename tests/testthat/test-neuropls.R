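# Behavioral PLS: correlation stack, SVD, permutation, bootstrap,
# brainscores, cluster extraction.

test_that("correlation stack matches a per-cell brute-force Pearson loop", {
  act <- make_activation(n = 40, V = 40, grid = c(5, 4, 2), seed = 31)
  score <- withr::with_seed(32, rnorm(40))
  R <- build_correlation_matrix(act, score)
  cells <- attr(R, "cells")
  expect_equal(nrow(R), 6L)  # 2 groups x 3 conditions
  for (i in seq_len(nrow(cells))) {
    gi <- which(unname(act$group) == cells$group[i])
    for (v in c(1, 17, 40)) {
      expect_equal(R[i, v],
                   cor(score[gi], act$conditions[[cells$condition[i]]][gi, v]),
                   tolerance = 1e-12)
    }
  }
})

test_that("self-correlated and constant voxels follow the declared rules", {
  act <- make_activation(n = 30, V = 12, grid = c(4, 3, 1), seed = 33)
  score <- withr::with_seed(34, rnorm(30))
  fi <- which(unname(act$group) == "female")
  act$conditions$shapes[fi, 1] <- score[fi]   # voxel equals the score
  act$conditions$shapes[, 2] <- 7             # constant voxel
  w <- capture_warnings(R <- build_correlation_matrix(act, score))
  expect_true(any(grepl("zero-variance", w)))
  expect_equal(R["female.shapes", 1], 1, tolerance = 1e-12)
  expect_equal(R["female.shapes", 2], 0)
  small <- make_activation(n = 5, V = 6, grid = c(3, 2, 1), seed = 35)
  small$group[] <- c("female", "female", "female", "female", "male")
  expect_error(build_correlation_matrix(small, rnorm(5)), "fewer than 3")
})

test_that("PLS SVD recovers rank-1 structure and matches an eigensolver", {
  u <- c(0.5, -0.5, 0.5, -0.5)
  v <- withr::with_seed(36, rnorm(30)); v <- v / sqrt(sum(v^2))
  R <- 3 * u %*% t(v)
  fit <- pls_svd(R)
  expect_equal(fit$singular_values[1], 3, tolerance = 1e-10)
  expect_equal(fit$pct_crossblock[1], 100, tolerance = 1e-8)
  expect_lt(abs(abs(sum(fit$voxel_saliences[, 1] * v)) - 1), 1e-10)
  # sign convention: largest-magnitude voxel salience entry positive
  expect_gt(fit$voxel_saliences[which.max(abs(fit$voxel_saliences[, 1])), 1], 0)

  R2 <- withr::with_seed(37, matrix(rnorm(6 * 50), 6, 50))
  fit2 <- pls_svd(R2)
  ev <- eigen(R2 %*% t(R2), symmetric = TRUE)$values
  expect_lt(max(abs(fit2$singular_values^2 - ev) / ev[1]), 1e-8)
  expect_equal(sum(fit2$pct_crossblock), 100, tolerance = 1e-6)
  expect_true(all(diff(fit2$singular_values) <= 1e-12))
  # reconstruction of R from the decomposition
  rec <- fit2$behavior_saliences %*% diag(fit2$singular_values) %*%
    t(fit2$voxel_saliences)
  expect_lt(max(abs(rec - R2)), 1e-10)
  # sign invariance of the spectrum
  fit3 <- pls_svd(-R2)
  expect_equal(fit3$singular_values, fit2$singular_values, tolerance = 1e-12)
  expect_equal(fit3$pct_crossblock, fit2$pct_crossblock, tolerance = 1e-12)
  expect_error(pls_svd(matrix(0, 2, 3)), "all zero")
})

test_that("permutation p attains its floor under strong planted signal", {
  cfg <- tiny_config(n_subjects = 200L, n_voxels = 100L,
                     grid_dims = c(5L, 5L, 4L), signal_fraction = 0.25,
                     noise_sd = 0.2, seed = 38L,
                     planted_effects = matrix(c(-0.8, 0, 0, 0, 0.6, 0), 2, 3))
  score <- withr::with_seed(39, rnorm(200))
  grp <- rep(c("female", "male"), 100)
  bd <- simulate_brain_data(score, grp, cfg)
  pt <- permutation_test(bd$activation, score, n_perm = 99, seed = 40)
  expect_equal(pt$perm_p[1], 1 / 100)
  pt2 <- permutation_test(bd$activation, score, n_perm = 99, seed = 40)
  expect_identical(pt, pt2)   # seed determinism
  expect_true(all(pt$perm_p > 0 & pt$perm_p <= 1))
})

test_that("bootstrap ratios diverge for noiseless signal and keep salience signs", {
  cfg <- tiny_config(n_subjects = 60L, n_voxels = 60L, noise_sd = 0,
                     signal_fraction = 0.4, seed = 41L)
  score <- withr::with_seed(42, rnorm(60))
  grp <- rep(c("female", "male"), 30)
  bd <- simulate_brain_data(score, grp, cfg)
  bs <- suppressWarnings(
    bootstrap_saliences(bd$activation, score, n_boot = 30, seed = 43))
  sig <- match(bd$truth$signal_voxels, bd$activation$voxel_table$voxel_id)
  expect_true(all(abs(bs$bsr[sig, 1]) >= 2.5))
  # BSR sign equals salience sign wherever the salience is nonzero
  v1 <- bs$fit$voxel_saliences[, 1]
  nz <- v1 != 0 & is.finite(bs$bsr[, 1]) & bs$bsr[, 1] != 0
  expect_true(all(sign(bs$bsr[nz, 1]) == sign(v1[nz])))
  bs2 <- suppressWarnings(
    bootstrap_saliences(bd$activation, score, n_boot = 30, seed = 43))
  expect_identical(bs$bsr, bs2$bsr)
  # asymmetric percentile intervals are ordered
  expect_true(all(bs$behavior_ci[, , "lower"] <= bs$behavior_ci[, , "upper"]))
})

test_that("brainscores are inner products with the salience pattern", {
  act <- make_activation(n = 10, V = 25, grid = c(5, 5, 1), seed = 44)
  v <- withr::with_seed(45, rnorm(25)); v <- v / sqrt(sum(v^2))
  act$conditions$shapes[1, ] <- v                      # subject matches pattern
  act$conditions$shapes[2, ] <- rep(0, 25)             # orthogonal (zero)
  b <- brainscores(act, v)
  expect_equal(unname(b[1, "shapes"]), 1, tolerance = 1e-12)
  expect_equal(unname(b[2, "shapes"]), 0, tolerance = 1e-12)
  # explicit summation oracle
  oracle <- sapply(names(act$conditions), function(cc)
    sapply(seq_len(10), function(s) sum(act$conditions[[cc]][s, ] * v)))
  expect_lt(max(abs(b - oracle)), 1e-12)
  expect_warning(brainscores(act, v * 2), "norm")
})

test_that("cluster extraction enforces strict size and connectivity rules", {
  # one isolated suprathreshold voxel: below the >20 rule
  grid <- c(6, 6, 6)
  V <- prod(grid)
  coords <- arrayInd(seq_len(V), grid)
  vox <- data.frame(voxel_id = sprintf("V%05d", seq_len(V)),
                    x = coords[, 1], y = coords[, 2], z = coords[, 3])
  bsr <- rep(0, V)
  bsr[1] <- 5
  expect_equal(nrow(cluster_report(bsr, vox)), 0L)
  # solid 3x3x3 block: 27 voxels, one cluster
  block <- which(coords[, 1] <= 3 & coords[, 2] <= 3 & coords[, 3] <= 3)
  bsr <- rep(0, V); bsr[block] <- 3
  cl <- cluster_report(bsr, vox)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_voxels, 27L)
  expect_equal(cl$sign, "positive")
  # exactly at the size boundary: 20 voxels are not reported (> rule)
  bsr <- rep(0, V); bsr[block[1:20]] <- 3
  expect_equal(nrow(cluster_report(bsr, vox)), 0L)
  # negative clusters are tracked separately
  bsr <- rep(0, V); bsr[block] <- -3
  cl <- cluster_report(bsr, vox)
  expect_equal(cl$sign, "negative")
})

test_that("cluster components agree with a flood-fill oracle", {
  withr::with_seed(46, {
    grid <- c(8, 8, 4)
    V <- prod(grid)
    coords <- arrayInd(seq_len(V), grid)
    vox <- data.frame(voxel_id = sprintf("V%05d", seq_len(V)),
                      x = coords[, 1], y = coords[, 2], z = coords[, 3])
    for (conn in c(6L, 26L)) {
      bsr <- rnorm(V, 0, 2)
      cl <- cluster_report(bsr, vox, threshold = 2, min_cluster_size = 0L,
                           connectivity = conn)
      for (sgn in c(1, -1)) {
        labels <- flood_fill_clusters(sgn * bsr > 2, vox, connectivity = conn)
        sizes <- sort(as.integer(table(labels)), decreasing = TRUE)
        got <- sort(cl$n_voxels[cl$sign == if (sgn > 0) "positive" else "negative"],
                    decreasing = TRUE)
        expect_equal(got, sizes[sizes > 0])
      }
    }
  })
})

test_that("activation data round-trips through the TSV directory layout", {
  act <- make_activation(n = 8, V = 12, grid = c(4, 3, 1), seed = 47)
  dir <- withr::local_tempdir()
  write_activations(act, dir)
  act2 <- read_activations(dir)
  expect_equal(act2$conditions[names(act$conditions)], act$conditions,
               tolerance = 1e-9)
  expect_equal(unname(act2$group), unname(act$group))
})
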