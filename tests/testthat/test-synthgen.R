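# Synthetic-data generators: determinism, planted structure, null behaviour.

test_that("invalid configuration fields are rejected with the field named", {
  expect_error(simulation_config(n_subjects = 0), "n_subjects")
  expect_error(simulation_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(simulation_config(within_block_r = 1), "within_block_r")
  expect_error(simulation_config(grid_dims = c(2, 2, 2), n_voxels = 100),
               "grid_dims")
  expect_error(simulation_config(snps_per_gene = 50, n_variants = 10),
               "snps_per_gene")
  pe <- matrix(1.2, 2, 3)
  expect_error(simulation_config(planted_effects = pe), "planted_effects")
})

test_that("every generator is bit-identical under a fixed seed", {
  cfg <- tiny_config(seed = 42L)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1, g2)
  e1 <- simulate_eqtl_weights(g1, cfg)
  e2 <- simulate_eqtl_weights(g1, cfg)
  expect_identical(e1, e2)
  s1 <- simulate_gwas_sumstats(g1, n_causal = 3, seed = 7)
  s2 <- simulate_gwas_sumstats(g1, n_causal = 3, seed = 7)
  expect_identical(s1, s2)
  score <- stats::setNames(rnorm(cfg$n_subjects), rownames(g1$dosages))
  grp <- rep(cfg$groups, length.out = cfg$n_subjects)
  b1 <- simulate_brain_data(score, grp, cfg)
  b2 <- simulate_brain_data(score, grp, cfg)
  expect_identical(b1, b2)
  y1 <- simulate_symptoms(score, cfg, group = grp)
  y2 <- simulate_symptoms(score, cfg, group = grp)
  expect_identical(y1, y2)
})

test_that("genotype panel matches its configuration", {
  cfg <- tiny_config(n_subjects = 2000L, n_variants = 60L, ld_block_size = 6L,
                     maf_range = c(0.2, 0.2), within_block_r = 0, seed = 2L)
  g <- simulate_genotypes(cfg)
  expect_true(all(g$dosages %in% 0:2))
  # empirical MAF within binomial tolerance of the target 0.2
  expect_true(all(abs(g$variants$maf - 0.2) < 0.03))
  expect_true(all(g$variants$info > 0.5 & g$variants$info <= 1))
  # positions monotone within chromosome
  for (ch in unique(g$variants$chrom))
    expect_true(!is.unsorted(g$variants$pos[g$variants$chrom == ch]))
  # r = 0: within-block dosage correlations near zero
  rr <- stats::cor(g$dosages[, 1:6])
  expect_lt(mean(abs(rr[upper.tri(rr)])), 0.05)
})

test_that("within-block correlation is induced when requested", {
  cfg <- tiny_config(n_subjects = 1500L, n_variants = 30L, ld_block_size = 5L,
                     within_block_r = 0.8, maf_range = c(0.3, 0.4), seed = 4L)
  g <- simulate_genotypes(cfg)
  rr <- stats::cor(g$dosages[, 1:5])
  expect_gt(mean(rr[upper.tri(rr)]), 0.4)
  # across blocks: independent
  expect_lt(abs(stats::cor(g$dosages[, 1], g$dosages[, 10])), 0.1)
})

test_that("eQTL weights reproduce their recorded true expression", {
  cfg <- tiny_config(seed = 9L)
  g <- simulate_genotypes(cfg)
  eq <- simulate_eqtl_weights(g, cfg)
  expect_equal(nrow(eq$weights), cfg$n_genes * cfg$snps_per_gene)
  expect_true(all(eq$weights$weight != 0))
  expr <- impute_expression(g, eq$weights)
  expect_equal(expr[, colnames(eq$true_expression)], eq$true_expression,
               tolerance = 1e-12)
})

test_that("null GWAS p-values are uniform and causal variants stand out", {
  cfg <- tiny_config(n_subjects = 50L, n_variants = 400L, seed = 3L)
  g <- simulate_genotypes(cfg)
  rejected <- 0L
  for (s in 1:20) {
    ss <- simulate_gwas_sumstats(g, n_causal = 0, seed = s)
    if (suppressWarnings(stats::ks.test(ss$p, "punif")$p.value) < 0.01)
      rejected <- rejected + 1L
  }
  expect_lte(rejected, 2L)
  ss <- simulate_gwas_sumstats(g, n_causal = 10, seed = 5)
  causal <- attr(ss, "causal_ids")
  expect_length(causal, 10L)
  expect_true(all(ss$p[ss$id %in% causal] < 1e-6))
  expect_true(all(abs(ss$beta[ss$id %in% causal]) > 0))
  # effect alleles always one of the variant's two alleles
  m <- match(ss$id, g$variants$id)
  expect_true(all(ss$effect_allele == g$variants$ref_allele[m] |
                    ss$effect_allele == g$variants$alt_allele[m]))
})

test_that("planted brain signal hits the target correlation structure", {
  cfg <- tiny_config(n_subjects = 400L, n_voxels = 60L,
                     signal_fraction = 0.35, noise_sd = 0, seed = 21L)
  score <- withr::with_seed(1, rnorm(400))
  grp <- rep(c("female", "male"), each = 200)
  bd <- simulate_brain_data(score, grp, cfg)
  # noiseless: signal voxels correlate +/-1 in planted cells
  fi <- which(grp == "female")
  r <- cor(score[fi], bd$activation$conditions$neutral_faces[fi, 1])
  expect_equal(abs(r), 1, tolerance = 1e-12)
  expect_equal(sign(r), sign(cfg$planted_effects["female", "neutral_faces"]))
  # salience unit norm, contiguous signal block of >= 21 voxels
  expect_equal(sum(bd$truth$true_voxel_salience^2), 1, tolerance = 1e-12)
  expect_gte(length(bd$truth$signal_voxels), 21)
  expect_identical(bd$truth$mediation_paths[["ab"]],
                   bd$truth$mediation_paths[["a"]] * bd$truth$mediation_paths[["b"]])
})

test_that("noiseless planted data give a numerically rank-1 correlation stack", {
  cfg <- tiny_config(n_subjects = 80L, noise_sd = 0, seed = 31L)
  score <- withr::with_seed(2, rnorm(80))
  grp <- rep(c("female", "male"), 40)
  bd <- simulate_brain_data(score, grp, cfg)
  R <- suppressWarnings(build_correlation_matrix(bd$activation, score))
  d <- svd(R)$d
  expect_lt(d[2], 1e-8 * d[1])
})

test_that("null planted effects give null-scale score-voxel correlations", {
  cfg <- tiny_config(n_subjects = 300L,
                     planted_effects = matrix(0, 2, 3), seed = 13L)
  score <- withr::with_seed(3, rnorm(300))
  grp <- rep(c("female", "male"), 150)
  bd <- simulate_brain_data(score, grp, cfg)
  fi <- which(grp == "female")
  r <- as.numeric(cor(score[fi], bd$activation$conditions$neutral_faces[fi, ]))
  expect_equal(mean(r), 0, tolerance = 3 / sqrt(length(fi) * length(r)))
  # E|r| under the null is about sqrt(2 / (pi n))
  expect_equal(mean(abs(r)), sqrt(2 / (pi * length(fi))), tolerance = 0.02)
})

test_that("group labels outside the config are rejected", {
  cfg <- tiny_config()
  score <- rnorm(cfg$n_subjects)
  expect_error(
    simulate_brain_data(score, rep("unknown", cfg$n_subjects), cfg),
    "unknown")
})

test_that("latent brainscore generator plants the score-mediator path", {
  cfg <- tiny_config(n_subjects = 800L, mediation_a = 0.5, seed = 23L)
  score <- withr::with_seed(6, rnorm(800))
  bs <- simulate_brainscore(score, cfg)
  expect_identical(bs, simulate_brainscore(score, cfg))
  # realized standardized slope near the planted raw-scale path
  expect_lt(abs(unname(coef(lm(bs ~ scale(score)))[2]) - 0.5), 3 / sqrt(800))
  cfg0 <- tiny_config(n_subjects = 800L, mediation_a = 0, seed = 23L)
  expect_lt(abs(cor(score, simulate_brainscore(score, cfg0))), 3 / sqrt(800))
})

test_that("symptom generator plants the outcome path and its null", {
  cfg <- tiny_config(n_subjects = 600L, mediation_b = 0, seed = 17L)
  bsc <- withr::with_seed(4, rnorm(600))
  sym <- simulate_symptoms(bsc, cfg)
  expect_lt(abs(cor(bsc, sym$anhedonia)), 3 / sqrt(600))
  expect_setequal(
    c("anhedonia", "anxious_arousal", "general_distress_depression",
      "general_distress_anxiety", "ctq_total", "life_events_total",
      "sex", "age"),
    setdiff(names(sym), "subject_id"))
  # noiseless b = 1: anhedonia is an affine image of the brainscore
  cfg2 <- tiny_config(n_subjects = 100L, mediation_b = 1,
                      symptom_noise_sd = 0, seed = 18L)
  bsc2 <- withr::with_seed(5, rnorm(100))
  sym2 <- simulate_symptoms(bsc2, cfg2)
  expect_equal(cor(bsc2, sym2$anhedonia), 1, tolerance = 1e-12)
})
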