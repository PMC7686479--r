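# Genotype I/O, QC filters, harmonisation, relatedness, MDS.

test_that("dosage TSV round-trips through write and read", {
  g <- withr::with_seed(1, make_geno(matrix(runif(12, 0, 2), 3, 4)))
  prefix <- file.path(withr::local_tempdir(), "toy")
  write_genotypes(g, prefix)
  g2 <- read_genotypes(paste0(prefix, "_dosages.tsv"))
  expect_equal(g2$dosages, g$dosages, tolerance = 1e-12)
  expect_equal(g2$variants$id, g$variants$id)
  expect_equal(g2$subject_ids, g$subject_ids)
})

test_that("VCF genotypes are read from GT counts and DS dosages", {
  path <- file.path(withr::local_tempdir(), "toy.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "sampleA", "sampleB", sep = "\t"),
    paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT", "0/1", "1/1",
          sep = "\t"),
    paste("1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT", "0/0", "0|1",
          sep = "\t")), path)
  g <- read_genotypes(path, format = "vcf")
  expect_equal(unname(g$dosages["sampleA", ]), c(1, 0))
  expect_equal(unname(g$dosages["sampleB", ]), c(2, 1))
  # DS field round-trip through the package's own VCF writer
  g0 <- withr::with_seed(2, make_geno(matrix(round(runif(20, 0, 2), 3), 4, 5)))
  vpath <- file.path(withr::local_tempdir(), "ds.vcf")
  write_vcf(g0, vpath)
  g1 <- read_genotypes(vpath, format = "vcf")
  expect_equal(unname(g1$dosages), unname(g0$dosages), tolerance = 1e-9)
})

test_that("QC filters apply strict bounds, ambiguity and duplicate rules", {
  # 8 variants: 2 low-MAF (one exactly at the boundary), 1 low-INFO,
  # 1 strand-ambiguous A/T, 1 duplicate of an earlier variant
  dos <- withr::with_seed(3, matrix(rbinom(40, 2, 0.3), 5, 8))
  g <- make_geno(dos,
                 chrom = rep(1L, 8),
                 pos = c(1000L, 2000L, 3000L, 4000L, 5000L, 6000L, 7000L, 1000L),
                 ref = c("A", "A", "A", "A", "A", "A", "A", "A"),
                 alt = c("G", "G", "G", "G", "G", "T", "G", "G"),
                 maf = c(0.3, 0.01, 0.005, 0.3, 0.3, 0.3, 0.3, 0.3),
                 info = c(0.9, 0.9, 0.9, 0.5, 0.9, 0.9, 0.9, 0.9))
  out <- qc_filter(g)
  rep <- out$report
  expect_equal(rep$n_input, 8L)
  expect_equal(rep$n_removed_maf, 2L)       # MAF == 0.01 is removed (strict >)
  expect_true("v002" %in% rep$removed_ids$maf)
  expect_equal(rep$n_removed_info, 1L)
  expect_equal(rep$n_removed_ambiguous, 1L)
  expect_equal(rep$n_removed_duplicate, 1L) # later duplicate of chrom:pos:alleles
  expect_equal(rep$removed_ids$duplicate, "v008")
  expect_equal(rep$n_retained, 3L)
  expect_equal(rep$n_input,
               rep$n_retained + rep$n_removed_maf + rep$n_removed_info +
                 rep$n_removed_ambiguous + rep$n_removed_duplicate)
  expect_setequal(out$genotypes$variants$id, c("v001", "v005", "v007"))
})

test_that("harmonisation keeps, flips or drops rows and is an involution", {
  g <- make_geno(matrix(c(0, 1, 2, 2, 1, 0), 3, 2),
                 ref = c("A", "C"), alt = c("G", "T"))
  tbl <- data.frame(id = c("v001", "v002"),
                    effect_allele = c("G", "C"), other_allele = c("A", "T"),
                    beta = c(0.3, 0.5), stringsAsFactors = FALSE)
  h <- harmonize(g, tbl)
  expect_equal(h$table$beta, c(0.3, -0.5))  # alt-effect kept, ref-effect negated
  expect_equal(h$report$n_flipped, 1L)
  # involution: harmonising the harmonised table changes nothing
  h2 <- harmonize(g, h$table)
  expect_equal(h2$table$beta, h$table$beta)
  expect_equal(h2$report$n_flipped, 0L)
  # allele-set mismatch is dropped and reported
  bad <- data.frame(id = "v001", effect_allele = "A", other_allele = "C",
                    beta = 1, stringsAsFactors = FALSE)
  hb <- harmonize(g, bad)
  expect_equal(nrow(hb$table), 0L)
  expect_equal(hb$report$dropped_ids, "v001")
})

test_that("negating beta is equivalent to reflecting dosages", {
  dos <- withr::with_seed(4, matrix(rbinom(60, 2, 0.4), 10, 6))
  g <- make_geno(dos, ref = rep("A", 6), alt = rep("G", 6))
  beta <- withr::with_seed(5, rnorm(6))
  # table written against the ref allele everywhere -> all rows flip
  tbl <- data.frame(id = g$variants$id, effect_allele = "A",
                    other_allele = "G", beta = beta, stringsAsFactors = FALSE)
  h <- harmonize(g, tbl)
  score_flip <- as.numeric(dos %*% h$table$beta)
  score_reflect <- as.numeric((2 - dos) %*% beta)
  expect_equal(score_flip - mean(score_flip),
               score_reflect - mean(score_reflect), tolerance = 1e-12)
})

test_that("duplicated subjects reach PIHAT ~ 1 and one member is excluded", {
  dos <- hwe_dosages(20, withr::with_seed(6, runif(300, 0.1, 0.5)), seed = 7)
  dos[2, ] <- dos[1, ]          # subject 2 duplicates subject 1
  dos[2, 1:30] <- NA            # and has higher missingness
  g <- make_geno(dos)
  rownames(g$dosages) <- sprintf("P%02d", 1:20)
  g$subject_ids <- rownames(g$dosages)
  rel <- estimate_relatedness(g)
  expect_gte(rel$pihat["P01", "P02"], 0.95)
  expect_true("P02" %in% rel$excluded$subject_id)  # higher missingness member
  expect_true(isSymmetric(rel$pihat))
  expect_true(all(rel$pihat >= 0 & rel$pihat <= 1))
  expect_equal(unname(diag(rel$pihat)), rep(1, 20))
})

test_that("unrelated HWE subjects give mean PIHAT near zero", {
  dos <- hwe_dosages(40, withr::with_seed(8, runif(5000, 0.1, 0.5)), seed = 9)
  g <- make_geno(dos)
  rel <- estimate_relatedness(g)
  off <- rel$pihat[upper.tri(rel$pihat)]
  expect_lt(abs(mean(off)), 0.02)
  expect_equal(nrow(rel$excluded), 0L)
})

test_that("the PIHAT exclusion threshold is strict", {
  dos <- hwe_dosages(10, rep(0.3, 500), seed = 10)
  dos[2, ] <- dos[1, ]
  g <- make_geno(dos)
  rel <- estimate_relatedness(g, pihat_max = 1)  # PIHAT 1 is not > 1
  expect_equal(nrow(rel$excluded), 0L)
  expect_error(estimate_relatedness(make_geno(matrix(2, 4, 3))),
               "monomorphic")
})

test_that("MDS separates divergent populations and matches a spectral oracle", {
  set.seed(11)
  n <- 100; V <- 1000
  p1 <- runif(V, 0.1, 0.9)
  # allele-frequency divergence akin to Fst ~ 0.1
  p2 <- pmin(pmax(p1 + rnorm(V, 0, sqrt(0.1 * p1 * (1 - p1))), 0.02), 0.98)
  dos <- rbind(sapply(p1, function(p) rbinom(n / 2, 2, p)),
               sapply(p2, function(p) rbinom(n / 2, 2, p)))
  g <- make_geno(dos)
  mds <- mds_components(g, k = 5)
  pop <- rep(c(0, 1), each = n / 2)
  expect_gt(abs(cor(mds$components[, 1], pop)), 0.9)
  expect_true(all(diff(mds$variance_explained) <= 1e-12))
  expect_lte(sum(mds$variance_explained), 1 + 1e-8)
  # centered, orthogonal coordinates
  expect_lt(max(abs(colMeans(mds$components))), 1e-8)
  gram <- crossprod(mds$components)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-6)
  # direct double-centering eigendecomposition oracle
  ibs <- 1 - outer(seq_len(n), seq_len(n),
                   Vectorize(function(i, j) mean(abs(dos[i, ] - dos[j, ])) / 2))
  D2 <- (1 - ibs)^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% D2 %*% J
  ev <- eigen(B, symmetric = TRUE)
  oracle <- ev$vectors[, 1:5] %*% diag(sqrt(pmax(ev$values[1:5], 0)))
  for (k in 1:5) {
    d <- min(max(abs(mds$components[, k] - oracle[, k])),
             max(abs(mds$components[, k] + oracle[, k])))
    expect_lt(d, 1e-6)
  }
})

test_that("identical subjects collapse to all-zero MDS coordinates", {
  g <- make_geno(matrix(1, 6, 10))
  g$variants$maf <- rep(0.5, 10)
  mds <- mds_components(g, k = 2)
  expect_lt(max(abs(mds$components)), 1e-10)
  expect_error(mds_components(g, k = 6), "smaller")
})

test_that("ancestry assignment flags subjects far from reference clusters", {
  set.seed(12)
  comp <- rbind(matrix(rnorm(40, 0, 0.1), 20, 2),
                matrix(rnorm(40, 3, 0.1), 20, 2),
                c(10, 10),   # outlier study subject
                c(0.05, 0))  # study subject inside cluster A
  rownames(comp) <- c(sprintf("refA%02d", 1:20), sprintf("refB%02d", 1:20),
                      "out1", "in1")
  labels <- stats::setNames(rep(c("EUR", "AFR"), each = 20),
                            rownames(comp)[1:40])
  res <- ancestry_assign(comp, labels, target_cluster = "EUR")
  expect_false(res$keep[res$subject_id == "out1"])
  expect_true(res$keep[res$subject_id == "in1"])
  expect_equal(res$cluster[res$subject_id == "in1"], "EUR")
})
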