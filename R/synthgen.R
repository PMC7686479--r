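#' Configuration for the synthetic study generator
#'
#' Bundles every parameter of the simulated study design: an LD-blocked
#' genotype panel, sparse cis-eQTL weight models, GWAS summary statistics,
#' three task conditions by two sex groups of voxel activation maps carrying
#' a planted score-correlated latent variable, and symptom scales with a
#' planted indirect (mediation) path.
#'
#' @param n_subjects number of subjects.
#' @param n_variants number of biallelic variants.
#' @param ld_block_size variants per LD block.
#' @param within_block_r latent Gaussian correlation within a block, in [0, 1).
#' @param maf_range length-2 interval within (0, 0.5] for simulated minor
#'   allele frequencies.
#' @param n_genes number of genes with eQTL models.
#' @param snps_per_gene non-zero-weight variants per gene.
#' @param n_voxels number of voxels.
#' @param grid_dims integer vector of 3 grid dimensions, product >= n_voxels.
#' @param conditions ordered task condition labels.
#' @param groups ordered group (sex) labels.
#' @param planted_effects groups x conditions matrix of target per-voxel
#'   score-activation correlations, each in (-1, 1). Default plants a
#'   negative association with neutral faces in women and positive
#'   associations with emotional faces and shapes in men.
#' @param signal_fraction fraction of voxels carrying the planted pattern.
#' @param noise_sd activation noise standard deviation.
#' @param mediation_a,mediation_b planted score-to-brainscore and
#'   brainscore-to-symptom path coefficients.
#' @param symptom_noise_sd noise SD of the simulated symptom scales.
#' @param symptom_cor correlation of the non-anhedonia MASQ scales with
#'   anhedonia; stress scales use half this value.
#' @param seed master seed; every generator derives its own sub-seed from it.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 478L,
                              n_variants = 2000L,
                              ld_block_size = 10L,
                              within_block_r = 0.7,
                              maf_range = c(0.05, 0.5),
                              n_genes = 76L,
                              snps_per_gene = 3L,
                              n_voxels = 500L,
                              grid_dims = c(10L, 10L, 5L),
                              conditions = c("emotional_faces", "neutral_faces", "shapes"),
                              groups = c("female", "male"),
                              planted_effects = NULL,
                              signal_fraction = 0.1,
                              noise_sd = 1,
                              mediation_a = 0.5,
                              mediation_b = 0.4,
                              symptom_noise_sd = 1,
                              symptom_cor = 0.4,
                              seed = 1L) {
  cfg <- list(
    n_subjects = check_count(n_subjects, "n_subjects"),
    n_variants = check_count(n_variants, "n_variants"),
    ld_block_size = check_count(ld_block_size, "ld_block_size"),
    within_block_r = check_number(within_block_r, "within_block_r", 0, 1,
                                  open_upper = TRUE),
    n_genes = check_count(n_genes, "n_genes"),
    snps_per_gene = check_count(snps_per_gene, "snps_per_gene"),
    n_voxels = check_count(n_voxels, "n_voxels"),
    signal_fraction = check_number(signal_fraction, "signal_fraction", 0, 1),
    noise_sd = check_number(noise_sd, "noise_sd", 0, Inf),
    mediation_a = check_number(mediation_a, "mediation_a"),
    mediation_b = check_number(mediation_b, "mediation_b"),
    symptom_noise_sd = check_number(symptom_noise_sd, "symptom_noise_sd", 0, Inf),
    symptom_cor = check_number(symptom_cor, "symptom_cor", -1, 1,
                               open_lower = TRUE, open_upper = TRUE),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (length(maf_range) != 2L || !is.numeric(maf_range) ||
      maf_range[1] > maf_range[2] || maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop_field("maf_range", "must be an interval within (0, 0.5]")
  cfg$maf_range <- as.numeric(maf_range)
  if (length(grid_dims) != 3L || any(grid_dims != as.integer(grid_dims)) ||
      any(grid_dims < 1))
    stop_field("grid_dims", "must be 3 positive integers")
  if (prod(grid_dims) < cfg$n_voxels)
    stop_field("grid_dims", "product must be >= n_voxels")
  cfg$grid_dims <- as.integer(grid_dims)
  if (length(conditions) < 1L || anyDuplicated(conditions))
    stop_field("conditions", "must be distinct labels")
  if (length(groups) < 1L || anyDuplicated(groups))
    stop_field("groups", "must be distinct labels")
  cfg$conditions <- as.character(conditions)
  cfg$groups <- as.character(groups)
  if (is.null(planted_effects)) {
    planted_effects <- matrix(0, length(cfg$groups), length(cfg$conditions),
                              dimnames = list(cfg$groups, cfg$conditions))
    if ("female" %in% cfg$groups && "neutral_faces" %in% cfg$conditions)
      planted_effects["female", "neutral_faces"] <- -0.3
    if ("male" %in% cfg$groups) {
      if ("emotional_faces" %in% cfg$conditions)
        planted_effects["male", "emotional_faces"] <- 0.2
      if ("shapes" %in% cfg$conditions)
        planted_effects["male", "shapes"] <- 0.2
    }
  }
  planted_effects <- as.matrix(planted_effects)
  if (!identical(dim(planted_effects),
                 c(length(cfg$groups), length(cfg$conditions))) ||
      any(abs(planted_effects) >= 1))
    stop_field("planted_effects",
               "must be a groups x conditions matrix with |entries| < 1")
  dimnames(planted_effects) <- list(cfg$groups, cfg$conditions)
  cfg$planted_effects <- planted_effects
  if (cfg$snps_per_gene > cfg$n_variants)
    stop_field("snps_per_gene", "cannot exceed n_variants")
  class(cfg) <- "simulation_config"
  cfg
}

# Fixed sub-seed slots for the individual generators.
.synth_stage <- c(genotypes = 1L, weights = 2L, sumstats = 3L,
                  brain = 4L, symptoms = 5L, scoreprep = 6L)

#' Simulate an LD-blocked biallelic dosage panel
#'
#' Dosages arise from two latent Gaussian haplotype draws per variant with an
#' exchangeable within-block correlation (a Gaussian copula thresholded at the
#' allele-frequency quantile), so linkage disequilibrium is tunable per block
#' without haplotype realism. Variants carry chromosome, monotone position,
#' ref/alt alleles, empirical MAF and a simulated imputation INFO in (0.5, 1].
#'
#' @param config a [simulation_config()].
#' @return A `genotype_matrix`: list with `dosages` (subjects x variants),
#'   `subject_ids` and a `variants` data frame.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_subjects
  V <- config$n_variants
  with_seed(derive_seed(config$seed, .synth_stage[["genotypes"]]), {
    maf <- stats::runif(V, config$maf_range[1], config$maf_range[2])
    block <- (seq_len(V) - 1L) %/% config$ld_block_size + 1L
    r <- config$within_block_r
    dos <- matrix(0L, n, V)
    for (b in unique(block)) {
      idx <- which(block == b)
      m <- length(idx)
      al <- matrix(0L, n, m)
      for (h in 1:2) {
        u <- stats::rnorm(n)
        z <- sqrt(r) * matrix(u, n, m) +
          sqrt(1 - r) * matrix(stats::rnorm(n * m), n, m)
        al <- al + (z < matrix(stats::qnorm(maf[idx]), n, m, byrow = TRUE))
      }
      dos[, idx] <- al
    }
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, V, replace = TRUE)
    alt <- vapply(ref, function(x) sample(setdiff(bases, x), 1L), "")
    blocks_per_chrom <- 50L
    chrom <- (block - 1L) %/% blocks_per_chrom + 1L
    pos <- integer(V)
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      pos[i] <- 100000L + (seq_along(i) - 1L) * 10000L
    }
    info <- stats::runif(V, 0.5, 1)
    ids <- sprintf("rs%06d", seq_len(V))
    dimnames(dos) <- list(sprintf("S%04d", seq_len(n)), ids)
    alt_freq <- colMeans(dos) / 2
    variants <- data.frame(
      id = ids, chrom = chrom, pos = pos,
      ref_allele = unname(ref), alt_allele = unname(alt),
      maf = pmin(alt_freq, 1 - alt_freq), info = info,
      missing_rate = 0, stringsAsFactors = FALSE
    )
    new_genotype_matrix(dos, variants)
  })
}

#' Simulate sparse cis-eQTL weight models and their implied expression
#'
#' Each gene receives `snps_per_gene` distinct variants with non-zero
#' normal weights on the alt allele; the ground-truth expression is the
#' dosage-by-weight linear combination, so `impute_expression()` on the
#' returned weights reproduces it exactly.
#'
#' @param genotypes a `genotype_matrix`.
#' @param config a [simulation_config()].
#' @return List with `weights` (gene, variant, allele, weight table) and
#'   `true_expression` (subjects x genes matrix).
#' @export
simulate_eqtl_weights <- function(genotypes, config) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(config, "simulation_config"))
  V <- ncol(genotypes$dosages)
  if (config$snps_per_gene > V)
    stop_field("snps_per_gene", "cannot exceed the number of variants")
  with_seed(derive_seed(config$seed, .synth_stage[["weights"]]), {
    genes <- sprintf("GENE%04d", seq_len(config$n_genes))
    rows <- vector("list", config$n_genes)
    expr <- matrix(0, nrow(genotypes$dosages), config$n_genes,
                   dimnames = list(genotypes$subject_ids, genes))
    for (gi in seq_along(genes)) {
      vs <- sample.int(V, config$snps_per_gene)
      w <- stats::rnorm(config$snps_per_gene)
      w[w == 0] <- 0.1
      rows[[gi]] <- data.frame(
        gene_id = genes[gi],
        variant_id = genotypes$variants$id[vs],
        effect_allele = genotypes$variants$alt_allele[vs],
        other_allele = genotypes$variants$ref_allele[vs],
        weight = w, stringsAsFactors = FALSE
      )
      expr[, gi] <- genotypes$dosages[, vs, drop = FALSE] %*% w
    }
    list(weights = do.call(rbind, rows), true_expression = expr)
  })
}

#' Simulate GWAS summary statistics over a genotype panel
#'
#' Null variants get standard-normal association z-scores (hence uniform
#' two-sided p-values); `n_causal` randomly chosen variants get inflated
#' |z| and correspondingly small p. The effect allele is the alt or ref
#' allele at random, with the stored beta flipped accordingly, so allele
#' harmonisation is exercised downstream.
#'
#' @param genotypes a `genotype_matrix`.
#' @param n_causal number of causal variants.
#' @param seed integer seed.
#' @return A summary-statistics data frame (id, chrom, pos, effect_allele,
#'   other_allele, beta, p, maf, info) with attribute `causal_ids`.
#' @export
simulate_gwas_sumstats <- function(genotypes, n_causal = 0L, seed = 1L) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  v <- genotypes$variants
  n_causal <- check_count(n_causal, "n_causal", min = 0L)
  if (n_causal > nrow(v)) stop_field("n_causal", "cannot exceed n_variants")
  with_seed(seed, {
    V <- nrow(v)
    z <- stats::rnorm(V)
    causal <- if (n_causal > 0) sample.int(V, n_causal) else integer(0)
    z[causal] <- sign(z[causal]) * (abs(z[causal]) + 6)
    p <- pmax(2 * stats::pnorm(-abs(z)), 1e-300)
    beta_alt <- z * 0.05
    flip <- stats::runif(V) < 0.5
    ss <- data.frame(
      id = v$id, chrom = v$chrom, pos = v$pos,
      effect_allele = ifelse(flip, v$ref_allele, v$alt_allele),
      other_allele = ifelse(flip, v$alt_allele, v$ref_allele),
      beta = ifelse(flip, -beta_alt, beta_alt),
      p = p, maf = v$maf, info = v$info, stringsAsFactors = FALSE
    )
    attr(ss, "causal_ids") <- v$id[causal]
    ss
  })
}

#' Simulate condition-wise voxel activation with a planted latent variable
#'
#' Within each (group, condition) cell the planted effect is the target
#' Pearson correlation between the score and every signal voxel. Signal
#' voxels form one contiguous block on the 3-D grid (at least 21 voxels
#' whenever the signal fraction is positive, so cluster reporting at the
#' >20-voxel rule is exercised); the planted voxel salience is flat over
#' the block and unit-norm. Activation is the scaled standardized score
#' times the salience plus Gaussian noise.
#'
#' @param score numeric score per subject (named or in subject order).
#' @param groups group label per subject; labels must appear in the config.
#' @param config a [simulation_config()].
#' @return List with `activation` (an `activation_data`) and `truth`
#'   (signal voxel ids, true unit-norm voxel salience, planted effects).
#' @export
simulate_brain_data <- function(score, groups, config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- length(score)
  if (length(groups) != n) stop("'groups' must match 'score' in length")
  if (!all(groups %in% config$groups))
    stop("group label absent from config: ",
         paste(setdiff(unique(groups), config$groups), collapse = ", "))
  subj <- names(score)
  if (is.null(subj)) subj <- sprintf("S%04d", seq_len(n))
  V <- config$n_voxels
  d <- config$grid_dims
  coords <- arrayInd(seq_len(V), d)
  voxel_table <- data.frame(voxel_id = sprintf("V%05d", seq_len(V)),
                            x = coords[, 1], y = coords[, 2], z = coords[, 3])
  k <- if (config$signal_fraction > 0)
    max(ceiling(config$signal_fraction * V), 21L) else 0L
  k <- min(k, V)
  signal <- seq_len(k)  # first k grid cells: contiguous by construction
  sal <- numeric(V)
  if (k > 0) sal[signal] <- 1 / sqrt(k)
  with_seed(derive_seed(config$seed, .synth_stage[["brain"]]), {
    acts <- lapply(config$conditions, function(cond) {
      m <- matrix(stats::rnorm(n * V, sd = config$noise_sd), n, V,
                  dimnames = list(subj, voxel_table$voxel_id))
      for (g in config$groups) {
        gi <- which(groups == g)
        if (length(gi) < 2L || k == 0L) next
        rho <- config$planted_effects[g, cond]
        if (rho == 0) next
        zs <- as.numeric(scale(score[gi]))
        amp <- if (config$noise_sd == 0) rho else
          rho / sqrt(1 - rho^2) * config$noise_sd
        m[gi, signal] <- m[gi, signal] + outer(zs, rep(amp, k))
      }
      m
    })
    names(acts) <- config$conditions
    act <- new_activation_data(acts, voxel_table,
                               stats::setNames(as.character(groups), subj))
    truth <- list(signal_voxels = voxel_table$voxel_id[signal],
                  true_voxel_salience = sal,
                  true_behavior_salience = config$planted_effects,
                  mediation_paths = c(a = config$mediation_a,
                                      b = config$mediation_b,
                                      ab = config$mediation_a * config$mediation_b))
    list(activation = act, truth = truth)
  })
}

#' Simulate a latent brainscore carrying the planted mediator path
#'
#' Generates the mediator of the score-brain-symptom chain directly:
#' `mediation_a` times the standardized score plus unit-variance Gaussian
#' noise, so `mediation_a` is the planted (raw-scale) score-to-brainscore
#' path. Set `mediation_a = 0` in the config for strata without the path.
#'
#' @param score numeric score per subject.
#' @param config a [simulation_config()].
#' @return Named numeric vector of brainscores.
#' @export
simulate_brainscore <- function(score, config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- length(score)
  subj <- names(score)
  if (is.null(subj)) subj <- sprintf("S%04d", seq_len(n))
  zs <- if (stats::sd(score) > 0) as.numeric(scale(score)) else
    score - mean(score)
  with_seed(derive_seed(config$seed, .synth_stage[["scoreprep"]]), {
    stats::setNames(config$mediation_a * zs + stats::rnorm(n), subj)
  })
}

#' Simulate symptom and covariate tables with a planted mediation path
#'
#' Anhedonia is `mediation_b` times the standardized brainscore plus
#' Gaussian noise, so the planted outcome path is a standardized
#' coefficient independent of the brainscore's raw scale; the
#' other three MASQ subscales share a configurable correlation with
#' anhedonia, and the stress scales (CTQ, life events) half of it. Scales
#' are left continuous.
#'
#' @param brainscore numeric per-subject brainscore (the mediator).
#' @param config a [simulation_config()].
#' @param group optional per-subject sex label copied into the table.
#' @return A data frame with the four MASQ subscales, CTQ and life-events
#'   totals, sex and age, one row per subject.
#' @export
simulate_symptoms <- function(brainscore, config, group = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  n <- length(brainscore)
  subj <- names(brainscore)
  if (is.null(subj)) subj <- sprintf("S%04d", seq_len(n))
  if (is.null(group)) group <- rep(config$groups[1], n)
  with_seed(derive_seed(config$seed, .synth_stage[["symptoms"]]), {
    bs <- as.numeric(brainscore)
    zb <- if (stats::sd(bs) > 0) as.numeric(scale(bs)) else bs - mean(bs)
    anh <- config$mediation_b * zb +
      stats::rnorm(n, sd = config$symptom_noise_sd)
    za <- if (stats::sd(anh) > 0) as.numeric(scale(anh)) else numeric(n)
    corr_scale <- function(rho)
      rho * za + sqrt(1 - rho^2) * stats::rnorm(n)
    r1 <- config$symptom_cor
    r2 <- config$symptom_cor / 2
    data.frame(
      subject_id = subj,
      anhedonia = anh,
      anxious_arousal = corr_scale(r1),
      general_distress_depression = corr_scale(r1),
      general_distress_anxiety = corr_scale(r1),
      ctq_total = corr_scale(r2),
      life_events_total = corr_scale(r2),
      sex = as.character(group),
      age = stats::rnorm(n, 19.79, 1.24),
      stringsAsFactors = FALSE
    )
  })
}
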