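# End-to-end orchestration: simulate -> qc -> scores -> pls -> symptoms.

#' Pipeline configuration
#'
#' Validates all stage parameters up front, before any stage runs.
#'
#' @param sim a [simulation_config()] for the synthetic inputs.
#' @param maf_min,info_min,pihat_max,mds_k genotype-QC parameters.
#' @param r2_max,window_kb,p_index_max,prs_thresholds clumping/PRS
#'   parameters.
#' @param n_perm,n_boot,bsr_threshold,min_cluster_size PLS inference
#'   parameters.
#' @param mediation_n_boot mediation bootstrap resamples.
#' @param n_causal causal variants in the simulated GWAS.
#' @param stages character vector of stages to run, in dependency order.
#' @param out_dir optional directory for TSV artifacts (NULL: in memory
#'   only).
#' @param seed master seed; per-stage sub-seeds follow [derive_seed()].
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            maf_min = 0.01, info_min = 0.80,
                            pihat_max = 0.2, mds_k = 10L,
                            r2_max = 0.1, window_kb = 250, p_index_max = 1,
                            prs_thresholds = c(5e-8, 1e-6, 1e-4, 1e-3, 1e-2,
                                               0.01, 0.05, 0.5, 1),
                            n_perm = 500L, n_boot = 1000L,
                            bsr_threshold = 2.5, min_cluster_size = 20L,
                            mediation_n_boot = 5000L, n_causal = 50L,
                            stages = c("simulate", "qc", "scores", "pls",
                                       "symptoms"),
                            out_dir = NULL, seed = 1L) {
  stopifnot(inherits(sim, "simulation_config"))
  cfg <- list(
    sim = sim,
    maf_min = check_number(maf_min, "maf_min", 0, 0.5),
    info_min = check_number(info_min, "info_min", 0, 1),
    pihat_max = check_number(pihat_max, "pihat_max", 0, 1),
    mds_k = check_count(mds_k, "mds_k"),
    r2_max = check_number(r2_max, "r2_max", 0, 1),
    window_kb = check_number(window_kb, "window_kb", 0, Inf, open_lower = TRUE),
    p_index_max = check_number(p_index_max, "p_index_max", 0, 1,
                               open_lower = TRUE),
    prs_thresholds = prs_thresholds,
    n_perm = check_count(n_perm, "n_perm"),
    n_boot = check_count(n_boot, "n_boot", min = 2L),
    bsr_threshold = check_number(bsr_threshold, "bsr_threshold", 0, Inf),
    min_cluster_size = check_count(min_cluster_size, "min_cluster_size", min = 0L),
    mediation_n_boot = check_count(mediation_n_boot, "mediation_n_boot", min = 2L),
    n_causal = check_count(n_causal, "n_causal", min = 0L),
    stages = stages, out_dir = out_dir,
    seed = check_count(seed, "seed", min = 0L)
  )
  if (any(cfg$prs_thresholds <= 0 | cfg$prs_thresholds > 1))
    stop_field("prs_thresholds", "must lie in (0, 1]")
  known <- c("simulate", "qc", "scores", "pls", "symptoms")
  if (!all(stages %in% known))
    stop_field("stages", paste("must be among:", paste(known, collapse = ", ")))
  if (cfg$mds_k >= sim$n_subjects)
    stop_field("mds_k", "must be smaller than n_subjects")
  class(cfg) <- "pipeline_config"
  cfg
}

file_checksums <- function(dir) {
  if (is.null(dir) || !dir.exists(dir)) return(character(0))
  files <- list.files(dir, recursive = TRUE, full.names = TRUE)
  sums <- tools::md5sum(files)
  names(sums) <- sub(paste0("^", dir, "/?"), "", names(sums))
  sums
}

#' Run the full synthetic-data analysis pipeline
#'
#' Stage order: `simulate` (genotypes, eQTL weights, GWAS summary
#' statistics), `qc` (variant filters, relatedness exclusion, MDS ancestry
#' component C1), `scores` (imputed expression, T-PRS, clumped PGC-PRS),
#' `pls` (behavioral PLS of the T-PRS with permutation/bootstrap inference
#' and cluster report; simulated activations planted on the T-PRS), and
#' `symptoms` (simulated symptom table from the LV1 neutral-faces
#' brainscore, brainscore-anhedonia association, adjusted regression, and
#' sex-stratified mediation). A skipped stage makes dependants abort,
#' naming the stage to run first.
#'
#' @param config a [pipeline_config()].
#' @return A list with a `manifest` (stage status, seeds, checksums of any
#'   written artifacts) and every stage's in-memory `results`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  st <- config$stages
  res <- list()
  status <- stats::setNames(rep("skipped", 5),
                            c("simulate", "qc", "scores", "pls", "symptoms"))
  need <- function(stage, dep) {
    if (is.null(res[[dep]]))
      stop(sprintf("stage '%s' requires output of stage '%s'; run it first",
                   stage, dep), call. = FALSE)
  }
  sim <- config$sim

  if ("simulate" %in% st) {
    g <- simulate_genotypes(sim)
    eq <- simulate_eqtl_weights(g, sim)
    ss <- simulate_gwas_sumstats(g, n_causal = config$n_causal,
                                 seed = derive_seed(sim$seed, .synth_stage[["sumstats"]]))
    res$simulate <- list(genotypes = g, weights = eq$weights,
                         true_expression = eq$true_expression, sumstats = ss)
    status["simulate"] <- "completed"
  }
  if ("qc" %in% st) {
    need("qc", "simulate")
    qc <- qc_filter(res$simulate$genotypes, maf_min = config$maf_min,
                    info_min = config$info_min)
    rel <- estimate_relatedness(qc$genotypes, pihat_max = config$pihat_max)
    keep <- rel$retained_subjects
    g2 <- new_genotype_matrix(qc$genotypes$dosages[keep, , drop = FALSE],
                              qc$genotypes$variants)
    mds <- mds_components(g2, k = min(config$mds_k, nrow(g2$dosages) - 1L))
    res$qc <- list(genotypes = g2, qc_report = qc$report,
                   relatedness = rel, mds = mds,
                   C1 = mds$components[, 1])
    status["qc"] <- "completed"
  }
  if ("scores" %in% st) {
    need("scores", "qc")
    g2 <- res$qc$genotypes
    hw <- harmonize(g2, res$simulate$weights)
    expr <- impute_expression(g2, hw$table)
    de <- data.frame(gene_id = colnames(expr),
                     direction = ifelse(seq_len(ncol(expr)) %% 2 == 0, -1, 1))
    tprs <- compute_tprs(expr, de)
    hs <- harmonize(g2, res$simulate$sumstats)
    clumps <- ld_clump(hs$table, g2, r2_max = config$r2_max,
                       window_kb = config$window_kb,
                       p_index_max = config$p_index_max)
    prs <- suppressWarnings(
      compute_pgc_prs(g2, hs$table, clumps, thresholds = config$prs_thresholds))
    res$scores <- list(expression = expr, de_table = de, tprs = tprs,
                       clumps = clumps, pgc_prs = prs,
                       harmonize_reports = list(weights = hw$report,
                                                sumstats = hs$report))
    status["scores"] <- "completed"
  }
  if ("pls" %in% st) {
    need("pls", "scores")
    tprs <- res$scores$tprs
    subj <- names(tprs$scores)
    groups <- rep(sim$groups, length.out = length(subj))
    names(groups) <- subj
    bd <- local({
      s2 <- tprs$scores
      cfg_b <- sim
      simulate_brain_data(s2, groups, cfg_b)
    })
    fit <- pls_analysis(bd$activation, tprs$scores,
                        n_perm = config$n_perm, n_boot = config$n_boot,
                        bsr_threshold = config$bsr_threshold,
                        min_cluster_size = config$min_cluster_size,
                        seed = derive_seed(config$seed, 10L))
    res$pls <- list(activation = bd$activation, truth = bd$truth, fit = fit,
                    groups = groups)
    status["pls"] <- "completed"
  }
  if ("symptoms" %in% st) {
    need("symptoms", "pls")
    fit <- res$pls$fit
    cond <- if ("neutral_faces" %in% colnames(fit$brainscores))
      "neutral_faces" else colnames(fit$brainscores)[1]
    bsc <- fit$brainscores[, cond]
    sym <- simulate_symptoms(bsc, sim, group = res$pls$groups)
    assoc <- brainscore_symptom_corr(bsc, sym$anhedonia)
    adj <- adjusted_regression(
      sym$anhedonia, bsc,
      sym[c("anxious_arousal", "general_distress_depression",
            "general_distress_anxiety", "ctq_total", "life_events_total")])
    med <- mediate(res$scores$tprs$scores, bsc, sym$anhedonia,
                   covariates = NULL, strata = sym$sex,
                   n_boot = config$mediation_n_boot,
                   seed = derive_seed(config$seed, 11L))
    res$symptoms <- list(symptoms = sym, association = assoc,
                         adjusted = adj, mediation = med,
                         brainscore_condition = cond)
    status["symptoms"] <- "completed"
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(res$simulate)) {
      write_genotypes(res$simulate$genotypes,
                      file.path(config$out_dir, "genotypes"))
      write_tsv(res$simulate$weights, file.path(config$out_dir, "weights.tsv"))
      write_tsv(res$simulate$sumstats, file.path(config$out_dir, "sumstats.tsv"))
    }
    if (!is.null(res$scores)) {
      tp <- res$scores$tprs
      write_tsv(data.frame(subject_id = names(tp$scores), score = tp$scores,
                           score_type = tp$score_type,
                           n_features_used = tp$n_features_used),
                file.path(config$out_dir, "tprs.tsv"))
    }
    if (!is.null(res$pls)) {
      write_activations(res$pls$activation,
                        file.path(config$out_dir, "activations"))
      write_pls_result(res$pls$fit, file.path(config$out_dir, "pls"))
    }
    if (!is.null(res$symptoms))
      write_tsv(res$symptoms$symptoms, file.path(config$out_dir, "symptoms.tsv"))
  }

  manifest <- list(
    seed = config$seed,
    stage_seeds = c(pls = derive_seed(config$seed, 10L),
                    mediation = derive_seed(config$seed, 11L),
                    sim = sim$seed),
    status = status,
    timestamp = format(Sys.time(), tz = "UTC"),
    checksums = file_checksums(config$out_dir)
  )
  list(manifest = manifest, results = res)
}
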