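# Transcriptome-imputed expression, T-PRS, LD clumping, thresholded PRS.

#' Impute gene expression from dosages and cis-eQTL weights
#'
#' Per subject and gene, the imputed expression is the sum over the gene's
#' weighted variants of dosage times weight (PrediXcan-style linear
#' prediction). Genes with no variant present in the panel are dropped
#' with a message; weights are assumed harmonised (see [harmonize()]).
#'
#' @param g a `genotype_matrix`.
#' @param w weight table (gene_id, variant_id, effect_allele, other_allele,
#'   weight).
#' @return subjects x genes numeric matrix (imputable genes only).
#' @export
impute_expression <- function(g, w) {
  stopifnot(inherits(g, "genotype_matrix"))
  req <- c("gene_id", "variant_id", "weight")
  if (!all(req %in% names(w))) stop("weight table needs gene_id, variant_id, weight")
  if (anyDuplicated(w[c("gene_id", "variant_id")]))
    stop("(gene, variant) pairs must be unique")
  dos <- mean_impute(g$dosages)
  w <- w[w$variant_id %in% colnames(dos), , drop = FALSE]
  genes <- unique(w$gene_id)
  if (!length(genes)) stop("no gene imputable: no weight variant present in panel")
  # sparse weight matrix as a dense variants x genes block (small in practice)
  W <- matrix(0, ncol(dos), length(genes),
              dimnames = list(colnames(dos), genes))
  W[cbind(match(w$variant_id, colnames(dos)), match(w$gene_id, genes))] <- w$weight
  expr <- dos %*% W
  rownames(expr) <- g$subject_ids
  expr
}

#' Transcriptome-based polygenic risk score
#'
#' Each imputed-expression column is normalised to a consistent scale
#' across genes (z-scored by default, rank-based inverse normal optionally)
#' and summed with the sign (and optional weight) of each gene's prior
#' association with depression, so higher scores reflect a more
#' depression-like cortical transcriptome.
#'
#' @param e subjects x genes imputed expression matrix.
#' @param de data frame with gene_id, direction (-1/+1) and optional
#'   effect_weight (defaults to 1).
#' @param normalization `"zscore"` or `"rank_inverse_normal"`.
#' @return A `score_vector`: list with per-subject `scores`, `score_type`,
#'   `n_features_used` and provenance.
#' @export
compute_tprs <- function(e, de, normalization = c("zscore", "rank_inverse_normal")) {
  normalization <- match.arg(normalization)
  if (!all(c("gene_id", "direction") %in% names(de)))
    stop("DE gene table needs gene_id and direction")
  if (anyDuplicated(de$gene_id)) stop("DE gene table has duplicate genes")
  if (any(de$direction == 0)) stop("direction must be -1 or +1")
  missing_genes <- setdiff(colnames(e), de$gene_id)
  if (length(missing_genes))
    stop("expression genes absent from DE table: ",
         paste(utils::head(missing_genes, 5), collapse = ", "))
  sds <- apply(e, 2, stats::sd)
  const <- sds == 0
  if (all(const)) stop("all genes constant across subjects")
  if (any(const))
    message(sprintf("dropping %d constant gene(s) from T-PRS", sum(const)))
  e <- e[, !const, drop = FALSE]
  z <- if (normalization == "zscore") {
    zscore_cols(e)
  } else {
    apply(e, 2, function(x)
      stats::qnorm((rank(x) - 0.5) / length(x)))
  }
  m <- match(colnames(e), de$gene_id)
  wt <- sign(de$direction[m])
  if ("effect_weight" %in% names(de)) wt <- wt * abs(de$effect_weight[m])
  scores <- as.numeric(z %*% wt)
  names(scores) <- rownames(e)
  structure(list(scores = scores, score_type = "tprs", threshold = NA_real_,
                 n_features_used = ncol(e),
                 provenance = sprintf("T-PRS: %d genes, %s normalization",
                                      ncol(e), normalization)),
            class = "score_vector")
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("score_vector [%s]: %d subjects, %d features\n",
              x$score_type, length(x$scores), x$n_features_used))
  invisible(x)
}

#' Greedy LD clumping of summary statistics
#'
#' Repeatedly takes the unassigned variant with the smallest p-value at or
#' below `p_index_max` as an index and assigns to it every unassigned
#' same-chromosome variant within `window_kb` whose dosage r-squared with
#' the index is at least `r2_max`. Ties on p are broken by smaller genomic
#' position, then lexicographic id.
#'
#' @param ss summary statistics restricted to variants present in `g`.
#' @param g a `genotype_matrix` supplying the LD (Pearson r^2 on
#'   mean-imputed dosages).
#' @param r2_max LD threshold for absorption into a clump.
#' @param window_kb physical window, in kilobases, around the index.
#' @param p_index_max maximum p for a variant to seed a clump.
#' @return A `clump_result`: `index_variants`, `membership` (variant ->
#'   index) and the parameters.
#' @export
ld_clump <- function(ss, g, r2_max = 0.1, window_kb = 250, p_index_max = 1.0) {
  stopifnot(inherits(g, "genotype_matrix"))
  ss <- ss[ss$id %in% colnames(g$dosages), , drop = FALSE]
  if (!nrow(ss))
    return(structure(list(index_variants = character(0),
                          membership = character(0),
                          parameters = list(r2_max = r2_max, window_kb = window_kb,
                                            p_index_max = p_index_max)),
                     class = "clump_result"))
  dos <- mean_impute(g$dosages)[, ss$id, drop = FALSE]
  ord <- order(ss$p, ss$pos, ss$id)
  assigned <- rep(NA_character_, nrow(ss))
  names(assigned) <- ss$id
  index_variants <- character(0)
  window <- window_kb * 1000
  for (i in ord) {
    if (!is.na(assigned[i]) || ss$p[i] > p_index_max) next
    assigned[i] <- ss$id[i]
    index_variants <- c(index_variants, ss$id[i])
    cand <- which(is.na(assigned) & ss$chrom == ss$chrom[i] &
                    abs(ss$pos - ss$pos[i]) <= window)
    if (!length(cand)) next
    r <- suppressWarnings(stats::cor(dos[, i], dos[, cand, drop = FALSE]))
    r[is.na(r)] <- 0
    hit <- cand[as.numeric(r)^2 >= r2_max]
    assigned[hit] <- ss$id[i]
  }
  structure(list(index_variants = index_variants, membership = assigned,
                 parameters = list(r2_max = r2_max, window_kb = window_kb,
                                   p_index_max = p_index_max)),
            class = "clump_result")
}

#' Clumping-and-thresholding polygenic scores
#'
#' For each p-value threshold, the score is the mean over index variants
#' with p at or below the threshold of beta times dosage (missing dosages
#' mean-imputed); `score_mode = "sum"` gives the plain weighted sum
#' instead. With no qualifying variant the score is all-zero with a
#' warning.
#'
#' @param g a `genotype_matrix`.
#' @param ss harmonised summary statistics.
#' @param clumps a `clump_result` computed from the same `g` and `ss`.
#' @param thresholds p-value inclusion thresholds in (0, 1].
#' @param score_mode `"mean"` or `"sum"` over used variants.
#' @return Named list of `score_vector`s, one per threshold.
#' @export
compute_pgc_prs <- function(g, ss, clumps,
                            thresholds = c(5e-8, 1e-6, 1e-4, 1e-3, 1e-2,
                                           0.01, 0.05, 0.5, 1),
                            score_mode = c("mean", "sum")) {
  score_mode <- match.arg(score_mode)
  stopifnot(inherits(g, "genotype_matrix"), inherits(clumps, "clump_result"))
  if (any(thresholds <= 0 | thresholds > 1))
    stop("thresholds must lie in (0, 1]")
  idx <- clumps$index_variants
  ssi <- ss[match(idx, ss$id), , drop = FALSE]
  dos <- mean_impute(g$dosages)
  out <- lapply(thresholds, function(t) {
    use <- idx[ssi$p <= t]
    if (!length(use)) {
      warning(sprintf("no variant passes threshold %g; zero score", t),
              call. = FALSE)
      sc <- stats::setNames(rep(0, nrow(dos)), g$subject_ids)
    } else {
      beta <- ssi$beta[match(use, ssi$id)]
      sc <- as.numeric(dos[, use, drop = FALSE] %*% beta)
      if (score_mode == "mean") sc <- sc / length(use)
      names(sc) <- g$subject_ids
    }
    structure(list(scores = sc, score_type = "pgc_prs", threshold = t,
                   n_features_used = length(use),
                   provenance = sprintf("PGC-PRS at p<=%g (%s over %d variants)",
                                        t, score_mode, length(use))),
              class = "score_vector")
  })
  names(out) <- make.unique(sprintf("p%g", thresholds))
  out
}
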