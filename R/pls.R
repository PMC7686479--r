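# Behavioral PLS: score-activation correlation matrix, SVD, permutation
# and bootstrap inference, brainscores, cluster reporting.

#' Construct condition-wise activation data
#'
#' @param conditions named list of subjects x voxels matrices, one per task
#'   condition, sharing subject and voxel ordering.
#' @param voxel_table data frame (voxel_id, x, y, z) of integer grid
#'   coordinates, unique per voxel.
#' @param group named character vector: group label per subject.
#' @return An object of class `activation_data`.
#' @export
new_activation_data <- function(conditions, voxel_table, group) {
  stopifnot(is.list(conditions), length(conditions) >= 1L)
  dims <- lapply(conditions, dim)
  if (length(unique(dims)) != 1L)
    stop("all condition matrices must share dimensions")
  if (anyDuplicated(voxel_table[c("x", "y", "z")]))
    stop("voxel coordinates must be unique")
  if (nrow(voxel_table) != ncol(conditions[[1]]))
    stop("voxel table rows must match activation columns")
  n <- nrow(conditions[[1]])
  if (length(group) != n) stop("one group label per subject required")
  subj <- rownames(conditions[[1]])
  if (is.null(subj)) subj <- sprintf("S%04d", seq_len(n))
  structure(list(conditions = conditions, voxel_table = voxel_table,
                 group = stats::setNames(as.character(group), subj),
                 subject_ids = subj),
            class = "activation_data")
}

#' @export
print.activation_data <- function(x, ...) {
  cat(sprintf("activation_data: %d subjects x %d voxels, conditions: %s\n",
              length(x$subject_ids), nrow(x$voxel_table),
              paste(names(x$conditions), collapse = ", ")))
  invisible(x)
}

# Cell bookkeeping: rows of the PLS matrix are (group, condition) pairs,
# group-major, in the order labels first appear / are given.
pls_cells <- function(act) {
  groups <- unique(unname(act$group))
  conds <- names(act$conditions)
  data.frame(group = rep(groups, each = length(conds)),
             condition = rep(conds, length(groups)),
             stringsAsFactors = FALSE)
}

#' Stacked (group x condition) by voxel correlation matrix
#'
#' Each row holds, for one group and task condition, the Pearson
#' correlation across that group's subjects between the score and every
#' voxel's activation. Zero-variance voxels within a cell give 0 with a
#' warning.
#'
#' @param act an `activation_data`.
#' @param score numeric score per subject (subject order of `act`).
#' @return cells x voxels matrix with `cells` data frame attached as an
#'   attribute.
#' @export
build_correlation_matrix <- function(act, score) {
  stopifnot(inherits(act, "activation_data"))
  if (length(score) != length(act$subject_ids))
    stop("score must cover all subjects")
  cells <- pls_cells(act)
  for (g in unique(cells$group))
    if (sum(act$group == g) < 3L)
      stop(sprintf("group '%s' has fewer than 3 subjects", g))
  R <- matrix(NA_real_, nrow(cells), nrow(act$voxel_table),
              dimnames = list(paste(cells$group, cells$condition, sep = "."),
                              act$voxel_table$voxel_id))
  for (i in seq_len(nrow(cells))) {
    gi <- which(act$group == cells$group[i])
    R[i, ] <- cor_vec_mat(score[gi],
                          act$conditions[[cells$condition[i]]][gi, , drop = FALSE])
  }
  attr(R, "cells") <- cells
  R
}

#' Singular value decomposition of the PLS correlation matrix
#'
#' Latent variable k consists of the k-th behavior salience column, voxel
#' salience column (unit norm) and singular value; the crossblock
#' covariance percentage of LV k is 100 s_k^2 over the sum of squared
#' singular values. Sign convention: the largest-magnitude entry of each
#' voxel salience column is positive.
#'
#' @param R cells x voxels correlation matrix.
#' @return A `pls_result` with `singular_values`, `behavior_saliences`,
#'   `voxel_saliences`, `pct_crossblock` and the input `R`.
#' @export
pls_svd <- function(R) {
  if (all(R == 0)) stop("correlation matrix is all zero")
  s <- svd(R)
  K <- length(s$d)
  for (k in seq_len(K)) {
    j <- which.max(abs(s$v[, k]))
    if (s$v[j, k] < 0) {
      s$v[, k] <- -s$v[, k]
      s$u[, k] <- -s$u[, k]
    }
  }
  rownames(s$u) <- rownames(R)
  rownames(s$v) <- colnames(R)
  structure(list(singular_values = s$d,
                 behavior_saliences = s$u,
                 voxel_saliences = s$v,
                 pct_crossblock = 100 * s$d^2 / sum(s$d^2),
                 cells = attr(R, "cells"),
                 R = R),
            class = "pls_result")
}

#' @export
print.pls_result <- function(x, ...) {
  cat("pls_result\n LV crossblock%:",
      paste(sprintf("%.2f", utils::head(x$pct_crossblock, 5)), collapse = " "),
      "\n")
  if (!is.null(x$perm_p))
    cat(" permutation p (LV1):", format(x$perm_p[1]), "\n")
  invisible(x)
}

# Precompute per-cell column-standardised activation blocks so the
# correlation matrix can be rebuilt cheaply under score permutation:
# r = t(A_std) %*% z(score) / (n_g - 1), with zero-variance columns -> 0.
prep_pls_cells <- function(act, score) {
  cells <- pls_cells(act)
  groups <- unique(cells$group)
  gidx <- lapply(groups, function(g) which(act$group == g))
  names(gidx) <- groups
  blocks <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    gi <- gidx[[cells$group[i]]]
    A <- act$conditions[[cells$condition[i]]][gi, , drop = FALSE]
    Ac <- sweep(A, 2L, colMeans(A), "-")
    ss <- sqrt(colSums(Ac^2))
    ss[ss == 0] <- Inf   # constant voxel -> standardized column 0 -> r 0
    blocks[[i]] <- sweep(Ac, 2L, ss, "/")
  }
  zscore_group <- lapply(gidx, function(gi) {
    z <- score[gi] - mean(score[gi])
    n <- sqrt(sum(z^2))
    if (n == 0) z else z / n
  })
  list(cells = cells, gidx = gidx, blocks = blocks, zscore = zscore_group)
}

# Rebuild R from prepped blocks, with an optional within-group permutation
# (named list of index vectors into each group's subjects).
corr_from_prep <- function(prep, perm = NULL) {
  R <- matrix(NA_real_, length(prep$blocks), ncol(prep$blocks[[1]]))
  for (i in seq_along(prep$blocks)) {
    z <- prep$zscore[[prep$cells$group[i]]]
    if (!is.null(perm)) z <- z[perm[[prep$cells$group[i]]]]
    R[i, ] <- as.numeric(crossprod(prep$blocks[[i]], z))
  }
  R
}

#' Permutation test of latent-variable significance
#'
#' The null of no score-brain association is generated by shuffling the
#' subject-to-score assignment independently within each group, rebuilding
#' the correlation matrix and re-running the SVD; the p-value of LV k is
#' (1 + #\{permuted s_k >= observed s_k\}) / (1 + n_perm), so the smallest
#' attainable p is 1/(n_perm + 1).
#'
#' @param act an `activation_data`.
#' @param score numeric score per subject.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return List with `perm_p` per LV, observed singular values and the
#'   permutation null matrix.
#' @export
permutation_test <- function(act, score, n_perm = 500L, seed = 1L) {
  n_perm <- check_count(n_perm, "n_perm")
  prep <- prep_pls_cells(act, score)
  d_obs <- svd(corr_from_prep(prep))$d
  K <- length(d_obs)
  groups <- names(prep$gidx)
  with_seed(seed, {
    null_d <- matrix(NA_real_, n_perm, K)
    for (b in seq_len(n_perm)) {
      perm <- lapply(prep$gidx, function(gi) sample.int(length(gi)))
      null_d[b, ] <- svd(corr_from_prep(prep, perm))$d
    }
    perm_p <- (1 + colSums(null_d >= matrix(d_obs, n_perm, K, byrow = TRUE))) /
      (1 + n_perm)
    list(perm_p = perm_p, observed = d_obs, null_singular_values = null_d)
  })
}

#' Bootstrap voxel-salience reliability and behavior-side intervals
#'
#' Subjects are resampled with replacement within group; each resampled
#' solution is aligned to the original by orthogonal Procrustes rotation on
#' the behavior saliences (the rotation applied to the voxel saliences),
#' resolving the SVD's axis and sign indeterminacy. The bootstrap ratio of
#' voxel v on LV k is the original voxel salience over its bootstrap
#' standard error. Behavior-side 95% intervals are the 2.5/97.5 percentiles
#' of the resampled correlation rows projected on the original voxel
#' salience (asymmetric by construction).
#'
#' @param act an `activation_data`.
#' @param score numeric score per subject.
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed.
#' @param max_redraw redraw cap for degenerate resamples (a group
#'   collapsing to fewer than 3 distinct subjects).
#' @return List with `bsr` (voxels x LV), `salience_sd`, `behavior_ci`
#'   (cells x LV x lower/upper) and `behavior_boot`.
#' @export
bootstrap_saliences <- function(act, score, n_boot = 1000L, seed = 1L,
                                max_redraw = 100L) {
  n_boot <- check_count(n_boot, "n_boot", min = 2L)
  prep <- prep_pls_cells(act, score)
  fit <- pls_svd(structure(corr_from_prep(prep),
                           dimnames = list(paste(prep$cells$group,
                                                 prep$cells$condition, sep = "."),
                                           act$voxel_table$voxel_id),
                           cells = prep$cells))
  U <- fit$behavior_saliences
  V <- fit$voxel_saliences
  K <- length(fit$singular_values)
  gidx <- lapply(unique(prep$cells$group), function(g) which(act$group == g))
  names(gidx) <- unique(prep$cells$group)
  nvox <- nrow(V)
  sum_v <- matrix(0, nvox, K)
  sumsq_v <- matrix(0, nvox, K)
  behavior_boot <- array(NA_real_, c(n_boot, nrow(U), K))
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- lapply(gidx, function(gi) {
        for (tries in seq_len(max_redraw)) {
          cand <- sample(gi, length(gi), replace = TRUE)
          if (length(unique(cand)) >= 3L) return(cand)
        }
        stop("degenerate bootstrap resample: group below 3 distinct subjects")
      })
      Rb <- matrix(NA_real_, nrow(prep$cells), nvox)
      for (i in seq_len(nrow(prep$cells))) {
        gi <- idx[[prep$cells$group[i]]]
        Rb[i, ] <- cor_vec_mat(score[gi],
                               act$conditions[[prep$cells$condition[i]]][gi, , drop = FALSE],
                               warn_constant = FALSE)
      }
      sb <- svd(Rb)
      pro <- svd(crossprod(sb$u, U))
      Q <- pro$u %*% t(pro$v)
      Vr <- sb$v %*% Q
      sum_v <- sum_v + Vr
      sumsq_v <- sumsq_v + Vr^2
      behavior_boot[b, , ] <- Rb %*% V
    }
  })
  sd_v <- sqrt(pmax(sumsq_v / n_boot - (sum_v / n_boot)^2, 0) *
                 n_boot / (n_boot - 1))
  bsr <- matrix(0, nvox, K, dimnames = dimnames(V))
  nz <- sd_v > 0
  bsr[nz] <- V[nz] / sd_v[nz]
  bsr[!nz & V != 0] <- sign(V[!nz & V != 0]) * Inf
  ci <- array(NA_real_, c(nrow(U), K, 2),
              dimnames = list(rownames(U), NULL, c("lower", "upper")))
  for (i in seq_len(nrow(U)))
    for (k in seq_len(K))
      ci[i, k, ] <- stats::quantile(behavior_boot[, i, k], c(0.025, 0.975),
                                    names = FALSE)
  list(bsr = bsr, salience_sd = sd_v, behavior_ci = ci,
       behavior_boot = behavior_boot, fit = fit)
}

#' Subject-level brainscores for one latent variable
#'
#' The brainscore of subject s in condition c is the inner product of the
#' subject's condition-c voxel activation with the (unit-norm) voxel
#' salience column: the subject-specific fit to the LV's spatial pattern.
#'
#' @param act an `activation_data`.
#' @param voxel_salience unit-norm numeric vector over voxels.
#' @return subjects x conditions numeric matrix.
#' @export
brainscores <- function(act, voxel_salience) {
  stopifnot(inherits(act, "activation_data"))
  if (length(voxel_salience) != nrow(act$voxel_table))
    stop("salience length must equal the number of voxels")
  nrm <- sqrt(sum(voxel_salience^2))
  if (abs(nrm - 1) > 1e-6)
    warning(sprintf("voxel salience norm %.4f differs from 1", nrm), call. = FALSE)
  out <- vapply(act$conditions,
                function(A) as.numeric(A %*% voxel_salience),
                numeric(length(act$subject_ids)))
  rownames(out) <- act$subject_ids
  out
}

# Neighbour offsets for 6/18/26-connectivity on a 3-D grid.
connectivity_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1,
                 "18" = nz >= 1 & rowSums(abs(off) > 0) <= 2,
                 "26" = nz >= 1,
                 stop("connectivity must be 6, 18 or 26"))
  off[keep, , drop = FALSE]
}

#' Connected suprathreshold clusters of a bootstrap-ratio map
#'
#' Voxels with |BSR| strictly above `threshold` are partitioned into
#' grid-connected components separately for positive and negative signs;
#' components with strictly more than `min_cluster_size` voxels are
#' reported, sorted by peak |BSR|.
#'
#' @param bsr numeric BSR per voxel (one LV column).
#' @param voxel_table data frame (voxel_id, x, y, z).
#' @param threshold BSR magnitude threshold (strict).
#' @param min_cluster_size minimum voxel count (strict).
#' @param connectivity 6, 18 or 26.
#' @param lv LV index recorded in the output.
#' @return Data frame: lv, sign, n_voxels, peak_bsr, peak coordinates and
#'   comma-joined member voxel ids.
#' @export
cluster_report <- function(bsr, voxel_table, threshold = 2.5,
                           min_cluster_size = 20L, connectivity = 6L, lv = 1L) {
  stopifnot(length(bsr) == nrow(voxel_table))
  off <- connectivity_offsets(connectivity)
  key <- function(x, y, z) paste(x, y, z)
  pos_index <- stats::setNames(seq_len(nrow(voxel_table)),
                               key(voxel_table$x, voxel_table$y, voxel_table$z))
  out <- list()
  for (sgn in c(1, -1)) {
    supra <- which(sgn * bsr > threshold)
    visited <- rep(FALSE, nrow(voxel_table))
    in_set <- rep(FALSE, nrow(voxel_table)); in_set[supra] <- TRUE
    for (v0 in supra) {
      if (visited[v0]) next
      comp <- integer(0); queue <- v0; visited[v0] <- TRUE
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        comp <- c(comp, v)
        nb_keys <- key(voxel_table$x[v] + off[, 1],
                       voxel_table$y[v] + off[, 2],
                       voxel_table$z[v] + off[, 3])
        nb <- pos_index[nb_keys]
        nb <- nb[!is.na(nb)]
        nb <- nb[in_set[nb] & !visited[nb]]
        visited[nb] <- TRUE
        queue <- c(queue, nb)
      }
      if (length(comp) > min_cluster_size) {
        pk <- comp[which.max(abs(bsr[comp]))]
        out[[length(out) + 1L]] <- data.frame(
          lv = lv, sign = if (sgn > 0) "positive" else "negative",
          n_voxels = length(comp), peak_bsr = bsr[pk],
          peak_x = voxel_table$x[pk], peak_y = voxel_table$y[pk],
          peak_z = voxel_table$z[pk],
          voxel_ids = paste(voxel_table$voxel_id[sort(comp)], collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(lv = integer(0), sign = character(0),
                      n_voxels = integer(0), peak_bsr = numeric(0),
                      peak_x = integer(0), peak_y = integer(0),
                      peak_z = integer(0), voxel_ids = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(-abs(res$peak_bsr)), , drop = FALSE]
}

#' Full behavioral-PLS analysis of one score
#'
#' Convenience wrapper running [build_correlation_matrix()], [pls_svd()],
#' [permutation_test()], [bootstrap_saliences()], [brainscores()] for LV1
#' and [cluster_report()].
#'
#' @param act an `activation_data`.
#' @param score numeric score per subject or a `score_vector`.
#' @param n_perm,n_boot permutation and bootstrap counts.
#' @param bsr_threshold,min_cluster_size,connectivity cluster-report
#'   parameters.
#' @param seed integer seed (permutations and bootstraps use derived
#'   sub-seeds).
#' @return A `pls_result` augmented with `perm_p`, `bsr`, `behavior_ci`,
#'   `brainscores` (LV1) and `clusters`.
#' @export
pls_analysis <- function(act, score, n_perm = 500L, n_boot = 1000L,
                         bsr_threshold = 2.5, min_cluster_size = 20L,
                         connectivity = 6L, seed = 1L) {
  if (inherits(score, "score_vector")) score <- score$scores
  R <- build_correlation_matrix(act, score)
  fit <- pls_svd(R)
  pt <- permutation_test(act, score, n_perm = n_perm,
                         seed = derive_seed(seed, 1L))
  bs <- bootstrap_saliences(act, score, n_boot = n_boot,
                            seed = derive_seed(seed, 2L))
  fit$perm_p <- pt$perm_p
  fit$null_singular_values <- pt$null_singular_values
  fit$bsr <- bs$bsr
  fit$behavior_ci <- bs$behavior_ci
  fit$brainscores <- brainscores(act, fit$voxel_saliences[, 1])
  fit$clusters <- cluster_report(bs$bsr[, 1], act$voxel_table,
                                 threshold = bsr_threshold,
                                 min_cluster_size = min_cluster_size,
                                 connectivity = connectivity, lv = 1L)
  fit
}
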