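# Brainscore-symptom association, covariate-adjusted regression,
# sex-stratified bootstrap mediation, Bonferroni gate.

#' Pearson association between brainscore and a symptom scale
#'
#' @param brainscore,symptom paired numeric vectors (>= 4 observations).
#' @return List with `r`, `r_squared` and the two-sided p from the
#'   t-transform of r.
#' @export
brainscore_symptom_corr <- function(brainscore, symptom) {
  ok <- stats::complete.cases(brainscore, symptom)
  x <- brainscore[ok]; y <- symptom[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in brainscore or symptom")
  r <- stats::cor(x, y)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  list(r = r, r_squared = r^2, p = p, n = n)
}

#' Covariate-adjusted standardized regression
#'
#' OLS of the standardized outcome on the standardized predictor plus
#' covariates (continuous covariates standardized too); reports the
#' predictor's standardized coefficient and its two-sided p.
#'
#' @param outcome,predictor numeric vectors.
#' @param covariates data frame or matrix of covariates (may be NULL).
#' @return List with `beta` (standardized), `p`, `se` and the fitted lm.
#' @export
adjusted_regression <- function(outcome, predictor, covariates = NULL) {
  z <- function(x) if (is.numeric(x) && stats::sd(x) > 0) as.numeric(scale(x)) else x
  df <- data.frame(.outcome = z(outcome), .predictor = z(predictor))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    for (nm in names(covariates)) df[[nm]] <- z(covariates[[nm]])
  }
  X <- stats::model.matrix(.outcome ~ ., data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm(.outcome ~ ., data = df)
  cf <- summary(fit)$coefficients
  list(beta = cf[".predictor", "Estimate"],
       se = cf[".predictor", "Std. Error"],
       p = cf[".predictor", "Pr(>|t|)"],
       fit = fit)
}

# One mediation point estimate from prebuilt design matrices; lm.fit's
# pivoting leaves aliased coefficients NA, which are zeroed so degenerate
# chains (mediator identical to score) stay estimable.
# X1: [1, score, covs] regressing the mediator; X2: [1, mediator, score,
# covs] regressing the outcome.
mediate_point <- function(X1, X2, mediator, outcome) {
  a <- unname(stats::lm.fit(X1, mediator)$coefficients[2])
  b <- unname(stats::lm.fit(X2, outcome)$coefficients[2])
  if (is.na(a)) a <- 0
  if (is.na(b)) b <- 0
  c(a = a, b = b, ab = a * b)
}

#' Stratified bootstrap mediation of a score-brain-symptom path
#'
#' Within each stratum, path a is the OLS coefficient of the mediator on
#' the score (plus covariates), path b the coefficient of the outcome on
#' the mediator adjusting for the score (plus covariates), and ab = a b is
#' the indirect effect. Subjects are bootstrap-resampled within stratum
#' for the SE and the 2.5/97.5 percentile interval; the between-stratum
#' difference in ab, with its own bootstrap interval, is reported as the
#' moderation index. Continuous variables are z-scored within stratum
#' before modelling so paths are on the standardized scale.
#'
#' @param score,mediator,outcome numeric vectors per subject.
#' @param covariates optional data frame of per-subject covariates.
#' @param strata factor/character stratification labels (e.g. sex); NULL
#'   for a single unstratified analysis.
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @param min_stratum_n smallest allowed stratum size.
#' @param standardize z-score continuous variables within stratum before
#'   modelling (standardized paths, the default); FALSE keeps the raw
#'   scale.
#' @return A `mediation_result`: per-stratum a, b, ab, se_ab, ci_ab and the
#'   moderation (difference) index when two or more strata are present.
#' @export
mediate <- function(score, mediator, outcome, covariates = NULL,
                    strata = NULL, n_boot = 5000L, seed = 1L,
                    min_stratum_n = 20L, standardize = TRUE) {
  n <- length(score)
  stopifnot(length(mediator) == n, length(outcome) == n)
  n_boot <- check_count(n_boot, "n_boot", min = 2L)
  if (is.null(strata)) strata <- rep("all", n)
  strata <- as.character(strata)
  labs <- unique(strata)
  z <- function(x) {
    if (!standardize) return(x)
    s <- stats::sd(x)
    if (is.na(s) || s == 0) x - mean(x) else as.numeric(scale(x))
  }
  boot_ab <- list()
  res <- list()
  with_seed(seed, {
    for (lab in labs) {
      i <- which(strata == lab)
      if (length(i) < min_stratum_n)
        stop(sprintf("stratum '%s' has %d subjects (< %d)", lab, length(i),
                     min_stratum_n))
      sc <- z(score[i]); md <- z(mediator[i]); oc <- z(outcome[i])
      C <- NULL
      if (!is.null(covariates)) {
        cv <- as.data.frame(covariates)[i, , drop = FALSE]
        cv[] <- lapply(cv, function(x) if (is.numeric(x)) z(x) else x)
        C <- stats::model.matrix(~ . - 1, data = cv)
      }
      ni <- length(i)
      X1 <- cbind(1, sc, C)
      X2 <- cbind(1, md, sc, C)
      pt <- mediate_point(X1, X2, md, oc)
      ab_b <- numeric(n_boot)
      for (b in seq_len(n_boot)) {
        j <- sample.int(ni, replace = TRUE)
        ab_b[b] <- mediate_point(X1[j, , drop = FALSE], X2[j, , drop = FALSE],
                                 md[j], oc[j])[["ab"]]
      }
      boot_ab[[lab]] <- ab_b
      res[[lab]] <- list(a = pt[["a"]], b = pt[["b"]], ab = pt[["ab"]],
                         se_ab = stats::sd(ab_b),
                         ci_ab = stats::quantile(ab_b, c(0.025, 0.975),
                                                 names = FALSE),
                         n = ni)
    }
  })
  out <- list(strata = res, n_boot = n_boot, seed = seed)
  if (length(labs) >= 2L) {
    d_point <- res[[labs[1]]]$ab - res[[labs[2]]]$ab
    d_boot <- boot_ab[[labs[1]]] - boot_ab[[labs[2]]]
    out$moderation <- list(
      contrast = paste(labs[1], "-", labs[2]),
      diff_ab = d_point, se = stats::sd(d_boot),
      ci = stats::quantile(d_boot, c(0.025, 0.975), names = FALSE))
  }
  class(out) <- "mediation_result"
  out
}

#' @export
print.mediation_result <- function(x, ...) {
  for (lab in names(x$strata)) {
    s <- x$strata[[lab]]
    cat(sprintf("%s: ab = %.3f, SE = %.3f, 95%% CI [%.3f; %.3f] (n = %d)\n",
                lab, s$ab, s$se_ab, s$ci_ab[1], s$ci_ab[2], s$n))
  }
  if (!is.null(x$moderation))
    cat(sprintf("moderation (%s): diff ab = %.3f, 95%% CI [%.3f; %.3f]\n",
                x$moderation$contrast, x$moderation$diff_ab,
                x$moderation$ci[1], x$moderation$ci[2]))
  invisible(x)
}

#' Bonferroni gate over a family of PLS analyses
#'
#' An analysis passes when its permutation p is strictly below alpha / m;
#' with the nine PGC-PRS thresholds and alpha 0.05 the gate is
#' 0.05 / 9 (about 0.005).
#'
#' @param perm_p numeric permutation p-values, one per analysis.
#' @param m number of analyses in the family.
#' @param alpha family-wise error rate.
#' @return List with the gate `threshold` and logical `pass` per analysis.
#' @export
multiple_comparison_gate <- function(perm_p, m = 9L, alpha = 0.05) {
  m <- check_count(m, "m")
  alpha <- check_number(alpha, "alpha", 0, 1, open_lower = TRUE)
  threshold <- alpha / m
  list(threshold = threshold, pass = perm_p < threshold)
}
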