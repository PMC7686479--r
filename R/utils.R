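# Shared internal helpers: argument checking, standardisation, seeds.

stop_field <- function(field, msg) {
  stop(sprintf("invalid field '%s': %s", field, msg), call. = FALSE)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min)
    stop_field(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_field(field, "must be a single finite number")
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_field(field, sprintf("must lie in %s%g, %g%s",
                              if (open_lower) "(" else "[", lower, upper,
                              if (open_upper) ")" else "]"))
  as.numeric(x)
}

#' Derive a per-stage random seed from a master seed
#'
#' Sub-seeds follow a fixed counter rule so individual stages can be
#' re-run in isolation and still reproduce a full pipeline run:
#' `seed_i = (master * 131 + 7 * i) mod (2^31 - 1)`.
#'
#' @param master integer master seed.
#' @param i stage counter (non-negative integer).
#' @return An integer seed.
#' @export
derive_seed <- function(master, i) {
  master <- check_count(master, "master", min = 0L)
  i <- check_count(i, "i", min = 0L)
  as.integer((as.numeric(master) * 131 + 7 * as.numeric(i)) %% 2147483647)
}

# Run expr with a local RNG state: seeds deterministically, restores
# the caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Column z-scores; columns with zero variance become NA (callers decide).
zscore_cols <- function(m) {
  m <- as.matrix(m)
  mu <- colMeans(m)
  sd <- apply(m, 2L, stats::sd)
  sweep(sweep(m, 2L, mu, "-"), 2L, sd, "/")
}

# Pearson correlations between a vector and every column of a matrix,
# vectorised; zero-variance columns yield 0 with an optional warning.
cor_vec_mat <- function(x, m, warn_constant = TRUE) {
  n <- length(x)
  stopifnot(nrow(m) == n)
  xc <- x - mean(x)
  xs <- sqrt(sum(xc^2))
  mc <- sweep(m, 2L, colMeans(m), "-")
  ss <- sqrt(colSums(mc^2))
  bad <- ss == 0 | xs == 0
  ss[bad] <- 1
  r <- as.numeric(crossprod(mc, xc)) / (ss * max(xs, .Machine$double.eps))
  if (any(bad)) {
    r[bad] <- 0
    if (warn_constant)
      warning(sprintf("%d zero-variance column(s); correlation set to 0", sum(bad)),
              call. = FALSE)
  }
  r
}

# Mean-impute missing values per column.
mean_impute <- function(m) {
  if (!anyNA(m)) return(m)
  for (j in seq_len(ncol(m))) {
    nas <- is.na(m[, j])
    if (any(nas)) m[nas, j] <- mean(m[!nas, j])
  }
  m
}
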