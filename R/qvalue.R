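#' Default lambda grid for pi0 estimation
#'
#' The tuning grid 0.00, 0.05, ..., 0.90 over which the raw estimates
#' `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))` are formed.
#'
#' @return Numeric vector of lambda values.
#' @export
default_lambda_grid <- function() seq(0, 0.90, by = 0.05)

.pi0_raw <- function(pvals, lambda) {
  m <- length(pvals)
  vapply(lambda, function(l) sum(pvals > l) / (m * (1 - l)), numeric(1))
}

.check_pvals <- function(pvals) {
  pvals <- as.numeric(pvals)
  if (length(pvals) < 2L) stop("need at least 2 p-values")
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  pvals
}

.clamp_pi0 <- function(pi0, raw) {
  pi0 <- min(pi0, 1)
  if (pi0 <= 0) {
    fallback <- min(raw[raw > 0], 1)
    if (!is.finite(fallback))
      stop("pi0 estimate is non-positive and no positive raw estimate exists")
    warning("pi0 estimate was non-positive; clamped to the smallest ",
            "positive raw estimate")
    pi0 <- fallback
  }
  pi0
}

#' Estimate pi0 by the smoother method
#'
#' The proportion of true null hypotheses pi0 is estimated by fitting a
#' cubic smoothing spline (3 df) to the raw estimates
#' `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))` over the lambda grid
#' and evaluating it at the largest lambda, then clamping into (0, 1].
#' With fewer than ~100 p-values the estimate is unstable; a warning
#' recommends supplying a fixed pi0 instead.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`, length >= 2.
#' @param lambda_grid Strictly increasing grid within `[0, 1)`.
#' @return The pi0 estimate (scalar in (0, 1]).
#' @export
pi0_smoother <- function(pvals, lambda_grid = default_lambda_grid()) {
  pvals <- .check_pvals(pvals)
  lambda_grid <- .check_lambda(lambda_grid)
  raw <- .pi0_raw(pvals, lambda_grid)
  if (length(pvals) < 100L)
    warning("pi0 estimation is unstable for fewer than 100 p-values; ",
            "consider a fixed pi0")
  if (length(lambda_grid) < 4L) {
    # too few knots for a 3-df spline; use the last raw estimate
    pi0 <- raw[length(raw)]
  } else {
    fit <- stats::smooth.spline(lambda_grid, raw, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda_grid))$y
  }
  .clamp_pi0(pi0, raw)
}

.check_lambda <- function(lambda_grid) {
  lambda_grid <- as.numeric(lambda_grid)
  if (length(lambda_grid) < 1L || any(lambda_grid < 0) ||
      any(lambda_grid >= 1) || is.unsorted(lambda_grid, strictly = TRUE))
    stop("`lambda_grid` must be strictly increasing within [0, 1)")
  lambda_grid
}

#' Estimate pi0 by the bootstrap method
#'
#' Chooses the lambda minimising the bootstrap-estimated mean squared error
#' of `pi0(lambda)` around the minimum raw estimate over the grid (the
#' plug-in target), then returns the raw estimate at that lambda, clamped
#' into (0, 1].
#'
#' @inheritParams pi0_smoother
#' @param B Number of bootstrap resamples (default 100).
#' @param seed Integer RNG seed.
#' @return The pi0 estimate (scalar in (0, 1]).
#' @export
pi0_bootstrap <- function(pvals, lambda_grid = default_lambda_grid(),
                          B = 100L, seed = 1L) {
  pvals <- .check_pvals(pvals)
  lambda_grid <- .check_lambda(lambda_grid)
  stopifnot(B >= 1L)
  raw <- .pi0_raw(pvals, lambda_grid)
  if (length(lambda_grid) == 1L)
    return(.clamp_pi0(raw, raw))
  m <- length(pvals)
  target <- min(raw)
  set.seed(as.integer(seed))
  mse <- numeric(length(lambda_grid))
  for (b in seq_len(B)) {
    pb <- pvals[sample.int(m, m, replace = TRUE)]
    mse <- mse + (.pi0_raw(pb, lambda_grid) - target)^2
  }
  .clamp_pi0(raw[which.min(mse)], raw)
}

#' Storey q-values from p-values
#'
#' Sorts the p-values, forms `raw_i = pi0 * p_(i) * m / i`, enforces
#' monotonicity by the forward minimum `q_(i) = min_{j >= i} raw_j`, and
#' maps the result back to the input order. Tied p-values share the q of
#' their largest rank. With `pi0 = 1` the q-values coincide with
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param pi0 Proportion of true nulls, in (0, 1]; typically an estimate
#'   from [pi0_smoother()] or [pi0_bootstrap()], or a fixed value.
#' @return Numeric vector of q-values, in the input order.
#' @examples
#' qvalues(c(0.02, 0.04, 1.0), pi0 = 0.5)  # 0.03 0.03 0.50
#' @export
qvalues <- function(pvals, pi0 = 1) {
  pvals <- .check_pvals(pvals)
  if (length(pi0) != 1L || is.na(pi0) || pi0 <= 0 || pi0 > 1)
    stop("`pi0` must be a scalar in (0, 1]")
  m <- length(pvals)
  o <- order(pvals)
  raw <- pi0 * pvals[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(raw)))       # forward min ensures monotonicity
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  # ties share the q of their largest rank; forward-min already guarantees
  # equal p => equal q, since cummin over equal raw tail values coincides
  q
}

#' Full q-value analysis of a labelled p-value set
#'
#' Bundles both pi0 estimators and the corresponding q-values for a set of
#' p-values, mirroring a per-stratum multiple-testing summary column block.
#'
#' @inheritParams pi0_bootstrap
#' @param labels Optional labels for the tests.
#' @param pi0 Optional fixed pi0 overriding both estimators (used when m is
#'   too small for stable estimation).
#' @return A `data.frame` (`label`, `p`, `q_smoother`, `q_bootstrap`) with
#'   attributes `pi0_smoother` and `pi0_bootstrap`.
#' @export
qvalue_set <- function(pvals, labels = NULL,
                       lambda_grid = default_lambda_grid(), B = 100L,
                       seed = 1L, pi0 = NULL) {
  pvals <- .check_pvals(pvals)
  if (is.null(labels)) labels <- sprintf("test%02d", seq_along(pvals))
  if (is.null(pi0)) {
    p0s <- pi0_smoother(pvals, lambda_grid)
    p0b <- pi0_bootstrap(pvals, lambda_grid, B = B, seed = seed)
  } else {
    p0s <- p0b <- pi0
  }
  structure(data.frame(label = labels, p = pvals,
                       q_smoother = qvalues(pvals, p0s),
                       q_bootstrap = qvalues(pvals, p0b),
                       stringsAsFactors = FALSE),
            pi0_smoother = p0s, pi0_bootstrap = p0b)
}
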