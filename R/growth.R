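#' Construct a growth curve
#'
#' An optical-density time series for one culture, used to quantify
#' interaction strength in the growth-based yeast two-hybrid readout.
#'
#' @param time Time points in hours, strictly increasing, length >= 2.
#' @param od OD600 readings, positive, same length as `time`.
#' @param strain Optional strain label.
#' @param replicate Optional replicate id.
#' @return An object of class `growth_curve`.
#' @export
growth_curve <- function(time, od, strain = NA_character_,
                         replicate = NA_integer_) {
  time <- as.numeric(time); od <- as.numeric(od)
  if (length(time) < 2L || length(od) != length(time))
    stop("need >= 2 (time, od) pairs of equal length")
  if (is.unsorted(time, strictly = TRUE))
    stop("`time` must be strictly increasing")
  if (any(!is.finite(od)) || any(od <= 0))
    stop("`od` must be positive")
  structure(list(time = time, od = od, strain = as.character(strain),
                 replicate = replicate), class = "growth_curve")
}

#' Generation (doubling) time from exponential growth
#'
#' Under exponential growth `OD_t = OD_0 * 2^(t / T)`, so log2(OD) is linear
#' in time with slope 1/T. The generation time T is estimated by a
#' least-squares fit of log2(OD) against time within the fitting window.
#'
#' The default window keeps points in the exponential phase: OD between
#' 1.5x the first reading and 0.5x the final reading (a plateau proxy).
#' When fewer than two points satisfy the filter — short, clean curves with
#' no lag or plateau — all points are used. An explicit `window` (a numeric
#' `c(t_min, t_max)` in hours) always takes precedence.
#'
#' @param curve A [growth_curve()].
#' @param window Optional numeric length-2 time window in hours; `NULL`
#'   applies the exponential-phase OD filter described above.
#' @return Generation time T in hours (positive scalar).
#' @examples
#' generation_time(growth_curve(c(0, 2, 4), c(1, 2, 4)))  # exactly 2 h
#' @export
generation_time <- function(curve, window = NULL) {
  stopifnot(inherits(curve, "growth_curve"))
  t <- curve$time; od <- curve$od
  if (!is.null(window)) {
    stopifnot(is.numeric(window), length(window) == 2L)
    keep <- t >= window[1] & t <= window[2]
  } else {
    keep <- od >= 1.5 * od[1] & od <= 0.5 * od[length(od)]
    if (sum(keep) < 2L) keep <- rep(TRUE, length(t))
  }
  if (sum(keep) < 2L) stop("fewer than 2 points in the fitting window")
  fit <- stats::lm(log2(od[keep]) ~ t[keep])
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stop("non-positive growth slope: no exponential growth in window")
  1 / slope
}

#' Interaction-affinity fold change between two strains
#'
#' Compares growth rates (reciprocal generation times, 1/T per hour) of a
#' mutant bait against the wild type across replicate cultures: the fold
#' change is the ratio of mean growth rates, and significance comes from a
#' pooled two-sample Student's t-test on the per-replicate rates.
#'
#' @param mutant_T_reps Numeric vector of replicate generation times (h) for
#'   the mutant, length >= 2.
#' @param wildtype_T_reps Same for the wild-type reference.
#' @return A list: `fold_change` (mutant rate / wild-type rate),
#'   `p_value`, `mutant_rate`, `wildtype_rate`, `t_statistic`, `df`.
#' @export
affinity_fold_change <- function(mutant_T_reps, wildtype_T_reps) {
  m <- as.numeric(mutant_T_reps); w <- as.numeric(wildtype_T_reps)
  if (length(m) < 2L || length(w) < 2L)
    stop("need at least 2 replicates per arm")
  if (any(m <= 0) || any(w <= 0)) stop("generation times must be positive")
  rm_ <- 1 / m; rw <- 1 / w
  df <- length(rm_) + length(rw) - 2L
  if (stats::sd(c(rm_ - mean(rm_), rw - mean(rw))) == 0) {
    # both arms internally constant: t-test degenerates
    same <- isTRUE(all.equal(mean(rm_), mean(rw)))
    tt <- list(p.value = if (same) 1 else 0,
               statistic = if (same) 0 else Inf, parameter = df)
  } else {
    tt <- stats::t.test(rm_, rw, var.equal = TRUE)
  }
  list(fold_change = mean(rm_) / mean(rw),
       p_value = tt$p.value,
       mutant_rate = mean(rm_),
       wildtype_rate = mean(rw),
       t_statistic = unname(tt$statistic),
       df = unname(tt$parameter))
}
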