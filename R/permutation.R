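#' Two-tailed permutation test for per-stratum case enrichment
#'
#' For each mitonuclear stratum g the statistic is the absolute deviation
#' `d_g = |p_g - p_bar|` of the stratum case proportion from the overall
#' case proportion. Disease labels are shuffled among all samples (the fixed
#' multiset of 0/1 statuses is permuted, so stratum sizes and the overall
#' case count are preserved), all stratum deviations are recomputed from the
#' same shuffle, and the p-value for stratum g is the proportion of
#' replicates whose deviation is equal to or greater than the observed one
#' (ties count as exceedances).
#'
#' By default every stratum is scored on one shared permutation stream; an
#' independent-stream mode (a fresh set of shuffles per stratum) is available
#' but non-default.
#'
#' @param records A cohort `data.frame` (see [as_cohort()]); records with a
#'   missing stratum are excluded with a warning.
#' @param n_permutations Number of label shuffles (default 10,000).
#' @param seed Integer RNG seed; required for reproducibility and echoed in
#'   the result.
#' @param estimator `"raw"` reports b/B, the plain exceedance proportion;
#'   `"add-one"` reports (b + 1)/(B + 1), which cannot be zero.
#' @param stream `"shared"` (default) or `"independent"`.
#' @return A `data.frame` of class `permutation_result`: per stratum
#'   `n_cases`, `n_total`, `proportion`, `deviation`, `n_exceed`, `p_perm`
#'   and the exact hypergeometric `p_exact`; attributes record the overall
#'   proportion, `n_permutations`, `seed`, `estimator` and `stream`.
#' @examples
#' coh <- expand_counts(load_fixture("table2"))
#' permutation_test(coh, n_permutations = 2000, seed = 1)
#' @export
permutation_test <- function(records, n_permutations = 10000L, seed,
                             estimator = c("raw", "add-one"),
                             stream = c("shared", "independent")) {
  estimator <- match.arg(estimator)
  stream <- match.arg(stream)
  n_permutations <- as.integer(n_permutations)
  stopifnot(n_permutations >= 1L)
  if (missing(seed)) stop("`seed` is required for a reproducible test")
  records <- as_cohort(records)
  if (any(!records$stratifiable)) {
    warning(sum(!records$stratifiable),
            " record(s) without a stratum excluded")
    records <- records[records$stratifiable, ]
  }
  stratum <- paste(records$cluster, records$genotype, sep = "_")
  labs <- sort(unique(stratum))
  idx0 <- match(stratum, labs)
  k <- length(labs)
  N <- nrow(records)
  K <- sum(records$status)
  pbar <- K / N
  n_g <- tabulate(idx0, nbins = k)
  k_obs <- as.integer(rowsum(records$status, idx0))
  d_obs <- abs(k_obs / n_g - pbar)
  # the shuffle null depends only on stratum sizes and the case total, so a
  # sorted index makes results exactly invariant to input record order
  idx <- sort(idx0)

  set.seed(as.integer(seed))
  count_exceed <- function(which_strata) {
    exceed <- integer(length(which_strata))
    for (b in seq_len(n_permutations)) {
      pos <- sample.int(N, K)            # case positions after the shuffle
      cnt <- tabulate(idx[pos], nbins = k)
      dev <- abs(cnt[which_strata] / n_g[which_strata] - pbar)
      exceed <- exceed + (dev >= d_obs[which_strata])
    }
    exceed
  }
  b_g <- if (stream == "shared") count_exceed(seq_len(k)) else
    vapply(seq_len(k), function(g) count_exceed(g), integer(1))

  p_perm <- switch(estimator,
                   "raw" = b_g / n_permutations,
                   "add-one" = (b_g + 1) / (n_permutations + 1))
  p_exact <- vapply(seq_len(k), function(g)
    exact_stratum_p(N, K, n_g[g], k_obs[g]), numeric(1))

  structure(data.frame(stratum = labs, n_cases = k_obs, n_total = n_g,
                       proportion = k_obs / n_g, deviation = d_obs,
                       n_exceed = b_g, p_perm = p_perm, p_exact = p_exact,
                       stringsAsFactors = FALSE),
            overall_proportion = pbar, n_permutations = n_permutations,
            seed = as.integer(seed), estimator = estimator, stream = stream,
            class = c("permutation_result", "data.frame"))
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(paste0("Stratum enrichment permutation test: %d shuffles, ",
                     "seed %d, overall case proportion %.3f\n"),
              attr(x, "n_permutations"), attr(x, "seed"),
              attr(x, "overall_proportion")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Exact two-tailed enrichment p-value under the shuffle null
#'
#' Under a random shuffle of the fixed status labels, the number of cases in
#' a stratum of size `n_stratum` is hypergeometric. This closed form sums
#' the hypergeometric probability mass over all outcomes k whose absolute
#' deviation `|k / n_stratum - p_bar|` is at least that of the observed
#' count — the exact limit of the Monte Carlo permutation p-value.
#'
#' @param n_total_cohort Cohort size N.
#' @param n_cases_cohort Total cases K (0 <= K <= N).
#' @param n_stratum Stratum size n (0 < n <= N).
#' @param k_observed Observed cases in the stratum (0 <= k <= n).
#' @return The exact two-tailed p-value in `[0, 1]`.
#' @examples
#' exact_stratum_p(6, 3, 2, 2)              # 0.4 by enumeration
#' exact_stratum_p(1477, 1118, 265, 183)    # ~0.006
#' @export
exact_stratum_p <- function(n_total_cohort, n_cases_cohort, n_stratum,
                            k_observed) {
  N <- as.integer(n_total_cohort); K <- as.integer(n_cases_cohort)
  n <- as.integer(n_stratum); k <- as.integer(k_observed)
  if (K < 0 || K > N || n < 1 || n > N || k < 0 || k > n || k > K ||
      (n - k) > (N - K))
    stop("impossible counts for the hypergeometric null")
  pbar <- K / N
  d <- abs(k / n - pbar)
  ks <- 0:n
  # small tolerance so outcomes tied with the observed deviation are included
  sel <- abs(ks / n - pbar) >= d - 1e-12
  sum(stats::dhyper(ks[sel], K, N - K, n))
}
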