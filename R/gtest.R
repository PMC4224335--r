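#' Likelihood-ratio (G) test of independence for R x C tables
#'
#' Computes the G statistic `G = 2 * sum(O * log(O / E))` over cells with
#' positive observed counts, where `E` are the usual independence
#' expectations (row total x column total / grand total), and refers it to a
#' chi-square distribution with `(r - 1)(c - 1)` degrees of freedom. Zero
#' observed cells contribute 0 (the `x log x -> 0` limit). No continuity
#' correction is applied by default; the Williams small-sample correction is
#' available behind a flag.
#'
#' @param x A numeric matrix or table of non-negative counts, at least 2 x 2.
#' @param williams If `TRUE`, divide G by the Williams correction factor
#'   `1 + (sum(N/row) - 1)(sum(N/col) - 1) / (6 N df)`.
#' @return An object of class `g_test` (a list): `G`, `df`, `p_value`,
#'   `expected`, `williams`.
#' @examples
#' tab1 <- load_fixture("table1")
#' g_test(cbind(tab1$n_cases, tab1$n_controls))
#' @export
g_test <- function(x, williams = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("contingency table must have at least 2 rows and 2 columns")
  if (any(is.na(x)) || any(x < 0))
    stop("counts must be non-negative and complete")
  rs <- rowSums(x); cs <- colSums(x); N <- sum(x)
  if (N <= 0 || any(rs == 0) || any(cs == 0))
    stop("all-zero row or column: degrees of freedom undefined")
  E <- outer(rs, cs) / N
  G <- 2 * sum(ifelse(x > 0, x * log(x / E), 0))
  df <- (nrow(x) - 1L) * (ncol(x) - 1L)
  if (williams) {
    q <- 1 + (sum(N / rs) - 1) * (sum(N / cs) - 1) / (6 * N * df)
    G <- G / q
  }
  structure(list(G = G, df = df,
                 p_value = stats::pchisq(G, df, lower.tail = FALSE),
                 expected = E, williams = williams),
            class = "g_test")
}

#' @export
print.g_test <- function(x, ...) {
  cat(sprintf("G-test of independence%s: G = %.4f, df = %d, p = %.4g\n",
              if (x$williams) " (Williams-corrected)" else "",
              x$G, x$df, x$p_value))
  invisible(x)
}
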