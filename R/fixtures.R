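#' Load a reference table fixture
#'
#' The package ships the published summary tables of the motivating
#' Ashkenazi Jewish T2DM mitonuclear association study as plain-TSV
#' fixtures: the haplogroup-cluster by status counts (`"table1"`), the
#' twelve-stratum permutation-test table with q-value columns (`"table2"`),
#' the logistic odds-ratio contrasts against the HV_CC reference
#' (`"table3"`), and the published pi0 estimates (`"pi0"`). Cross-table
#' arithmetic invariants (stratum counts summing to the cohort margins and
#' to the per-cluster counts of table 1) are validated at load time.
#'
#' @param name One of `"table1"`, `"table2"`, `"table3"`, `"pi0"`.
#' @return A `data.frame`; for `"table2"` the `stratum_table` margins
#'   attributes are attached so it can feed [expand_counts()] directly.
#' @examples
#' load_fixture("table1")
#' @export
load_fixture <- function(name = c("table1", "table2", "table3", "pi0")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"),
                      package = "mitonuclear", mustWork = TRUE)
  d <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                         stringsAsFactors = FALSE)
  switch(name,
    table1 = {
      stopifnot(nrow(d) == 4L,
                sum(d$n_cases) == 1118L, sum(d$n_controls) == 359L)
      d
    },
    table2 = {
      stopifnot(nrow(d) == 12L,
                sum(d$n_cases) == 1118L, sum(d$n_total) == 1477L,
                all(d$n_cases <= d$n_total))
      t1 <- utils::read.delim(system.file("extdata", "table1.tsv",
                                          package = "mitonuclear"),
                              comment.char = "#")
      cl <- substr(d$stratum, 1, 2)
      cases_by_cl <- tapply(d$n_cases, cl, sum)
      if (!all(cases_by_cl[t1$cluster] == t1$n_cases))
        stop("table2 per-cluster case sums do not reproduce table1")
      parts <- .split_stratum(d$stratum)
      d$cluster <- parts$cluster
      d$genotype <- parts$genotype
      structure(d, n_cases = sum(d$n_cases), n_total = sum(d$n_total),
                proportion = sum(d$n_cases) / sum(d$n_total),
                class = c("stratum_table", "data.frame"))
    },
    table3 = {
      stopifnot(nrow(d) == 12L, "(Intercept)" %in% d$term ||
                  "Constant" %in% d$term)
      d
    },
    pi0 = {
      stopifnot(nrow(d) == 4L, all(d$pi0 > 0), all(d$pi0 <= 1))
      d
    })
}
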