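#' Run the full mitonuclear association pipeline
#'
#' Orchestrates the three-step analysis on an individual-level cohort:
#' (1) G-tests of independence for the haplogroup-cluster-by-status and
#' genotype-by-status margins; (2) the two-tailed per-stratum permutation
#' enrichment test with Storey q-values computed across exactly the k
#' stratum p-values of that run; (3) dummy-coded logistic regression odds
#' ratios against the reference stratum. All randomness flows from `seed`,
#' which is echoed in the result, so a re-run with the same configuration
#' reproduces every output. With a single stratum the G-tests and the
#' logistic contrasts are degenerate and skipped with a warning, and the
#' permutation table carries the trivial p = 1 without q-value columns.
#'
#' @param cohort A cohort `data.frame` or a path to a cohort TSV (see
#'   [read_cohort()]).
#' @param reference Reference stratum for the logistic contrasts (default
#'   `"HV_CC"`).
#' @param n_permutations Number of label shuffles (default 10,000).
#' @param seed Integer RNG seed (required).
#' @param pi0 `"smoother"`, `"bootstrap"`, or a fixed numeric value in
#'   (0, 1]. For the typical k = 12 strata the estimators are unstable, so
#'   a fixed pi0 is recommended and a warning is issued otherwise.
#' @param covariates Optional covariates for the logistic model, subset of
#'   `c("sex", "age")`.
#' @param output_dir Optional directory; when given, each table is also
#'   written as a TSV (`gtest.tsv`, `permutation.tsv`, `logistic.tsv`).
#' @return A list of class `mitonuclear_report`: `stratum_table`,
#'   `g_test_haplogroup`, `g_test_genotype`, `permutation` (with `q_smoother`
#'   / `q_bootstrap` columns), `logistic`, `seed`, `pi0`.
#' @examples
#' coh <- expand_counts(load_fixture("table2"))
#' rep <- run_pipeline(coh, n_permutations = 1000, seed = 1, pi0 = 0.227)
#' @export
run_pipeline <- function(cohort, reference = "HV_CC",
                         n_permutations = 10000L, seed,
                         pi0 = "smoother", covariates = NULL,
                         output_dir = NULL) {
  if (missing(seed)) stop("`seed` is required")
  if (is.character(cohort) && length(cohort) == 1L)
    cohort <- read_cohort(cohort)
  cohort <- as_cohort(cohort)
  tab <- stratify(cohort)

  single <- nrow(tab) < 2L
  if (single)
    warning("single stratum: independence tests, q-values and logistic ",
            "contrasts skipped")

  g_hap <- g_gen <- NULL
  if (!single) {
    cl_cases <- tapply(tab$n_cases, tab$cluster, sum)
    cl_tot <- tapply(tab$n_total, tab$cluster, sum)
    if (length(cl_cases) >= 2L)
      g_hap <- g_test(cbind(cases = cl_cases,
                            controls = cl_tot - cl_cases))
    gm <- genotype_margins(tab)
    if (nrow(gm$counts) >= 2L) g_gen <- g_test(gm$counts)
  }

  perm <- permutation_test(cohort, n_permutations = n_permutations,
                           seed = seed)
  if (!single) {
    if (is.character(pi0)) {
      pi0 <- match.arg(pi0, c("smoother", "bootstrap"))
      if (nrow(perm) < 100L)
        warning("pi0 estimation is unstable for fewer than 100 tests; ",
                "consider a fixed pi0")
      p0s <- suppressWarnings(pi0_smoother(perm$p_perm))
      p0b <- suppressWarnings(pi0_bootstrap(perm$p_perm, seed = seed))
      pi0_used <- c(smoother = p0s, bootstrap = p0b)
    } else {
      p0s <- p0b <- pi0
      pi0_used <- c(fixed = pi0)
    }
    perm$q_smoother <- qvalues(perm$p_perm, p0s)
    perm$q_bootstrap <- qvalues(perm$p_perm, p0b)
  } else pi0_used <- NULL

  logit <- if (!single)
    stratum_odds_ratios(cohort, reference = reference,
                        covariates = covariates) else NULL

  report <- structure(list(stratum_table = tab,
                           g_test_haplogroup = g_hap,
                           g_test_genotype = g_gen,
                           permutation = perm,
                           logistic = logit,
                           seed = as.integer(seed),
                           pi0 = pi0_used),
                      class = "mitonuclear_report")
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' Write the pipeline report tables to a directory
#'
#' Renders each stage output of a [run_pipeline()] report to TSV without
#' recomputing anything.
#'
#' @param report A `mitonuclear_report`.
#' @param output_dir Directory (created if absent).
#' @return `output_dir`, invisibly.
#' @export
write_report <- function(report, output_dir) {
  stopifnot(inherits(report, "mitonuclear_report"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, file)
    utils::write.table(x, file.path(output_dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
  wt(as.data.frame(report$stratum_table), "strata.tsv")
  gl <- Filter(Negate(is.null), list(haplogroup = report$g_test_haplogroup,
                                     genotype = report$g_test_genotype))
  if (length(gl)) {
    gs <- do.call(rbind, Map(function(g, nm)
      data.frame(margin = nm, G = g$G, df = g$df, p_value = g$p_value),
      gl, names(gl)))
    wt(gs, "gtest.tsv")
  }
  if (!is.null(report$permutation))
    wt(as.data.frame(report$permutation), "permutation.tsv")
  if (!is.null(report$logistic))
    wt(report$logistic, "logistic.tsv")
  invisible(output_dir)
}

#' @export
print.mitonuclear_report <- function(x, ...) {
  cat("Mitonuclear association report (seed ", x$seed, ")\n\n", sep = "")
  print(x$stratum_table)
  if (!is.null(x$g_test_haplogroup)) {
    cat("\nHaplogroup-cluster margin: "); print(x$g_test_haplogroup)
  }
  if (!is.null(x$g_test_genotype)) {
    cat("Nuclear-genotype margin:   "); print(x$g_test_genotype)
  }
  if (!is.null(x$permutation)) { cat("\n"); print(x$permutation) }
  if (!is.null(x$logistic)) {
    cat("\nLogistic contrasts vs ", attr(x$logistic, "reference"), ":\n",
        sep = "")
    print(x$logistic, digits = 3)
  }
  invisible(x)
}
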