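#' Read a case-control cohort table
#'
#' Reads an individual-level cohort from a tab-separated file with columns
#' `sample_id`, `status` (0 = healthy, 1 = case), `sex` (M/F), `age` (years),
#' `cluster` (or `haplogroup`, mapped via [cluster_haplogroup()]) and
#' `genotype` (two-letter allele pair). `NA` marks missing values. Records
#' lacking a cluster or genotype are retained but flagged so stratification
#' can exclude them; their count is reported in a message.
#'
#' @param path Path to the cohort TSV. Lines starting with `#` are ignored.
#' @param map Haplogroup-to-cluster map used when the file carries a
#'   `haplogroup` column instead of `cluster`.
#' @return A `data.frame` of class `cohort` with columns `sample_id`,
#'   `status`, `sex`, `age`, `cluster`, `genotype` and logical
#'   `stratifiable`.
#' @export
read_cohort <- function(path, map = haplogroup_cluster_map()) {
  d <- utils::read.delim(path, colClasses = "character", comment.char = "#",
                         na.strings = "NA", check.names = FALSE)
  required <- c("sample_id", "status", "sex", "age", "genotype")
  if (!all(required %in% names(d)) ||
      !any(c("cluster", "haplogroup") %in% names(d)))
    stop("cohort file must have columns sample_id, status, sex, age, ",
         "genotype and either cluster or haplogroup")
  bad <- which(!d$status %in% c("0", "1"))
  if (length(bad))
    stop("non-binary `status` at data row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         " (values must be 0 or 1)")
  cl <- if ("cluster" %in% names(d)) d$cluster else
    cluster_haplogroup(d$haplogroup, map)
  as_cohort(data.frame(
    sample_id = d$sample_id,
    status = as.integer(d$status),
    sex = ifelse(d$sex %in% c("M", "F"), d$sex, NA_character_),
    age = suppressWarnings(as.numeric(d$age)),
    cluster = cl,
    genotype = normalise_genotype(d$genotype),
    stringsAsFactors = FALSE))
}

#' @rdname read_cohort
#' @param records A cohort `data.frame`.
#' @export
write_cohort <- function(records, path) {
  records <- as_cohort(records)
  out <- records[c("sample_id", "status", "sex", "age", "cluster", "genotype")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Coerce a data frame to a validated cohort
#'
#' Normalises genotypes (alleles sorted, so "GC" becomes "CG"; phase is never
#' distinguished), checks status is binary, and flags records usable for
#' stratification (non-missing cluster and genotype).
#'
#' @param x A `data.frame` with at least `status`, `cluster`, `genotype`.
#' @return The validated `data.frame` with class `cohort` and a
#'   `stratifiable` column.
#' @export
as_cohort <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("status", "cluster", "genotype")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("cohort lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(x$status %in% c(0L, 1L)))
    stop("`status` must be binary 0/1")
  if (!"sample_id" %in% names(x))
    x$sample_id <- sprintf("S%05d", seq_len(nrow(x)))
  if (!"sex" %in% names(x)) x$sex <- NA_character_
  if (!"age" %in% names(x)) x$age <- NA_real_
  x$status <- as.integer(x$status)
  x$genotype <- normalise_genotype(x$genotype)
  x$stratifiable <- !is.na(x$cluster) & !is.na(x$genotype)
  class(x) <- c("cohort", "data.frame")
  x
}

#' Normalise diploid genotype labels
#'
#' Sorts the two allele letters lexicographically so that heterozygotes have
#' a single canonical spelling.
#'
#' @param genotype Character vector of two-letter genotypes.
#' @return Character vector with alleles sorted; `NA` preserved.
#' @export
normalise_genotype <- function(genotype) {
  g <- toupper(as.character(genotype))
  ok <- !is.na(g) & nchar(g) == 2L
  g[ok] <- vapply(strsplit(g[ok], ""),
                  function(a) paste(sort(a), collapse = ""), character(1))
  g[!ok & !is.na(g)] <- NA_character_
  g
}

#' Stratify a cohort into mitonuclear genotypes
#'
#' Cross-classifies records by (haplogroup cluster, nuclear genotype) into
#' strata labelled `<CLUSTER>_<GENOTYPE>` (e.g. `HV_CC`) and tallies cases
#' and totals per stratum together with the cohort margins. Strata with no
#' members are omitted. Records with a missing cluster or genotype are
#' excluded, with their number reported via a message.
#'
#' @param records A cohort `data.frame` (see [as_cohort()]).
#' @return A `data.frame` of class `stratum_table` with columns `stratum`,
#'   `cluster`, `genotype`, `n_cases`, `n_total`, `proportion`, plus
#'   attributes `n_cases`, `n_total`, `proportion` for the margins.
#' @examples
#' tab <- load_fixture("table2")
#' stratify(expand_counts(tab))
#' @export
stratify <- function(records) {
  records <- as_cohort(records)
  dropped <- sum(!records$stratifiable)
  if (dropped > 0)
    message(dropped, " record(s) without cluster or genotype excluded ",
            "from stratification")
  r <- records[records$stratifiable, ]
  if (nrow(r) == 0L) stop("no stratifiable records")
  stratum <- paste(r$cluster, r$genotype, sep = "_")
  n_total <- tapply(r$status, stratum, length)
  n_cases <- tapply(r$status, stratum, sum)
  lab <- sort(names(n_total))
  parts <- strsplit(lab, "_", fixed = TRUE)
  out <- data.frame(
    stratum = lab,
    cluster = vapply(parts, `[`, character(1), 1L),
    genotype = vapply(parts, `[`, character(1), 2L),
    n_cases = as.integer(n_cases[lab]),
    n_total = as.integer(n_total[lab]),
    stringsAsFactors = FALSE)
  out$proportion <- out$n_cases / out$n_total
  structure(out,
            n_cases = sum(out$n_cases),
            n_total = sum(out$n_total),
            proportion = sum(out$n_cases) / sum(out$n_total),
            class = c("stratum_table", "data.frame"))
}

#' @export
print.stratum_table <- function(x, ...) {
  cat("Mitonuclear stratum table:", nrow(x), "strata,",
      attr(x, "n_cases"), "cases /", attr(x, "n_total"), "subjects",
      sprintf("(overall case proportion %.3f)\n", attr(x, "proportion")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Genotype margins and allele frequencies by status group
#'
#' Collapses a stratum table over haplogroup clusters to a genotype-by-status
#' count table and computes per-group allele frequencies for a biallelic
#' variant: freq(allele) = (2 x homozygotes + heterozygotes) / (2 x group
#' size).
#'
#' @param table A `stratum_table` from [stratify()].
#' @return A list with `counts` (genotype x status matrix, columns `case`,
#'   `control`) and `allele_freq` (allele x status matrix; frequencies per
#'   group sum to 1).
#' @export
genotype_margins <- function(table) {
  stopifnot(inherits(table, "stratum_table"))
  cases <- tapply(table$n_cases, table$genotype, sum)
  totals <- tapply(table$n_total, table$genotype, sum)
  genos <- sort(names(totals))
  counts <- cbind(case = as.integer(cases[genos]),
                  control = as.integer(totals[genos] - cases[genos]))
  rownames(counts) <- genos
  alleles <- sort(unique(unlist(strsplit(genos, ""))))
  if (length(alleles) > 2L)
    stop("allele frequencies require a biallelic genotype set")
  af <- vapply(colnames(counts), function(grp) {
    cnt <- stats::setNames(numeric(length(alleles)), alleles)
    for (g in genos) {
      a <- strsplit(g, "")[[1]]
      cnt[a[1]] <- cnt[a[1]] + counts[g, grp]
      cnt[a[2]] <- cnt[a[2]] + counts[g, grp]
    }
    cnt / (2 * sum(counts[, grp]))
  }, numeric(length(alleles)))
  af <- matrix(af, nrow = length(alleles),
               dimnames = list(alleles, colnames(counts)))
  list(counts = counts, allele_freq = af)
}
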