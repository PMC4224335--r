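#' Restriction digestion specification
#'
#' Describes a restriction enzyme by its recognition motif and the 0-based
#' offset within the motif after which the cut falls. The default corresponds
#' to HpyCH4IV, which recognises ACGT and cuts A^CGT (a palindromic four-cutter used to
#' genotype the biallelic NDUFC2 exon-1 variant: only the rare allele creates
#' the site).
#'
#' @param motif Recognition sequence, characters from A/C/G/T.
#' @param cut_offset Integer in `[0, nchar(motif))`; the cut falls after this
#'   many bases of the motif.
#' @return An object of class `digest_spec`.
#' @examples
#' digest_spec("ACGT", 0)  # HpyCH4IV, A^CGT
#' @export
digest_spec <- function(motif = "ACGT", cut_offset = 0L) {
  motif <- toupper(as.character(motif))
  if (nchar(motif) == 0L || grepl("[^ACGT]", motif))
    stop("`motif` must be a non-empty string over the A/C/G/T alphabet")
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset >= nchar(motif))
    stop("`cut_offset` must lie in [0, nchar(motif))")
  structure(list(motif = motif, cut_offset = cut_offset),
            class = "digest_spec")
}

#' In-silico restriction digestion
#'
#' Cuts a DNA sequence at every non-overlapping occurrence of the recognition
#' motif, scanned left to right (standard digestion semantics), and returns
#' the fragment lengths in order along the sequence. Fragment lengths always
#' sum to the input length.
#'
#' @param sequence A DNA string (character scalar or
#'   [Biostrings::DNAString-class]); alphabet A/C/G/T.
#' @param spec A [digest_spec()].
#' @return Integer vector of fragment lengths (bp), 5' to 3'.
#' @examples
#' rflp_digest("AAACGTAA", digest_spec("ACGT", 0))  # 3, 5
#' @export
rflp_digest <- function(sequence, spec = digest_spec()) {
  if (inherits(sequence, "DNAString") || inherits(sequence, "XString"))
    sequence <- as.character(sequence)
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || nchar(sequence) == 0L)
    stop("`sequence` must be a single non-empty DNA string")
  if (grepl("[^ACGT]", sequence))
    stop("`sequence` contains characters outside the A/C/G/T alphabet")
  stopifnot(inherits(spec, "digest_spec"))

  hits <- Biostrings::matchPattern(spec$motif, Biostrings::DNAString(sequence))
  starts <- Biostrings::start(hits)
  # greedy left-to-right: drop occurrences overlapping an accepted one
  keep <- integer(0)
  last_end <- 0L
  for (s in starts) {
    if (s > last_end) {
      keep <- c(keep, s)
      last_end <- s + nchar(spec$motif) - 1L
    }
  }
  cuts <- keep + spec$cut_offset            # cut after this position (1-based)
  n <- nchar(sequence)
  bounds <- unique(c(0L, cuts, n))          # a cut at the end adds no fragment
  as.integer(diff(bounds))
}

#' Allele model for PCR-RFLP genotyping
#'
#' Ties a biallelic variant to its digestion signature: the uncut allele
#' leaves the amplicon whole, the cut allele splits it into `cut_fragments`.
#' Defaults encode the NDUFC2 rs8875 assay: a 326-bp amplicon in which the
#' rare G allele creates the HpyCH4IV site yielding 215 + 111 bp, while the
#' common C allele does not.
#'
#' @param uncut_allele,cut_allele Single-letter allele labels (distinct).
#' @param amplicon_length Amplicon size in bp.
#' @param cut_fragments Fragment sizes produced by digestion of the cut
#'   allele; must sum to `amplicon_length`.
#' @return An object of class `allele_model`.
#' @export
allele_model <- function(uncut_allele = "C", cut_allele = "G",
                         amplicon_length = 326L,
                         cut_fragments = c(215L, 111L)) {
  uncut_allele <- as.character(uncut_allele)
  cut_allele <- as.character(cut_allele)
  if (identical(uncut_allele, cut_allele))
    stop("allele labels must be distinct")
  amplicon_length <- as.integer(amplicon_length)
  cut_fragments <- sort(as.integer(cut_fragments), decreasing = TRUE)
  if (any(cut_fragments <= 0L) || sum(cut_fragments) != amplicon_length)
    stop("`cut_fragments` must be positive and sum to `amplicon_length`")
  structure(list(uncut_allele = uncut_allele, cut_allele = cut_allele,
                 amplicon_length = amplicon_length,
                 cut_fragments = cut_fragments),
            class = "allele_model")
}

# multiset equality of band sizes within a per-band tolerance
.bands_match <- function(observed, expected, tolerance) {
  if (length(observed) != length(expected)) return(FALSE)
  all(abs(sort(observed) - sort(expected)) <= tolerance)
}

#' Call a diploid genotype from a gel band pattern
#'
#' Interprets observed restriction-fragment lengths under an [allele_model()]:
#' the intact amplicon alone is homozygous uncut, the cut fragments alone are
#' homozygous cut, and the union of both patterns is heterozygous. Bands are
#' matched within `tolerance_bp` (default 5 bp, typical agarose resolution).
#' Any other combination returns `NA` (a missing call), never an error, so
#' cohort assembly is robust to failed lanes.
#'
#' @param bands Numeric vector of observed fragment lengths (bp).
#' @param model An [allele_model()].
#' @param tolerance_bp Non-negative per-band matching tolerance in bp.
#' @return Two-letter genotype string with alleles sorted (e.g. "CG"), or
#'   `NA_character_` if the pattern matches no expected signature.
#' @examples
#' m <- allele_model()
#' genotype_from_bands(326, m)              # "CC"
#' genotype_from_bands(c(215, 111), m)      # "GG"
#' genotype_from_bands(c(326, 215, 111), m) # "CG"
#' @export
genotype_from_bands <- function(bands, model = allele_model(),
                                tolerance_bp = 5) {
  stopifnot(inherits(model, "allele_model"), tolerance_bp >= 0)
  bands <- sort(as.numeric(bands), decreasing = TRUE)
  if (length(bands) == 0L || any(bands <= 0)) return(NA_character_)
  uncut <- model$amplicon_length
  cut <- model$cut_fragments
  geno <- function(a, b) paste(sort(c(a, b)), collapse = "")
  if (.bands_match(bands, uncut, tolerance_bp))
    return(geno(model$uncut_allele, model$uncut_allele))
  if (.bands_match(bands, cut, tolerance_bp))
    return(geno(model$cut_allele, model$cut_allele))
  if (.bands_match(bands, c(uncut, cut), tolerance_bp))
    return(geno(model$uncut_allele, model$cut_allele))
  NA_character_
}

#' Default haplogroup-to-cluster map
#'
#' The four phylogenetically merged European mtDNA haplogroup clusters:
#' HV (haplogroups H and V), UK (U and K), JT (J and T), and IW (I, W, X
#' and N1).
#'
#' @return Named character vector mapping top-level haplogroup labels to
#'   cluster labels.
#' @export
haplogroup_cluster_map <- function() {
  c(H = "HV", V = "HV",
    U = "UK", K = "UK",
    J = "JT", T = "JT",
    I = "IW", W = "IW", X = "IW", N1 = "IW")
}

#' Assign fine haplogroups to merged clusters
#'
#' Sub-haplogroups (e.g. "H1a", "U5b") resolve by longest-prefix match on the
#' map's keys, so only top-level lineages need be listed. Labels with no
#' matching prefix (e.g. African L lineages, Asian M) yield `NA` with one
#' summary warning.
#'
#' @param haplogroup Character vector of haplogroup labels.
#' @param map Named character vector, as [haplogroup_cluster_map()].
#' @return Character vector of cluster labels, `NA` where unmapped.
#' @examples
#' cluster_haplogroup(c("K", "N1", "H1a", "L3"))
#' @export
cluster_haplogroup <- function(haplogroup, map = haplogroup_cluster_map()) {
  stopifnot(length(map) > 0, !is.null(names(map)))
  keys <- names(map)[order(nchar(names(map)), decreasing = TRUE)]
  hg <- toupper(trimws(as.character(haplogroup)))
  out <- rep(NA_character_, length(hg))
  for (key in keys) {
    hit <- is.na(out) & !is.na(hg) & startsWith(hg, key)
    out[hit] <- unname(map[[key]])
  }
  unmapped <- !is.na(hg) & hg != "" & is.na(out)
  if (any(unmapped))
    warning(sum(unmapped), " haplogroup label(s) outside the cluster map ",
            "set to missing: ",
            paste(unique(hg[unmapped]), collapse = ", "))
  out
}

#' Read amplicon sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning plain named
#' character strings suitable for [rflp_digest()].
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_amplicons <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(seqs), names(seqs))
}

#' Read observed band patterns from a TSV file
#'
#' Expects columns `sample_id` and `bands`, the latter comma-separated
#' fragment lengths in bp.
#'
#' @param path Path to a tab-separated file.
#' @return Named list of numeric band-length vectors, one per sample.
#' @export
read_band_patterns <- function(path) {
  d <- utils::read.delim(path, colClasses = "character",
                         comment.char = "#", check.names = FALSE)
  if (!all(c("sample_id", "bands") %in% names(d)))
    stop("band-pattern file needs `sample_id` and `bands` columns")
  out <- lapply(strsplit(d$bands, ","), function(x) as.numeric(trimws(x)))
  stats::setNames(out, d$sample_id)
}
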