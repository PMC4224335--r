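test_that("digestion cuts at motif sites and partitions the sequence", {
  expect_equal(rflp_digest("AAACGTAA", digest_spec("ACGT", 0)), c(3L, 5L))
  expect_equal(rflp_digest("AAAA"), 4L)
  expect_error(rflp_digest("AANCGT"), "alphabet")
  expect_error(digest_spec("ACGT", 4), "cut_offset")
})

test_that("digestion matches a brute-force scan on planted-site sequences", {
  for (seed in 1:10) {
    left <- random_sitefree_dna(18, seed)
    mid <- random_sitefree_dna(20, seed + 100)
    right <- random_sitefree_dna(14, seed + 200)
    seq <- paste0(left, "ACGT", mid, "ACGT", right)
    frags <- rflp_digest(seq, digest_spec("ACGT", 0))
    # independent oracle: locate sites by a plain string scan and split
    sites <- gregexpr("ACGT", seq, fixed = TRUE)[[1]]
    cuts <- sites  # cut after the first base of each site (offset 0)
    expect_equal(frags, diff(c(0L, as.integer(cuts), nchar(seq))))
    expect_length(frags, 3L)
    expect_equal(sum(frags), nchar(seq))
  }
})

test_that("fragment lengths always sum to the sequence length", {
  set.seed(11)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(10:120, 1),
                      replace = TRUE), collapse = "")
    off <- sample(0:3, 1)
    expect_equal(sum(rflp_digest(s, digest_spec("ACGT", off))), nchar(s))
  }
})

test_that("digestion of a palindromic motif is strand-symmetric", {
  revcomp <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  set.seed(23)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
               collapse = "")
    # ACGT equals its reverse complement, so site positions mirror and the
    # fragment multisets coincide (cut in the middle keeps symmetry exact)
    spec <- digest_spec("ACGT", 1)
    expect_equal(sort(rflp_digest(s, spec)),
                 sort(rflp_digest(revcomp(s), spec)))
  }
})

test_that("band patterns call the three rs8875 genotypes", {
  m <- allele_model()
  expect_equal(genotype_from_bands(326, m), "CC")
  expect_equal(genotype_from_bands(c(215, 111), m), "GG")
  expect_equal(genotype_from_bands(c(326, 215, 111), m), "CG")
  # gel sizing slop within the 5-bp default tolerance still calls
  expect_equal(genotype_from_bands(c(323, 218, 108), m), "CG")
  # anything else is a missing call, not an error
  expect_true(is.na(genotype_from_bands(c(326, 215), m)))
  expect_true(is.na(genotype_from_bands(c(400), m)))
  # slop beyond the tolerance no longer matches
  expect_true(is.na(genotype_from_bands(c(318, 215, 111), m)))
  expect_equal(genotype_from_bands(c(326, 215, 111), m, tolerance_bp = 0),
               "CG")
})

test_that("digest + band-calling round-trip recovers planted genotypes", {
  spec <- digest_spec("ACGT", 0)
  left <- random_sitefree_dna(214, 5)
  right <- random_sitefree_dna(108, 6)
  cut_amp <- paste0(left, "ACGT", right)     # 326 bp, one site -> 215 + 111
  uncut_amp <- paste0(left, "AGCT", right)   # site destroyed
  expect_equal(rflp_digest(cut_amp, spec), c(215L, 111L))
  expect_equal(rflp_digest(uncut_amp, spec), 326L)
  m <- allele_model()
  call2 <- function(a1, a2)
    genotype_from_bands(unique(c(rflp_digest(a1, spec),
                                 rflp_digest(a2, spec))), m)
  expect_equal(call2(uncut_amp, uncut_amp), "CC")
  expect_equal(call2(cut_amp, cut_amp), "GG")
  expect_equal(call2(uncut_amp, cut_amp), "CG")
})

test_that("haplogroups map to the four clusters by longest prefix", {
  expect_equal(cluster_haplogroup("K"), "UK")
  expect_equal(cluster_haplogroup("N1"), "IW")
  expect_equal(cluster_haplogroup("H1a"), "HV")
  expect_equal(cluster_haplogroup(c("U5b", "J1c", "X2", "W6", "V7", "T2b")),
               c("UK", "JT", "IW", "IW", "HV", "JT"))
  expect_warning(res <- cluster_haplogroup(c("L3", "M", "H")), "cluster map")
  expect_equal(res, c(NA, NA, "HV"))
  expect_setequal(unique(haplogroup_cluster_map()),
                  c("HV", "UK", "JT", "IW"))
})
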