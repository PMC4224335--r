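# shared fixture builders; everything is generated in code at test time

# random cohort over a clusters-x-genotypes grid with independent statuses
random_cohort <- function(n, seed, clusters = c("HV", "UK", "JT", "IW"),
                          genotypes = c("CC", "CG", "GG"),
                          case_prob = 0.5) {
  set.seed(seed)
  as_cohort(data.frame(
    sample_id = sprintf("R%05d", seq_len(n)),
    status = rbinom(n, 1L, case_prob),
    sex = sample(c("M", "F"), n, replace = TRUE),
    age = round(rnorm(n, 65, 8), 1),
    cluster = sample(clusters, n, replace = TRUE),
    genotype = sample(genotypes, n, replace = TRUE),
    stringsAsFactors = FALSE))
}

# random count table guaranteed non-degenerate in every stratum
random_count_table <- function(seed, clusters = c("HV", "UK"),
                               genotypes = c("CC", "CG")) {
  set.seed(seed)
  grid <- expand.grid(cluster = clusters, genotype = genotypes,
                      stringsAsFactors = FALSE)
  n_total <- sample(5:40, nrow(grid), replace = TRUE)
  n_cases <- vapply(n_total, function(n) sample.int(n - 1L, 1L), integer(1))
  data.frame(stratum = paste(grid$cluster, grid$genotype, sep = "_"),
             n_cases = n_cases, n_total = n_total,
             stringsAsFactors = FALSE)
}

# random DNA string with no ACGT site, by rejection on a site-free alphabet
random_sitefree_dna <- function(n, seed) {
  set.seed(seed)
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
               collapse = "")
    if (!grepl("ACGT", s, fixed = TRUE)) return(s)
  }
}

# independent textbook G computation: explicit double loop, no shared code
g_oracle <- function(O) {
  rs <- rowSums(O); cs <- colSums(O); N <- sum(O)
  G <- 0
  for (i in seq_len(nrow(O))) for (j in seq_len(ncol(O))) {
    if (O[i, j] > 0) {
      E <- rs[i] * cs[j] / N
      G <- G + O[i, j] * log(O[i, j] / E)
    }
  }
  2 * G
}

# brute-force q-value oracle: min over thresholds t >= p_i of pi0*t*m/#{p<=t}
q_oracle <- function(p, pi0) {
  m <- length(p)
  vapply(p, function(pi) {
    ts <- p[p >= pi]
    min(1, min(vapply(ts, function(t) pi0 * t * m / sum(p <= t), numeric(1))))
  }, numeric(1))
}
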