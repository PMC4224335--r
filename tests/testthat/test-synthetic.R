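test_that("expand_counts then stratify is the identity on count tables", {
  for (s in 1:8) {
    ct <- random_count_table(seed = s)
    st <- stratify(expand_counts(ct))
    ct <- ct[order(ct$stratum), ]
    expect_equal(st$stratum, ct$stratum)
    expect_equal(st$n_cases, ct$n_cases)
    expect_equal(st$n_total, ct$n_total)
  }
  expect_error(expand_counts(data.frame()), "column|empty")
  bad <- data.frame(stratum = "HV_CC", n_cases = 5, n_total = 3)
  expect_error(expand_counts(bad), "n_total")
})

test_that("the reference count fixture expands to the full cohort", {
  coh <- expand_counts(load_fixture("table2"))
  expect_equal(nrow(coh), 1477L)
  expect_equal(sum(coh$status), 1118L)
  # deterministic: same expansion twice
  expect_identical(coh, expand_counts(load_fixture("table2")))
})

test_that("population mode hits the expected case fraction", {
  spec <- simulation_spec(stratum_freq = c(HV_CC = 1), baseline_odds = 1,
                          mode = "population", N = 10000)
  coh <- simulate_cohort(spec, seed = 19)
  expect_equal(nrow(coh), 10000L)
  expect_lt(abs(mean(coh$status) - 0.5), 0.02)
})

test_that("null model gives matching stratum distributions by status", {
  fails <- 0
  for (s in 1:100) {
    spec <- simulation_spec(n_cases = 400, n_controls = 400)
    coh <- simulate_cohort(spec, seed = 5000 + s)
    tab <- table(paste(coh$cluster, coh$genotype, sep = "_"), coh$status)
    keep <- rowSums(tab) > 0
    p <- suppressWarnings(chisq.test(tab[keep, ]))$p.value
    if (p <= 0.001) fails <- fails + 1
  }
  expect_lte(fails, 1)
})

test_that("case-control mode reproduces the design margins and strata", {
  spec <- simulation_spec()  # defaults: 12 strata, 1118 / 359
  coh <- simulate_cohort(spec, seed = 23)
  st <- stratify(coh)
  expect_equal(nrow(st), 12L)
  expect_equal(attr(st, "n_cases"), 1118L)
  expect_equal(attr(st, "n_total"), 1477L)
  # deterministic given seed
  expect_identical(as.data.frame(simulate_cohort(spec, seed = 23)),
                   as.data.frame(coh))
  expect_false(identical(as.data.frame(simulate_cohort(spec, seed = 24)),
                         as.data.frame(coh)))
})

test_that("ages are status-conditional and sexes near balanced", {
  coh <- simulate_cohort(simulation_spec(n_cases = 4000, n_controls = 4000),
                         seed = 31)
  expect_lt(abs(mean(coh$age[coh$status == 1]) - 65.8), 0.5)
  expect_lt(abs(mean(coh$age[coh$status == 0]) - 69.7), 0.5)
  expect_lt(abs(mean(coh$sex == "M") - 0.5), 0.05)
})

test_that("simulation spec validates frequencies and odds ratios", {
  expect_error(simulation_spec(stratum_freq = c(A_CC = 0.6, B_CC = 0.6)),
               "sum to 1")
  expect_error(simulation_spec(stratum_freq = c(A_CC = 0.5, B_CC = 0.5),
                               odds_ratios = c(A_CC = 1, C_CC = 2)),
               "names")
  expect_error(simulation_spec(stratum_freq = c(A_CC = 0.5, B_CC = 0.5),
                               odds_ratios = c(A_CC = 1, B_CC = -2)),
               "positive")
})

test_that("fitting simulated cohorts recovers the generating log odds", {
  # two-stratum design, true OR 2; mean log-OR error across seeds is small
  spec <- simulation_spec(stratum_freq = c(HV_CC = 0.5, UK_CG = 0.5),
                          baseline_odds = 1,
                          odds_ratios = c(HV_CC = 1, UK_CG = 2),
                          n_cases = 1000, n_controls = 1000)
  est <- vapply(1:200, function(s) {
    coh <- simulate_cohort(spec, seed = 100 + s)
    fit <- attr(stratum_odds_ratios(coh, reference = "HV_CC"), "fit")
    unname(fit$coefficients["UK_CG"])
  }, numeric(1))
  expect_lt(abs(mean(est) - log(2)), 0.15)
})
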