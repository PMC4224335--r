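test_that("dummy coding yields k-1 indicators against the reference", {
  coh <- expand_counts(load_fixture("table2"))
  d <- encode_design(coh, reference = "HV_CC")
  expect_equal(ncol(d$X), 12L)  # intercept + 11 indicators
  expect_equal(colnames(d$X)[1], "(Intercept)")
  expect_false("HV_CC" %in% colnames(d$X))
  # reference rows carry all-zero indicators
  ref_rows <- coh$cluster == "HV" & coh$genotype == "CC"
  expect_true(all(d$X[ref_rows, -1] == 0))
  # indicator column sums equal the stratum sizes
  st <- stratify(coh)
  for (s in setdiff(st$stratum, "HV_CC"))
    expect_equal(sum(d$X[, s]), st$n_total[st$stratum == s])
  expect_error(encode_design(coh, reference = "ZZ_XX"), "absent")

  two <- random_cohort(50, seed = 1, clusters = "HV",
                       genotypes = c("CC", "CG"))
  expect_equal(ncol(encode_design(two, reference = "HV_CC")$X), 2L)
})

test_that("intercept-only fit on a balanced response is the null model", {
  y <- rep(c(0, 1), 50)
  fit <- fit_logistic(matrix(1, 100, 1, dimnames = list(NULL, "(Intercept)")),
                      y)
  expect_equal(unname(fit$coefficients), 0, tolerance = 1e-9)
  expect_equal(unname(fit$odds_ratio), 1, tolerance = 1e-9)
  expect_true(fit$converged)
})

test_that("single binary predictor recovers the 2x2 closed form", {
  set.seed(55)
  for (i in 1:10) {
    cell <- sample(10:80, 4)  # a, b, c, d all positive
    a <- cell[1]; b <- cell[2]; c_ <- cell[3]; d <- cell[4]
    x <- c(rep(1, a + b), rep(0, c_ + d))
    y <- c(rep(1, a), rep(0, b), rep(1, c_), rep(0, d))
    X <- cbind("(Intercept)" = 1, exposed = x)
    fit <- fit_logistic(X, y)
    expect_equal(unname(fit$coefficients["exposed"]),
                 log(a * d / (b * c_)), tolerance = 1e-6)
    expect_equal(unname(fit$se["exposed"]),
                 sqrt(1 / a + 1 / b + 1 / c_ + 1 / d), tolerance = 1e-6)
  }
  # the 2x2 drawn from the HV_CC / HV_CG rows of the reference table
  x <- c(rep(1, 236), rep(0, 265))
  y <- c(rep(1, 184), rep(0, 52), rep(1, 183), rep(0, 82))
  fit <- fit_logistic(cbind(1, x), y)
  expect_equal(unname(fit$odds_ratio[2]), (184 * 82) / (52 * 183),
               tolerance = 1e-6)
})

test_that("IRLS agrees with the reference GLM fitter", {
  coh <- random_cohort(500, seed = 12)
  d <- encode_design(coh, reference = "HV_CC", covariates = c("sex", "age"))
  fit <- fit_logistic(d$X, d$y)
  ref <- glm.fit(d$X, d$y, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-8)
  se_ref <- sqrt(diag(chol2inv(chol(
    t(d$X * ref$weights) %*% d$X))))
  expect_equal(unname(fit$se), se_ref, tolerance = 1e-6)
})

test_that("saturated stratum model reproduces observed proportions", {
  coh <- expand_counts(load_fixture("table2"))
  d <- encode_design(coh, reference = "HV_CC")
  fit <- fit_logistic(d$X, d$y)
  st <- stratify(coh)
  mu <- plogis(drop(d$X %*% fit$coefficients))
  stratum <- paste(coh$cluster, coh$genotype, sep = "_")
  fitted_by_stratum <- tapply(mu, stratum, mean)
  expect_equal(as.numeric(fitted_by_stratum[st$stratum]),
               st$proportion, tolerance = 1e-8)
})

test_that("the headline stratum odds ratio matches the published contrast", {
  coh <- expand_counts(load_fixture("table2"))
  orr <- stratum_odds_ratios(coh, reference = "HV_CC")
  hv_cg <- orr[orr$term == "HV_CG", ]
  expect_equal(hv_cg$odds_ratio, 1.58, tolerance = 0.01)
  expect_true(hv_cg$ci_lower < hv_cg$odds_ratio &
                hv_cg$odds_ratio < hv_cg$ci_upper)
  expect_equal(nrow(orr), 12L)
})

test_that("rank deficiency and separation are reported", {
  X <- cbind(1, c(0, 0, 1, 1), c(0, 0, 2, 2))
  colnames(X) <- c("(Intercept)", "a", "b")
  expect_error(fit_logistic(X, c(0, 1, 0, 1)), "rank deficient")
  # perfectly separated predictor
  x <- c(rep(0, 20), rep(1, 20))
  y <- x
  expect_warning(fit <- fit_logistic(cbind(1, x), y), "separation")
  expect_false(fit$converged)
})
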