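test_that("known generating coefficients are recovered within 3 SE", {
  set.seed(47)
  n <- 20000
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.5)
  beta <- c(-2, 0.8, -0.5)
  y <- rbinom(n, 1, plogis(beta[1] + beta[2] * x1 + beta[3] * x2))
  fit <- fit_weighted_logistic(data.frame(x1 = x1, x2 = x2), y)
  se <- sqrt(diag(vcov(fit$fit)))
  expect_true(all(abs(coef(fit) - beta) < 3 * se))
  expect_true(fit$converged)
  expect_false(fit$separation)
})

test_that("a covariate unrelated to the outcome gets a near-zero coefficient", {
  set.seed(53)
  n <- 8000
  x <- rnorm(n)
  junk <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + x))
  fit <- fit_weighted_logistic(data.frame(x = x, junk = junk), y)
  se <- sqrt(diag(vcov(fit$fit)))
  expect_lt(abs(coef(fit)[["junk"]]), 3 * se[["junk"]])
})

test_that("likelihood scale invariance: doubling all weights changes nothing", {
  set.seed(59)
  n <- 500
  x <- rnorm(n); y <- rbinom(n, 1, plogis(x))
  w <- runif(n, 0.5, 2)
  f1 <- fit_weighted_logistic(data.frame(x = x), y, w)
  f2 <- fit_weighted_logistic(data.frame(x = x), y, 2 * w)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-9)
  expect_equal(f1$fitted, f2$fitted, tolerance = 1e-9)
})

test_that("the score identity holds: weighted mean risk equals event rate", {
  set.seed(61)
  n <- 1000
  x <- rnorm(n); y <- rbinom(n, 1, plogis(-0.5 + x))
  w <- runif(n, 0.5, 2)
  fit <- fit_weighted_logistic(data.frame(x = x), y, w)
  expect_true(all(fit$fitted > 0 & fit$fitted < 1))
  expect_equal(weighted.mean(fit$fitted, w), weighted.mean(y, w),
               tolerance = 1e-8)
})

test_that("row order does not affect the fit", {
  set.seed(67)
  n <- 400
  dat <- data.frame(x = rnorm(n), z = rnorm(n))
  y <- rbinom(n, 1, plogis(dat$x))
  w <- runif(n, 0.5, 2)
  perm <- sample(n)
  f1 <- fit_weighted_logistic(dat, y, w)
  f2 <- fit_weighted_logistic(dat[perm, ], y[perm], w[perm])
  expect_equal(coef(f1), coef(f2), tolerance = 1e-9)
})

test_that("degenerate designs and outcomes are rejected", {
  x <- rnorm(50); y <- rbinom(50, 1, 0.5)
  expect_error(fit_weighted_logistic(data.frame(a = x, b = 2 * x), y),
               "rank deficient")
  expect_error(fit_weighted_logistic(data.frame(x = x), rep(1, 50)),
               "at least one")
})

test_that("separation is flagged rather than silently truncated", {
  x <- c(rep(0, 20), rep(1, 20))
  y <- x
  fit <- suppressWarnings(fit_weighted_logistic(data.frame(x = x), y))
  expect_true(fit$separation)
})

test_that("the common sample excludes exactly the right participants", {
  cohort <- tiny_cohort(n = 10)
  d <- toy_dictionary()
  dm <- code_deficits(cohort, d)
  fi_loo <- frailty_index_excluding(dm, names(d), "alb",
                                    completeness_min = 0.5)$value
  expect_true(all(common_sample_mask(cohort, "alb", fi_loo)))  # no missingness
  # missing focal biomarker: excluded everywhere
  cohort2 <- cohort; cohort2$alb[3] <- NA
  fi2 <- frailty_index_excluding(code_deficits(cohort2, d), names(d), "alb",
                                 completeness_min = 0.5)$value
  m <- common_sample_mask(cohort2, "alb", fi2)
  expect_false(m[3]); expect_true(all(m[-3]))
  # undefined leave-one-out FI (completeness below threshold): excluded
  cohort3 <- cohort
  cohort3$grip[5] <- NA; cohort3$walk[5] <- NA
  fi3 <- frailty_index_excluding(code_deficits(cohort3, d), names(d),
                                 "alb")$value  # 0 of 2 considered items
  m3 <- common_sample_mask(cohort3, "alb", fi3)
  expect_false(m3[5])
  expect_error(common_sample_mask(cohort, "alb", rep(NA_real_, 10)),
               "degenerate sample")
})

test_that("the four nested models share a sample and nest in likelihood", {
  d <- default_dictionary()
  cohort <- simulate_default_cohort(n = 2500, seed = 71)
  fit <- fit_biomarker_models(cohort, d, "Albumin")
  lls <- vapply(fit$models, `[[`, numeric(1), "loglik")
  ns <- vapply(fit$models, `[[`, numeric(1), "n_used")
  expect_true(all(ns == fit$n_used))
  expect_gte(lls[["M4"]], lls[["M3"]])
  expect_gte(lls[["M4"]], lls[["M2"]])
  expect_gte(lls[["M2"]], lls[["M1"]])
  expect_gte(lls[["M3"]], lls[["M1"]])
  # M4's design is M3's plus the biomarker column
  cf <- coef(fit)
  expect_setequal(colnames(cf), c("(Intercept)", "age", "male", "biomarker", "fi"))
  expect_true(is.na(cf["M1", "fi"]) && is.na(cf["M1", "biomarker"]))
  expect_true(all(!is.na(cf["M4", ])))
  # blood sample restriction: block-missing blood panels are excluded
  expect_lt(fit$n_used, nrow(cohort))
})

test_that("an uninformative focal biomarker leaves the age-sex AUC unchanged", {
  d0 <- fi_dictionary(default_dictionary()[dictionary_items(default_dictionary(),
                                                            "blood")[1:5]])
  cfg <- cohort_config(n = 8000, seed = 73, latent_loading = 0, age_slope = 0)
  cohort <- simulate_cohort(cfg, d0)
  fit <- fit_biomarker_models(cohort, d0, names(d0)[1])
  expect_equal(fit$aucs$M2$auc, fit$aucs$M1$auc, tolerance = 0.02)
  expect_gt(fit$comparisons$M2vsM1$p_value, 0.001)
})
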