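test_that("weighted AUC handles separation, ties and degenerate outcomes", {
  y <- c(1, 1, 0, 0)
  expect_equal(auc_weighted(c(4, 3, 2, 1), y)$auc, 1)   # perfect separation
  expect_equal(auc_weighted(rep(2, 4), y)$auc, 0.5)     # all ties
  expect_error(auc_weighted(1:4, rep(1, 4)), "undefined AUC")
  expect_error(auc_weighted(1:3, c(1, 0, 0), c(1, -1, 1)), "positive")
  expect_error(auc_weighted(1:3, c(1, 0, 2)), "binary")
})

test_that("an 8-observation weighted instance with ties matches the double sum", {
  s <- c(1, 2, 2, 3, 1, 2, 4, 4)
  y <- c(1, 1, 0, 1, 0, 0, 1, 0)
  w <- c(0.5, 2, 1, 1.5, 3, 0.7, 1, 2.2)
  expect_equal(auc_weighted(s, y, w)$auc, oracle_auc_double_sum(s, y, w))
})

test_that("rank-based AUC equals the explicit double sum on random instances", {
  set.seed(17)
  for (rep in 1:300) {
    inst <- random_roc_instance()
    expect_equal(
      placement_components(inst$scores, inst$outcome, inst$weights)$auc,
      oracle_auc_double_sum(inst$scores, inst$outcome, inst$weights))
  }
})

test_that("placements match direct enumeration and average to the AUC", {
  set.seed(19)
  for (rep in 1:50) {
    inst <- random_roc_instance()
    pc <- placement_components(inst$scores, inst$outcome, inst$weights)
    ref <- oracle_placements(inst$scores, inst$outcome, inst$weights)
    expect_equal(pc$v_event, ref$v_event)
    expect_equal(pc$v_nonevent, ref$v_nonevent)
    expect_equal(weighted.mean(pc$v_event, pc$w_event), pc$auc)
    expect_equal(weighted.mean(pc$v_nonevent, pc$w_nonevent), pc$auc)
  }
  # perfect separation: every placement is 1
  pc <- placement_components(c(5, 6, 1, 2), c(1, 1, 0, 0))
  expect_equal(pc$v_event, c(1, 1))
  expect_equal(pc$v_nonevent, c(1, 1))
})

test_that("AUC and the equality test obey the symmetry invariants", {
  set.seed(23)
  n <- 120
  y <- rbinom(n, 1, 0.4)
  z <- rnorm(n)
  s1 <- round(z + y, 1)           # rounding forces ties
  s2 <- round(0.5 * z + y + rnorm(n), 1)
  w <- runif(n, 0.5, 2)
  a <- auc_weighted(s1, y, w)$auc
  # strictly increasing transform leaves everything unchanged
  expect_equal(auc_weighted(exp(2 * s1), y, w)$auc, a)
  t1 <- test_auc_equality(s1, s2, y, w)
  t2 <- test_auc_equality(exp(s1), exp(s2), y, w)
  expect_equal(t1$chi2, t2$chi2)
  # complement symmetry
  expect_equal(auc_weighted(-s1, y, w)$auc, 1 - a)
  t3 <- test_auc_equality(-s1, -s2, y, w)
  expect_equal(t3$chi2, t1$chi2)
  # weight homogeneity
  expect_equal(auc_weighted(s1, y, 7 * w)$auc, a)
  t4 <- test_auc_equality(s1, s2, y, 7 * w)
  expect_equal(t4$chi2, t1$chi2)
})

test_that("the covariance matches its definitional computation", {
  set.seed(29)
  for (rep in 1:30) {
    n <- sample(6:12, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.5))
    S <- cbind(round(rnorm(n), 1), round(rnorm(n), 1))
    w <- runif(n, 0.3, 2.5)
    expect_equal(unname(auc_covariance(S, y, w)), oracle_auc_cov(S, y, w))
    # unit weights: classical placement variance, k = 1
    expect_equal(unname(auc_covariance(S[, 1, drop = FALSE], y)),
                 oracle_auc_cov(S[, 1, drop = FALSE], y))
  }
})

test_that("covariance is symmetric PSD and collapses for identical scores", {
  set.seed(31)
  n <- 200
  y <- rbinom(n, 1, 0.3)
  z <- rnorm(n)
  S <- cbind(z + y, z + y, 0.3 * z + rnorm(n))
  V <- auc_covariance(S, y)
  expect_equal(V, t(V))
  expect_true(all(eigen(V, symmetric = TRUE, only.values = TRUE)$values > -1e-12))
  # identical columns: zero variance of the difference
  expect_equal(V[1, 1] + V[2, 2] - 2 * V[1, 2], 0, tolerance = 1e-14)
  tt <- test_auc_equality(S[, 1], S[, 2], y)
  expect_equal(tt$chi2, 0)
  expect_equal(tt$p_value, 1)
})

test_that("zero variance with unequal AUCs is a degenerate comparison", {
  expect_error(test_auc_equality(c(1, 0), c(0, 1), c(1, 0)),
               "degenerate comparison")
})

test_that("unit-weight results agree with pROC's DeLong implementation", {
  skip_if_not_installed("pROC")
  set.seed(37)
  n <- 250
  y <- rbinom(n, 1, 0.35)
  z <- rnorm(n)
  s1 <- z + 1.2 * y + rnorm(n)
  s2 <- 0.8 * z + y + rnorm(n)
  a1 <- auc_weighted(s1, y)
  r1 <- pROC::roc(y, s1, quiet = TRUE, direction = "<")
  expect_equal(a1$auc, as.numeric(pROC::auc(r1)))
  expect_equal(a1$se^2, pROC::var(r1, method = "delong"), tolerance = 1e-12)
  r2 <- pROC::roc(y, s2, quiet = TRUE, direction = "<")
  ours <- test_auc_equality(s1, s2, y)
  theirs <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
  # pROC reports a z statistic; square it for the chi-square form
  expect_equal(ours$chi2, unname(theirs$statistic)^2, tolerance = 1e-10)
  expect_equal(ours$p_value, theirs$p.value, tolerance = 1e-10)
})

test_that("the joint k-model test reduces to the pairwise test at k = 2", {
  set.seed(41)
  n <- 150
  y <- rbinom(n, 1, 0.4)
  S <- cbind(rnorm(n) + y, rnorm(n) + 0.5 * y)
  joint <- test_auc_equality_joint(S, y)
  pair <- test_auc_equality(S[, 1], S[, 2], y)
  expect_equal(joint$chi2, pair$chi2)
  expect_equal(joint$df, 1L)
  expect_equal(joint$p_value, pair$p_value)
})

test_that("confidence intervals stay inside [0,1] on both scales", {
  y <- c(1, 1, 1, 0, 0, 0)
  a <- auc_weighted(c(4, 5, 6, 1, 2, 3), y)           # AUC 1, tiny n
  expect_true(all(a$ci95 >= 0 & a$ci95 <= 1))
  set.seed(43)
  yy <- rbinom(80, 1, 0.4)
  ss <- rnorm(80) + yy
  al <- auc_weighted(ss, yy, ci_scale = "logit")
  expect_true(all(al$ci95 > 0 & al$ci95 < 1))
  expect_lt(al$ci95[1], al$auc); expect_gt(al$ci95[2], al$auc)
})
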