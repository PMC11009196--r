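# Nested weighted logistic mortality models.
#
# Per focal biomarker, four models are fitted on one common complete-case
# sample: M1 age + sex; M2 age + sex + biomarker; M3 age + sex +
# leave-one-out FI; M4 age + sex + biomarker + leave-one-out FI. The FI in
# M3/M4 excludes the focal biomarker to avoid collinearity (a 22-item blood
# FI or 46-item examination FI under the default catalogue). The biomarker
# enters on its raw scale as a single linear term. Analytic weights scale
# the Bernoulli likelihood; discrimination (AUC), not coefficient
# inference, is the downstream surface.

#' Weighted logistic fit
#'
#' Maximizes the weight-multiplied Bernoulli log-likelihood via IRLS
#' (through [stats::glm()] with a quasibinomial family, which accepts
#' non-integer analytic weights and returns the identical point estimates).
#' Separation or non-convergence is flagged, not silently truncated.
#'
#' @param design Data frame or matrix of predictor columns (no intercept
#'   column; one is added).
#' @param outcome Binary 0/1 outcome.
#' @param weights Strictly positive analytic weights.
#' @param epsilon IRLS convergence tolerance on the relative deviance
#'   change.
#' @param maxit Maximum IRLS iterations.
#' @return A list of class `"wlogit"`: `coefficients`, `fitted` (predicted
#'   risks), `loglik` (weighted Bernoulli log-likelihood), `n_used`,
#'   `converged`, `separation`, and the `glm` object in `$fit`.
#' @examples
#' x <- rnorm(500); y <- rbinom(500, 1, plogis(-1 + x))
#' coef(fit_weighted_logistic(data.frame(x = x), y))
#' @export
fit_weighted_logistic <- function(design, outcome, weights = rep(1, length(outcome)),
                                  epsilon = 1e-8, maxit = 100L) {
  design <- as.data.frame(design)
  if (nrow(design) != length(outcome) || length(weights) != length(outcome))
    stop("design, outcome and weights must be aligned", call. = FALSE)
  if (any(weights <= 0)) stop("weights must be strictly positive", call. = FALSE)
  if (!any(outcome == 1) || !any(outcome == 0))
    stop("need at least one event and one non-event", call. = FALSE)
  X <- stats::model.matrix(~ ., data = design)
  if (qr(X)$rank < ncol(X))
    stop("design error: predictor matrix is rank deficient", call. = FALSE)
  dat <- cbind(.y = outcome, design)
  fit <- stats::glm(.y ~ ., family = stats::quasibinomial(), data = dat,
                    weights = weights,
                    control = stats::glm.control(epsilon = epsilon,
                                                 maxit = maxit))
  p <- stats::fitted(fit)
  separation <- any(abs(stats::coef(fit)) > 50) || any(p < 1e-10 | p > 1 - 1e-10)
  ll <- sum(weights * (outcome * log(pmax(p, 1e-300)) +
                         (1 - outcome) * log(pmax(1 - p, 1e-300))))
  structure(list(coefficients = stats::coef(fit), fitted = as.numeric(p),
                 loglik = ll, n_used = length(outcome),
                 converged = fit$converged, separation = separation,
                 fit = fit),
            class = "wlogit")
}

#' @export
coef.wlogit <- function(object, ...) object$coefficients

#' @export
print.wlogit <- function(x, ...) {
  cat("Weighted logistic model, n =", x$n_used,
      if (!x$converged) "(NOT converged)" else "", "\n")
  print(round(x$coefficients, 4))
  if (x$separation) cat("warning: possible separation detected\n")
  invisible(x)
}

#' Common complete-case sample for one biomarker's four models
#'
#' Returns the participants usable by all four nested models for a focal
#' biomarker: non-missing age, sex, weight, death indicator and focal
#' biomarker value, and a defined leave-one-out FI (80% completeness on the
#' reduced item set). All four models are then fitted on exactly this set
#' so their AUCs are directly comparable.
#'
#' @param cohort Cohort data frame with demographics and raw biomarkers.
#' @param biomarker Focal biomarker column name.
#' @param fi_loo Leave-one-out FI values aligned with `cohort` rows (from
#'   [frailty_index_excluding()]).
#' @return Logical row mask.
#' @export
common_sample_mask <- function(cohort, biomarker, fi_loo) {
  if (length(fi_loo) != nrow(cohort))
    stop("fi_loo must align with cohort rows", call. = FALSE)
  mask <- !is.na(cohort$age) & !is.na(cohort$sex) & !is.na(cohort$weight) &
    !is.na(cohort$died) & !is.na(cohort[[biomarker]]) & !is.na(fi_loo)
  if (!any(mask))
    stop("degenerate sample: no participant has complete data for '",
         biomarker, "'", call. = FALSE)
  mask
}

#' Fit the four nested mortality models for one biomarker
#'
#' The core model-family fit: builds the common complete-case sample, the
#' leave-one-out FI for the biomarker's panel, and fits the four weighted
#' logistic models (age+sex; +biomarker; +FI; +both) on that identical
#' sample, then computes their weighted AUCs and the four pairwise
#' DeLong-type contrasts (M2 vs M1, M3 vs M1, M4 vs M2, M4 vs M3).
#'
#' @param cohort An `fi_cohort` (or any data frame with `age`, `sex`,
#'   `weight`, `died` and raw biomarker columns).
#' @param dictionary An [fi_dictionary()].
#' @param biomarker Focal biomarker name (must be a dictionary item).
#' @param deficits Optional precomputed [code_deficits()] matrix (saves
#'   recoding when fitting many biomarkers).
#' @return An object of class `"fi_mortality_fit"` with elements
#'   `biomarker`, `panel`, `n_used`, `models` (list of M1-M4 [wlogit]
#'   fits), `aucs` (list of [auc_weighted()] results), `comparisons`
#'   (list of [test_auc_equality()] results), `sample_mask`.
#' @examples
#' d <- default_dictionary()
#' cohort <- simulate_default_cohort(n = 2000, seed = 5)
#' fit <- fit_biomarker_models(cohort, d, "Pulse")
#' fit
#' coef(fit)["M4", ]
#' @export
fit_biomarker_models <- function(cohort, dictionary, biomarker,
                                 deficits = NULL) {
  stopifnot(inherits(dictionary, "fi_dictionary"))
  if (!biomarker %in% names(dictionary))
    stop("'", biomarker, "' is not a dictionary item", call. = FALSE)
  panel <- dictionary[[biomarker]]$panel
  items <- dictionary_items(dictionary, panel)
  if (is.null(deficits)) deficits <- code_deficits(cohort, dictionary)
  fi_loo <- frailty_index_excluding(deficits, items, biomarker)$value
  mask <- common_sample_mask(cohort, biomarker, fi_loo)

  sub <- cohort[mask, , drop = FALSE]
  w <- sub$weight
  y <- sub$died
  base <- data.frame(age = sub$age, male = as.numeric(sub$sex == "male"))
  bm <- sub[[biomarker]]
  fi <- fi_loo[mask]
  designs <- list(
    M1 = base,
    M2 = cbind(base, biomarker = bm),
    M3 = cbind(base, fi = fi),
    M4 = cbind(base, biomarker = bm, fi = fi))
  models <- lapply(designs, fit_weighted_logistic, outcome = y, weights = w)
  scores <- vapply(models, `[[`, numeric(sum(mask)), "fitted")
  aucs <- lapply(seq_len(4), function(j) auc_weighted(scores[, j], y, w))
  names(aucs) <- names(designs)
  contrasts <- list(M2vsM1 = c("M2", "M1"), M3vsM1 = c("M3", "M1"),
                    M4vsM2 = c("M4", "M2"), M4vsM3 = c("M4", "M3"))
  comparisons <- lapply(contrasts, function(ct)
    test_auc_equality(scores[, ct[1]], scores[, ct[2]], y, w,
                      label_a = ct[1], label_b = ct[2]))
  structure(list(biomarker = biomarker, panel = panel,
                 n_used = sum(mask), models = models, aucs = aucs,
                 comparisons = comparisons, sample_mask = mask),
            class = "fi_mortality_fit")
}

#' @export
print.fi_mortality_fit <- function(x, digits = 3, ...) {
  cat("Four nested mortality models for '", x$biomarker, "' (",
      x$panel, " panel), n = ", x$n_used, "\n", sep = "")
  for (m in names(x$models)) {
    a <- x$aucs[[m]]
    cat(sprintf("  %s: AUC %.*f (%.*f-%.*f)\n", m, digits, a$auc,
                digits, a$ci95[1], digits, a$ci95[2]))
  }
  invisible(x)
}

#' @export
summary.fi_mortality_fit <- function(object, ...) {
  print(object, ...)
  cat("Pairwise AUC equality tests:\n")
  for (ct in names(object$comparisons)) {
    cmp <- object$comparisons[[ct]]
    cat(sprintf("  %s: diff %+0.4f, chi2 %.3g, p %.3g\n",
                ct, cmp$auc_a - cmp$auc_b, cmp$chi2, cmp$p_value))
  }
  invisible(object)
}

#' @export
coef.fi_mortality_fit <- function(object, ...) {
  nm <- unique(unlist(lapply(object$models, function(m) names(m$coefficients))))
  out <- matrix(NA_real_, nrow = 4, ncol = length(nm),
                dimnames = list(names(object$models), nm))
  for (m in names(object$models))
    out[m, names(object$models[[m]]$coefficients)] <-
      object$models[[m]]$coefficients
  out
}

#' @export
predict.fi_mortality_fit <- function(object, newdata = NULL, model = "M4", ...) {
  model <- match.arg(model, names(object$models))
  if (is.null(newdata)) return(object$models[[model]]$fitted)
  as.numeric(stats::predict(object$models[[model]]$fit, newdata = newdata,
                            type = "response"))
}
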