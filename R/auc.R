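# Weighted AUC and DeLong-type comparison of correlated ROC curves.
#
# The weighted AUC is the weighted Mann-Whitney statistic
#   AUC = sum_{i in events, j in non-events} w_i w_j psi(s_i, s_j) / (W1 W0),
# psi = 1 if s_i > s_j, 1/2 on ties, 0 otherwise. It is computed through
# per-observation placements (structural components): for an event, the
# weighted fraction of non-events it outranks (ties half-credited), and
# symmetrically for non-events. The weighted means of both placement
# vectors equal the AUC, and their empirical covariances scaled by Kish
# effective sample sizes give the DeLong-type covariance matrix for k
# correlated score vectors over the same sample. With unit weights this
# reduces exactly to the classical DeLong estimator.

#' Placement components of a weighted AUC
#'
#' @param scores Numeric risk scores (higher = more event-like).
#' @param outcome Binary 0/1 outcome (1 = event).
#' @param weights Strictly positive analytic weights.
#' @return A list with `v_event` (placements of events among non-events),
#'   `v_nonevent` (placements of non-events among events, oriented so its
#'   weighted mean is also the AUC), `auc`, and the weight sums `W1`, `W0`.
#' @seealso [auc_weighted()], [auc_covariance()]
#' @export
placement_components <- function(scores, outcome, weights = rep(1, length(scores))) {
  check_roc_inputs(scores, outcome, weights)
  is_event <- outcome == 1
  W1 <- sum(weights[is_event]); W0 <- sum(weights[!is_event])
  o <- order(scores)
  s <- scores[o]
  w1 <- ifelse(is_event[o], weights[o], 0)
  w0 <- ifelse(is_event[o], 0, weights[o])
  grp <- cumsum(c(TRUE, s[-1] != s[-length(s)]))
  g1 <- rowsum(w1, grp); g0 <- rowsum(w0, grp)
  below0 <- cumsum(g0) - g0            # non-event weight strictly below
  below1 <- cumsum(g1) - g1            # event weight strictly below
  ve_g <- (below0 + 0.5 * g0) / W0                 # for events at each value
  vn_g <- (W1 - below1 - 0.5 * g1) / W1            # event weight above + ties
  ve <- vn <- numeric(length(scores))
  ve[o] <- ve_g[grp]
  vn[o] <- vn_g[grp]
  auc <- sum(weights[is_event] * ve[is_event]) / W1
  list(v_event = ve[is_event], v_nonevent = vn[!is_event],
       w_event = weights[is_event], w_nonevent = weights[!is_event],
       auc = auc, W1 = W1, W0 = W0)
}

#' @noRd
check_roc_inputs <- function(scores, outcome, weights) {
  n <- length(scores)
  if (length(outcome) != n || length(weights) != n)
    stop("alignment error: scores, outcome and weights must have equal length",
         call. = FALSE)
  if (anyNA(scores) || anyNA(outcome) || anyNA(weights))
    stop("scores, outcome and weights must be complete (no NA)", call. = FALSE)
  if (!all(outcome %in% c(0, 1)))
    stop("outcome must be binary 0/1", call. = FALSE)
  if (any(weights <= 0)) stop("weights must be strictly positive", call. = FALSE)
  if (!any(outcome == 1) || !any(outcome == 0))
    stop("undefined AUC: need at least one event and one non-event",
         call. = FALSE)
  invisible(TRUE)
}

#' Weighted AUC with a DeLong-type confidence interval
#'
#' @inheritParams placement_components
#' @param conf_level Confidence level for the interval (default 0.95).
#' @param ci_scale `"auc"` for a Wald interval on the AUC scale truncated
#'   to \[0, 1\] (the default), or `"logit"` for an interval built on the
#'   logit scale and back-transformed.
#' @return A list of class `"auc_result"`: `auc`, `se`, `ci95`,
#'   `n_events`, `n_nonevents`.
#' @examples
#' set.seed(1)
#' y <- rbinom(200, 1, 0.3)
#' s <- y + rnorm(200)
#' auc_weighted(s, y)
#' @export
auc_weighted <- function(scores, outcome, weights = rep(1, length(scores)),
                         conf_level = 0.95, ci_scale = c("auc", "logit")) {
  ci_scale <- match.arg(ci_scale)
  pc <- placement_components(scores, outcome, weights)
  V <- auc_covariance(matrix(scores, ncol = 1), outcome, weights)
  se <- sqrt(V[1, 1])
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- if (ci_scale == "auc") {
    pmin(pmax(pc$auc + c(-1, 1) * z * se, 0), 1)
  } else {
    lg <- qlogis(pc$auc)
    se_lg <- se / (pc$auc * (1 - pc$auc))
    plogis(lg + c(-1, 1) * z * se_lg)
  }
  structure(list(auc = pc$auc, se = se, ci95 = ci,
                 n_events = sum(outcome == 1),
                 n_nonevents = sum(outcome == 0)),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, digits = 3, ...) {
  cat(sprintf("AUC %.*f (%d%% CI %.*f-%.*f), %d events / %d non-events\n",
              digits, x$auc, 95, digits, x$ci95[1], digits, x$ci95[2],
              x$n_events, x$n_nonevents))
  invisible(x)
}

#' DeLong-type covariance of k correlated weighted AUCs
#'
#' All score vectors must be computed on the same sample (same outcome and
#' weights). The covariance combines the weighted empirical covariances of
#' the event-side and non-event-side placements, each scaled by the Kish
#' effective number of events/non-events `(sum w)^2 / sum(w^2)`; under unit
#' weights this is exactly the classical DeLong estimator.
#'
#' @param score_sets A numeric matrix with one column per score vector (or
#'   a list of equal-length vectors).
#' @inheritParams placement_components
#' @return A symmetric k-by-k covariance matrix of the AUC estimates.
#' @export
auc_covariance <- function(score_sets, outcome, weights = NULL) {
  if (is.list(score_sets)) score_sets <- do.call(cbind, score_sets)
  score_sets <- as.matrix(score_sets)
  if (is.null(weights)) weights <- rep(1, nrow(score_sets))
  if (nrow(score_sets) != length(outcome))
    stop("alignment error: score vectors and outcome differ in length",
         call. = FALSE)
  k <- ncol(score_sets)
  pcs <- lapply(seq_len(k), function(j)
    placement_components(score_sets[, j], outcome, weights))
  V10 <- do.call(cbind, lapply(pcs, `[[`, "v_event"))
  V01 <- do.call(cbind, lapply(pcs, `[[`, "v_nonevent"))
  aucs <- vapply(pcs, `[[`, numeric(1), "auc")
  w1 <- pcs[[1]]$w_event; w0 <- pcs[[1]]$w_nonevent
  S10 <- weighted_cov(V10, aucs, w1)
  S01 <- weighted_cov(V01, aucs, w0)
  m_eff <- sum(w1)^2 / sum(w1^2)
  n_eff <- sum(w0)^2 / sum(w0^2)
  V <- S10 / m_eff + S01 / n_eff
  dimnames(V) <- list(colnames(score_sets), colnames(score_sets))
  V
}

# Weighted covariance of placement columns, centred at the AUCs (the exact
# weighted means of the placements) with a weighted Bessel correction that
# reduces to n-1 under unit weights.
#' @noRd
weighted_cov <- function(V, centers, w) {
  V <- as.matrix(V)
  Vc <- sweep(V, 2, centers)
  denom <- sum(w) - sum(w^2) / sum(w)
  if (denom <= 0) return(matrix(0, ncol(V), ncol(V)))
  crossprod(Vc * w, Vc) / denom
}

#' Test equality of two correlated weighted AUCs
#'
#' DeLong-type chi-square test for paired ROC curves on the same sample:
#' `chi2 = (auc_a - auc_b)^2 / var(auc_a - auc_b)` on 1 degree of freedom,
#' with the variance of the difference from [auc_covariance()]. Identical
#' score vectors (zero variance, equal AUCs) give `chi2 = 0`, `p = 1`.
#'
#' @param scores_a,scores_b Two score vectors over the same sample.
#' @inheritParams placement_components
#' @param label_a,label_b Labels carried into the result.
#' @return A list of class `"auc_comparison"`: `auc_a`, `auc_b`,
#'   `covariance` (2x2), `chi2`, `df`, `p_value`, labels.
#' @examples
#' set.seed(2)
#' y <- rbinom(300, 1, 0.3); z <- rnorm(300)
#' test_auc_equality(z + y + rnorm(300), z + y + rnorm(300), y)
#' @export
test_auc_equality <- function(scores_a, scores_b, outcome,
                              weights = rep(1, length(outcome)),
                              label_a = "A", label_b = "B") {
  V <- auc_covariance(cbind(scores_a, scores_b), outcome, weights)
  pa <- placement_components(scores_a, outcome, weights)$auc
  pb <- placement_components(scores_b, outcome, weights)$auc
  d <- pa - pb
  vd <- V[1, 1] + V[2, 2] - 2 * V[1, 2]
  if (vd <= 0) {
    # exact-zero variance can only arise from (numerically) identical
    # placements; with equal AUCs that is a null comparison, otherwise the
    # contrast is ill-posed
    if (abs(d) < 1e-12) {
      chi2 <- 0; p <- 1
    } else {
      stop("degenerate comparison: zero variance with unequal AUCs",
           call. = FALSE)
    }
  } else {
    chi2 <- d^2 / vd
    p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  structure(list(label_a = label_a, label_b = label_b,
                 auc_a = pa, auc_b = pb, covariance = V,
                 chi2 = chi2, df = 1L, p_value = p),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, digits = 4, ...) {
  cat(sprintf("AUC equality test: %s (%.*f) vs %s (%.*f)\n",
              x$label_a, digits, x$auc_a, x$label_b, digits, x$auc_b))
  cat(sprintf("  chi2 = %.4g on %d df, p = %.4g\n", x$chi2, x$df, x$p_value))
  invisible(x)
}

#' Joint equality test across k correlated AUCs
#'
#' Generalized contrast test: for k score vectors, tests whether all AUCs
#' are equal using the contrast matrix of successive differences and the
#' DeLong-type covariance, on k-1 degrees of freedom. Provided for
#' completeness; the pipeline's inference is pairwise.
#'
#' @inheritParams auc_covariance
#' @return A list with `aucs`, `chi2`, `df`, `p_value`.
#' @export
test_auc_equality_joint <- function(score_sets, outcome,
                                    weights = rep(1, length(outcome))) {
  if (is.list(score_sets)) score_sets <- do.call(cbind, score_sets)
  k <- ncol(score_sets)
  if (k < 2) stop("need at least two score vectors", call. = FALSE)
  V <- auc_covariance(score_sets, outcome, weights)
  aucs <- vapply(seq_len(k), function(j)
    placement_components(score_sets[, j], outcome, weights)$auc, numeric(1))
  L <- diff(diag(k))            # successive differences, (k-1) x k
  d <- L %*% aucs
  S <- L %*% V %*% t(L)
  chi2 <- drop(t(d) %*% solve(S, d))
  list(aucs = aucs, chi2 = chi2, df = k - 1L,
       p_value = pchisq(chi2, df = k - 1L, lower.tail = FALSE))
}
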