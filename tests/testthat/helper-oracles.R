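# Independent brute-force oracles and small fixtures used across tests.
# These deliberately re-derive quantities from first principles (explicit
# loops over pairs/observations) so they stay independent of the package's
# rank-based implementations.

# Weighted AUC as the explicit double sum over (event, non-event) pairs,
# ties half-credited.
oracle_auc_double_sum <- function(scores, outcome, weights = rep(1, length(scores))) {
  ev <- which(outcome == 1)
  ne <- which(outcome == 0)
  num <- 0
  for (i in ev) for (j in ne) {
    psi <- if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0
    num <- num + weights[i] * weights[j] * psi
  }
  num / (sum(weights[ev]) * sum(weights[ne]))
}

# Per-observation placements by direct enumeration.
oracle_placements <- function(scores, outcome, weights = rep(1, length(scores))) {
  ev <- which(outcome == 1)
  ne <- which(outcome == 0)
  W1 <- sum(weights[ev]); W0 <- sum(weights[ne])
  v10 <- vapply(ev, function(i) {
    sum(weights[ne] * ((scores[i] > scores[ne]) + 0.5 * (scores[i] == scores[ne]))) / W0
  }, numeric(1))
  v01 <- vapply(ne, function(j) {
    sum(weights[ev] * ((scores[ev] > scores[j]) + 0.5 * (scores[ev] == scores[j]))) / W1
  }, numeric(1))
  list(v_event = v10, v_nonevent = v01)
}

# Definitional DeLong-type covariance from enumerated placements (unit or
# general weights), mirroring the estimator's definition independently.
oracle_auc_cov <- function(score_sets, outcome, weights = rep(1, length(outcome))) {
  score_sets <- as.matrix(score_sets)
  k <- ncol(score_sets)
  ev <- outcome == 1; ne <- !ev
  pls <- lapply(seq_len(k), function(j)
    oracle_placements(score_sets[, j], outcome, weights))
  aucs <- vapply(seq_len(k), function(j)
    oracle_auc_double_sum(score_sets[, j], outcome, weights), numeric(1))
  w1 <- weights[ev]; w0 <- weights[ne]
  wc <- function(V, w, centers) {
    V <- as.matrix(V)
    out <- matrix(0, k, k)
    denom <- sum(w) - sum(w^2) / sum(w)
    if (denom <= 0) return(out)
    for (a in seq_len(k)) for (b in seq_len(k))
      out[a, b] <- sum(w * (V[, a] - centers[a]) * (V[, b] - centers[b])) / denom
    out
  }
  V10 <- do.call(cbind, lapply(pls, `[[`, "v_event"))
  V01 <- do.call(cbind, lapply(pls, `[[`, "v_nonevent"))
  S10 <- wc(V10, w1, aucs); S01 <- wc(V01, w0, aucs)
  S10 / (sum(w1)^2 / sum(w1^2)) + S01 / (sum(w0)^2 / sum(w0^2))
}

# Random small ROC instance with ties and (optionally) unequal weights.
random_roc_instance <- function(max_n = 12, weighted = TRUE) {
  repeat {
    n <- sample(3:max_n, 1)
    y <- rbinom(n, 1, 0.5)
    if (any(y == 1) && any(y == 0)) break
  }
  s <- sample(seq(0, 2, by = 0.5), n, replace = TRUE)  # coarse grid forces ties
  w <- if (weighted) runif(n, 0.2, 3) else rep(1, n)
  list(scores = s, outcome = y, weights = w)
}

# A tiny three-kind dictionary for coding tests.
toy_dictionary <- function() {
  fi_dictionary(list(
    coding_rule("alb", "blood", "blood chemistry", "binary_range",
                normal_range = c(35, 50)),
    coding_rule("grip", "examination", "physical performance", "normalized",
                reference_min = 5, reference_max = 60,
                direction = "lower_is_deficit"),
    coding_rule("walk", "examination", "physical performance", "ordinal",
                cut_points = c(10, 20), levels = c(0, 0.5, 1))
  ))
}

# Random coding rule of a random kind (for range/monotonicity properties).
random_rule <- function(item = "x") {
  kind <- sample(c("binary_range", "ordinal", "normalized"), 1)
  if (kind == "binary_range") {
    lo <- runif(1, -5, 5)
    coding_rule(item, "blood", "blood chemistry", "binary_range",
                normal_range = c(lo, lo + runif(1, 0.5, 10)))
  } else if (kind == "ordinal") {
    k <- sample(1:4, 1)
    cp <- sort(runif(k, -5, 5))
    lv <- if (k == 1) c(0, 1) else sort(c(0, 1, runif(k - 1, 0.01, 0.99)))
    while (any(duplicated(lv))) lv <- sort(c(0, 1, runif(k - 1, 0.01, 0.99)))
    coding_rule(item, "examination", "cognitive", "ordinal",
                cut_points = cp, levels = lv)
  } else {
    lo <- runif(1, -5, 5)
    coding_rule(item, "examination", "cardiac", "normalized",
                reference_min = lo, reference_max = lo + runif(1, 0.5, 10),
                direction = sample(c("higher_is_deficit", "lower_is_deficit"), 1))
  }
}

# Small cohort with full demographics and two biomarker columns.
tiny_cohort <- function(n = 8, seed = 1) {
  set.seed(seed)
  data.frame(participant_id = paste0("P", seq_len(n)),
             age = runif(n, 45, 85),
             sex = sample(c("female", "male"), n, replace = TRUE),
             weight = rep(1, n),
             died = rbinom(n, 1, 0.4),
             alb = runif(n, 30, 60),
             grip = runif(n, 5, 60),
             walk = runif(n, 5, 30),
             stringsAsFactors = FALSE)
}
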