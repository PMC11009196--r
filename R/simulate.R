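# Synthetic cohort generator.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: ages on 45-85 with a given mean/SD, a shared standard-normal
# latent vulnerability factor, biomarkers whose coded deficit probability
# (or normalized severity) rises with age and with the latent factor, and a
# binary death outcome from a logistic model in age, sex and the latent
# factor. All marginals are calibrated deterministically (closed-form
# truncated-normal moments; quadrature-solved per-item intercepts) so that
# expected values equal the configured targets exactly, leaving only
# Monte-Carlo noise in a realized cohort.

#' Simulation configuration for synthetic cohorts
#'
#' @param n Number of participants (>= 1).
#' @param age_mean,age_sd Target mean and SD of the realized (truncated)
#'   age distribution, in years.
#' @param age_range Truncation bounds `c(low, high)` in years.
#' @param prop_female Proportion female, in \[0, 1\].
#' @param latent_loading Per-item log-odds loading on the shared latent
#'   vulnerability factor (standard normal across participants).
#' @param age_slope Per-item log-odds change per decade of age.
#' @param exam_noise_sd SD of the item-specific noise added to the linear
#'   predictor of normalized (examination) severities.
#' @param mortality_coef Named numeric vector
#'   `c(intercept, age10, male, latent)`: log-odds of death per decade of
#'   age, for male sex, and per SD of the latent factor. The default
#'   intercept is a reasonable starting value; use
#'   [calibrate_mortality_intercept()] to pin the death prevalence to
#'   `target_death_prevalence`.
#' @param deficit_mean Named vector `c(blood=, examination=)`: target mean
#'   deficit value per panel (equals the expected panel FI mean). All items
#'   in a panel share the target, so each column's distribution depends
#'   only on its own rule and substream, never on the rest of the
#'   dictionary.
#' @param blood_block_missing_rate Probability a participant's entire blood
#'   panel is missing (no blood sample taken).
#' @param item_missing_rate Independent per-cell missingness rate applied
#'   to remaining biomarker cells.
#' @param target_death_prevalence Weighted death prevalence targeted by
#'   [calibrate_mortality_intercept()].
#' @param weight_scheme `"unit"` (all analytic weights 1) or `"random"`
#'   (uniform on \[0.5, 2\], normalized to mean 1, to exercise weighted
#'   code paths).
#' @param seed Root seed; every column is drawn under its own named
#'   substream derived from it.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n = 30000,
                          age_mean = 59.4, age_sd = 9.9,
                          age_range = c(45, 85),
                          prop_female = 0.503,
                          latent_loading = 0.5,
                          age_slope = 0.3,
                          exam_noise_sd = 1.2,
                          mortality_coef = c(intercept = -3.7, age10 = 0.9,
                                             male = 0.4, latent = 0.6),
                          deficit_mean = c(blood = 0.15, examination = 0.27),
                          blood_block_missing_rate = 0.10,
                          item_missing_rate = 0.02,
                          target_death_prevalence = 0.031,
                          weight_scheme = c("unit", "random"),
                          seed = 1L) {
  cfg <- list(n = n, age_mean = age_mean, age_sd = age_sd,
              age_range = age_range, prop_female = prop_female,
              latent_loading = latent_loading, age_slope = age_slope,
              exam_noise_sd = exam_noise_sd,
              mortality_coef = mortality_coef,
              deficit_mean = deficit_mean,
              blood_block_missing_rate = blood_block_missing_rate,
              item_missing_rate = item_missing_rate,
              target_death_prevalence = target_death_prevalence,
              weight_scheme = match.arg(weight_scheme),
              seed = as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

#' @noRd
validate_config <- function(cfg) {
  bad <- function(field, why)
    stop("configuration error in '", field, "': ", why, call. = FALSE)
  if (!is.numeric(cfg$n) || length(cfg$n) != 1 || cfg$n < 1 ||
      cfg$n != round(cfg$n)) bad("n", "must be a whole number >= 1")
  if (!is.numeric(cfg$age_sd) || cfg$age_sd <= 0) bad("age_sd", "must be > 0")
  if (length(cfg$age_range) != 2 || cfg$age_range[1] >= cfg$age_range[2])
    bad("age_range", "must be c(low, high) with low < high")
  if (cfg$age_mean <= cfg$age_range[1] || cfg$age_mean >= cfg$age_range[2])
    bad("age_mean", "must lie strictly inside age_range")
  for (f in c("prop_female", "blood_block_missing_rate", "item_missing_rate"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      bad(f, "must be a fraction in [0, 1]")
  if (cfg$target_death_prevalence < 0 || cfg$target_death_prevalence > 1)
    bad("target_death_prevalence", "must be a fraction in [0, 1]")
  if (!all(c("intercept", "age10", "male", "latent") %in%
           names(cfg$mortality_coef)))
    bad("mortality_coef", "needs named entries intercept, age10, male, latent")
  if (cfg$exam_noise_sd < 0) bad("exam_noise_sd", "must be >= 0")
  if (any(cfg$deficit_mean <= 0 | cfg$deficit_mean >= 1))
    bad("deficit_mean", "entries must lie strictly in (0, 1)")
  invisible(cfg)
}

# --- truncated-normal machinery ------------------------------------------

# Mean and SD of N(mu, sigma^2) truncated to [lo, hi] (closed form).
#' @noRd
truncnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
  Z <- pnorm(b) - pnorm(a)
  m <- mu + sigma * (dnorm(a) - dnorm(b)) / Z
  v <- sigma^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z -
                    ((dnorm(a) - dnorm(b)) / Z)^2)
  c(mean = m, sd = sqrt(v))
}

# Solve for underlying (mu, sigma) so the truncated distribution has the
# requested mean and SD. Truncating N(59.4, 9.9^2) to [45, 85] would push
# the realized mean up by more than a year, so the match matters.
#' @noRd
solve_truncnorm <- function(target_mean, target_sd, lo, hi) {
  obj <- function(p) {
    mo <- truncnorm_moments(p[1], exp(p[2]), lo, hi)
    (mo["mean"] - target_mean)^2 + (mo["sd"] - target_sd)^2
  }
  fit <- optim(c(target_mean, log(target_sd)), obj,
               control = list(reltol = 1e-14, maxit = 5000))
  mu <- fit$par[1]; sigma <- exp(fit$par[2])
  mo <- truncnorm_moments(mu, sigma, lo, hi)
  if (abs(mo["mean"] - target_mean) > 1e-4 || abs(mo["sd"] - target_sd) > 1e-3)
    stop("could not match the truncated age distribution to the requested ",
         "mean/SD within [", lo, ", ", hi, "]", call. = FALSE)
  list(mu = mu, sigma = sigma)
}

#' @noRd
qtruncnorm <- function(p, mu, sigma, lo, hi) {
  pa <- pnorm(lo, mu, sigma); pb <- pnorm(hi, mu, sigma)
  qnorm(pa + p * (pb - pa), mu, sigma)
}

# --- per-item intercept calibration --------------------------------------

# Deterministic quadrature grid over the linear-predictor distribution:
# quantile midpoints of age times quantile midpoints of the normal part
# (latent loading plus, for normalized items, the item noise).
#' @noRd
eta_quadrature <- function(cfg, normal_sd, K = 128L) {
  tn <- solve_truncnorm(cfg$age_mean, cfg$age_sd, cfg$age_range[1],
                        cfg$age_range[2])
  u <- (seq_len(K) - 0.5) / K
  ages <- qtruncnorm(u, tn$mu, tn$sigma, cfg$age_range[1], cfg$age_range[2])
  age_part <- cfg$age_slope * (ages - cfg$age_mean) / 10
  if (normal_sd == 0) return(age_part)
  norm_part <- qnorm(u) * normal_sd
  as.vector(outer(age_part, norm_part, `+`))
}

#' @noRd
solve_item_intercept <- function(target, eta_grid) {
  uniroot(function(b) mean(plogis(b + eta_grid)) - target,
          lower = -40, upper = 40, tol = 1e-11)$root
}

# --- cohort generation ---------------------------------------------------

#' Generate a synthetic cohort
#'
#' Draws a seeded cohort under `config`: ages from a moment-matched
#' truncated normal, sex Bernoulli, one standard-normal latent
#' vulnerability per participant, raw biomarker values whose coded deficit
#' probability (binary blood items) or normalized severity (examination
#' items) increases with age and the latent factor, and death from a
#' logistic model in age (per decade), male sex and the latent factor.
#' Every column is drawn under its own named RNG substream, so adding an
#' item to the dictionary does not perturb any other column. The same
#' config yields a bit-identical table.
#'
#' Missingness is *not* applied here; see [inject_missingness()].
#'
#' @param config A [cohort_config()].
#' @param dictionary An [fi_dictionary()]; defaults to the 70-item
#'   catalogue.
#' @return A data frame of class `"fi_cohort"`: `participant_id`, `age`,
#'   `sex` (`"female"`/`"male"`), `weight`, `died` (0/1), `latent`
#'   (the generating factor, kept for diagnostics) and one numeric column
#'   per dictionary item.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n = 200, seed = 7))
#' mean(cohort$died)
#' @export
simulate_cohort <- function(config, dictionary = default_dictionary()) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(dictionary, "fi_dictionary"))
  validate_config(config)
  cfg <- config
  n <- as.integer(cfg$n)
  tn <- solve_truncnorm(cfg$age_mean, cfg$age_sd, cfg$age_range[1],
                        cfg$age_range[2])

  age <- with_stream(cfg$seed, "age",
    qtruncnorm(runif(n), tn$mu, tn$sigma, cfg$age_range[1], cfg$age_range[2]))
  sex <- with_stream(cfg$seed, "sex",
    ifelse(runif(n) < cfg$prop_female, "female", "male"))
  latent <- with_stream(cfg$seed, "latent", rnorm(n))
  weight <- if (cfg$weight_scheme == "unit") rep(1, n) else
    with_stream(cfg$seed, "weight", { w <- runif(n, 0.5, 2); w / mean(w) })

  cohort <- data.frame(participant_id = sprintf("P%06d", seq_len(n)),
                       age = age, sex = sex, weight = weight,
                       stringsAsFactors = FALSE)

  # biomarkers: intercepts solved by quadrature so E[deficit] hits target
  panels <- vapply(dictionary, `[[`, character(1), "panel")
  eta_obs_shared <- cfg$age_slope * (age - cfg$age_mean) / 10 +
    cfg$latent_loading * latent
  grids <- list(
    blood = eta_quadrature(cfg, abs(cfg$latent_loading)),
    examination = eta_quadrature(
      cfg, sqrt(cfg$latent_loading^2 + cfg$exam_noise_sd^2)))
  b0_panel <- vapply(unique(panels), function(p)
    solve_item_intercept(cfg$deficit_mean[[p]], grids[[p]]), numeric(1))
  for (j in seq_along(dictionary)) {
    rule <- dictionary[[j]]
    b0 <- b0_panel[[rule$panel]]
    cohort[[rule$item]] <- with_stream(cfg$seed, paste0("item:", rule$item),
      draw_item(rule, b0, eta_obs_shared, cfg))
  }

  mc <- cfg$mortality_coef
  eta_death <- mc[["intercept"]] + mc[["age10"]] * (age - cfg$age_mean) / 10 +
    mc[["male"]] * (sex == "male") + mc[["latent"]] * latent
  cohort$died <- with_stream(cfg$seed, "death",
    as.integer(runif(n) < plogis(eta_death)))
  cohort$latent <- latent
  cohort <- cohort[c("participant_id", "age", "sex", "weight", "died",
                     "latent", names(dictionary))]
  class(cohort) <- c("fi_cohort", "data.frame")
  attr(cohort, "config") <- cfg
  cohort
}

# Draw one raw biomarker column given its solved intercept. Raw values are
# constructed so that coding with the dictionary rule recovers the intended
# deficit exactly: binary items place deficits just outside the normal
# range, normalized items invert the min-max map.
#' @noRd
draw_item <- function(rule, b0, eta_shared, cfg) {
  n <- length(eta_shared)
  if (rule$kind == "binary_range") {
    p <- plogis(b0 + eta_shared)
    deficit <- runif(n) < p
    lo <- rule$normal_range[1]; hi <- rule$normal_range[2]
    span <- hi - lo
    raw <- lo + runif(n) * span                 # inside the normal range
    raw[deficit] <- hi + runif(sum(deficit)) * 0.3 * span  # above it
    raw
  } else if (rule$kind == "normalized") {
    d <- plogis(b0 + eta_shared + cfg$exam_noise_sd * rnorm(n))
    span <- rule$reference_max - rule$reference_min
    if (rule$direction == "higher_is_deficit")
      rule$reference_min + d * span
    else rule$reference_max - d * span
  } else {
    # ordinal: draw a continuous severity, snap it to the nearest deficit
    # level, then emit a raw value inside that level's cut-point interval
    # so coding recovers the level exactly
    d <- plogis(b0 + eta_shared + cfg$exam_noise_sd * rnorm(n))
    mids <- (rule$levels[-1] + rule$levels[-length(rule$levels)]) / 2
    lev <- findInterval(d, mids) + 1L
    cuts <- c(rule$cut_points[1] - 1, rule$cut_points,
              rule$cut_points[length(rule$cut_points)] + 1)
    cuts[lev] + 0.5 * (cuts[lev + 1L] - cuts[lev])
  }
}

#' Calibrate the mortality intercept to a target death prevalence
#'
#' Pins the expected weighted death prevalence of [simulate_cohort()] to
#' `config$target_death_prevalence` by monotone root-finding over the
#' intercept on a pilot draw of covariates: the pilot expected prevalence
#' is the weighted mean of `plogis(intercept + eta)` over the pilot linear
#' predictors, which is smooth and strictly increasing in the intercept.
#'
#' @param config A [cohort_config()].
#' @param dictionary Unused by the mortality model itself, accepted for
#'   interface symmetry.
#' @param n_pilot Pilot sample size (>= 1000).
#' @return `config` with `mortality_coef["intercept"]` replaced.
#' @examples
#' cfg <- calibrate_mortality_intercept(cohort_config(n = 1000, seed = 3))
#' cfg$mortality_coef[["intercept"]]
#' @export
calibrate_mortality_intercept <- function(config,
                                          dictionary = default_dictionary(),
                                          n_pilot = 50000L) {
  stopifnot(inherits(config, "cohort_config"))
  if (n_pilot < 1000) stop("n_pilot must be >= 1000", call. = FALSE)
  target <- config$target_death_prevalence
  if (target <= 0 || target >= 1)
    stop("calibration failure: a prevalence of ", target,
         " is unattainable on the log-odds scale", call. = FALSE)
  cfg <- config
  tn <- solve_truncnorm(cfg$age_mean, cfg$age_sd, cfg$age_range[1],
                        cfg$age_range[2])
  pilot <- with_stream(cfg$seed, "calibrate-mortality", {
    age <- qtruncnorm(runif(n_pilot), tn$mu, tn$sigma,
                      cfg$age_range[1], cfg$age_range[2])
    male <- runif(n_pilot) >= cfg$prop_female
    latent <- rnorm(n_pilot)
    w <- if (cfg$weight_scheme == "unit") rep(1, n_pilot) else
      { w0 <- runif(n_pilot, 0.5, 2); w0 / mean(w0) }
    mc <- cfg$mortality_coef
    eta <- mc[["age10"]] * (age - cfg$age_mean) / 10 + mc[["male"]] * male +
      mc[["latent"]] * latent
    list(eta = eta, w = w)
  })
  f <- function(b0) weighted_mean(plogis(b0 + pilot$eta), pilot$w) - target
  root <- tryCatch(
    uniroot(f, lower = -40, upper = 40, tol = 1e-10),
    error = function(e) stop("calibration failure: ", conditionMessage(e),
                             call. = FALSE))
  cfg$mortality_coef[["intercept"]] <- root$root
  cfg
}

#' Inject missingness into a simulated cohort
#'
#' With probability `blood_block_missing_rate` a participant's entire blood
#' panel is set missing (emulating participants with no blood sample);
#' independently, each remaining biomarker cell is set missing with
#' probability `item_missing_rate`. Demographics, analytic weight and the
#' death indicator are never touched. Missingness is completely at random
#' and reproducible under the config seed.
#'
#' @param cohort An `fi_cohort` from [simulate_cohort()].
#' @param config The [cohort_config()] holding the rates (defaults to the
#'   config the cohort was generated under).
#' @param dictionary The dictionary defining panel membership.
#' @return The cohort with NA holes punched into biomarker columns.
#' @export
inject_missingness <- function(cohort, config = attr(cohort, "config"),
                               dictionary = default_dictionary()) {
  stopifnot(is.data.frame(cohort), inherits(config, "cohort_config"))
  validate_config(config)
  blood <- intersect(dictionary_items(dictionary, "blood"), names(cohort))
  all_items <- intersect(dictionary_items(dictionary), names(cohort))
  n <- nrow(cohort)
  if (length(blood) && config$blood_block_missing_rate > 0) {
    block <- with_stream(config$seed, "missing:block",
                         runif(n) < config$blood_block_missing_rate)
    cohort[block, blood] <- NA_real_
  }
  if (length(all_items) && config$item_missing_rate > 0) {
    holes <- with_stream(config$seed, "missing:item",
      matrix(runif(n * length(all_items)) < config$item_missing_rate,
             nrow = n))
    for (j in seq_along(all_items))
      cohort[holes[, j], all_items[j]] <- NA_real_
  }
  cohort
}

#' Calibrated default cohort in one call
#'
#' Convenience wrapper running [calibrate_mortality_intercept()],
#' [simulate_cohort()] and [inject_missingness()] under the default
#' configuration.
#'
#' @param n Cohort size.
#' @param seed Root seed.
#' @param dictionary Item dictionary.
#' @param ... Overrides passed to [cohort_config()].
#' @return An `fi_cohort` with missingness applied.
#' @export
simulate_default_cohort <- function(n = 30000, seed = 1L,
                                    dictionary = default_dictionary(), ...) {
  cfg <- cohort_config(n = n, seed = seed, ...)
  cfg <- calibrate_mortality_intercept(cfg, dictionary)
  cohort <- simulate_cohort(cfg, dictionary)
  inject_missingness(cohort, cfg, dictionary)
}
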