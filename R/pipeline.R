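# Panel-level orchestration: code deficits, build leave-one-out FIs, fit
# the four models per biomarker, test AUC equality, screen with BH, and
# summarise in the four-flag table layout.

#' Run the full analysis for one biomarker panel
#'
#' For every biomarker in the panel: build the common complete-case
#' sample, fit the four nested weighted logistic mortality models, compute
#' weighted AUCs, test the four pairwise AUC contrasts (M2 vs M1, M3 vs
#' M1, M4 vs M2, M4 vs M3), then screen each contrast's p-values across
#' the panel with Benjamini-Hochberg at FDR `q`. A biomarker whose common
#' sample is degenerate is reported as skipped, not fatal.
#'
#' @param cohort An `fi_cohort` (or compatible data frame).
#' @param dictionary An [fi_dictionary()].
#' @param panel `"blood"` or `"examination"`.
#' @param q False discovery rate for the screening step.
#' @param family_mode Passed to [screen_family()]; the default screens
#'   each contrast across the panel's biomarkers as one family.
#' @param verbose Print a progress line per biomarker.
#' @return A data frame of class `"fi_panel_summary"`, one row per
#'   biomarker: `biomarker`, `panel`, `domain`, `n_used`, the four AUCs
#'   with CI bounds, per-contrast p-values (`p_M2vsM1`, ...) and improved
#'   flags (`improved_M2vsM1`, ...). Attributes: `totals` (named
#'   per-contrast improvement counts), `skipped`, `q`, `family_mode`,
#'   `manifest` (a reproducibility record, see [run_manifest()]).
#' @examples
#' \donttest{
#' cohort <- simulate_default_cohort(n = 4000, seed = 11)
#' run_panel(cohort, default_dictionary(), "blood")
#' }
#' @export
run_panel <- function(cohort, dictionary = default_dictionary(),
                      panel = c("blood", "examination"), q = 0.05,
                      family_mode = "contrast", verbose = FALSE) {
  panel <- match.arg(panel)
  items <- dictionary_items(dictionary, panel)
  if (!length(items)) stop("no items in panel '", panel, "'", call. = FALSE)
  deficits <- code_deficits(cohort, dictionary)
  contrasts <- c("M2vsM1", "M3vsM1", "M4vsM2", "M4vsM3")
  rows <- vector("list", length(items))
  skipped <- character(0)
  for (i in seq_along(items)) {
    bm <- items[i]
    fit <- tryCatch(
      fit_biomarker_models(cohort, dictionary, bm, deficits = deficits),
      error = function(e) e)
    if (inherits(fit, "error")) {
      skipped <- c(skipped, bm)
      warning("skipping '", bm, "': ", conditionMessage(fit), call. = FALSE)
      next
    }
    if (verbose)
      message(sprintf("%-40s n=%d  conv=%s", bm, fit$n_used,
                      all(vapply(fit$models, `[[`, logical(1), "converged"))))
    row <- data.frame(biomarker = bm, panel = panel,
                      domain = dictionary[[bm]]$domain,
                      n_used = fit$n_used, stringsAsFactors = FALSE)
    for (m in names(fit$aucs)) {
      a <- fit$aucs[[m]]
      row[[paste0("auc_", m)]] <- a$auc
      row[[paste0("auc_", m, "_lo")]] <- a$ci95[1]
      row[[paste0("auc_", m, "_hi")]] <- a$ci95[2]
    }
    for (ct in contrasts)
      row[[paste0("p_", ct)]] <- fit$comparisons[[ct]]$p_value
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("every biomarker in panel '", panel, "' was skipped", call. = FALSE)
  for (ct in contrasts) {
    fam <- data.frame(biomarker = out$biomarker, panel = out$panel,
                      contrast = ct, p = out[[paste0("p_", ct)]])
    out[[paste0("improved_", ct)]] <-
      screen_family(fam, q = q, family_mode = family_mode)$rejected
  }
  totals <- vapply(contrasts, function(ct)
    sum(out[[paste0("improved_", ct)]]), integer(1))
  attr(out, "totals") <- totals
  attr(out, "skipped") <- skipped
  attr(out, "q") <- q
  attr(out, "family_mode") <- family_mode
  attr(out, "manifest") <- make_manifest(cohort, dictionary, out)
  class(out) <- c("fi_panel_summary", "data.frame")
  out
}

#' @noRd
make_manifest <- function(cohort, dictionary, summary_table) {
  cfg <- attr(cohort, "config")
  list(package = "frailtymark",
       version = as.character(utils::packageVersion("frailtymark")),
       created = format(Sys.time(), tz = "UTC", usetz = TRUE),
       seed = if (!is.null(cfg)) cfg$seed else NA_integer_,
       config_hash = if (!is.null(cfg)) content_hash(unclass(cfg)) else NA,
       dictionary_hash = content_hash(lapply(unname(dictionary), unclass)),
       n_participants = nrow(cohort),
       n_biomarkers = nrow(summary_table),
       artifacts = list(summary = content_hash(canonical_df(summary_table))))
}

#' Reproducibility manifest of a panel run
#'
#' @param x An `fi_panel_summary` from [run_panel()].
#' @return The manifest list: package version, timestamp, seed, content
#'   hashes of the config, dictionary and emitted summary, and stage row
#'   counts.
#' @export
run_manifest <- function(x) {
  stopifnot(inherits(x, "fi_panel_summary"))
  attr(x, "manifest")
}

#' @export
print.fi_panel_summary <- function(x, ...) {
  cat("Panel summary (", x$panel[1], "): ", nrow(x), " biomarkers, FDR q = ",
      attr(x, "q"), "\n", sep = "")
  print(render_summary(x), right = FALSE)
  sk <- attr(x, "skipped")
  if (length(sk)) cat("skipped:", paste(sk, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.fi_panel_summary <- function(x, model = "M2", ...) {
  a <- x[[paste0("auc_", model)]]
  lo <- x[[paste0("auc_", model, "_lo")]]
  hi <- x[[paste0("auc_", model, "_hi")]]
  o <- order(a)
  n <- nrow(x)
  graphics::plot(a[o], seq_len(n), xlim = range(c(lo, hi, 0.5)),
                 yaxt = "n", xlab = paste("AUC,", model), ylab = "",
                 pch = 19, cex = 0.6, ...)
  graphics::segments(lo[o], seq_len(n), hi[o], seq_len(n))
  graphics::axis(2, at = seq_len(n), labels = x$biomarker[o], las = 2,
                 cex.axis = 0.5)
  graphics::abline(v = 0.5, lty = 3)
  invisible(x)
}

#' Render a panel summary in the publication table layout
#'
#' One row per biomarker with a glyph per contrast column (improved /
#' not improved) and a totals row counting improvements per column.
#'
#' @param x An `fi_panel_summary`.
#' @param mark Glyph for an improved contrast (default a check mark).
#' @param dash Glyph for no significant improvement.
#' @return A plain data frame: `biomarker`, `domain`, the four contrast
#'   columns, and a final `Total` row of column-wise counts.
#' @export
render_summary <- function(x, mark = "\u2713", dash = "\u2013") {
  contrasts <- c("M2vsM1", "M3vsM1", "M4vsM2", "M4vsM3")
  if (nrow(x) == 0) {
    out <- data.frame(biomarker = "Total", domain = "",
                      M2vsM1 = "0", M3vsM1 = "0", M4vsM2 = "0", M4vsM3 = "0",
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- data.frame(biomarker = x$biomarker, domain = x$domain,
                    stringsAsFactors = FALSE)
  for (ct in contrasts)
    out[[ct]] <- ifelse(x[[paste0("improved_", ct)]], mark, dash)
  out <- out[order(match(out$domain, unique(out$domain))), ]
  totals <- vapply(contrasts, function(ct)
    as.character(sum(x[[paste0("improved_", ct)]])), character(1))
  rbind(out, c(biomarker = "Total", domain = "", as.list(totals)))
}

#' Baseline characteristics by mortality status
#'
#' Weighted descriptive report in the usual cohort-table layout: mean (SD)
#' age and FI scores, percent female, and counts, for the overall sample
#' and split by survival status. Invariant to rescaling all weights by a
#' constant.
#'
#' @param cohort Cohort data frame (`age`, `sex`, `weight`, `died`).
#' @param fi_blood,fi_exam Per-participant FI values aligned with the
#'   cohort rows (NA where undefined); either may be omitted.
#' @return A data frame with rows n, age, percent female, FI means, and
#'   columns `overall`, `survived`, `died`.
#' @export
describe_cohort <- function(cohort, fi_blood = NULL, fi_exam = NULL) {
  groups <- list(overall = rep(TRUE, nrow(cohort)),
                 survived = cohort$died == 0,
                 died = cohort$died == 1)
  one <- function(mask) {
    if (!any(mask))
      return(c(n = 0, age_mean = NA, age_sd = NA, pct_female = NA,
               fi_blood_mean = NA, fi_blood_sd = NA,
               fi_exam_mean = NA, fi_exam_sd = NA))
    w <- cohort$weight[mask]
    c(n = sum(mask),
      age_mean = weighted_mean(cohort$age[mask], w),
      age_sd = weighted_sd(cohort$age[mask], w),
      pct_female = 100 * weighted_mean(cohort$sex[mask] == "female", w),
      fi_blood_mean = if (is.null(fi_blood)) NA else
        weighted_mean(fi_blood[mask], w),
      fi_blood_sd = if (is.null(fi_blood)) NA else
        weighted_sd(fi_blood[mask], w),
      fi_exam_mean = if (is.null(fi_exam)) NA else
        weighted_mean(fi_exam[mask], w),
      fi_exam_sd = if (is.null(fi_exam)) NA else
        weighted_sd(fi_exam[mask], w))
  }
  as.data.frame(lapply(groups, one))
}

#' Cohort CSV round trip
#'
#' Cohorts are serialized as plain CSV with a header row and empty fields
#' for missing values, one row per participant.
#'
#' @param cohort Cohort data frame.
#' @param path File path.
#' @return `read_cohort()` returns the cohort data frame;
#'   `write_cohort()` returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, check.names = FALSE,
                         na.strings = c("", "NA"),
                         stringsAsFactors = FALSE)
  class(out) <- c("fi_cohort", "data.frame")
  out
}
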