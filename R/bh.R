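#' Benjamini-Hochberg step-up screening
#'
#' Sorts the p-values ascending, computes the rank-i critical value
#' `i / m * q`, finds the largest rank whose p-value does not exceed its
#' critical value, and rejects the hypotheses with the smallest p-values up
#' to that rank. Tied p-values at the boundary share a fate (all rejected
#' or none), as the step-up rule implies.
#'
#' @param pvalues Numeric vector of raw p-values in \[0, 1\].
#' @param q False discovery rate (default 0.05).
#' @param ids Optional hypothesis identifiers.
#' @return A data frame of class `"bh_result"`, in the input order:
#'   `id`, `p`, `rank` (rank among sorted p-values), `critical`
#'   (that rank's critical value), `rejected`.
#' @examples
#' bh_screen(c(0.01, 0.02, 0.04), q = 0.05)  # all rejected
#' @export
bh_screen <- function(pvalues, q = 0.05, ids = NULL) {
  m <- length(pvalues)
  if (m < 1) stop("need at least one p-value", call. = FALSE)
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)", call. = FALSE)
  if (is.null(ids)) ids <- paste0("H", seq_len(m))
  ord <- order(pvalues)
  ranks <- integer(m); ranks[ord] <- seq_len(m)
  critical <- ranks / m * q
  sorted_p <- pvalues[ord]
  ok <- which(sorted_p <= seq_len(m) / m * q)
  k <- if (length(ok)) max(ok) else 0L
  # step-up: reject everything with p <= the k-th sorted p (ties share fate)
  rejected <- if (k == 0L) rep(FALSE, m) else pvalues <= sorted_p[k]
  out <- data.frame(id = ids, p = pvalues, rank = ranks,
                    critical = critical, rejected = rejected,
                    stringsAsFactors = FALSE)
  attr(out, "q") <- q
  attr(out, "n_rejected") <- sum(rejected)
  class(out) <- c("bh_result", "data.frame")
  out
}

#' Screen one family of AUC comparisons
#'
#' Applies [bh_screen()] within a family of comparison rows that share one
#' contrast label (and panel): the narrowest family consistent with
#' per-column significance marks in a summary table. A pooled mode
#' treating all supplied rows as one family is available for sensitivity
#' analysis.
#'
#' @param comparisons Data frame with columns `biomarker`, `panel`,
#'   `contrast`, `p`.
#' @param q False discovery rate.
#' @param family_mode `"contrast"` (default: one family per contrast label
#'   x panel; all rows must already share both) or `"pooled"` (all rows
#'   form one family regardless of label).
#' @return `comparisons` with `critical` and `rejected` columns appended.
#' @export
screen_family <- function(comparisons, q = 0.05,
                          family_mode = c("contrast", "pooled")) {
  family_mode <- match.arg(family_mode)
  req <- c("biomarker", "panel", "contrast", "p")
  if (!all(req %in% names(comparisons)))
    stop("comparisons needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (family_mode == "contrast" &&
      (length(unique(comparisons$contrast)) > 1 ||
       length(unique(comparisons$panel)) > 1))
    stop("grouping error: rows mix contrast labels or panels; ",
         "split into families first or use family_mode = 'pooled'",
         call. = FALSE)
  res <- bh_screen(comparisons$p, q = q, ids = comparisons$biomarker)
  comparisons$critical <- res$critical
  comparisons$rejected <- res$rejected
  comparisons
}
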