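#' Frailty index scores from a deficit matrix
#'
#' The frailty index (FI) for one participant is the sum of their
#' non-missing deficit values divided by the number of non-missing
#' considered items. An FI is defined only when at least 80% of the
#' considered items are non-missing for that participant (the completeness
#' rule); otherwise the value is NA, never silently 0, so downstream sample
#' restriction stays auditable.
#'
#' `frailty_index()` computes the FI for every row of a deficit matrix over
#' a considered item set; `frailty_index_excluding()` is the leave-one-out
#' variant used when the FI enters a model alongside the focal biomarker
#' itself (e.g. a 22-item blood FI or 46-item examination FI), identical to
#' `frailty_index()` on the reduced item set.
#'
#' @param deficits A matrix (or `deficit_matrix`) with entries in \[0, 1\]
#'   or NA, columns named by item.
#' @param items Character vector of considered item names (non-empty,
#'   all present as columns).
#' @param focal_item For the leave-one-out variant, the single item to
#'   exclude (must be in `items`).
#' @param completeness_min Minimum fraction of considered items that must
#'   be non-missing for the FI to be defined (default 0.8, inclusive).
#' @return A data frame with one row per participant and columns
#'   `numerator`, `denominator`, `completeness`, `value` (NA when the
#'   completeness rule fails).
#' @examples
#' m <- matrix(c(1, 1, 0, 0, NA, 1), nrow = 2,
#'             dimnames = list(NULL, c("a", "b", "c")))
#' frailty_index(m, c("a", "b", "c"), completeness_min = 0.6)
#' @export
frailty_index <- function(deficits, items = colnames(deficits),
                          completeness_min = 0.8) {
  if (!length(items)) stop("'items' must be non-empty", call. = FALSE)
  missing_items <- setdiff(items, colnames(deficits))
  if (length(missing_items))
    stop("items not in deficit matrix: ", paste(missing_items, collapse = ", "),
         call. = FALSE)
  sub <- deficits[, items, drop = FALSE]
  numerator <- rowSums(sub, na.rm = TRUE)
  denominator <- rowSums(!is.na(sub))
  completeness <- denominator / length(items)
  value <- ifelse(completeness >= completeness_min, numerator / denominator,
                  NA_real_)
  data.frame(numerator = numerator, denominator = denominator,
             completeness = completeness, value = value,
             row.names = rownames(sub))
}

#' @rdname frailty_index
#' @export
frailty_index_excluding <- function(deficits, items, focal_item,
                                    completeness_min = 0.8) {
  if (!focal_item %in% items)
    stop("focal_item '", focal_item, "' is not in the considered item set",
         call. = FALSE)
  frailty_index(deficits, setdiff(items, focal_item),
                completeness_min = completeness_min)
}

#' Frailty index for a single participant
#'
#' Convenience scalar form of [frailty_index()]: takes one named (or
#' positional) vector of deficit values and returns the score components.
#'
#' @param row Numeric vector of deficit values in \[0, 1\], NA allowed.
#' @param items Considered items; by default all entries of `row`. If `row`
#'   is named, `items` selects by name.
#' @inheritParams frailty_index
#' @return A one-row data frame as in [frailty_index()].
#' @examples
#' compute_fi(c(rep(1, 20), rep(0, 20)))  # value 0.5
#' @export
compute_fi <- function(row, items = NULL, completeness_min = 0.8) {
  row <- unlist(row)
  if (is.null(items)) {
    if (is.null(names(row))) names(row) <- paste0("item", seq_along(row))
    items <- names(row)
  }
  m <- matrix(row, nrow = 1, dimnames = list(NULL, names(row)))
  frailty_index(m, items, completeness_min = completeness_min)
}
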