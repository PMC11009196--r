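#' Code raw biomarker values as deficits
#'
#' Scalar coders mapping raw values to the deficit scale under a single
#' [coding_rule()]. All three are vectorized over `value` and propagate
#' missing values unchanged.
#'
#' * `code_binary()`: 0 if the value lies within the normal range
#'   (boundaries inclusive), 1 otherwise.
#' * `code_ordinal()`: the deficit level of the highest cut-point not
#'   exceeding the value; values below the first cut-point map to the first
#'   level. A value equal to a cut-point belongs to the higher deficit
#'   level.
#' * `code_normalized()`: min-max rescaling to \[0, 1\], clamped outside the
#'   reference interval; `lower_is_deficit` rules use the complement.
#'
#' @param value Numeric vector of raw values (NA allowed).
#' @param rule A [coding_rule()] of the matching kind.
#' @return Numeric vector of deficit values in \[0, 1\], NA where the input
#'   was missing.
#' @examples
#' r <- coding_rule("Albumin", "blood", "blood chemistry", "binary_range",
#'                  normal_range = c(35, 50))
#' code_binary(c(40, 55, NA), r)  # 0 1 NA
#' @export
code_binary <- function(value, rule) {
  check_rule_kind(rule, "binary_range")
  lo <- rule$normal_range[1]; hi <- rule$normal_range[2]
  out <- ifelse(value >= lo & value <= hi, 0, 1)
  out[is.na(value)] <- NA_real_
  out
}

#' @rdname code_binary
#' @export
code_ordinal <- function(value, rule) {
  check_rule_kind(rule, "ordinal")
  # findInterval with left-closed upper intervals: value == cut-point maps up
  idx <- findInterval(value, rule$cut_points, left.open = FALSE) + 1L
  out <- rule$levels[idx]
  out[is.na(value)] <- NA_real_
  out
}

#' @rdname code_binary
#' @export
code_normalized <- function(value, rule) {
  check_rule_kind(rule, "normalized")
  z <- (value - rule$reference_min) / (rule$reference_max - rule$reference_min)
  z <- pmin(pmax(z, 0), 1)
  if (rule$direction == "lower_is_deficit") z <- 1 - z
  z[is.na(value)] <- NA_real_
  z
}

#' @noRd
check_rule_kind <- function(rule, kind) {
  if (!inherits(rule, "coding_rule"))
    stop("dictionary error: not a coding_rule", call. = FALSE)
  if (!identical(rule$kind, kind))
    stop("dictionary error: rule for '", rule$item, "' has kind '", rule$kind,
         "', expected '", kind, "'", call. = FALSE)
}

#' @noRd
code_value <- function(value, rule) {
  switch(rule$kind,
         binary_range = code_binary(value, rule),
         ordinal = code_ordinal(value, rule),
         normalized = code_normalized(value, rule),
         stop("dictionary error: unknown rule kind '", rule$kind, "'",
              call. = FALSE))
}

#' Code a whole cohort table into a deficit matrix
#'
#' Applies each dictionary rule to its matching column of `cohort`,
#' producing the participants-by-items deficit matrix that frailty indices
#' are computed from. Missingness is preserved entrywise; non-numeric raw
#' entries are treated as missing with a warning.
#'
#' @param cohort A data frame with one column per dictionary item (extra
#'   columns such as demographics are ignored).
#' @param dictionary An [fi_dictionary()].
#' @return A numeric matrix of class `"deficit_matrix"` with entries in
#'   \[0, 1\] or NA; rows follow `cohort`, columns follow dictionary order,
#'   with a `"panel"` attribute giving each column's panel tag.
#' @examples
#' d <- default_dictionary()
#' cohort <- simulate_cohort(cohort_config(n = 50, seed = 1), d)
#' dm <- code_deficits(cohort, d)
#' range(dm, na.rm = TRUE)
#' @export
code_deficits <- function(cohort, dictionary) {
  stopifnot(inherits(dictionary, "fi_dictionary"), is.data.frame(cohort))
  items <- names(dictionary)
  missing_cols <- setdiff(items, names(cohort))
  if (length(missing_cols))
    stop("schema error: cohort lacks dictionary item(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out <- matrix(NA_real_, nrow = nrow(cohort), ncol = length(items),
                dimnames = list(cohort$participant_id %||% rownames(cohort),
                                items))
  bad <- character(0)
  for (it in items) {
    raw <- cohort[[it]]
    if (!is.numeric(raw)) {
      conv <- suppressWarnings(as.numeric(as.character(raw)))
      if (any(is.na(conv) & !is.na(raw))) bad <- c(bad, it)
      raw <- conv
    }
    out[, it] <- code_value(raw, dictionary[[it]])
  }
  if (length(bad))
    warning("non-numeric entries treated as missing in: ",
            paste(bad, collapse = ", "), call. = FALSE)
  attr(out, "panel") <- vapply(dictionary, `[[`, character(1), "panel")
  class(out) <- c("deficit_matrix", class(out))
  out
}
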