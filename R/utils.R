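# Internal helpers shared across modules.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a reproducible sub-seed from a root seed and a stream name, so each
# simulated column has its own named stream: adding a biomarker to the
# dictionary cannot perturb draws for any other column.
#' @noRd
stream_seed <- function(root_seed, name) {
  stopifnot(length(root_seed) == 1L, is.finite(root_seed))
  codes <- utf8ToInt(as.character(name))
  h <- 5381
  for (ch in codes) h <- (h * 33 + ch) %% 2147483647
  as.integer((abs(as.integer(root_seed)) + h) %% 2147483647)
}

# Evaluate a draw under its own seed without disturbing the caller's RNG
# stream.
#' @noRd
with_stream <- function(root_seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(root_seed, name))
  force(expr)
}

#' @noRd
weighted_mean <- function(x, w, na.rm = TRUE) {
  if (na.rm) {
    keep <- !is.na(x)
    x <- x[keep]; w <- w[keep]
  }
  sum(w * x) / sum(w)
}

#' @noRd
weighted_sd <- function(x, w, na.rm = TRUE) {
  if (na.rm) {
    keep <- !is.na(x)
    x <- x[keep]; w <- w[keep]
  }
  m <- sum(w * x) / sum(w)
  # weighted Bessel correction: reduces to the usual n-1 form at unit weights
  v <- sum(w * (x - m)^2) / (sum(w) - sum(w^2) / sum(w))
  sqrt(v)
}

# Strip a data frame down to its column data (drops class and any ad-hoc
# attributes) so hashing and identity checks see only the values.
#' @noRd
canonical_df <- function(d) {
  d <- as.data.frame(d)
  lapply(stats::setNames(names(d), names(d)), function(nm) d[[nm]])
}

# md5 of an arbitrary R object via canonical serialization (base R only).
#' @noRd
content_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  con <- file(tf, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(tf))
}
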