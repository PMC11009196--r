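#' Construct a deficit coding rule
#'
#' A coding rule describes how one raw biomarker maps to a deficit value on
#' the 0 (no deficit) to 1 (highest deficit) scale. Three kinds are
#' supported: `binary_range` (0 inside a normal range, 1 outside),
#' `ordinal` (ascending cut-points mapped to increasing deficit levels),
#' and `normalized` (min-max rescaling between two reference values, with a
#' direction flag saying whether high or low raw values are the deficit).
#'
#' Exactly the parameter block matching `kind` must be supplied:
#' `normal_range` for `binary_range`; `cut_points` and `levels` for
#' `ordinal`; `reference_min`, `reference_max` and `direction` for
#' `normalized`.
#'
#' @param item Item name (must be unique within a dictionary).
#' @param panel `"blood"` or `"examination"`.
#' @param domain Health domain tag, e.g. `"blood chemistry"`,
#'   `"physical performance"`, `"cognitive"`, `"anthropometric"`,
#'   `"spirometry"`, `"hearing/vision"`, `"cardiac"`.
#' @param kind `"binary_range"`, `"ordinal"` or `"normalized"`.
#' @param normal_range Length-2 numeric `c(low, high)`, in item units.
#' @param cut_points Ascending numeric thresholds (ordinal rules).
#' @param levels Deficit levels, length `length(cut_points) + 1`, strictly
#'   increasing within \[0, 1\] and containing 0 and 1.
#' @param reference_min,reference_max Reference values bounding the
#'   normalization, in item units (`reference_min < reference_max`).
#' @param direction `"higher_is_deficit"` or `"lower_is_deficit"`.
#'
#' @return A list of class `"coding_rule"`.
#' @examples
#' coding_rule("Albumin", "blood", "blood chemistry", "binary_range",
#'             normal_range = c(35, 50))
#' @export
coding_rule <- function(item, panel = c("blood", "examination"),
                        domain, kind = c("binary_range", "ordinal", "normalized"),
                        normal_range = NULL, cut_points = NULL, levels = NULL,
                        reference_min = NULL, reference_max = NULL,
                        direction = NULL) {
  panel <- match.arg(panel)
  kind <- match.arg(kind)
  if (!is.character(item) || length(item) != 1L || !nzchar(item))
    stop("'item' must be a non-empty string", call. = FALSE)
  rule <- list(item = item, panel = panel, domain = domain, kind = kind)
  if (kind == "binary_range") {
    if (is.null(normal_range) || length(normal_range) != 2L ||
        !is.numeric(normal_range) || normal_range[1] >= normal_range[2])
      stop("binary_range rule for '", item,
           "' needs normal_range = c(low, high) with low < high", call. = FALSE)
    if (!is.null(cut_points) || !is.null(reference_min))
      stop("rule for '", item, "': only the binary_range block may be present",
           call. = FALSE)
    rule$normal_range <- as.numeric(normal_range)
  } else if (kind == "ordinal") {
    if (is.null(cut_points) || is.null(levels))
      stop("ordinal rule for '", item, "' needs cut_points and levels",
           call. = FALSE)
    if (is.unsorted(cut_points, strictly = TRUE))
      stop("ordinal rule for '", item, "': cut_points must be strictly ascending",
           call. = FALSE)
    if (length(levels) != length(cut_points) + 1L)
      stop("ordinal rule for '", item,
           "': need length(levels) == length(cut_points) + 1", call. = FALSE)
    if (is.unsorted(levels, strictly = TRUE) || min(levels) != 0 || max(levels) != 1)
      stop("ordinal rule for '", item,
           "': levels must be strictly increasing in [0,1] and include 0 and 1",
           call. = FALSE)
    if (!is.null(normal_range) || !is.null(reference_min))
      stop("rule for '", item, "': only the ordinal block may be present",
           call. = FALSE)
    rule$cut_points <- as.numeric(cut_points)
    rule$levels <- as.numeric(levels)
  } else {
    if (is.null(reference_min) || is.null(reference_max) || is.null(direction))
      stop("normalized rule for '", item,
           "' needs reference_min, reference_max and direction", call. = FALSE)
    if (reference_min >= reference_max)
      stop("normalized rule for '", item, "': reference_min must be < reference_max",
           call. = FALSE)
    direction <- match.arg(direction, c("higher_is_deficit", "lower_is_deficit"))
    if (!is.null(normal_range) || !is.null(cut_points))
      stop("rule for '", item, "': only the normalized block may be present",
           call. = FALSE)
    rule$reference_min <- as.numeric(reference_min)
    rule$reference_max <- as.numeric(reference_max)
    rule$direction <- direction
  }
  class(rule) <- "coding_rule"
  rule
}

#' Assemble a data dictionary from coding rules
#'
#' @param rules A list of [coding_rule()] objects.
#' @return A list of class `"fi_dictionary"`.
#' @seealso [default_dictionary()], [read_dictionary()], [write_dictionary()]
#' @export
fi_dictionary <- function(rules) {
  if (!length(rules)) stop("a dictionary needs at least one rule", call. = FALSE)
  if (!all(vapply(rules, inherits, logical(1), "coding_rule")))
    stop("all entries must be coding_rule objects", call. = FALSE)
  nm <- vapply(rules, `[[`, character(1), "item")
  if (anyDuplicated(nm))
    stop("duplicate item names: ", paste(nm[duplicated(nm)], collapse = ", "),
         call. = FALSE)
  names(rules) <- nm
  class(rules) <- "fi_dictionary"
  rules
}

#' @export
print.fi_dictionary <- function(x, ...) {
  df <- as.data.frame(x)
  cat("Deficit coding dictionary:", length(x), "items\n")
  print(table(panel = df$panel, kind = df$kind))
  invisible(x)
}

#' @export
as.data.frame.fi_dictionary <- function(x, ...) {
  data.frame(
    item = vapply(x, `[[`, character(1), "item"),
    panel = vapply(x, `[[`, character(1), "panel"),
    domain = vapply(x, `[[`, character(1), "domain"),
    kind = vapply(x, `[[`, character(1), "kind"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Item names in a dictionary, optionally restricted to one panel
#'
#' @param dictionary An `fi_dictionary`.
#' @param panel `NULL` for all items, otherwise `"blood"` or `"examination"`.
#' @return Character vector of item names in dictionary order.
#' @export
dictionary_items <- function(dictionary, panel = NULL) {
  stopifnot(inherits(dictionary, "fi_dictionary"))
  nm <- names(dictionary)
  if (is.null(panel)) return(nm)
  panel <- match.arg(panel, c("blood", "examination"))
  nm[vapply(dictionary, `[[`, character(1), "panel") == panel]
}

#' Write / read a dictionary as YAML
#'
#' The on-disk form is a list of rule records; round-tripping through
#' [write_dictionary()] and [read_dictionary()] is lossless.
#'
#' @param dictionary An `fi_dictionary`.
#' @param path File path.
#' @return `read_dictionary()` returns an `fi_dictionary`;
#'   `write_dictionary()` returns `path` invisibly.
#' @export
write_dictionary <- function(dictionary, path) {
  stopifnot(inherits(dictionary, "fi_dictionary"))
  recs <- lapply(unname(dictionary), function(r) unclass(r))
  yaml::write_yaml(recs, path)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  recs <- yaml::read_yaml(path)
  rules <- lapply(recs, function(r) {
    do.call(coding_rule, r[intersect(names(r),
      c("item", "panel", "domain", "kind", "normal_range", "cut_points",
        "levels", "reference_min", "reference_max", "direction"))])
  })
  fi_dictionary(rules)
}

# --- default 70-item catalogue -------------------------------------------
#
# The item names, panel membership and domain tags follow the published
# blood (23) and examination (47) frailty-biomarker catalogues. The concrete
# numeric rules are synthetic placeholders on plausible clinical scales:
# blood chemistries get binary normal ranges, examination measures get
# min-max normalized scores. They are NOT the restricted cohort's cut-points.

.blood_items <- list(
  # item, low, high (normal range, item units)
  list("Red blood cell distribution width",   11.5, 14.5),
  list("High-sensitivity C-reactive protein",  0.0,  3.0),
  list("White blood cells",                    4.0, 11.0),
  list("Hemoglobin A1c",                       4.0,  6.0),
  list("Hematocrit",                           0.36, 0.50),
  list("Mean corpuscular hemoglobin",         27.0, 33.0),
  list("Hemoglobin",                         120.0, 170.0),
  list("Red blood cells",                      3.8,  5.8),
  list("Albumin",                             35.0, 50.0),
  list("Creatinine",                          45.0, 110.0),
  list("Free thyroxine",                      10.0, 25.0),
  list("Mean corpuscular volume",             80.0, 100.0),
  list("Mean platelet volume",                 7.5, 11.5),
  list("Cholesterol",                          2.5,  5.2),
  list("Ferritin",                            15.0, 300.0),
  list("Triglycerides",                        0.4,  1.7),
  list("Granulocytes",                         2.0,  7.5),
  list("Lymphocytes",                          1.0,  4.0),
  list("Monocytes",                            0.2,  1.0),
  list("Platelets",                          150.0, 400.0),
  list("25-Hydroxyvitamin D",                 50.0, 250.0),
  list("Estimated glomerular filtration rate", 60.0, 150.0),
  list("Thyroid-stimulating hormone",          0.4,  4.5)
)

.exam_items <- list(
  # item, domain, ref_min, ref_max, direction ("h" = higher_is_deficit)
  list("Timed 4-m walk",            "physical performance",  2,   15, "h"),
  list("Chair rise",                "physical performance",  5,   60, "h"),
  list("Timed get up and go",       "physical performance",  4,   30, "h"),
  list("Standing balance",          "physical performance",  0,   60, "l"),
  list("Grip strength",             "physical performance",  5,   60, "l"),
  list("Stroop interference time",  "cognitive",            10,  120, "h"),
  list("Delayed recall",            "cognitive",             0,   15, "l"),
  list("Event-based memory",        "cognitive",             0,    8, "l"),
  list("Animal fluency",            "cognitive",             0,   40, "l"),
  list("Controlled oral word association", "cognitive",      0,   60, "l"),
  list("Immediate recall",          "cognitive",             0,   15, "l"),
  list("Mental alteration test",    "cognitive",             0,   50, "l"),
  list("Choice reaction time",      "cognitive",           400, 1500, "h"),
  list("Time-based memory",         "cognitive",             0,    4, "l"),
  list("Waist-hip ratio",           "anthropometric",       0.7, 1.2, "h"),
  list("Body mass index",           "anthropometric",      18.5,  40, "h"),
  list("Whole body BMD, T-score",   "anthropometric",       -4,  1.5, "l"),
  list("BMD, multiple body regions","anthropometric",       -4,  1.5, "l"),
  list("Appendage lean mass",       "anthropometric",       10,   35, "l"),
  list("Body fat percent",          "anthropometric",       10,   50, "h"),
  list("Adiposity, multiple body regions", "anthropometric", 10,  55, "h"),
  list("Forced vital capacity (FVC)", "spirometry",          1,    6, "l"),
  list("FEV 1/FVC ratio",           "spirometry",           0.4, 0.9, "l"),
  list("Hearing pure tone average, right", "hearing/vision", 0,   80, "h"),
  list("Hearing pure tone average, left",  "hearing/vision", 0,   80, "h"),
  list("Visual acuity, left eye",   "hearing/vision",       0.1, 1.2, "l"),
  list("Visual acuity, right eye",  "hearing/vision",       0.1, 1.2, "l"),
  list("Intraocular pressure, right", "hearing/vision",      8,   30, "h"),
  list("Intraocular pressure, left",  "hearing/vision",      8,   30, "h"),
  list("Corneal hysteresis, right", "hearing/vision",        6,   14, "l"),
  list("Corneal hysteresis, left",  "hearing/vision",        6,   14, "l"),
  list("Mean ocular perfusion pressure", "hearing/vision",  35,   60, "l"),
  list("Pulse",                     "cardiac",              50,  110, "h"),
  list("Max carotid intima thickness", "cardiac",          0.4,  1.8, "h"),
  list("ECG, QT interval",          "cardiac",             350,  500, "h"),
  list("ECG, PQ interval",          "cardiac",             120,  240, "h"),
  list("ECG, P axis",               "cardiac",               0,   90, "h"),
  list("ECG, R axis",               "cardiac",             -30,  110, "h"),
  list("ECG, T axis",               "cardiac",               0,  100, "h"),
  list("ECG, P duration",           "cardiac",              60,  140, "h"),
  list("ECG, QRS duration",         "cardiac",              70,  130, "h"),
  list("ECG diagnosis summary",     "cardiac",               0,    6, "h"),
  list("Systolic BP",               "cardiac",              95,  190, "h"),
  list("Diastolic BP",              "cardiac",              55,  110, "h"),
  list("Pulse pressure",            "cardiac",              30,   90, "h"),
  list("Carotid intima thickness, right", "cardiac",       0.4,  1.8, "h"),
  list("Carotid intima thickness, left",  "cardiac",       0.4,  1.8, "h")
)

#' Default 70-item biomarker dictionary
#'
#' The catalogue of 23 blood biomarkers and 47 examination-based tests
#' (5 physical performance, 9 cognitive, 7 anthropometric, 2 spirometry,
#' 9 hearing/vision, 15 cardiac) used by the frailty-index mortality
#' analysis. Blood items carry synthetic binary normal-range rules on
#' plausible clinical scales; examination items carry synthetic min-max
#' normalized rules. The placeholder numeric rules are suitable for
#' simulation and method exercise, not for coding real cohort data.
#'
#' @return An `fi_dictionary` with 70 entries.
#' @examples
#' d <- default_dictionary()
#' length(dictionary_items(d, "blood"))        # 23
#' length(dictionary_items(d, "examination"))  # 47
#' @export
default_dictionary <- function() {
  blood <- lapply(.blood_items, function(e)
    coding_rule(e[[1]], "blood", "blood chemistry", "binary_range",
                normal_range = c(e[[2]], e[[3]])))
  exam <- lapply(.exam_items, function(e)
    coding_rule(e[[1]], "examination", e[[2]], "normalized",
                reference_min = e[[3]], reference_max = e[[4]],
                direction = if (e[[5]] == "h") "higher_is_deficit"
                            else "lower_is_deficit"))
  fi_dictionary(c(blood, exam))
}
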