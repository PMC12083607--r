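# Cross-device melanin-index calibration and skin-tone classification.
#
# Two handheld colorimeters report melanin on different scales; the bridge is
# a log-linear calibration y = exp((x + c_offset) / c_scale), where x is the
# SkinColorCatch melanin index and y the ColorMeter-scale value on which the
# modified Eumelanin skin-tone categories are defined.

#' Construct a melanin calibration curve
#'
#' The curve maps a SkinColorCatch melanin index `x` to the ColorMeter scale
#' via `y = exp((x + c_offset) / c_scale)`. The default constants are the
#' published cross-device calibration fitted on 28 PANTONE skin-tone swatches.
#'
#' @param c_offset Additive constant on the input scale.
#' @param c_scale Divisor constant; must be positive so the conversion is
#'   strictly increasing.
#' @param r_squared Coefficient of determination of the log-linear fit, if
#'   known (computed on the `log(y)` scale).
#' @param n_swatches Number of swatch pairs behind the fit, if known.
#' @return An object of class `calibration_curve`.
#' @examples
#' curve <- calibration_curve()
#' convert_melanin(-623.18, curve) # exactly 1
#' @export
calibration_curve <- function(c_offset = 623.18, c_scale = 334.81,
                              r_squared = NA_real_, n_swatches = NA_integer_) {
  if (!is.numeric(c_scale) || length(c_scale) != 1L || c_scale <= 0) {
    abort("`c_scale` must be a single positive number.", class = "thermoroi_domain_error")
  }
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1)) {
    abort("`r_squared` must lie in [0, 1].", class = "thermoroi_domain_error")
  }
  structure(
    list(c_offset = c_offset, c_scale = c_scale,
         r_squared = r_squared, n_swatches = n_swatches),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("Melanin calibration curve: y = exp((x + ",
      format(x$c_offset), ") / ", format(x$c_scale), ")\n", sep = "")
  if (!is.na(x$r_squared)) {
    cat(sprintf("  log-scale R^2 = %.4f on %s swatch pairs\n",
                x$r_squared, format(x$n_swatches)))
  }
  invisible(x)
}

#' Convert a SkinColorCatch melanin index to the ColorMeter scale
#'
#' @param x Numeric vector of SkinColorCatch melanin indices.
#' @param curve A [calibration_curve()]; defaults to the published constants.
#' @return Numeric vector of ColorMeter-scale melanin values.
#' @export
convert_melanin <- function(x, curve = calibration_curve()) {
  stopifnot(inherits(curve, "calibration_curve"))
  exp((x + curve$c_offset) / curve$c_scale)
}

#' Invert the melanin calibration curve
#'
#' Analytic inverse of [convert_melanin()]: `x = c_scale * log(y) - c_offset`.
#'
#' @param y Numeric vector of ColorMeter-scale values; must be positive.
#' @inheritParams convert_melanin
#' @return Numeric vector of SkinColorCatch melanin indices.
#' @export
invert_melanin <- function(y, curve = calibration_curve()) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(!is.finite(y) | y <= 0)) {
    abort("`y` must be positive: the calibration is log-linear.",
          class = "thermoroi_domain_error")
  }
  curve$c_scale * log(y) - curve$c_offset
}

#' Category table for the modified Eumelanin skin-tone scale
#'
#' Six contiguous, lower-inclusive intervals on the ColorMeter melanin scale
#' with boundaries at 25, 37.5, 50, 75 and 100.
#'
#' @return A tibble with columns `label`, `lower` (inclusive) and `upper`
#'   (exclusive; `Inf` for the top category).
#' @export
eumelanin_categories <- function() {
  bounds <- c(0, 25, 37.5, 50, 75, 100, Inf)
  tibble::tibble(
    label = factor(
      c("low", "intermediate_low", "intermediate", "intermediate_mid",
        "intermediate_high", "high"),
      levels = c("low", "intermediate_low", "intermediate", "intermediate_mid",
                 "intermediate_high", "high"),
      ordered = TRUE
    ),
    lower = bounds[-length(bounds)],
    upper = bounds[-1]
  )
}

#' Classify a melanin value on the modified Eumelanin scale
#'
#' Intervals are lower-inclusive/upper-exclusive, so e.g. 37.5 falls in
#' `intermediate`, not `intermediate_low`.
#'
#' @param y Numeric vector of ColorMeter-scale melanin values (non-negative).
#' @return An ordered factor of category labels.
#' @export
classify_eumelanin <- function(y) {
  if (any(!is.finite(y) | y < 0)) {
    abort("Melanin values must be finite and non-negative.",
          class = "thermoroi_domain_error")
  }
  cats <- eumelanin_categories()
  idx <- findInterval(y, cats$lower)  # lower-inclusive by construction
  cats$label[idx]
}

#' Average triplicate swatch measurements
#'
#' Calibration swatches are measured in triplicate on each device; this
#' collapses replicates to one (x, y) pair per swatch before fitting.
#'
#' @param swatches Data frame with columns `swatch_id`, `x_scc`, `y_cm`.
#' @return A tibble with one row per swatch and mean `x_scc`, `y_cm`.
#' @export
average_swatches <- function(swatches) {
  check_columns(swatches, c("swatch_id", "x_scc", "y_cm"), "swatches")
  swatches |>
    dplyr::group_by(.data$swatch_id) |>
    dplyr::summarise(x_scc = mean(.data$x_scc), y_cm = mean(.data$y_cm),
                     .groups = "drop")
}

#' Fit the cross-device melanin calibration
#'
#' Ordinary least squares of `log(y_cm)` on `x_scc`, re-parameterised as
#' `log(y) = (x + c_offset) / c_scale`. The fit requires a positive slope
#' (the conversion must be strictly increasing) and at least three distinct
#' swatch pairs.
#'
#' @param pairs Data frame with columns `x_scc` and `y_cm` (one row per
#'   swatch; use [average_swatches()] to collapse triplicates first).
#' @return A [calibration_curve()] with `r_squared` computed on the log scale
#'   and `n_swatches` recorded.
#' @export
fit_calibration <- function(pairs) {
  check_columns(pairs, c("x_scc", "y_cm"), "pairs")
  if (nrow(pairs) < 3L) {
    abort("At least 3 swatch pairs are required to fit the calibration.",
          class = "thermoroi_input_error")
  }
  if (any(pairs$y_cm <= 0)) {
    abort("All `y_cm` must be positive: the fit is on the log scale.",
          class = "thermoroi_input_error")
  }
  if (length(unique(pairs$x_scc)) < 2L) {
    abort("Degenerate swatch set: all `x_scc` values are equal.",
          class = "thermoroi_input_error")
  }
  fit <- lm(log(y_cm) ~ x_scc, data = pairs)
  slope <- coef(fit)[["x_scc"]]
  intercept <- coef(fit)[["(Intercept)"]]
  if (slope <= 0) {
    abort("Fitted calibration is not increasing (non-positive log-slope).",
          class = "thermoroi_input_error")
  }
  ly <- log(pairs$y_cm)
  r2 <- 1 - sum(fit$residuals^2) / sum((ly - mean(ly))^2)
  calibration_curve(
    c_offset = intercept / slope,
    c_scale = 1 / slope,
    r_squared = min(1, max(0, r2)),
    n_swatches = nrow(pairs)
  )
}

#' Append converted melanin and skin-tone category to a participant table
#'
#' @param participants Data frame with a `melanin_index_scc` column holding
#'   raw SkinColorCatch indices.
#' @param curve A [calibration_curve()].
#' @return The input as a tibble with `melanin_cm` (ColorMeter scale) and
#'   `eumelanin_category` columns appended.
#' @export
add_skin_tone <- function(participants, curve = calibration_curve()) {
  check_columns(participants, "melanin_index_scc", "participants")
  participants |>
    tibble::as_tibble() |>
    dplyr::mutate(
      melanin_cm = convert_melanin(.data$melanin_index_scc, curve),
      eumelanin_category = classify_eumelanin(.data$melanin_cm)
    )
}

# shared column-presence check
check_columns <- function(df, cols, what) {
  if (!is.data.frame(df)) {
    abort(sprintf("`%s` must be a data frame.", what),
          class = "thermoroi_input_error")
  }
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("`%s` is missing column(s): %s.", what,
                  paste(missing, collapse = ", ")),
          class = "thermoroi_input_error")
  }
  invisible(df)
}
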