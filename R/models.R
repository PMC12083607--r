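# Linear mixed-effects models for camera, environment, and skin-tone effects.
#
# All models share a participant random intercept (the simplest structure
# consistent with the repeated-measures design), REML estimation, and
# Satterthwaite-approximation p-values on the fixed effects.

model_response <- function(observations,
                           response = c("roi_temp", "roi_minus_control")) {
  response <- match.arg(response)
  obs <- canonicalize_observations(observations)
  if (response == "roi_temp") {
    out <- dplyr::filter(obs, .data$region == "roi")
    if (!nrow(out)) {
      abort("No ROI rows in observations.", class = "thermoroi_input_error")
    }
    out
  } else {
    roi_minus_control(obs)
  }
}

new_thermo_model <- function(fit, response_label, model_label) {
  cf <- as.data.frame(coef(summary(fit)))
  terms <- tibble::tibble(
    term = rownames(cf),
    estimate = cf[["Estimate"]],
    std.error = cf[["Std. Error"]],
    df = if ("df" %in% names(cf)) cf[["df"]] else NA_real_,
    statistic = cf[["t value"]],
    p.value = if ("Pr(>|t|)" %in% names(cf)) cf[["Pr(>|t|)"]] else NA_real_
  )
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  # a boundary (singular) fit is a legitimate zero variance component, e.g.
  # when the participant intercept cancels in a difference response
  real_problems <- msgs[!grepl("boundary \\(singular\\)", msgs)]
  conv <- length(real_problems) == 0L && fit@optinfo$conv$opt == 0L
  structure(
    list(fit = fit, terms = terms,
         response_label = response_label, model_label = model_label,
         n_obs = nrow(fit@frame),
         n_groups = lme4::ngrps(fit)[["participant_id"]],
         converged = conv),
    class = "thermo_model"
  )
}

#' @export
print.thermo_model <- function(x, ...) {
  cat(sprintf("Linear mixed model (%s), response: %s\n",
              x$model_label, x$response_label))
  cat(sprintf("  %d observations, %d participants%s\n", x$n_obs, x$n_groups,
              if (x$converged) "" else "  [did not converge]"))
  print(as.data.frame(x$terms), digits = 4)
  invisible(x)
}

#' Tidy a fitted thermal mixed model
#'
#' @param x A `thermo_model` from [fit_camera_model()],
#'   [fit_environment_model()], or [fit_melanin_model()].
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`, `df`,
#'   `statistic`, `p.value`.
#' @method tidy thermo_model
#' @export
tidy.thermo_model <- function(x, ...) {
  x$terms
}

#' One-row model summary
#'
#' @inheritParams tidy.thermo_model
#' @return A tibble with `model`, `response`, `n_obs`, `n_groups`, `sigma`
#'   (residual SD), `sd_participant` (random-intercept SD), `converged`.
#' @method glance thermo_model
#' @export
glance.thermo_model <- function(x, ...) {
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  tibble::tibble(
    model = x$model_label,
    response = x$response_label,
    n_obs = x$n_obs,
    n_groups = x$n_groups,
    sigma = vc$sdcor[vc$grp == "Residual"],
    sd_participant = vc$sdcor[vc$grp == "participant_id"][1],
    converged = x$converged
  )
}

fit_lmm <- function(formula, data, response_label, model_label,
                    random = "(1 | participant_id)") {
  full <- stats::as.formula(paste(deparse(formula), "+", random))
  # the participant intercept legitimately vanishes on within-participant
  # difference responses, so boundary (singular) fits are routine, not errors
  fit <- withCallingHandlers(
    lmerTest::lmer(full, data = data, REML = TRUE),
    warning = function(w) {
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) {
        invokeRestart("muffleWarning")
      }
    },
    message = function(m) {
      if (grepl("singular", conditionMessage(m), ignore.case = TRUE)) {
        invokeRestart("muffleMessage")
      }
    }
  )
  new_thermo_model(fit, response_label, model_label)
}

#' Camera-effect mixed model
#'
#' Fixed effects: cooling period, camera, and their interaction; random
#' intercept per participant. On the absolute ROI response the camera term is
#' the between-camera baseline offset and the interaction is the
#' between-camera difference in measured cooling; on the ROI-minus-control
#' response the same terms describe the clinically relevant relative signal.
#'
#' @param observations Long-format observation table.
#' @param response `"roi_temp"` (absolute ROI temperature) or
#'   `"roi_minus_control"` (per-image difference).
#' @param random Random-effects term; the default participant intercept can
#'   be widened to `"(1 | participant_id) + (1 | participant_id:camera)"` for
#'   sensitivity analysis.
#' @return A `thermo_model`.
#' @export
fit_camera_model <- function(observations,
                             response = c("roi_temp", "roi_minus_control"),
                             random = "(1 | participant_id)") {
  response <- match.arg(response)
  data <- model_response(observations, response)
  if (dplyr::n_distinct(data$camera) < 2L || dplyr::n_distinct(data$period) < 2L) {
    abort("Both cameras and both periods are required for the camera model.",
          class = "thermoroi_input_error")
  }
  check_grouping(data)
  fit_lmm(median_temp_c ~ period * camera, data, response, "camera", random)
}

#' Environment-effect mixed model (reference camera only)
#'
#' Fit on E8-XT rows only. Fixed effects: cooling period, camera distance,
#' lighting, posture, plus cooling-by-distance (and optionally
#' cooling-by-lighting / cooling-by-posture) interactions; participant random
#' intercept.
#'
#' @inheritParams fit_camera_model
#' @param interactions Which factors get a cooling interaction; default
#'   distance only.
#' @return A `thermo_model`.
#' @export
fit_environment_model <- function(observations,
                                  response = c("roi_temp", "roi_minus_control"),
                                  interactions = c("distance"),
                                  random = "(1 | participant_id)") {
  response <- match.arg(response)
  data <- model_response(observations, response) |>
    dplyr::filter(.data$camera == "E8XT")
  if (!nrow(data)) {
    abort("No E8XT rows: the environment model uses the reference camera only.",
          class = "thermoroi_input_error")
  }
  for (fac in c("distance_cm", "lighting", "posture", "period")) {
    absent <- setdiff(levels(data[[fac]]), as.character(unique(data[[fac]])))
    if (length(absent)) {
      abort(sprintf("Missing %s level(s): %s.", fac,
                    paste(absent, collapse = ", ")),
            class = "thermoroi_input_error")
    }
  }
  check_grouping(data)
  inter <- intersect(interactions, c("distance", "lighting", "posture"))
  inter_terms <- c(distance = "period:distance_cm",
                   lighting = "period:lighting",
                   posture = "period:posture")[inter]
  rhs <- paste(c("period", "distance_cm", "lighting", "posture", inter_terms),
               collapse = " + ")
  fit_lmm(stats::as.formula(paste("median_temp_c ~", rhs)), data,
          response, "environment", random)
}

#' Skin-tone (melanin) mixed model
#'
#' Fixed effects: cooling period, continuous melanin (centered at the cohort
#' mean so the cooling main effect is interpretable at average skin tone),
#' and the cooling-by-melanin interaction — the term that quantifies how
#' measured temperature change varies with pigmentation. Participant random
#' intercept.
#'
#' @inheritParams fit_camera_model
#' @param center Center melanin at the cohort mean (default `TRUE`).
#' @return A `thermo_model`; the interaction term is
#'   `periodcooled:melanin_c`, in degrees Celsius per melanin unit.
#' @export
fit_melanin_model <- function(observations, response = "roi_minus_control",
                              center = TRUE,
                              random = "(1 | participant_id)") {
  response <- match.arg(response, c("roi_minus_control", "roi_temp"))
  data <- model_response(observations, response)
  check_columns(data, "melanin", "observations")
  if (anyNA(data$melanin)) {
    abort("Melanin must be present for every participant.",
          class = "thermoroi_input_error")
  }
  participant_mel <- data |>
    dplyr::distinct(.data$participant_id, .data$melanin)
  if (var(participant_mel$melanin) == 0) {
    abort("Melanin is constant across the cohort: interaction not identifiable.",
          class = "thermoroi_collinearity_error")
  }
  data$melanin_c <- data$melanin -
    if (center) mean(participant_mel$melanin) else 0
  check_grouping(data)
  fit_lmm(median_temp_c ~ period * melanin_c, data, response, "melanin", random)
}

check_grouping <- function(data) {
  if (dplyr::n_distinct(data$participant_id) < 2L) {
    abort("At least 2 participants are required for a random intercept.",
          class = "thermoroi_input_error")
  }
  invisible(data)
}

#' Temperature effect per skin-tone category
#'
#' Converts a fitted cooling-by-melanin slope (degrees C per melanin unit)
#' into the measured temperature difference spanned by whole skin-tone
#' categories, the categories being `units_per_category` melanin units wide.
#' Sign of the slope is preserved.
#'
#' @param slope_per_unit Degrees C per melanin unit.
#' @param units_per_category Melanin units per category (default 25).
#' @param n_categories Number of category steps (non-negative integer).
#' @return Degrees C spanned by `n_categories` categories.
#' @examples
#' category_effect(-0.013, 25, 1) # -0.325
#' category_effect(-0.013, 25, 3) # -0.975
#' @export
category_effect <- function(slope_per_unit, units_per_category = 25,
                            n_categories = 1) {
  if (units_per_category <= 0) {
    abort("`units_per_category` must be positive.",
          class = "thermoroi_domain_error")
  }
  if (any(n_categories < 0)) {
    abort("`n_categories` must be non-negative.",
          class = "thermoroi_domain_error")
  }
  slope_per_unit * units_per_category * n_categories
}

#' Write fitted model terms to JSON
#'
#' @param model A `thermo_model`.
#' @param path Output path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "thermo_model"))
  jsonlite::write_json(
    list(model = model$model_label, response = model$response_label,
         n_obs = model$n_obs, n_groups = model$n_groups,
         converged = model$converged,
         terms = model$terms),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(path)
}
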