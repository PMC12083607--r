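# Synthetic cohort, design, and observation generator.
#
# The generative model is the analysis model run forward: per-image median
# temperatures are drawn from the fixed-effect structure the mixed models
# estimate (cooling, camera, distance, lighting, posture, cooling x melanin)
# plus a participant random intercept and i.i.d. Gaussian residuals. Defaults
# store the published coefficient values so simulated cohorts reproduce the
# study's summary moments and the models' estimands.

#' Generative configuration for the synthetic study
#'
#' Fixed-effect defaults are the published coefficients: cooling lowers ROI
#' temperature by 4.19 degrees C on the reference camera, the ProOne reads
#' 2.43 degrees C lower at baseline and measures 1.89 degrees C less cooling
#' on absolute ROI temperature (1.04 degrees C less on the ROI-minus-control
#' difference, hence the separate control-region interaction of 0.85), ROI
#' temperature is 0.11 degrees C lower at 50 cm with a +0.20 cooling
#' interaction, lighting and posture are null, and the cooling-by-melanin
#' slope is -0.013 degrees C per melanin unit. `baseline_roi_mean` is the
#' design-pooled baseline ROI mean (the quantity the study's summary table
#' reports), so the model intercept is derived by removing the average
#' camera/distance/lighting/posture contribution. Variance components
#' (between-participant 1.7, residual 0.9 degrees C) are calibrated so
#' simulated summary-table SDs land near the reported 2.0 / 1.7 / 1.2
#' degrees C, and are conventions rather than published values.
#'
#' @param n_participants Cohort size.
#' @param melanin_mean,melanin_sd Cohort melanin distribution (classification
#'   scale), truncated at zero.
#' @param baseline_roi_mean Design-pooled baseline ROI mean, degrees C.
#' @param between_participant_sd Random-intercept SD, degrees C.
#' @param residual_sd Residual SD, degrees C.
#' @param beta_cooled Cooling main effect on ROI temperature (reference
#'   camera, 35 cm), degrees C.
#' @param beta_camera ProOne baseline offset, degrees C.
#' @param beta_cooled_x_camera Cooling-by-camera interaction on ROI
#'   temperature, degrees C.
#' @param beta_cooled_x_camera_control Cooling-by-camera interaction on the
#'   control region, degrees C; the ROI-minus-control interaction is the
#'   difference of the two.
#' @param beta_distance50 50 cm baseline offset, degrees C.
#' @param beta_cooled_x_distance Cooling-by-distance interaction (ROI only),
#'   degrees C.
#' @param beta_lighting Ring-light offset, degrees C.
#' @param beta_posture_knee_forward,beta_posture_knee_behind Posture offsets
#'   vs knees stacked, degrees C.
#' @param beta_cooled_x_melanin Cooling-by-melanin slope, degrees C per
#'   melanin unit (melanin centered at `melanin_mean`).
#' @param control_cooling_drift Cooling effect on the control region
#'   (reference camera), degrees C.
#' @param control_baseline_offset Control minus ROI baseline offset, degrees
#'   C (the ROI-minus-control baseline difference is its negative).
#' @param seed Default seed used when generator functions are called without
#'   one.
#' @return A list of class `generative_config`.
#' @export
generative_config <- function(n_participants = 35,
                              melanin_mean = 55.94,
                              melanin_sd = 13.54,
                              baseline_roi_mean = 30.8,
                              between_participant_sd = 1.7,
                              residual_sd = 0.9,
                              beta_cooled = -4.19,
                              beta_camera = -2.43,
                              beta_cooled_x_camera = 1.89,
                              beta_cooled_x_camera_control = 0.85,
                              beta_distance50 = -0.11,
                              beta_cooled_x_distance = 0.20,
                              beta_lighting = 0,
                              beta_posture_knee_forward = 0,
                              beta_posture_knee_behind = 0,
                              beta_cooled_x_melanin = -0.013,
                              control_cooling_drift = -0.2,
                              control_baseline_offset = 0.3,
                              seed = 1L) {
  if (n_participants < 2L) {
    abort("`n_participants` must be at least 2.", class = "thermoroi_domain_error")
  }
  if (melanin_sd <= 0 || between_participant_sd <= 0 || residual_sd <= 0) {
    abort("All SDs must be positive.", class = "thermoroi_domain_error")
  }
  structure(as.list(environment()), class = "generative_config")
}

#' @export
print.generative_config <- function(x, ...) {
  cat("Generative configuration:\n")
  utils::str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

#' Generate a synthetic participant cohort
#'
#' Melanin is drawn from a Normal(`melanin_mean`, `melanin_sd`) truncated to
#' positive values on the classification scale, and categorized on the
#' modified Eumelanin scale; demographics are plausible fillers and carry no
#' signal.
#'
#' @param config A [generative_config()].
#' @param seed Integer seed; generation is a pure function of
#'   `(config, seed)`.
#' @return A tibble with `participant_id`, `melanin`, `eumelanin_category`,
#'   `monk_level`, `age`, `sex`, `bmi`.
#' @export
generate_cohort <- function(config = generative_config(), seed = config$seed) {
  stopifnot(inherits(config, "generative_config"))
  set.seed(seed)
  n <- config$n_participants
  melanin <- rnorm(n, config$melanin_mean, config$melanin_sd)
  while (any(melanin <= 0)) {  # truncation; essentially never at defaults
    bad <- melanin <= 0
    melanin[bad] <- rnorm(sum(bad), config$melanin_mean, config$melanin_sd)
  }
  category <- classify_eumelanin(melanin)
  tibble::tibble(
    participant_id = sprintf("P%03d", seq_len(n)),
    melanin = melanin,
    eumelanin_category = category,
    monk_level = pmin(10L, pmax(1L, as.integer(round(melanin / 12)))),
    age = sample(18:73, n, replace = TRUE),
    sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.6, 0.4)),
    bmi = round(rnorm(n, 27, 4.5), 1)
  )
}

#' Generate the repeated-measures imaging design
#'
#' Full factorial of 2 lightings x 2 distances x 3 postures = 12 imaging
#' conditions, imaged at baseline and after cooling with each of two cameras:
#' 48 image rows per participant. The condition order is randomized per
#' participant and repeated identically for the second camera, matching the
#' study protocol; camera order is randomized per participant.
#'
#' @inheritParams generate_cohort
#' @return A tibble with one row per image: `image_id`, `participant_id`,
#'   `camera`, `camera_order`, `period`, `condition_order`, `lighting`,
#'   `distance_cm`, `posture`.
#' @export
generate_design <- function(config = generative_config(), seed = config$seed) {
  stopifnot(inherits(config, "generative_config"))
  set.seed(seed + 1L)
  conditions <- tidyr::expand_grid(
    lighting = LIGHTING_LEVELS,
    distance_cm = DISTANCE_LEVELS,
    posture = POSTURE_LEVELS
  )
  per_participant <- function(pid) {
    order_idx <- sample.int(nrow(conditions))
    cameras <- sample(CAMERA_LEVELS)
    purrr::map_dfr(seq_along(cameras), function(ci) {
      purrr::map_dfr(PERIOD_LEVELS, function(per) {
        cond <- conditions[order_idx, ]
        cond$condition_order <- seq_len(nrow(cond))
        cond$camera <- cameras[ci]
        cond$camera_order <- ci
        cond$period <- per
        cond
      })
    }) |>
      dplyr::mutate(
        participant_id = pid,
        image_id = sprintf("%s_%s_%s_c%02d", pid, .data$camera, .data$period,
                           .data$condition_order)
      )
  }
  ids <- sprintf("P%03d", seq_len(config$n_participants))
  purrr::map_dfr(ids, per_participant) |>
    dplyr::select("image_id", "participant_id", "camera", "camera_order",
                  "period", "condition_order", "lighting", "distance_cm",
                  "posture") |>
    canonicalize_observations()
}

# model intercept for the reference cell (E8XT, baseline, 35 cm, ambient,
# stacked): baseline_roi_mean is the design-pooled baseline mean, so the
# average design contribution is removed
roi_intercept <- function(config) {
  config$baseline_roi_mean -
    0.5 * config$beta_camera -
    0.5 * config$beta_distance50 -
    0.5 * config$beta_lighting -
    (config$beta_posture_knee_forward + config$beta_posture_knee_behind) / 3
}

#' Generate per-image median-temperature observations
#'
#' Runs the generative fixed-effect structure forward for both regions of
#' every design row, adding a shared participant random intercept and
#' i.i.d. Gaussian residuals. The ROI receives the cooling, camera
#' interaction, distance interaction, and cooling-by-melanin terms; the
#' control region receives the shared baseline terms plus its own (smaller)
#' cooling drift and cooling-by-camera interaction.
#'
#' @param cohort Participant table from [generate_cohort()].
#' @param design Design table from [generate_design()].
#' @inheritParams generate_cohort
#' @return A long-format observation tibble, one row per image x region.
#' @export
generate_observations <- function(cohort, design,
                                  config = generative_config(),
                                  seed = config$seed) {
  stopifnot(inherits(config, "generative_config"))
  set.seed(seed + 2L)
  u <- setNames(rnorm(nrow(cohort), 0, config$between_participant_sd),
                cohort$participant_id)
  base <- design |>
    dplyr::inner_join(dplyr::select(cohort, "participant_id", "melanin",
                                    "eumelanin_category"),
                      by = "participant_id") |>
    dplyr::mutate(
      cooled = as.numeric(.data$period == "cooled"),
      proone = as.numeric(.data$camera == "ProOne"),
      d50 = as.numeric(.data$distance_cm == "50"),
      ring = as.numeric(.data$lighting == "ring"),
      kf = as.numeric(.data$posture == "knee_forward"),
      kb = as.numeric(.data$posture == "knee_behind"),
      mel_c = .data$melanin - config$melanin_mean,
      shared = roi_intercept(config) + unname(u[.data$participant_id]) +
        config$beta_camera * .data$proone +
        config$beta_distance50 * .data$d50 +
        config$beta_lighting * .data$ring +
        config$beta_posture_knee_forward * .data$kf +
        config$beta_posture_knee_behind * .data$kb,
      mu_roi = .data$shared +
        config$beta_cooled * .data$cooled +
        config$beta_cooled_x_camera * .data$cooled * .data$proone +
        config$beta_cooled_x_distance * .data$cooled * .data$d50 +
        config$beta_cooled_x_melanin * .data$cooled * .data$mel_c,
      mu_control = .data$shared + config$control_baseline_offset +
        config$control_cooling_drift * .data$cooled +
        config$beta_cooled_x_camera_control * .data$cooled * .data$proone
    )
  long <- dplyr::bind_rows(
    dplyr::mutate(base, region = "roi", mu = .data$mu_roi),
    dplyr::mutate(base, region = "control", mu = .data$mu_control)
  )
  long$median_temp_c <- long$mu + rnorm(nrow(long), 0, config$residual_sd)
  long |>
    dplyr::mutate(pixel_count = NA_integer_, relocated = FALSE) |>
    dplyr::select("participant_id", "image_id", "camera", "period",
                  "lighting", "distance_cm", "posture", "region",
                  "median_temp_c", "pixel_count", "relocated", "melanin",
                  "eumelanin_category") |>
    canonicalize_observations()
}

#' Generate a full synthetic study (cohort, design, observations)
#'
#' @inheritParams generate_cohort
#' @return A list with `cohort`, `design`, `observations`, and the `config`.
#' @export
generate_study <- function(config = generative_config(), seed = config$seed) {
  cohort <- generate_cohort(config, seed)
  design <- generate_design(config, seed)
  observations <- generate_observations(cohort, design, config, seed)
  list(cohort = cohort, design = design, observations = observations,
       config = config)
}

#' Analytic marginal estimands implied by a generative configuration
#'
#' The camera and melanin models omit the distance/lighting/posture terms, so
#' under the balanced design their coefficients estimate marginal
#' (design-averaged) combinations of the generative betas. This returns those
#' closed-form values — the ground truth that parameter-recovery checks
#' compare fitted coefficients against.
#'
#' @param config A [generative_config()].
#' @return A named list of expected coefficients and summary means.
#' @export
expected_effects <- function(config = generative_config()) {
  stopifnot(inherits(config, "generative_config"))
  b <- config
  mean_posture <- (b$beta_posture_knee_forward + b$beta_posture_knee_behind) / 3
  camera_roi_cooled <- b$beta_cooled + 0.5 * b$beta_cooled_x_distance
  camera_diff_cooled <- camera_roi_cooled - b$control_cooling_drift
  diff_interaction <- b$beta_cooled_x_camera - b$beta_cooled_x_camera_control
  list(
    camera_roi_camera = b$beta_camera,
    camera_roi_cooled = camera_roi_cooled,
    camera_roi_interaction = b$beta_cooled_x_camera,
    camera_diff_camera = 0,
    camera_diff_cooled = camera_diff_cooled,
    camera_diff_interaction = diff_interaction,
    env_roi_cooled = b$beta_cooled,
    env_roi_distance50 = b$beta_distance50,
    env_roi_cooled_x_distance = b$beta_cooled_x_distance,
    env_roi_lighting = b$beta_lighting,
    melanin_diff_cooled = camera_diff_cooled +
      0.5 * diff_interaction,
    melanin_diff_interaction = b$beta_cooled_x_melanin,
    mean_baseline_roi = b$baseline_roi_mean,
    mean_roi_cooling_magnitude = -(b$beta_cooled +
                                     0.5 * b$beta_cooled_x_camera +
                                     0.5 * b$beta_cooled_x_distance),
    mean_baseline_diff = -b$control_baseline_offset,
    mean_cooled_diff = -b$control_baseline_offset + b$beta_cooled +
      0.5 * b$beta_cooled_x_camera + 0.5 * b$beta_cooled_x_distance -
      b$control_cooling_drift - 0.5 * b$beta_cooled_x_camera_control
  )
}
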