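# Long-format observation table and descriptive cooling summaries.

PERIOD_LEVELS <- c("baseline", "cooled")
CAMERA_LEVELS <- c("E8XT", "ProOne")
LIGHTING_LEVELS <- c("ambient", "ring")
DISTANCE_LEVELS <- c(35, 50)
POSTURE_LEVELS <- c("stacked", "knee_forward", "knee_behind")

#' Coerce observation factor columns to their canonical levels
#'
#' Reference levels (first): E8XT, baseline, 35 cm, ambient, stacked — chosen
#' so model coefficients read directly as the ProOne offset, the cooling
#' effect, the 50 cm offset, etc.
#'
#' @param observations Long-format observation data frame.
#' @return The observations as a tibble with canonical factor coding.
#' @export
canonicalize_observations <- function(observations) {
  obs <- tibble::as_tibble(observations)
  if ("camera" %in% names(obs))
    obs$camera <- factor(as.character(obs$camera), levels = CAMERA_LEVELS)
  if ("period" %in% names(obs))
    obs$period <- factor(as.character(obs$period), levels = PERIOD_LEVELS)
  if ("lighting" %in% names(obs))
    obs$lighting <- factor(as.character(obs$lighting), levels = LIGHTING_LEVELS)
  if ("distance_cm" %in% names(obs))
    obs$distance_cm <- factor(as.numeric(as.character(obs$distance_cm)),
                              levels = DISTANCE_LEVELS)
  if ("posture" %in% names(obs))
    obs$posture <- factor(as.character(obs$posture), levels = POSTURE_LEVELS)
  bad <- vapply(intersect(names(obs),
                          c("camera", "period", "lighting", "distance_cm", "posture")),
                function(cl) anyNA(obs[[cl]]), logical(1))
  if (any(bad)) {
    abort(sprintf("Unrecognized level(s) in column(s): %s.",
                  paste(names(bad)[bad], collapse = ", ")),
          class = "thermoroi_input_error")
  }
  obs
}

#' Assemble the long-format analysis table
#'
#' Joins per-image region summaries to the imaging-design table (by
#' `image_id`) and the participant table (by `participant_id`), yielding one
#' row per image x region with melanin and skin-tone columns attached.
#'
#' @param region_summaries Data frame with columns `image_id`, `region`,
#'   `median_temp_c`, `pixel_count` (and optionally `relocated`).
#' @param participants Data frame with `participant_id` and `melanin` (plus
#'   any skin-tone columns to carry along, e.g. `eumelanin_category`).
#' @param design Data frame with one row per image: `image_id`,
#'   `participant_id`, `camera`, `period`, `lighting`, `distance_cm`,
#'   `posture`.
#' @return A tibble of temperature observations, canonically coded.
#' @export
build_long_table <- function(region_summaries, participants, design) {
  check_columns(region_summaries, c("image_id", "region", "median_temp_c"),
                "region_summaries")
  check_columns(participants, c("participant_id", "melanin"), "participants")
  check_columns(design,
                c("image_id", "participant_id", "camera", "period",
                  "lighting", "distance_cm", "posture"), "design")
  if (nrow(region_summaries) == 0L) {
    return(tibble::tibble())
  }
  if (anyDuplicated(design$image_id)) {
    abort("Duplicate `image_id` in design table.", class = "thermoroi_join_error")
  }
  if (anyDuplicated(participants$participant_id)) {
    abort("Duplicate `participant_id` in participant table.",
          class = "thermoroi_join_error")
  }
  if (anyDuplicated(region_summaries[c("image_id", "region")])) {
    abort("Duplicate image x region rows in region summaries.",
          class = "thermoroi_join_error")
  }
  unmatched <- setdiff(region_summaries$image_id, design$image_id)
  if (length(unmatched)) {
    abort(sprintf("Region summaries reference unknown image_id(s): %s.",
                  paste(utils::head(unmatched, 5), collapse = ", ")),
          class = "thermoroi_join_error")
  }
  out <- region_summaries |>
    dplyr::inner_join(design, by = "image_id") |>
    dplyr::inner_join(participants, by = "participant_id")
  if (nrow(out) != nrow(region_summaries)) {
    abort("Join dropped rows: participant table does not cover all images.",
          class = "thermoroi_join_error")
  }
  canonicalize_observations(out) |>
    dplyr::relocate("participant_id", "image_id", "camera", "period",
                    "lighting", "distance_cm", "posture", "region",
                    "median_temp_c")
}

# per-image ROI - control differences, one row per image
roi_minus_control <- function(observations) {
  obs <- canonicalize_observations(observations)
  check_columns(obs, c("region", "median_temp_c"), "observations")
  keys <- intersect(
    c("participant_id", "image_id", "camera", "period", "lighting",
      "distance_cm", "posture", "melanin", "eumelanin_category"),
    names(obs))
  wide <- obs |>
    dplyr::select(dplyr::all_of(c(keys, "region", "median_temp_c"))) |>
    tidyr::pivot_wider(names_from = "region", values_from = "median_temp_c")
  if (!all(c("roi", "control") %in% names(wide))) {
    abort("Both 'roi' and 'control' regions are required.",
          class = "thermoroi_input_error")
  }
  wide |>
    dplyr::filter(!is.na(.data$roi), !is.na(.data$control)) |>
    dplyr::mutate(median_temp_c = .data$roi - .data$control,
                  region = "roi_minus_control")
}

# within-condition cooled - baseline changes, one row per paired condition
period_change <- function(values) {
  keys <- intersect(
    c("participant_id", "camera", "lighting", "distance_cm", "posture",
      "region", "melanin", "eumelanin_category"),
    names(values))
  wide <- values |>
    dplyr::select(dplyr::all_of(c(keys, "period", "median_temp_c"))) |>
    tidyr::pivot_wider(names_from = "period", values_from = "median_temp_c")
  if (!all(PERIOD_LEVELS %in% names(wide))) {
    abort("Both baseline and cooled periods are required.",
          class = "thermoroi_insufficient_error")
  }
  wide |>
    dplyr::filter(!is.na(.data$baseline), !is.na(.data$cooled)) |>
    dplyr::mutate(change = .data$cooled - .data$baseline)
}

# one-sample t robust to zero-variance input (t.test() refuses constant data;
# the exactly-null case must report statistic 0, p = 1)
safe_one_sample_t <- function(x, mu = 0) {
  if (sd(x) == 0) {
    m <- mean(x) - mu
    return(list(statistic = if (m == 0) 0 else sign(m) * Inf,
                p.value = if (m == 0) 1 else 0))
  }
  tt <- t.test(x, mu = mu)
  list(statistic = unname(tt$statistic), p.value = tt$p.value)
}

one_row_summary <- function(x, region, measure, test = NA_character_,
                            statistic = NA_real_, p_value = NA_real_) {
  tibble::tibble(region = region, measure = measure,
                 mean = mean(x), sd = sd(x), n = length(x),
                 statistic = statistic, p_value = p_value,
                 test = test)
}

#' Descriptive cooling summary with t-tests
#'
#' Reproduces the study-style summary table: per-region baseline and cooled
#' means (+/- SD), within-region change (cooled minus baseline) tested
#' against zero with a one-sample t-test, and the per-image ROI-minus-control
#' difference at each period tested with a paired t-test of ROI vs control.
#'
#' @param observations Long-format observation table (see
#'   [build_long_table()]).
#' @return A tibble with columns `region`, `measure`, `mean`, `sd`, `n`,
#'   `statistic`, `p_value`, `test`.
#' @export
summarize_cooling <- function(observations) {
  obs <- canonicalize_observations(observations)
  check_columns(obs, c("region", "period", "median_temp_c"), "observations")
  rows <- list()
  for (reg in c("roi", "control")) {
    sub <- dplyr::filter(obs, .data$region == reg)
    if (!nrow(sub)) next
    for (per in PERIOD_LEVELS) {
      vals <- sub$median_temp_c[sub$period == per]
      if (length(vals)) {
        rows[[length(rows) + 1L]] <- one_row_summary(vals, reg, per)
      }
    }
    chg <- period_change(sub)
    if (nrow(chg) < 2L) {
      abort(sprintf("No complete baseline/cooled pairs for region '%s'.", reg),
            class = "thermoroi_insufficient_error")
    }
    tt <- safe_one_sample_t(chg$change)
    rows[[length(rows) + 1L]] <- one_row_summary(
      chg$change, reg, "cooled_minus_baseline",
      test = "one_sample_t", statistic = tt$statistic,
      p_value = tt$p.value)
  }
  diffs <- roi_minus_control(obs)
  for (per in PERIOD_LEVELS) {
    sub <- dplyr::filter(diffs, .data$period == per)
    if (!nrow(sub)) next
    tt <- safe_one_sample_t(sub$roi - sub$control)
    rows[[length(rows) + 1L]] <- one_row_summary(
      sub$median_temp_c, "roi_minus_control", per,
      test = "paired_t", statistic = tt$statistic,
      p_value = tt$p.value)
  }
  chg <- period_change(diffs)
  tt <- safe_one_sample_t(chg$change)
  rows[[length(rows) + 1L]] <- one_row_summary(
    chg$change, "roi_minus_control", "cooled_minus_baseline",
    test = "one_sample_t", statistic = tt$statistic,
    p_value = tt$p.value)
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cooling_summary", class(out))
  out
}

#' Write / read the long-format observations CSV
#'
#' @param observations Observation tibble.
#' @param path CSV path.
#' @return `read_observations()` returns the canonically coded tibble.
#' @export
write_observations <- function(observations, path) {
  utils::write.csv(observations, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  canonicalize_observations(utils::read.csv(path))
}
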