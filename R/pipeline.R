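# Pipeline orchestration: annotate -> register -> extract -> summarize -> fit.

#' Pipeline configuration
#'
#' @param direction Control-region displacement direction in `(col, row)`;
#'   one of `c(-1, 0)` or `c(1, 0)` (the rule fixes the axis, framing fixes
#'   the sign).
#' @param width_rule Offset width rule passed to [make_control_region()].
#' @param interactions Cooling interactions for the environment model.
#' @param random Random-effects term for all models.
#' @param models Which mixed models to fit.
#' @param seed Seed recorded in the run log (the extraction itself is
#'   deterministic).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(direction = c(-1, 0),
                            width_rule = c("control", "roi"),
                            interactions = "distance",
                            random = "(1 | participant_id)",
                            models = c("camera", "environment", "melanin"),
                            seed = 1L) {
  width_rule <- match.arg(width_rule)
  if (!(length(direction) == 2L && all(direction %in% c(-1, 0, 1)) &&
        sum(direction != 0) == 1L)) {
    abort("`direction` must be a signed unit axis, e.g. c(-1, 0).",
          class = "thermoroi_config_error")
  }
  bad <- setdiff(interactions, c("distance", "lighting", "posture"))
  if (length(bad)) {
    abort(sprintf("Unknown interaction(s): %s.", paste(bad, collapse = ", ")),
          class = "thermoroi_config_error")
  }
  bad <- setdiff(models, c("camera", "environment", "melanin"))
  if (length(bad)) {
    abort(sprintf("Unknown model(s): %s.", paste(bad, collapse = ", ")),
          class = "thermoroi_config_error")
  }
  structure(list(direction = direction, width_rule = width_rule,
                 interactions = interactions, random = random,
                 models = models, seed = seed),
            class = "pipeline_config")
}

# tiny polynomial string hash for the run log
config_hash <- function(config) {
  s <- utf8ToInt(paste(deparse(unclass(config)), collapse = ""))
  h <- 17
  for (ch in s) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Extract region summaries from one annotated image pair
#'
#' Registers the optical annotations into the thermal frame, fits the
#' cooling ROI ellipse, constructs (and if necessary relocates) the control
#' region, and extracts both median temperatures.
#'
#' @param thermal Thermal matrix, degrees C.
#' @param annotations List with `pairs` (correspondence tibble),
#'   `roi_boundary` (optical-frame clicks), and optional `exclusions`
#'   (polygons, thermal frame).
#' @param config A [pipeline_config()].
#' @return A two-row tibble (`roi`, `control`) with `median_temp_c`,
#'   `pixel_count`, `relocated`, plus the fitted `roi`/`control` ellipses and
#'   registration RMS as attributes.
#' @export
extract_image_regions <- function(thermal, annotations,
                                  config = pipeline_config()) {
  transform <- estimate_affine(annotations$pairs)
  boundary_thermal <- warp_annotations(transform, annotations$roi_boundary)
  roi <- fit_ellipse(boundary_thermal)
  shape <- dim(thermal)
  excl <- if (length(annotations$exclusions)) {
    polygon_mask(annotations$exclusions, shape)
  } else NULL
  pair <- region_pair(roi, shape, exclusion_mask = excl,
                      direction = config$direction,
                      width_rule = config$width_rule)
  out <- dplyr::bind_rows(
    extract_region_median(thermal, pair$roi, "roi"),
    extract_region_median(thermal, pair$control, "control")
  )
  out$relocated <- pair$relocated
  attr(out, "roi") <- pair$roi
  attr(out, "control") <- pair$control
  attr(out, "registration_rms") <- attr(transform, "residual_rms")
  out
}

#' Run the full analysis pipeline on a study bundle
#'
#' Reads a bundle directory (see [generate_study_bundle()]). If an `images/`
#' subdirectory is present, every design row's image is registered and its
#' regions extracted; otherwise `observations.csv` is used directly. Then the
#' cooling summary and the requested mixed models are computed, and
#' `observations.csv`, `summary.csv`, per-model JSON, a text report, and a
#' run log are written to `output_dir`. Given identical inputs and config the
#' outputs are identical (the log's timestamp aside).
#'
#' @param input_dir Bundle directory.
#' @param output_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @return A list with `observations`, `summary`, `models`, and `log`.
#' @export
run_pipeline <- function(input_dir, output_dir,
                         config = pipeline_config()) {
  log <- character()
  say <- function(fmt, ...) {
    log <<- c(log, sprintf(fmt, ...))
    invisible(NULL)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "thermoroi_pipeline_error")
    })
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  say("thermoroi pipeline, package %s, R %s",
      as.character(utils::packageVersion("thermoroi")),
      paste(R.version$major, R.version$minor, sep = "."))
  say("config hash %s", config_hash(config))

  participants <- stage("load", {
    check_bundle_file <- function(f) {
      p <- file.path(input_dir, f)
      if (!file.exists(p)) stop(sprintf("missing %s", f), call. = FALSE)
      p
    }
    utils::read.csv(check_bundle_file("participants.csv"))
  })
  design <- stage("load", canonicalize_observations(
    utils::read.csv(file.path(input_dir, "design.csv"))))

  img_root <- file.path(input_dir, "images")
  if (dir.exists(img_root)) {
    say("stage extract: %d images", nrow(design))
    summaries <- stage("extract", {
      purrr::map_dfr(seq_len(nrow(design)), function(i) {
        id <- design$image_id[i]
        d <- file.path(img_root, id)
        ann_path <- file.path(d, "annotations.json")
        th_path <- file.path(d, "thermal.csv")
        if (!file.exists(ann_path) || !file.exists(th_path)) {
          stop(sprintf("image '%s': missing annotations or thermal data", id),
               call. = FALSE)
        }
        res <- extract_image_regions(read_thermal_csv(th_path),
                                     read_annotations_json(ann_path), config)
        if (res$relocated[1]) say("image %s: control region relocated", id)
        dplyr::mutate(res, image_id = id)
      })
    })
    observations <- stage("assemble",
                          build_long_table(summaries, participants, design))
  } else {
    say("stage extract: skipped (tabular bundle)")
    observations <- stage("load", read_observations(
      file.path(input_dir, "observations.csv")))
  }

  say("stage summarize: %d observation rows", nrow(observations))
  summary_tbl <- stage("summarize", summarize_cooling(observations))

  models <- list()
  if ("camera" %in% config$models) {
    say("stage fit: camera model")
    models$camera_roi <- stage("fit", fit_camera_model(
      observations, "roi_temp", random = config$random))
    models$camera_diff <- stage("fit", fit_camera_model(
      observations, "roi_minus_control", random = config$random))
  }
  if ("environment" %in% config$models) {
    say("stage fit: environment model")
    models$environment_roi <- stage("fit", fit_environment_model(
      observations, "roi_temp", interactions = config$interactions,
      random = config$random))
  }
  if ("melanin" %in% config$models) {
    say("stage fit: melanin model")
    models$melanin_diff <- stage("fit", fit_melanin_model(
      observations, "roi_minus_control", random = config$random))
  }

  stage("write", {
    write_observations(observations, file.path(output_dir, "observations.csv"))
    utils::write.csv(summary_tbl, file.path(output_dir, "summary.csv"),
                     row.names = FALSE)
    for (nm in names(models)) {
      write_model_json(models[[nm]],
                       file.path(output_dir, paste0("model_", nm, ".json")))
    }
    writeLines(format_report(summary_tbl, models),
               file.path(output_dir, "report.txt"))
    writeLines(c(log, sprintf("finished %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
               file.path(output_dir, "run_log.txt"))
  })
  list(observations = observations, summary = summary_tbl, models = models,
       log = log)
}

format_report <- function(summary_tbl, models) {
  lines <- c("Cooling summary (median temperature, degrees C)",
             "===============================================")
  fmt <- function(r) {
    sprintf("%-18s %-24s %7.2f +/- %.2f (n = %d)%s", r$region, r$measure,
            r$mean, r$sd, r$n,
            if (!is.na(r$test)) sprintf("  [%s t = %.2f, p = %.3g]",
                                        r$test, r$statistic, r$p_value)
            else "")
  }
  lines <- c(lines, vapply(seq_len(nrow(summary_tbl)),
                           function(i) fmt(summary_tbl[i, ]), character(1)))
  for (nm in names(models)) {
    m <- models[[nm]]
    lines <- c(lines, "",
               sprintf("Mixed model '%s' (response %s, %d obs, %d participants)",
                       nm, m$response_label, m$n_obs, m$n_groups))
    t <- m$terms
    lines <- c(lines, vapply(seq_len(nrow(t)), function(i) {
      sprintf("  %-28s %8.3f (SE %.3f), p = %.3g",
              t$term[i], t$estimate[i], t$std.error[i], t$p.value[i])
    }, character(1)))
  }
  lines
}
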