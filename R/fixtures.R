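# Paired optical/thermal image fixtures with known ground truth.
#
# Each fixture emulates one study image pair: an optical photo showing the
# drawn marker circle and a fiducial card, and a radiometric thermal matrix
# with a Gaussian cold spot where the cooling stone sat. The true affine
# between the frames, the circle, and the cold-spot parameters are all
# stored, so registration, ellipse fitting, and extraction can be validated
# end to end.

#' Specification of a synthetic optical/thermal image pair
#'
#' @param optical_shape,thermal_shape `(rows, cols)` of the two frames.
#' @param true_affine [affine_transform()] mapping optical to thermal pixel
#'   coordinates; default is the 0.5x scaling of a half-resolution thermal
#'   sensor.
#' @param marker_center,marker_radius Drawn skin circle, optical frame,
#'   pixels.
#' @param card_corners 4x2 matrix of fiducial card corners, optical frame.
#' @param coldspot_depth Peak temperature depression, degrees C (0 for a
#'   baseline image).
#' @param coldspot_sd Spatial SD of the Gaussian cold spot, thermal pixels.
#' @param background_temp Skin background temperature, degrees C.
#' @param noise_sd Thermal pixel noise SD, degrees C (i.i.d. Gaussian — a
#'   simplification; real microbolometer noise is spatially correlated).
#' @param optical_skin_rgb Length-3 RGB in `[0, 1]` for the skin background.
#' @param n_boundary Number of marker-circle boundary clicks to emit.
#' @param annotation_sd SD of annotation click jitter, optical pixels.
#' @return A list of class `image_fixture_spec`. The cold spot is centered on
#'   the marker circle's center (mapped into the thermal frame), so it always
#'   lies inside the marker circle.
#' @export
image_fixture_spec <- function(optical_shape = c(240, 320),
                               thermal_shape = c(120, 160),
                               true_affine = affine_transform(
                                 cbind(0.5 * diag(2), c(0, 0))),
                               marker_center = c(190, 120),
                               marker_radius = 42,
                               card_corners = rbind(c(30, 30), c(110, 30),
                                                    c(110, 82), c(30, 82)),
                               coldspot_depth = 3.5,
                               coldspot_sd = 30,
                               background_temp = 30.8,
                               noise_sd = 0.1,
                               optical_skin_rgb = c(0.76, 0.57, 0.46),
                               n_boundary = 8,
                               annotation_sd = 0.2) {
  if (coldspot_depth < 0 || coldspot_sd <= 0 || noise_sd < 0) {
    abort("Invalid cold-spot or noise parameters.",
          class = "thermoroi_domain_error")
  }
  if (n_boundary < 5L) {
    abort("At least 5 boundary clicks are required downstream.",
          class = "thermoroi_domain_error")
  }
  spec <- as.list(environment())
  spec$card_corners <- as_point_matrix(card_corners)
  structure(spec, class = "image_fixture_spec")
}

#' Generate one synthetic optical/thermal image pair with annotations
#'
#' @param spec An [image_fixture_spec()].
#' @param seed Integer seed; the pair is a pure function of `(spec, seed)`.
#' @return A list with `optical` (rows x cols x 3 array in `[0, 1]`),
#'   `thermal` (matrix, degrees C), `annotations` (fiducial correspondences,
#'   ROI boundary clicks, empty exclusion list), and `truth` (the marker
#'   circle in both frames, cold-spot parameters, true affine).
#' @export
generate_image_pair <- function(spec = image_fixture_spec(), seed = 1L) {
  stopifnot(inherits(spec, "image_fixture_spec"))
  set.seed(seed)
  ro <- spec$optical_shape[1]; co <- spec$optical_shape[2]
  rt <- spec$thermal_shape[1]; ct <- spec$thermal_shape[2]

  # optical render: skin background, dark marker ring, light card
  cc <- base::matrix(0:(co - 1), ro, co, byrow = TRUE)
  rr <- base::matrix(0:(ro - 1), ro, co)
  dist_marker <- sqrt((cc - spec$marker_center[1])^2 +
                        (rr - spec$marker_center[2])^2)
  ring <- abs(dist_marker - spec$marker_radius) <= 1.5
  card <- cc >= min(spec$card_corners[, 1]) & cc <= max(spec$card_corners[, 1]) &
    rr >= min(spec$card_corners[, 2]) & rr <= max(spec$card_corners[, 2])
  optical <- array(0, dim = c(ro, co, 3))
  for (ch in 1:3) {
    plane <- spec$optical_skin_rgb[ch] + rnorm(ro * co, 0, 0.02)
    plane[card] <- 0.92
    plane[ring] <- 0.12
    optical[, , ch] <- pmin(1, pmax(0, plane))
  }

  # thermal render: background minus Gaussian cold spot, plus pixel noise
  cold_center <- as_point_matrix(
    apply_affine(spec$true_affine, rbind(spec$marker_center)))[1, ]
  tc <- base::matrix(0:(ct - 1), rt, ct, byrow = TRUE)
  tr <- base::matrix(0:(rt - 1), rt, ct)
  depress <- spec$coldspot_depth *
    exp(-((tc - cold_center[1])^2 + (tr - cold_center[2])^2) /
          (2 * spec$coldspot_sd^2))
  thermal <- spec$background_temp - depress +
    base::matrix(rnorm(rt * ct, 0, spec$noise_sd), rt, ct)

  # annotations: fiducial correspondences + jittered marker-boundary clicks
  corners_thermal <- apply_affine(spec$true_affine, spec$card_corners)
  angles <- sort(runif(spec$n_boundary, 0, 2 * pi))
  boundary <- tibble::tibble(
    col = spec$marker_center[1] + spec$marker_radius * cos(angles) +
      rnorm(spec$n_boundary, 0, spec$annotation_sd),
    row = spec$marker_center[2] + spec$marker_radius * sin(angles) +
      rnorm(spec$n_boundary, 0, spec$annotation_sd)
  )
  annotations <- list(
    pairs = tibble::tibble(
      source_col = spec$card_corners[, 1],
      source_row = spec$card_corners[, 2],
      target_col = corners_thermal$col,
      target_row = corners_thermal$row
    ),
    roi_boundary = boundary,
    exclusions = list()
  )
  marker_thermal <- as_point_matrix(
    apply_affine(spec$true_affine, rbind(spec$marker_center)))[1, ]
  scale_factor <- sqrt(abs(det(spec$true_affine$matrix[, 1:2])))
  truth <- list(
    marker_center_optical = spec$marker_center,
    marker_radius_optical = spec$marker_radius,
    marker_center_thermal = marker_thermal,
    marker_radius_thermal = spec$marker_radius * scale_factor,
    coldspot_center_thermal = cold_center,
    coldspot_depth = spec$coldspot_depth,
    coldspot_sd = spec$coldspot_sd,
    background_temp = spec$background_temp,
    affine = spec$true_affine$matrix
  )
  list(optical = optical, thermal = thermal, annotations = annotations,
       truth = truth)
}

#' Analytic mean Gaussian depression over an elliptical mask
#'
#' Averages the cold-spot model `depth * exp(-d^2 / (2 sd^2))` over the
#' pixel centers of a rasterized ellipse — the independent oracle the
#' extracted ROI-minus-control contrast is checked against.
#'
#' @param e A [roi_ellipse()].
#' @param image_shape `(rows, cols)`.
#' @param center Cold-spot center `(col, row)`.
#' @param depth Peak depression, degrees C.
#' @param sd Spatial SD, pixels.
#' @return Mean depression over the mask, degrees C.
#' @export
mean_gaussian_depression <- function(e, image_shape, center, depth, sd) {
  mask <- rasterize_ellipse(e, image_shape)
  idx <- which(mask, arr.ind = TRUE)
  cols0 <- idx[, 2] - 1; rows0 <- idx[, 1] - 1
  mean(depth * exp(-((cols0 - center[1])^2 + (rows0 - center[2])^2) /
                     (2 * sd^2)))
}

write_annotations_json <- function(annotations, path) {
  jsonlite::write_json(
    list(
      pairs = purrr::pmap(annotations$pairs, function(source_col, source_row,
                                                      target_col, target_row) {
        list(optical = c(source_col, source_row),
             thermal = c(target_col, target_row))
      }),
      roi_boundary = purrr::map2(annotations$roi_boundary$col,
                                 annotations$roi_boundary$row, c),
      exclusions = annotations$exclusions
    ),
    path, digits = NA, auto_unbox = FALSE
  )
  invisible(path)
}

read_annotations_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  pairs <- purrr::map_dfr(doc$pairs, function(p) {
    tibble::tibble(source_col = p$optical[[1]], source_row = p$optical[[2]],
                   target_col = p$thermal[[1]], target_row = p$thermal[[2]])
  })
  boundary <- purrr::map_dfr(doc$roi_boundary, function(p) {
    tibble::tibble(col = p[[1]], row = p[[2]])
  })
  exclusions <- purrr::map(doc$exclusions, function(poly) {
    do.call(rbind, purrr::map(poly, ~ c(.x[[1]], .x[[2]])))
  })
  list(pairs = pairs, roi_boundary = boundary, exclusions = exclusions)
}

#' Write a synthetic study bundle to disk
#'
#' Emits `participants.csv`, `design.csv`, and `observations.csv`; with
#' `write_images = TRUE` also an `images/<image_id>/` directory per image
#' holding `optical.png`, `thermal.csv` (and optionally a centi-Kelvin
#' `thermal.tif`), `annotations.json`, and `truth.json`. Image-mode bundles
#' render a cold spot only in cooled-period images.
#'
#' @param dir Output directory (created if needed).
#' @param config A [generative_config()]; for image bundles keep
#'   `n_participants` small.
#' @param seed Integer seed.
#' @param write_images Render per-image fixtures (slower).
#' @param image_spec Base [image_fixture_spec()] for rendered images.
#' @param tiff Also write the 16-bit centi-Kelvin TIFF dialect.
#' @return Invisibly, the study list from [generate_study()].
#' @export
generate_study_bundle <- function(dir, config = generative_config(),
                                  seed = config$seed, write_images = FALSE,
                                  image_spec = image_fixture_spec(),
                                  tiff = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  study <- generate_study(config, seed)
  utils::write.csv(study$cohort, file.path(dir, "participants.csv"),
                   row.names = FALSE)
  utils::write.csv(study$design, file.path(dir, "design.csv"),
                   row.names = FALSE)
  write_observations(study$observations, file.path(dir, "observations.csv"))
  if (write_images) {
    img_root <- file.path(dir, "images")
    dir.create(img_root, showWarnings = FALSE)
    roi_rows <- dplyr::filter(study$observations, .data$region == "roi")
    for (i in seq_len(nrow(roi_rows))) {
      row <- roi_rows[i, ]
      spec_i <- image_fixture_spec(
        optical_shape = image_spec$optical_shape,
        thermal_shape = image_spec$thermal_shape,
        true_affine = image_spec$true_affine,
        marker_center = image_spec$marker_center,
        marker_radius = image_spec$marker_radius,
        card_corners = image_spec$card_corners,
        coldspot_depth = if (row$period == "cooled") image_spec$coldspot_depth else 0,
        coldspot_sd = image_spec$coldspot_sd,
        background_temp = row$median_temp_c +
          if (row$period == "cooled") image_spec$coldspot_depth / 2 else 0,
        noise_sd = image_spec$noise_sd,
        optical_skin_rgb = image_spec$optical_skin_rgb,
        n_boundary = image_spec$n_boundary,
        annotation_sd = image_spec$annotation_sd
      )
      pair <- generate_image_pair(spec_i, seed = seed + 100L + i)
      d <- file.path(img_root, row$image_id)
      dir.create(d, showWarnings = FALSE)
      png::writePNG(pair$optical, file.path(d, "optical.png"))
      write_thermal_csv(pair$thermal, file.path(d, "thermal.csv"))
      if (tiff) write_thermal_tiff(pair$thermal, file.path(d, "thermal.tif"))
      write_annotations_json(pair$annotations, file.path(d, "annotations.json"))
      jsonlite::write_json(pair$truth, file.path(d, "truth.json"),
                           digits = NA, auto_unbox = TRUE)
    }
  }
  invisible(study)
}
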