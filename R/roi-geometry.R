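# Elliptical region-of-interest geometry.
#
# The cooling region is traced as >=5 clicks on the drawn skin circle; a
# direct algebraic least-squares conic fit with an ellipse-specific
# constraint turns the clicks into an ellipse (an unconstrained conic fit on
# five noisy points can return a hyperbola). The control region is a copy
# scaled to one quarter of each semi-axis, displaced along the image column
# axis, and relocated deterministically if it collides with exclusions.

#' Construct an ellipse
#'
#' @param center_col,center_row Center in 0-based `(col, row)` pixel
#'   coordinates.
#' @param semi_major,semi_minor Semi-axis lengths in pixels;
#'   `semi_major >= semi_minor > 0` is enforced (axes are swapped and the
#'   rotation adjusted if given in the other order).
#' @param rotation Angle of the major axis from the +col axis, radians;
#'   normalized to `[0, pi)`.
#' @return An object of class `roi_ellipse`.
#' @export
roi_ellipse <- function(center_col, center_row, semi_major, semi_minor,
                        rotation = 0) {
  if (!all(is.finite(c(center_col, center_row, semi_major, semi_minor, rotation)))) {
    abort("Ellipse parameters must be finite.", class = "thermoroi_domain_error")
  }
  if (semi_major <= 0 || semi_minor <= 0) {
    abort("Semi-axes must be positive.", class = "thermoroi_domain_error")
  }
  if (semi_minor > semi_major) {
    tmp <- semi_major; semi_major <- semi_minor; semi_minor <- tmp
    rotation <- rotation + pi / 2
  }
  rotation <- rotation %% pi
  structure(
    list(center_col = center_col, center_row = center_row,
         semi_major = semi_major, semi_minor = semi_minor,
         rotation = rotation),
    class = "roi_ellipse"
  )
}

#' @export
print.roi_ellipse <- function(x, ...) {
  cat(sprintf(
    "Ellipse: center (%.2f, %.2f) px, semi-axes (%.2f, %.2f) px, rotation %.3f rad\n",
    x$center_col, x$center_row, x$semi_major, x$semi_minor, x$rotation))
  invisible(x)
}

#' Sample points on an ellipse boundary
#'
#' @param e A [roi_ellipse()].
#' @param angles Parametric angles (radians); default 64 equally spaced.
#' @return A tibble with columns `col`, `row`.
#' @export
ellipse_points <- function(e, angles = seq(0, 2 * pi, length.out = 65)[-65]) {
  stopifnot(inherits(e, "roi_ellipse"))
  u <- e$semi_major * cos(angles)
  v <- e$semi_minor * sin(angles)
  tibble::tibble(
    col = e$center_col + u * cos(e$rotation) - v * sin(e$rotation),
    row = e$center_row + u * sin(e$rotation) + v * cos(e$rotation)
  )
}

# conic coefficients (A, B, C, D, E, F) with A x^2 + B x y + C y^2 + D x + E y + F = 0
ellipse_to_conic <- function(e) {
  ct <- cos(e$rotation); st <- sin(e$rotation)
  a2 <- e$semi_major^2; b2 <- e$semi_minor^2
  A <- ct^2 / a2 + st^2 / b2
  C <- st^2 / a2 + ct^2 / b2
  B <- 2 * ct * st * (1 / a2 - 1 / b2)
  cx <- e$center_col; cy <- e$center_row
  D <- -2 * A * cx - B * cy
  E <- -B * cx - 2 * C * cy
  F <- A * cx^2 + B * cx * cy + C * cy^2 - 1
  c(A = A, B = B, C = C, D = D, E = E, F = F)
}

conic_to_ellipse <- function(k) {
  A <- k[[1]]; B <- k[[2]]; C <- k[[3]]; D <- k[[4]]; E <- k[[5]]; F <- k[[6]]
  disc <- B^2 - 4 * A * C
  if (!is.finite(disc) || disc >= 0) {
    abort("Fitted conic is not an ellipse.", class = "thermoroi_fit_error")
  }
  ctr <- solve(base::matrix(c(2 * A, B, B, 2 * C), 2, 2), -c(D, E))
  Fc <- F + (D * ctr[1] + E * ctr[2]) / 2
  M <- base::matrix(c(A, B / 2, B / 2, C), 2, 2)
  ev <- eigen(M, symmetric = TRUE)
  ax2 <- -Fc / ev$values
  if (any(ax2 <= 0)) {
    abort("Fitted conic is degenerate.", class = "thermoroi_fit_error")
  }
  axes <- sqrt(ax2)
  i_major <- which.max(axes)
  vec <- ev$vectors[, i_major]
  roi_ellipse(ctr[1], ctr[2], axes[i_major], min(axes),
              rotation = atan2(vec[2], vec[1]))
}

#' Fit an ellipse to boundary points
#'
#' Direct algebraic least-squares conic fit with the ellipse constraint
#' `4AC - B^2 = 1` (numerically stable partitioned formulation), guaranteeing
#' the returned conic is an ellipse. Exact when the points lie on a true
#' ellipse.
#'
#' @param points Data frame with columns `col`, `row`, or a 2-column matrix;
#'   at least 5 non-collinear points.
#' @return A [roi_ellipse()].
#' @export
fit_ellipse <- function(points) {
  p <- as_point_matrix(points)
  if (any(!is.finite(p))) {
    abort("Boundary points must be finite.", class = "thermoroi_domain_error")
  }
  if (nrow(p) < 5L) {
    abort("At least 5 boundary points are required to fit an ellipse.",
          class = "thermoroi_fit_error")
  }
  if (qr(cbind(p, 1))$rank < 3L) {
    abort("Boundary points are collinear: no ellipse fits them.",
          class = "thermoroi_fit_error")
  }
  # center for numerical stability
  mu <- colMeans(p)
  x <- p[, 1] - mu[1]; y <- p[, 2] - mu[2]
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  T_ <- -solve(S3, t(S2))
  M <- S1 + S2 %*% T_
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  ok <- which(cond > 1e-12)
  if (!length(ok)) {
    abort("Conic fit did not yield an ellipse.", class = "thermoroi_fit_error")
  }
  a1 <- evec[, ok[1]]
  coefs <- c(a1, as.numeric(T_ %*% a1))  # on centered coordinates
  # un-shift: substitute x -> x - mu1, y -> y - mu2
  A <- coefs[1]; B <- coefs[2]; C <- coefs[3]
  D <- coefs[4] - 2 * A * mu[1] - B * mu[2]
  E <- coefs[5] - B * mu[1] - 2 * C * mu[2]
  F <- coefs[6] + A * mu[1]^2 + B * mu[1] * mu[2] + C * mu[2]^2 -
    coefs[4] * mu[1] - coefs[5] * mu[2]
  conic_to_ellipse(c(A, B, C, D, E, F))
}

# full extent (support width) of an ellipse along a unit direction
ellipse_extent <- function(e, direction) {
  u <- direction / sqrt(sum(direction^2))
  e1 <- c(cos(e$rotation), sin(e$rotation))
  e2 <- c(-sin(e$rotation), cos(e$rotation))
  2 * sqrt((e$semi_major * sum(u * e1))^2 + (e$semi_minor * sum(u * e2))^2)
}

#' Construct the control region for a cooling ROI
#'
#' The control ellipse copies the ROI's rotation with both semi-axes scaled
#' by 1/4, and is displaced from the ROI center along the image column axis
#' (toward the participant's head; sign configurable since left/right framing
#' varies) by the control ellipse's own full width along that axis plus the
#' ROI's semi-major axis length.
#'
#' @param roi A [roi_ellipse()] for the cooling region.
#' @param direction Length-2 displacement direction in `(col, row)`; default
#'   `c(-1, 0)` (toward decreasing column index).
#' @param width_rule Which ellipse's width enters the offset: the control
#'   ellipse (`"control"`, default — the rule's nearest antecedent) or the
#'   cooling ROI (`"roi"`), kept for sensitivity checks.
#' @return A [roi_ellipse()] for the control region.
#' @export
make_control_region <- function(roi, direction = c(-1, 0),
                                width_rule = c("control", "roi")) {
  stopifnot(inherits(roi, "roi_ellipse"))
  width_rule <- match.arg(width_rule)
  u <- direction / sqrt(sum(direction^2))
  control <- roi_ellipse(roi$center_col, roi$center_row,
                         roi$semi_major / 4, roi$semi_minor / 4,
                         roi$rotation)
  w <- ellipse_extent(if (width_rule == "control") control else roi, u)
  d <- w + roi$semi_major
  roi_ellipse(roi$center_col + d * u[1], roi$center_row + d * u[2],
              control$semi_major, control$semi_minor, control$rotation)
}

#' Rasterize an ellipse to a binary pixel mask
#'
#' A pixel is inside iff its center `(col, row)` (0-based integers) satisfies
#' the ellipse interior inequality `<= 1`; pixels outside the image bounds
#' are dropped.
#'
#' @param e A [roi_ellipse()].
#' @param image_shape Integer `(rows, cols)`.
#' @return A logical matrix of dimension `image_shape`.
#' @export
rasterize_ellipse <- function(e, image_shape) {
  stopifnot(inherits(e, "roi_ellipse"), length(image_shape) == 2L)
  rows <- image_shape[1]; cols <- image_shape[2]
  cc <- base::matrix(0:(cols - 1), rows, cols, byrow = TRUE) - e$center_col
  rr <- base::matrix(0:(rows - 1), rows, cols) - e$center_row
  ct <- cos(e$rotation); st <- sin(e$rotation)
  u <- cc * ct + rr * st
  v <- -cc * st + rr * ct
  (u / e$semi_major)^2 + (v / e$semi_minor)^2 <= 1
}

ellipse_inside_image <- function(e, image_shape) {
  # bounding half-extents along col and row axes
  hx <- ellipse_extent(e, c(1, 0)) / 2
  hy <- ellipse_extent(e, c(0, 1)) / 2
  e$center_col - hx >= 0 && e$center_col + hx <= image_shape[2] - 1 &&
    e$center_row - hy >= 0 && e$center_row + hy <= image_shape[1] - 1
}

#' Relocate a control region away from exclusions
#'
#' The default control placement can land on a sticker, clothing, or outside
#' the frame. This deterministic stand-in for manual relocation searches
#' centers on expanding discrete rings around the default position (1 px
#' radial step, 32 angular steps) and accepts the first valid position,
#' preferring smaller radial distance and, within a ring, the smallest
#' angular deviation from the default displacement direction (positive
#' deviation wins exact ties). A position is valid when the control ellipse
#' lies fully inside the image and its rasterized mask is disjoint from both
#' the ROI mask and the exclusion mask.
#'
#' @param control Control ellipse from [make_control_region()].
#' @param roi The cooling ROI ellipse.
#' @param exclusion_mask Logical matrix marking excluded pixels, or `NULL`.
#' @param image_shape `(rows, cols)` of the thermal image.
#' @param direction Default displacement direction used for angular
#'   tie-breaking; should match the one given to [make_control_region()].
#' @return A list with `control` (possibly moved [roi_ellipse()]) and
#'   `relocated` (logical).
#' @export
relocate_control <- function(control, roi, exclusion_mask = NULL, image_shape,
                             direction = c(-1, 0)) {
  stopifnot(inherits(control, "roi_ellipse"), inherits(roi, "roi_ellipse"))
  if (!is.null(exclusion_mask) &&
      !all(dim(exclusion_mask) == image_shape)) {
    abort("`exclusion_mask` must match `image_shape`.",
          class = "thermoroi_input_error")
  }
  roi_mask <- rasterize_ellipse(roi, image_shape)
  valid_at <- function(cx, cy) {
    cand <- roi_ellipse(cx, cy, control$semi_major, control$semi_minor,
                        control$rotation)
    if (!ellipse_inside_image(cand, image_shape)) return(NULL)
    m <- rasterize_ellipse(cand, image_shape)
    if (any(m & roi_mask)) return(NULL)
    if (!is.null(exclusion_mask) && any(m & exclusion_mask)) return(NULL)
    cand
  }
  hit <- valid_at(control$center_col, control$center_row)
  if (!is.null(hit)) {
    return(list(control = hit, relocated = FALSE))
  }
  theta0 <- atan2(direction[2], direction[1])
  # angular offsets ordered by |deviation|, positive first on ties
  k <- seq_len(16)
  offsets <- c(0, as.numeric(rbind(k, -k)))[1:32] * (2 * pi / 32)
  max_radius <- max(image_shape)
  for (radius in seq_len(max_radius)) {
    for (off in offsets) {
      cx <- control$center_col + radius * cos(theta0 + off)
      cy <- control$center_row + radius * sin(theta0 + off)
      hit <- valid_at(cx, cy)
      if (!is.null(hit)) {
        return(list(control = hit, relocated = TRUE))
      }
    }
  }
  abort("No valid control-region placement exists within the image.",
        class = "thermoroi_placement_error")
}

#' Pair a cooling ROI with its (possibly relocated) control region
#'
#' Convenience wrapper running [make_control_region()] then
#' [relocate_control()], returning the validated pair.
#'
#' @inheritParams relocate_control
#' @inheritParams make_control_region
#' @return A list of class `region_pair` with `roi`, `control`, `relocated`,
#'   and `exclusion_overlap_checked`.
#' @export
region_pair <- function(roi, image_shape, exclusion_mask = NULL,
                        direction = c(-1, 0),
                        width_rule = c("control", "roi")) {
  control <- make_control_region(roi, direction, width_rule)
  res <- relocate_control(control, roi, exclusion_mask, image_shape, direction)
  structure(
    list(roi = roi, control = res$control, relocated = res$relocated,
         exclusion_overlap_checked = !is.null(exclusion_mask)),
    class = "region_pair"
  )
}

#' Median temperature within an elliptical region
#'
#' The even-count median is the mean of the two central order statistics
#' (the [stats::median()] convention), stated because it affects bit-level
#' reproducibility of region summaries.
#'
#' @param thermal Numeric matrix of temperatures in degrees Celsius.
#' @param e A [roi_ellipse()].
#' @param region_label Label recorded in the output (`"roi"` or `"control"`).
#' @return A one-row tibble with `region`, `median_temp_c`, `pixel_count`.
#' @export
extract_region_median <- function(thermal, e, region_label = "roi") {
  stopifnot(is.matrix(thermal), inherits(e, "roi_ellipse"))
  mask <- rasterize_ellipse(e, dim(thermal))
  vals <- thermal[mask]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) {
    abort("Region mask is empty: ellipse lies outside the image.",
          class = "thermoroi_region_error")
  }
  tibble::tibble(region = region_label,
                 median_temp_c = median(vals),
                 pixel_count = length(vals))
}

#' Rasterize polygons to an exclusion mask
#'
#' Even-odd (crossing-number) point-in-polygon test evaluated at pixel
#' centers; used to turn annotated sticker/clothing outlines into the binary
#' exclusion mask consumed by [relocate_control()].
#'
#' @param polygons List of polygons, each a data frame or matrix of `(col,
#'   row)` vertices.
#' @param image_shape `(rows, cols)`.
#' @return Logical matrix, `TRUE` inside any polygon.
#' @export
polygon_mask <- function(polygons, image_shape) {
  rows <- image_shape[1]; cols <- image_shape[2]
  mask <- base::matrix(FALSE, rows, cols)
  if (!length(polygons)) return(mask)
  px <- base::matrix(0:(cols - 1), rows, cols, byrow = TRUE)
  py <- base::matrix(0:(rows - 1), rows, cols)
  for (poly in polygons) {
    v <- as_point_matrix(poly)
    n <- nrow(v)
    inside <- base::matrix(FALSE, rows, cols)
    j <- n
    for (i in seq_len(n)) {
      xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
      crosses <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
      j <- i
    }
    mask <- mask | inside
  }
  mask
}
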