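# Optical-to-thermal registration from fiducial point correspondences.
#
# Coordinate convention (shared by all modules): 0-based (col, row) pixel
# coordinates, origin at the top-left pixel center, rows increasing downward.

#' Construct an affine transform
#'
#' @param matrix A 2x3 numeric matrix `[A | t]` mapping `(col, row)` source
#'   coordinates to target coordinates as `A %*% p + t`. The 2x2 linear part
#'   must be invertible.
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(matrix) {
  matrix <- base::matrix(as.numeric(matrix), nrow = 2L, ncol = 3L)
  if (any(!is.finite(matrix))) {
    abort("Affine matrix entries must be finite.", class = "thermoroi_domain_error")
  }
  if (abs(det(matrix[, 1:2])) < 1e-12) {
    abort("Affine transform is degenerate: linear part is singular.",
          class = "thermoroi_degenerate_error")
  }
  structure(list(matrix = matrix), class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("Affine transform (target = A source + t):\n")
  print(x$matrix)
  invisible(x)
}

#' Identity affine transform
#' @return An `affine_transform` that maps every point to itself.
#' @export
identity_affine <- function() {
  affine_transform(cbind(diag(2), c(0, 0)))
}

as_point_matrix <- function(points) {
  if (is.data.frame(points)) {
    check_columns(points, c("col", "row"), "points")
    cbind(points$col, points$row)
  } else {
    m <- base::matrix(as.numeric(points), ncol = 2L)
    m
  }
}

#' Estimate an affine transform from point correspondences
#'
#' Least-squares fit of the full 6-parameter affine map taking optical-frame
#' source points to thermal-frame target points; with exactly three
#' non-collinear pairs the fit interpolates them exactly.
#'
#' @param correspondences Data frame with columns `source_col`, `source_row`,
#'   `target_col`, `target_row` (one fiducial per row), e.g. from
#'   [read_correspondences()].
#' @return An [affine_transform()] with attributes `residual_rms` (root mean
#'   squared target residual in pixels) and `n_points`.
#' @export
estimate_affine <- function(correspondences) {
  check_columns(correspondences,
                c("source_col", "source_row", "target_col", "target_row"),
                "correspondences")
  n <- nrow(correspondences)
  if (n < 3L) {
    abort("At least 3 point correspondences are required.",
          class = "thermoroi_degenerate_error")
  }
  src <- cbind(correspondences$source_col, correspondences$source_row)
  tgt <- cbind(correspondences$target_col, correspondences$target_row)
  if (any(!is.finite(src)) || any(!is.finite(tgt))) {
    abort("Correspondence coordinates must be finite.",
          class = "thermoroi_domain_error")
  }
  X <- cbind(src, 1)
  if (qr(X)$rank < 3L) {
    abort("Source points are collinear: affine transform is not identifiable.",
          class = "thermoroi_degenerate_error")
  }
  beta <- qr.solve(X, tgt)          # 3x2: rows (a, b, t) per output coordinate
  m <- t(beta)[, c(1, 2, 3), drop = FALSE]
  out <- affine_transform(m)
  resid <- X %*% beta - tgt
  attr(out, "residual_rms") <- sqrt(mean(rowSums(resid^2)))
  attr(out, "n_points") <- n
  out
}

#' Apply an affine transform to points
#'
#' @param transform An [affine_transform()].
#' @param points Data frame with columns `col`, `row`, or a 2-column matrix.
#' @return A tibble with columns `col`, `row` in the target frame, in input
#'   order.
#' @export
apply_affine <- function(transform, points) {
  stopifnot(inherits(transform, "affine_transform"))
  p <- as_point_matrix(points)
  out <- p %*% t(transform$matrix[, 1:2]) +
    base::matrix(transform$matrix[, 3], nrow(p), 2, byrow = TRUE)
  tibble::tibble(col = out[, 1], row = out[, 2])
}

#' Invert an affine transform
#'
#' @param a An [affine_transform()].
#' @param b Unused (S3 signature of [solve()]).
#' @param ... Unused.
#' @return The inverse `affine_transform`.
#' @export
solve.affine_transform <- function(a, b, ...) {
  A <- a$matrix[, 1:2]
  t_ <- a$matrix[, 3]
  Ainv <- solve(A)
  affine_transform(cbind(Ainv, -Ainv %*% t_))
}

#' Warp annotation points from the optical to the thermal frame
#'
#' ROI boundary clicks are digitized on the optical image; expressing them in
#' thermal-pixel coordinates (rather than resampling temperatures) avoids
#' interpolating the thermal data. Ordering is preserved.
#'
#' @inheritParams apply_affine
#' @param boundary_points Data frame with `col`, `row` in the optical frame.
#' @return A tibble of the same points in the thermal frame.
#' @export
warp_annotations <- function(transform, boundary_points) {
  apply_affine(transform, boundary_points)
}

#' Root-mean-square registration residual
#'
#' @inheritParams estimate_affine
#' @param transform An [affine_transform()].
#' @return RMS of target-frame residuals, in pixels.
#' @export
affine_rms <- function(transform, correspondences) {
  check_columns(correspondences,
                c("source_col", "source_row", "target_col", "target_row"),
                "correspondences")
  pred <- apply_affine(transform,
                       cbind(correspondences$source_col,
                             correspondences$source_row))
  sqrt(mean((pred$col - correspondences$target_col)^2 +
              (pred$row - correspondences$target_row)^2))
}

#' Read point correspondences from JSON
#'
#' Expects `{"pairs": [{"optical": [c, r], "thermal": [c, r]}, ...]}`.
#'
#' @param path Path to the JSON file.
#' @return A tibble with columns `source_col`, `source_row`, `target_col`,
#'   `target_row`.
#' @export
read_correspondences <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$pairs)) {
    abort(sprintf("No 'pairs' field in %s.", path), class = "thermoroi_io_error")
  }
  pairs <- doc$pairs
  opt <- do.call(rbind, lapply(pairs$optical, as.numeric))
  thm <- do.call(rbind, lapply(pairs$thermal, as.numeric))
  if (is.null(opt)) {  # simplifyVector may already give matrices
    opt <- base::matrix(unlist(pairs$optical), ncol = 2, byrow = TRUE)
    thm <- base::matrix(unlist(pairs$thermal), ncol = 2, byrow = TRUE)
  }
  tibble::tibble(source_col = opt[, 1], source_row = opt[, 2],
                 target_col = thm[, 1], target_row = thm[, 2])
}

#' Write an affine transform to JSON
#'
#' Serialised as a row-major 2x3 matrix under `"matrix"`.
#'
#' @param transform An [affine_transform()].
#' @param path Output path.
#' @export
write_affine_json <- function(transform, path) {
  stopifnot(inherits(transform, "affine_transform"))
  jsonlite::write_json(
    list(matrix = list(as.numeric(transform$matrix[1, ]),
                       as.numeric(transform$matrix[2, ]))),
    path, digits = NA
  )
  invisible(path)
}

#' Read an affine transform from JSON
#' @param path Path written by [write_affine_json()].
#' @return An [affine_transform()].
#' @export
read_affine_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  affine_transform(rbind(as.numeric(doc$matrix[1, ]),
                         as.numeric(doc$matrix[2, ])))
}

#' Resample an image through an affine transform (visualization helper)
#'
#' Bilinear resampling of a single-band image into the target frame. Intended
#' only for overlay figures; quantitative extraction always warps annotations
#' instead of temperatures.
#'
#' @param image Numeric matrix (rows x cols), source frame.
#' @param transform [affine_transform()] mapping source to target coordinates.
#' @param out_shape `(rows, cols)` of the output.
#' @return Numeric matrix of shape `out_shape`; pixels mapping outside the
#'   source are `NA`.
#' @export
resample_affine <- function(image, transform, out_shape) {
  inv <- solve(transform)
  rows <- out_shape[1]; cols <- out_shape[2]
  grid <- cbind(rep(seq_len(cols) - 1, each = rows),
                rep(seq_len(rows) - 1, times = cols))
  src <- as_point_matrix(apply_affine(inv, grid))
  c0 <- floor(src[, 1]); r0 <- floor(src[, 2])
  fc <- src[, 1] - c0;   fr <- src[, 2] - r0
  get <- function(r, c) {
    ok <- r >= 0 & r <= nrow(image) - 1 & c >= 0 & c <= ncol(image) - 1
    v <- rep(NA_real_, length(r))
    v[ok] <- image[cbind(r[ok] + 1, c[ok] + 1)]
    v
  }
  v <- (1 - fr) * ((1 - fc) * get(r0, c0) + fc * get(r0, c0 + 1)) +
    fr * ((1 - fc) * get(r0 + 1, c0) + fc * get(r0 + 1, c0 + 1))
  base::matrix(v, nrow = rows, ncol = cols)
}
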