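# Shared fixtures built in code.

# noiseless swatch pairs generated from a calibration curve
make_swatches <- function(curve = calibration_curve(), n = 28,
                          x_range = c(-550, 450)) {
  x <- seq(x_range[1], x_range[2], length.out = n)
  tibble::tibble(swatch_id = sprintf("S%02d", seq_len(n)),
                 x_scc = x, y_cm = convert_melanin(x, curve))
}

# random invertible affine with moderate conditioning
random_affine <- function() {
  repeat {
    A <- matrix(rnorm(4, sd = 0.8), 2, 2) + diag(2)
    if (abs(det(A)) > 0.2) break
  }
  affine_transform(cbind(A, rnorm(2, sd = 20)))
}

# correspondences mapping src through a transform, with optional noise
make_correspondences <- function(transform, src, noise_sd = 0) {
  tgt <- apply_affine(transform, src)
  tibble::tibble(
    source_col = src[, 1], source_row = src[, 2],
    target_col = tgt$col + rnorm(nrow(src), 0, noise_sd),
    target_row = tgt$row + rnorm(nrow(src), 0, noise_sd)
  )
}

# independent normal-equations solution for the affine least-squares problem
affine_normal_equations <- function(correspondences) {
  X <- cbind(correspondences$source_col, correspondences$source_row, 1)
  Y <- cbind(correspondences$target_col, correspondences$target_row)
  beta <- solve(t(X) %*% X, t(X) %*% Y)
  t(beta)[, c(1, 2, 3)]
}

# independent conic-based ellipse parameters: transform the conic matrix of
# `e` through an affine map and re-extract geometric parameters by eigen
# decomposition (no shared code with fit_ellipse / conic_to_ellipse)
transformed_ellipse_params <- function(e, transform) {
  ct <- cos(e$rotation); st <- sin(e$rotation)
  R <- matrix(c(ct, st, -st, ct), 2, 2)
  Dm <- diag(1 / c(e$semi_major^2, e$semi_minor^2))
  Q2 <- R %*% Dm %*% t(R)               # (p - c)' Q2 (p - c) = 1
  c0 <- c(e$center_col, e$center_row)
  M <- rbind(cbind(transform$matrix[, 1:2], transform$matrix[, 3]), c(0, 0, 1))
  Q3 <- rbind(cbind(Q2, -Q2 %*% c0),
              c(-t(c0) %*% Q2, t(c0) %*% Q2 %*% c0 - 1))
  Minv <- solve(M)
  Q3t <- t(Minv) %*% Q3 %*% Minv
  A2 <- Q3t[1:2, 1:2]
  center <- solve(A2, -Q3t[1:2, 3])
  k <- -(Q3t[3, 3] - t(center) %*% A2 %*% center)[1, 1]
  ev <- eigen(A2 / k, symmetric = TRUE)
  axes <- 1 / sqrt(ev$values)
  i <- which.max(axes)
  vec <- ev$vectors[, i]
  list(center = center, semi_major = max(axes), semi_minor = min(axes),
       rotation = atan2(vec[2], vec[1]) %% pi)
}

# minimal hand-built observation table: one participant per paired condition,
# roi change configurable, control flat
make_paired_obs <- function(roi_changes, baseline_roi = 31,
                            baseline_control = 31.3) {
  n <- length(roi_changes)
  base <- tibble::tibble(
    participant_id = sprintf("P%03d", seq_len(n)),
    camera = "E8XT", lighting = "ambient", distance_cm = 35,
    posture = "stacked", melanin = 50 + seq_len(n)
  )
  dplyr::bind_rows(
    dplyr::mutate(base, period = "baseline", region = "roi",
                  median_temp_c = baseline_roi),
    dplyr::mutate(base, period = "cooled", region = "roi",
                  median_temp_c = baseline_roi + roi_changes),
    dplyr::mutate(base, period = "baseline", region = "control",
                  median_temp_c = baseline_control),
    dplyr::mutate(base, period = "cooled", region = "control",
                  median_temp_c = baseline_control)
  )
}

# per-participant cluster standard error of a mean
cluster_se <- function(values, participant) {
  m <- tapply(values, participant, mean)
  sd(m) / sqrt(length(m))
}
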