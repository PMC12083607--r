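test_that("circles and ellipses are recovered exactly from noiseless samples", {
  circ5 <- as.matrix(ellipse_points(roi_ellipse(50, 50, 20, 20),
                                    seq(0, 2 * pi, length.out = 6)[1:5]))
  fit <- fit_ellipse(circ5)
  expect_equal(c(fit$center_col, fit$center_row), c(50, 50), tolerance = 1e-6)
  expect_equal(c(fit$semi_major, fit$semi_minor), c(20, 20), tolerance = 1e-6)

  e <- roi_ellipse(30, 40, 15, 9, 0.6)
  pts8 <- as.matrix(ellipse_points(e, seq(0.1, 2 * pi, length.out = 9)[1:8]))
  fit8 <- fit_ellipse(pts8)
  expect_equal(c(fit8$center_col, fit8$center_row), c(30, 40), tolerance = 1e-6)
  expect_equal(fit8$semi_major, 15, tolerance = 1e-6)
  expect_equal(fit8$semi_minor, 9, tolerance = 1e-6)
  expect_equal(fit8$rotation, 0.6, tolerance = 1e-6)
})

test_that("noisy boundary points recover the center within 0.3 px", {
  set.seed(21)
  e <- roi_ellipse(30, 40, 15, 9, 0.6)
  pts <- as.matrix(ellipse_points(e, runif(50, 0, 2 * pi))) +
    matrix(rnorm(100, 0, 0.3), ncol = 2)
  fit <- fit_ellipse(pts)
  expect_lt(sqrt((fit$center_col - 30)^2 + (fit$center_row - 40)^2), 0.3)
})

test_that("ellipse fitting rejects degenerate point sets", {
  expect_error(fit_ellipse(cbind(1:4, 1:4 + 0.5)), class = "thermoroi_fit_error")
  line <- cbind(seq(0, 10, length.out = 6), 2 * seq(0, 10, length.out = 6))
  expect_error(fit_ellipse(line), class = "thermoroi_fit_error")
})

test_that("ellipse fitting is equivariant under rigid motions", {
  set.seed(22)
  e <- roi_ellipse(12, -5, 11, 6, 1.1)
  pts <- as.matrix(ellipse_points(e, runif(12, 0, 2 * pi)))
  for (i in 1:4) {
    th <- runif(1, 0, pi)
    shift <- runif(2, -30, 30)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    moved <- fit_ellipse(pts %*% t(R) + matrix(shift, 12, 2, byrow = TRUE))
    expected_center <- R %*% c(12, -5) + shift
    expect_equal(c(moved$center_col, moved$center_row),
                 as.numeric(expected_center), tolerance = 1e-6)
    expect_equal(moved$semi_major, 11, tolerance = 1e-6)
    expect_equal(moved$semi_minor, 6, tolerance = 1e-6)
    expect_equal(moved$rotation, (1.1 + th) %% pi, tolerance = 1e-6)
  }
})

test_that("control region scales by 1/4 and sits at the prescribed offset", {
  roi <- roi_ellipse(100, 100, 40, 40)
  ctl <- make_control_region(roi)
  expect_equal(ctl$semi_major, 10, tolerance = 1e-12)
  expect_equal(ctl$semi_minor, 10, tolerance = 1e-12)
  # displacement = control width (20) + roi semi-major (40)
  expect_equal(c(ctl$center_col, ctl$center_row), c(40, 100), tolerance = 1e-9)

  set.seed(23)
  for (i in 1:6) {
    r <- roi_ellipse(runif(1, 60, 140), runif(1, 60, 140),
                     runif(1, 20, 45), runif(1, 10, 20), runif(1, 0, pi))
    c_i <- make_control_region(r)
    expect_equal(c_i$semi_major / r$semi_major, 0.25, tolerance = 1e-12)
    expect_equal(c_i$semi_minor / r$semi_minor, 0.25, tolerance = 1e-12)
    expect_equal(c_i$rotation, r$rotation, tolerance = 1e-12)
    m_roi <- rasterize_ellipse(r, c(220, 220))
    m_ctl <- rasterize_ellipse(c_i, c(220, 220))
    expect_false(any(m_roi & m_ctl))
  }

  # degenerate-small ROI still yields a disjoint control
  small <- roi_ellipse(20, 10, 4, 2)
  ctl_s <- make_control_region(small)
  expect_equal(c(ctl_s$semi_major, ctl_s$semi_minor), c(1, 0.5))
  expect_false(any(rasterize_ellipse(small, c(30, 40)) &
                     rasterize_ellipse(ctl_s, c(30, 40))))

  # alternative width rule uses the cooling ROI's extent
  ctl_alt <- make_control_region(roi, width_rule = "roi")
  expect_equal(ctl_alt$center_col, 100 - (80 + 40), tolerance = 1e-9)
})

test_that("rasterization matches the per-pixel-center oracle", {
  tiny <- roi_ellipse(50, 50, 0.4, 0.4)
  m <- rasterize_ellipse(tiny, c(100, 100))
  expect_equal(sum(m), 1L)
  expect_true(m[51, 51])

  oracle_mask <- function(e, shape) {
    m <- matrix(FALSE, shape[1], shape[2])
    for (r in 0:(shape[1] - 1)) for (c in 0:(shape[2] - 1)) {
      dx <- c - e$center_col; dy <- r - e$center_row
      u <- dx * cos(e$rotation) + dy * sin(e$rotation)
      v <- -dx * sin(e$rotation) + dy * cos(e$rotation)
      m[r + 1, c + 1] <- (u / e$semi_major)^2 + (v / e$semi_minor)^2 <= 1
    }
    m
  }
  circ <- roi_ellipse(100, 100, 20, 20)
  m2 <- rasterize_ellipse(circ, c(200, 200))
  expect_lt(abs(sum(m2) - pi * 400) / (pi * 400), 0.01)
  expect_identical(m2, oracle_mask(circ, c(200, 200)))

  partial <- roi_ellipse(5, 60, 12, 7, 0.8)
  m3 <- rasterize_ellipse(partial, c(80, 40))
  expect_identical(m3, oracle_mask(partial, c(80, 40)))
  expect_equal(dim(m3), c(80L, 40L))
})

test_that("control relocation is a no-op when the default position is valid", {
  roi <- roi_ellipse(100, 80, 30, 20)
  ctl <- make_control_region(roi)
  res <- relocate_control(ctl, roi, NULL, c(160, 200))
  expect_false(res$relocated)
  expect_equal(res$control$center_col, ctl$center_col)
})

test_that("relocation finds the nearest valid position under exclusions", {
  roi <- roi_ellipse(100, 80, 30, 20)
  ctl <- make_control_region(roi)
  shape <- c(160, 200)
  excl <- matrix(FALSE, shape[1], shape[2])
  excl[, 1:60] <- TRUE  # blocks the default control placement
  res <- relocate_control(ctl, roi, excl, shape)
  expect_true(res$relocated)
  m <- rasterize_ellipse(res$control, shape)
  expect_false(any(m & excl))
  expect_false(any(m & rasterize_ellipse(roi, shape)))

  # brute-force oracle: nearest valid integer-grid center (candidates sorted
  # by distance; the first valid one is the grid optimum)
  roi_mask <- rasterize_ellipse(roi, shape)
  valid <- function(cx, cy) {
    if (cx - ctl$semi_major < 0 || cx + ctl$semi_major > shape[2] - 1 ||
        cy - ctl$semi_minor < 0 || cy + ctl$semi_minor > shape[1] - 1) {
      return(FALSE)
    }
    cand <- roi_ellipse(cx, cy, ctl$semi_major, ctl$semi_minor, ctl$rotation)
    mm <- rasterize_ellipse(cand, shape)
    !any(mm & excl) && !any(mm & roi_mask)
  }
  grid <- expand.grid(cx = 0:(shape[2] - 1), cy = 0:(shape[1] - 1))
  grid$d <- sqrt((grid$cx - ctl$center_col)^2 + (grid$cy - ctl$center_row)^2)
  grid <- grid[order(grid$d), ]
  best <- NA_real_
  for (i in seq_len(nrow(grid))) {
    if (valid(grid$cx[i], grid$cy[i])) { best <- grid$d[i]; break }
  }
  moved <- sqrt((res$control$center_col - ctl$center_col)^2 +
                  (res$control$center_row - ctl$center_row)^2)
  # ring search (1 px radial step) cannot beat the grid optimum by more than
  # the discretization of either search
  expect_lte(moved, best + 2.5)

  full <- matrix(TRUE, shape[1], shape[2])
  expect_error(relocate_control(ctl, roi, full, shape),
               class = "thermoroi_placement_error")
})

test_that("region_pair enforces the scaling and disjointness invariants", {
  roi <- roi_ellipse(90, 70, 28, 18, 0.4)
  rp <- region_pair(roi, c(150, 180))
  expect_s3_class(rp, "region_pair")
  expect_equal(rp$control$semi_major, roi$semi_major / 4, tolerance = 1e-12)
  expect_false(rp$relocated)
  expect_false(any(rasterize_ellipse(rp$roi, c(150, 180)) &
                     rasterize_ellipse(rp$control, c(150, 180))))
})

test_that("region medians follow the even-count convention and ignore outside pixels", {
  img <- matrix(31, 40, 40)
  any_e <- roi_ellipse(20, 20, 6, 4, 0.3)
  expect_equal(extract_region_median(img, any_e)$median_temp_c, 31)

  # mask of exactly 4 pixels in a row with values 27..30
  img2 <- matrix(99, 3, 4)
  img2[2, ] <- c(27, 28, 29, 30)
  strip <- roi_ellipse(1.5, 1, 2, 0.4)
  res <- extract_region_median(img2, strip)
  expect_equal(res$pixel_count, 4L)
  expect_equal(res$median_temp_c, 28.5)

  # changing pixels outside the mask does not alter the median
  img3 <- img2
  img3[1, ] <- -50
  expect_equal(extract_region_median(img3, strip)$median_temp_c, 28.5)

  outside <- roi_ellipse(300, 300, 5, 5)
  expect_error(extract_region_median(img, outside),
               class = "thermoroi_region_error")
})

test_that("median extraction agrees with full enumeration on a cold-spot field", {
  shape <- c(80, 100)
  cc <- matrix(0:(shape[2] - 1), shape[1], shape[2], byrow = TRUE)
  rr <- matrix(0:(shape[1] - 1), shape[1], shape[2])
  field <- 31 - 3.5 * exp(-((cc - 50)^2 + (rr - 40)^2) / (2 * 15^2))
  e <- roi_ellipse(50, 40, 18, 12, 0.5)
  res <- extract_region_median(field, e)
  vals <- c()
  for (r in 0:(shape[1] - 1)) for (c in 0:(shape[2] - 1)) {
    dx <- c - 50; dy <- r - 40
    u <- dx * cos(0.5) + dy * sin(0.5)
    v <- -dx * sin(0.5) + dy * cos(0.5)
    if ((u / 18)^2 + (v / 12)^2 <= 1) vals <- c(vals, field[r + 1, c + 1])
  }
  expect_equal(res$pixel_count, length(vals))
  expect_equal(res$median_temp_c, median(vals), tolerance = 1e-12)
})

test_that("polygon exclusion masks follow the even-odd rule", {
  sq <- rbind(c(2, 2), c(6, 2), c(6, 5), c(2, 5))
  m <- polygon_mask(list(sq), c(10, 10))
  expect_true(m[4, 4])    # (col 3, row 3)
  expect_false(m[1, 1])
  expect_equal(sum(m), 4 * 3)  # half-open coverage of the square
  expect_equal(sum(polygon_mask(list(), c(5, 5))), 0)
})
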