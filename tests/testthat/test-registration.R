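test_that("three noiseless pairs are interpolated exactly", {
  src <- rbind(c(0, 0), c(10, 0), c(3, 8))
  ident <- make_correspondences(identity_affine(), src)
  fit <- estimate_affine(ident)
  expect_equal(fit$matrix, cbind(diag(2), c(0, 0)), tolerance = 1e-9)
  expect_lt(attr(fit, "residual_rms"), 1e-9)

  shift <- affine_transform(cbind(diag(2), c(10, -5)))
  fit2 <- estimate_affine(make_correspondences(shift, rbind(src, c(7, 5))))
  expect_equal(fit2$matrix, shift$matrix, tolerance = 1e-9)
  expect_lt(attr(fit2, "residual_rms"), 1e-9)
})

test_that("six-point estimation matches the normal-equations oracle", {
  set.seed(11)
  src <- matrix(runif(12, 0, 100), ncol = 2)
  truth <- random_affine()
  clean <- make_correspondences(truth, src)
  expect_equal(estimate_affine(clean)$matrix, truth$matrix, tolerance = 1e-9)

  noisy <- make_correspondences(truth, src, noise_sd = 0.5)
  fit <- estimate_affine(noisy)
  oracle <- affine_normal_equations(noisy)
  expect_equal(fit$matrix, oracle, tolerance = 1e-9)
  expect_equal(attr(fit, "residual_rms"), affine_rms(fit, noisy),
               tolerance = 1e-12)
})

test_that("estimation is equivariant under composition with a known affine", {
  set.seed(12)
  for (i in 1:5) {
    src <- matrix(runif(10, 0, 50), ncol = 2)
    base <- make_correspondences(random_affine(), src, noise_sd = 0.3)
    A <- random_affine()
    fit0 <- estimate_affine(base)
    composed <- base
    moved <- apply_affine(A, cbind(base$target_col, base$target_row))
    composed$target_col <- moved$col
    composed$target_row <- moved$row
    fit1 <- estimate_affine(composed)
    # A o fit0 as a single matrix
    expected <- cbind(A$matrix[, 1:2] %*% fit0$matrix[, 1:2],
                      A$matrix[, 1:2] %*% fit0$matrix[, 3] + A$matrix[, 3])
    expect_equal(fit1$matrix, expected, tolerance = 1e-9)
  }
})

test_that("overdetermined solution is a least-squares minimum", {
  set.seed(13)
  src <- matrix(runif(16, 0, 80), ncol = 2)
  noisy <- make_correspondences(random_affine(), src, noise_sd = 1)
  fit <- estimate_affine(noisy)
  ssr <- function(m) {
    pred <- cbind(src, 1) %*% t(m)
    sum((pred[, 1] - noisy$target_col)^2 + (pred[, 2] - noisy$target_row)^2)
  }
  base_ssr <- ssr(fit$matrix)
  for (i in 1:2) for (j in 1:3) for (d in c(-1e-3, 1e-3)) {
    m <- fit$matrix
    m[i, j] <- m[i, j] + d
    expect_gte(ssr(m), base_ssr)
  }
})

test_that("degenerate configurations are rejected", {
  two <- make_correspondences(identity_affine(), rbind(c(0, 0), c(1, 1)))
  expect_error(estimate_affine(two), class = "thermoroi_degenerate_error")
  collinear <- make_correspondences(identity_affine(),
                                    cbind(0:4, 2 * (0:4) + 1))
  expect_error(estimate_affine(collinear), class = "thermoroi_degenerate_error")
  expect_error(affine_transform(rbind(c(1, 2, 0), c(2, 4, 0))),
               class = "thermoroi_degenerate_error")
})

test_that("apply_affine handles identity, translation, and inversion", {
  p <- rbind(c(3, 4), c(-1, 7))
  expect_equal(as.matrix(apply_affine(identity_affine(), p)),
               p, ignore_attr = TRUE)
  shift <- affine_transform(cbind(diag(2), c(10, -5)))
  expect_equal(unlist(apply_affine(shift, rbind(c(0, 0)))), c(col = 10, row = -5))
  set.seed(14)
  for (i in 1:5) {
    T_ <- random_affine()
    pts <- matrix(runif(10, -50, 50), ncol = 2)
    back <- apply_affine(solve(T_), as.matrix(apply_affine(T_, pts)))
    expect_equal(as.matrix(back), pts, ignore_attr = TRUE, tolerance = 1e-9)
  }
})

test_that("warped circle and ellipse annotations match conic oracles", {
  # similarity: scaling by 2 doubles the circle radius
  circ <- roi_ellipse(20, 30, 8, 8)
  pts <- as.matrix(ellipse_points(circ, seq(0, 2 * pi, length.out = 6)[1:5]))
  scale2 <- affine_transform(cbind(2 * diag(2), c(0, 0)))
  warped <- warp_annotations(scale2, pts)
  d <- sqrt((warped$col - 40)^2 + (warped$row - 60)^2)
  expect_equal(d, rep(16, 5), tolerance = 1e-9)
  # ordering preserved
  expect_equal(as.matrix(warped), 2 * pts, ignore_attr = TRUE)

  # shear: fitted ellipse equals the analytically sheared conic
  e <- roi_ellipse(30, 40, 15, 9, 0.6)
  shear <- affine_transform(rbind(c(1, 0.4, 5), c(0, 1, -3)))
  bpts <- as.matrix(ellipse_points(e, seq(0.2, 2 * pi, length.out = 8)[1:7]))
  fitted <- fit_ellipse(as.matrix(warp_annotations(shear, bpts)))
  oracle <- transformed_ellipse_params(e, shear)
  expect_equal(c(fitted$center_col, fitted$center_row), as.numeric(oracle$center),
               tolerance = 1e-6)
  expect_equal(fitted$semi_major, oracle$semi_major, tolerance = 1e-6)
  expect_equal(fitted$semi_minor, oracle$semi_minor, tolerance = 1e-6)
  expect_equal(fitted$rotation, oracle$rotation, tolerance = 1e-6)
})

test_that("correspondence and transform JSON round-trip", {
  tmp <- withr::local_tempdir()
  ann <- file.path(tmp, "pairs.json")
  jsonlite::write_json(
    list(pairs = list(
      list(optical = c(0, 0), thermal = c(1, 2)),
      list(optical = c(10, 0), thermal = c(11, 2)),
      list(optical = c(0, 10), thermal = c(1, 12)))),
    ann, auto_unbox = FALSE)
  cor <- read_correspondences(ann)
  expect_equal(cor$target_col, c(1, 11, 1))
  fit <- estimate_affine(cor)
  out <- file.path(tmp, "affine.json")
  write_affine_json(fit, out)
  back <- read_affine_json(out)
  expect_equal(back$matrix, fit$matrix, tolerance = 1e-12)
})

test_that("bilinear resampling inverts a translation on a smooth field", {
  img <- outer(0:19, 0:29, function(r, c) 20 + 0.3 * r - 0.1 * c)
  shift <- affine_transform(cbind(diag(2), c(3, 2)))
  res <- resample_affine(img, shift, c(20, 30))
  # interior pixels of the output equal the source shifted by (3, 2)
  expect_equal(res[10, 10], img[8, 7], tolerance = 1e-9)
  expect_true(all(is.na(res[1:2, ])))
})
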