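null_config <- function(n = 12) {
  generative_config(
    n_participants = n,
    beta_cooled = 0, beta_camera = 0, beta_cooled_x_camera = 0,
    beta_cooled_x_camera_control = 0, beta_distance50 = 0,
    beta_cooled_x_distance = 0, beta_cooled_x_melanin = 0,
    control_cooling_drift = 0, control_baseline_offset = 0
  )
}

test_that("null simulations give camera and interaction estimates near zero", {
  cfg <- null_config()
  est <- purrr::map_dfr(1:5, function(s) {
    obs <- generate_observations(generate_cohort(cfg, s),
                                 generate_design(cfg, s), cfg, s)
    tidy(fit_camera_model(obs, "roi_temp"))
  })
  for (term in c("cameraProOne", "periodcooled:cameraProOne")) {
    vals <- est$estimate[est$term == term]
    expect_lt(abs(mean(vals)), 2 * sd(vals) / sqrt(length(vals)) + 0.05)
  }
})

test_that("a default cohort recovers the configured camera-model effects", {
  cfg <- generative_config()
  obs <- generate_observations(generate_cohort(cfg, 101),
                               generate_design(cfg, 101), cfg, 101)
  truth <- expected_effects(cfg)
  t_roi <- tidy(fit_camera_model(obs, "roi_temp"))
  pick <- function(tt, term) tt[tt$term == term, ]
  r <- pick(t_roi, "cameraProOne")
  expect_lt(abs(r$estimate - truth$camera_roi_camera), 4 * r$std.error)
  r <- pick(t_roi, "periodcooled:cameraProOne")
  expect_lt(abs(r$estimate - truth$camera_roi_interaction), 4 * r$std.error)
  t_diff <- tidy(fit_camera_model(obs, "roi_minus_control"))
  r <- pick(t_diff, "periodcooled")
  expect_lt(abs(r$estimate - truth$camera_diff_cooled), 4 * r$std.error)
  r <- pick(t_diff, "periodcooled:cameraProOne")
  expect_lt(abs(r$estimate - truth$camera_diff_interaction), 4 * r$std.error)
})

test_that("the environment model recovers distance effects on the reference camera", {
  cfg <- generative_config()
  est <- purrr::map_dfr(1:40, function(s) {
    obs <- generate_observations(generate_cohort(cfg, 200 + s),
                                 generate_design(cfg, 200 + s), cfg, 200 + s)
    tidy(fit_environment_model(obs, "roi_temp"))
  })
  mc <- function(term) {
    v <- est$estimate[est$term == term]
    c(mean = mean(v), se = sd(v) / sqrt(length(v)))
  }
  d <- mc("distance_cm50")
  expect_lt(abs(d["mean"] - (-0.11)), 2 * d["se"])
  i <- mc("periodcooled:distance_cm50")
  expect_lt(abs(i["mean"] - 0.20), 2 * i["se"])
  p <- mc("periodcooled")
  expect_lt(abs(p["mean"] - (-4.19)), 2 * p["se"])
  lt <- mc("lightingring")
  expect_lt(abs(lt["mean"]), 2 * lt["se"] + 0.02)
})

test_that("balanced-design mixed-model contrasts equal raw cell-mean contrasts", {
  cfg <- generative_config()
  obs <- generate_observations(generate_cohort(cfg, 201),
                               generate_design(cfg, 201), cfg, 201)
  roi <- dplyr::filter(obs, region == "roi", camera == "E8XT")
  cm <- tapply(roi$median_temp_c, list(roi$period, roi$distance_cm), mean)
  oracle <- (cm["cooled", "50"] - cm["cooled", "35"]) -
    (cm["baseline", "50"] - cm["baseline", "35"])
  f <- tidy(fit_environment_model(obs, "roi_temp"))
  expect_equal(f$estimate[f$term == "periodcooled:distance_cm50"], oracle,
               tolerance = 1e-8)
})

test_that("the melanin interaction slope is recovered and nulls stay null", {
  cfg <- generative_config()
  est <- purrr::map_dfr(1:6, function(s) {
    obs <- generate_observations(generate_cohort(cfg, 300 + s),
                                 generate_design(cfg, 300 + s), cfg, 300 + s)
    tidy(fit_melanin_model(obs))
  })
  v <- est$estimate[est$term == "periodcooled:melanin_c"]
  expect_lt(abs(mean(v) - (-0.013)), 2 * sd(v) / sqrt(length(v)) + 0.002)

  cfg0 <- null_config()
  obs0 <- generate_observations(generate_cohort(cfg0, 9),
                                generate_design(cfg0, 9), cfg0, 9)
  t0 <- tidy(fit_melanin_model(obs0))
  r0 <- t0[t0$term == "periodcooled:melanin_c", ]
  expect_lt(abs(r0$estimate), 4 * r0$std.error)
})

test_that("model preconditions are enforced with informative errors", {
  cfg <- generative_config(n_participants = 3)
  obs <- generate_observations(generate_cohort(cfg, 4),
                               generate_design(cfg, 4), cfg, 4)
  one_cam <- dplyr::filter(obs, camera == "E8XT")
  expect_error(fit_camera_model(one_cam), class = "thermoroi_input_error")

  solo <- dplyr::filter(obs, participant_id == "P001")
  expect_error(fit_camera_model(solo), class = "thermoroi_input_error")

  no_posture <- dplyr::filter(obs, posture != "knee_behind")
  expect_error(fit_environment_model(no_posture),
               regexp = "knee_behind", class = "thermoroi_input_error")

  flat <- dplyr::mutate(obs, melanin = 55)
  expect_error(fit_melanin_model(flat), class = "thermoroi_collinearity_error")
})

test_that("tidy and glance expose a broom-style interface", {
  cfg <- generative_config(n_participants = 6)
  obs <- generate_observations(generate_cohort(cfg, 8),
                               generate_design(cfg, 8), cfg, 8)
  fit <- fit_camera_model(obs, "roi_temp")
  tt <- tidy(fit)
  expect_named(tt, c("term", "estimate", "std.error", "df", "statistic",
                     "p.value"))
  expect_true(all(tt$std.error > 0))
  gl <- glance(fit)
  expect_equal(gl$n_obs, nrow(obs) / 2)
  expect_equal(gl$n_groups, 6)
  expect_lte(gl$n_groups, gl$n_obs)
  expect_true(gl$converged)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("category effects scale the melanin slope by category width", {
  expect_equal(abs(category_effect(-0.013, 25, 1)), 0.325, tolerance = 1e-12)
  expect_equal(category_effect(-0.013, 25, 1), -0.325, tolerance = 1e-12)
  expect_equal(abs(category_effect(-0.013, 25, 3)), 0.975, tolerance = 1e-12)
  expect_equal(category_effect(0, 25, 4), 0)
  expect_equal(category_effect(0.02, 10, 2), 0.4, tolerance = 1e-12)
  expect_error(category_effect(1, 0, 1), class = "thermoroi_domain_error")
  expect_error(category_effect(1, 25, -1), class = "thermoroi_domain_error")
})
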