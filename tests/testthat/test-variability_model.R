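test_that("offset adjustment centres each horse-condition cell", {
  rec <- dplyr::bind_rows(
    balanced_records(c(4, 6), horses = "H1"),
    balanced_records(c(3, 4, 8), horses = "H2"),
    balanced_records(5, horses = "H3")
  )
  devs <- offset_adjust(rec, parameters = "p")
  d1 <- devs[devs$horse == "H1", ]
  expect_equal(d1$deviation, c(-1, 1))
  expect_equal(d1$y, c(1, 1))
  d2 <- devs[devs$horse == "H2", ]
  expect_equal(d2$deviation, c(-2, -1, 3))
  expect_equal(d2$y, c(sqrt(2), 1, sqrt(3)), tolerance = 1e-12)
  # singleton cell: zero deviation
  expect_equal(devs$deviation[devs$horse == "H3"], 0)
  # cells sum to zero by construction
  sums <- as.numeric(tapply(devs$deviation, devs$horse, sum))
  expect_equal(sums, rep(0, 3), tolerance = 1e-12)
})

test_that("offset adjustment is idempotent and removes horse constants", {
  set.seed(31)
  rec <- simulate_measurement_dataset(study_sim_config(n_horses = 6,
                                                       seed = 31))
  devs <- offset_adjust(rec, parameters = "pelvis_roll_rom")
  # adjusting the adjusted data changes nothing
  rec2 <- rec
  dev_wide <- devs$deviation
  rec2$pelvis_roll_rom <- dev_wide
  devs2 <- offset_adjust(rec2, parameters = "pelvis_roll_rom")
  expect_equal(devs2$deviation, devs$deviation, tolerance = 1e-12)
  # adding a constant to one horse's raw values changes nothing downstream
  rec3 <- rec
  rec3$pelvis_roll_rom[rec3$horse == "H02"] <-
    rec3$pelvis_roll_rom[rec3$horse == "H02"] + 57.3
  devs3 <- offset_adjust(rec3, parameters = "pelvis_roll_rom")
  expect_equal(devs3$y, devs$y, tolerance = 1e-9)
  f1 <- fit_variability_model(devs)
  f3 <- fit_variability_model(devs3)
  expect_equal(f3$vc, f1$vc, tolerance = 1e-6)
})

test_that("constant response gives an exactly degenerate fit", {
  devs <- make_devs(rep(0.4, 48), horse = rep(sprintf("H%d", 1:4), each = 12),
                    measurement = rep(1:12, 4),
                    day = rep(rep(c("1", "2", "recheck"), c(5, 5, 2)), 4))
  fit <- suppressMessages(fit_variability_model(devs))
  expect_null(fit$model)
  expect_equal(unname(fit$vc), c(0, 0))
  expect_equal(unname(fit$beta["(Intercept)"]), 0.4)
  lims <- prediction_upper_limits(fit)
  expect_equal(lims$limits$upper_limit, 0.16, tolerance = 1e-12)
})

test_that("REML variance components match method of moments when balanced", {
  set.seed(33)
  horses <- sprintf("H%02d", 1:12)
  b <- rnorm(12, sd = 0.5)
  y <- rep(b, each = 10) + rnorm(120, sd = 0.3)
  devs <- make_devs(y, horse = rep(horses, each = 10),
                    measurement = rep(1:10, 12),
                    day = rep(rep(c("1", "2"), each = 5), 12))
  fit <- suppressMessages(fit_variability_model(devs))
  # REML on balanced one-way data equals the ANOVA moment estimators when
  # the model has no other terms; with day/rep in the model they stay close
  oracle <- mom_varcomp(y, rep(horses, each = 10))
  expect_equal(unname(fit$vc["sigma2_horse"]),
               unname(oracle["sigma2_group"]), tolerance = 0.05)
  expect_equal(unname(fit$vc["sigma2_resid"]),
               unname(oracle["sigma2_resid"]), tolerance = 0.05)
})

test_that("aliased designs are rejected with the offending columns named", {
  # only hard-straight and soft-left measured: path and surface confounded
  set.seed(34)
  devs <- dplyr::bind_rows(
    make_devs(rnorm(24), horse = rep(sprintf("H%d", 1:2), each = 12),
              measurement = rep(1:12, 2),
              day = rep(rep(c("1", "2", "recheck"), c(5, 5, 2)), 2),
              path = "straight", surface = "hard"),
    make_devs(rnorm(24), horse = rep(sprintf("H%d", 1:2), each = 12),
              measurement = rep(1:12, 2),
              day = rep(rep(c("1", "2", "recheck"), c(5, 5, 2)), 2),
              path = "lunge_left", surface = "soft")
  )
  expect_error(fit_variability_model(devs), "rank deficient")
})

test_that("prediction limits follow the back-transformed construction", {
  fit <- structure(list(
    parameter = "p", with_speed = FALSE, n = 100,
    data = tibble::tibble(condition = conditions_all()),
    terms = c("path", "surface"),
    rep_center = NA_real_, speed_center = NA_real_,
    model = NA,
    beta = c(`(Intercept)` = 0.7, pathlunge_left = 0, pathlunge_right = 0,
             surfacehard = 0),
    vc = c(sigma2_horse = 0.005, sigma2_resid = 0.005)
  ), class = "variability_fit")
  out <- prediction_upper_limits(fit)
  expected <- (0.7 + qnorm(0.975) * 0.1)^2 # = 0.8028
  expect_equal(out$limits$upper_limit, rep(expected, 4), tolerance = 1e-9)
  expect_equal(out$mean_variation, expected, tolerance = 1e-9)
  # Student-t quantile option widens the limit
  out_t <- prediction_upper_limits(fit, quantile = "t")
  expect_true(all(out_t$limits$upper_limit > out$limits$upper_limit))
})

test_that("a recheck effect on the transformed scale is recovered", {
  set.seed(36)
  horses <- sprintf("H%02d", 1:12)
  n_per <- 12
  day <- rep(rep(c("1", "2", "recheck"), c(5, 5, 2)), 12)
  y <- 0.6 + rep(rnorm(12, sd = 0.1), each = n_per) +
    0.3 * (day == "recheck") + rnorm(12 * n_per, sd = 0.12)
  devs <- make_devs(y, horse = rep(horses, each = n_per),
                    measurement = rep(1:12, 12), day = day)
  fit <- suppressMessages(fit_variability_model(devs))
  tests <- fixed_effect_tests(fit)
  rc <- tests[tests$term == "dayrecheck", ]
  expect_equal(rc$estimate, 0.3, tolerance = 0.33)
  expect_lt(rc$p_value, 0.001)
  # z-approximation agrees with Satterthwaite at these sample sizes
  tz <- fixed_effect_tests(fit, ddf = "z")
  expect_equal(tz$p_value[tz$term == "dayrecheck"], rc$p_value,
               tolerance = 0.2)
})

test_that("adding an uncorrelated speed covariate barely moves the limits", {
  set.seed(37)
  rec <- simulate_measurement_dataset(study_sim_config(seed = 37))
  devs <- offset_adjust(rec, parameters = "back_flexext_rom")
  f0 <- suppressMessages(fit_variability_model(devs))
  f1 <- suppressMessages(fit_variability_model(devs, with_speed = TRUE))
  l0 <- prediction_upper_limits(f0)$limits$upper_limit
  l1 <- prediction_upper_limits(f1)$limits$upper_limit
  expect_equal(l1, l0, tolerance = 0.05)
})
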