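test_that("mean_spectrum pools spectra pointwise", {
  w <- seq(400, 410)
  s0 <- sers_spectrum(w, rep(0, 11))
  s2 <- sers_spectrum(w, rep(2, 11))
  expect_equal(mean_spectrum(list(s0, s2))$intensities, rep(1, 11))
  expect_equal(mean_spectrum(s2)$intensities, s2$intensities)
  expect_error(mean_spectrum(list()), class = "sersquant_argument_error")

  # pooling maps weights by spectrum count
  m1 <- spectral_map("a", w, matrix(1, 11, 3),
                     data.frame(line = 1, position = 1:3))
  m2 <- spectral_map("b", w, matrix(5, 11, 1),
                     data.frame(line = 1, position = 1))
  expect_equal(mean_spectrum(list(m1, m2))$intensities, rep(2, 11))
})

test_that("peak_response is the 792 - 723 intensity difference", {
  w <- seq(700, 800)
  y <- rep(0, length(w))
  y[w == 792] <- 500
  y[w == 723] <- 120
  expect_equal(peak_response(sers_spectrum(w, y)), 380)
  expect_equal(peak_response(sers_spectrum(w, rep(4, length(w)))), 0)

  # linearity: response of (s - blank) = response(s) - response(blank)
  set.seed(5)
  s <- sers_spectrum(w, stats::rnorm(length(w), 100, 20))
  blank <- sers_spectrum(w, stats::rnorm(length(w), 80, 10))
  expect_equal(peak_response(sers_spectrum(w, s$intensities - blank$intensities)),
               peak_response(s) - peak_response(blank))
})

test_that("top-k selection ranks by quality index with stable ties", {
  w <- seq(400, 440)
  m <- spectral_map("x", w, matrix(seq_len(4 * 41), 41, 4),
                    data.frame(line = 1, position = 1:4))
  sel <- select_top_k_by_qi(m, c(5, 3, 9, 1), 2)
  expect_equal(sel$intensities, m$intensities[, c(3, 1)], ignore_attr = TRUE)
  # ties broken by raster order (earlier first)
  sel2 <- select_top_k_by_qi(m, c(2, 7, 7, 2), 3)
  expect_equal(sel2$coords$position, c(2, 3, 1))
  # k = population returns everything
  expect_equal(n_spectra(select_top_k_by_qi(m, c(1, 2, 3, 4), 4)), 4)
  expect_error(select_top_k_by_qi(m, c(1, 2, 3, 4), 5),
               class = "sersquant_argument_error")
  expect_error(select_top_k_by_qi(m, c(1, 2, 3, 4), 0),
               class = "sersquant_argument_error")
})

test_that("linear_regression matches a normal-equations oracle", {
  expect_equal(linear_regression(1:5, 2 * (1:5) + 1)[c("slope", "intercept",
                                                       "r_squared")],
               list(slope = 2, intercept = 1, r_squared = 1))
  # constant response: slope 0, R^2 = 0 by convention
  cst <- linear_regression(1:4, rep(3, 4))
  expect_equal(cst$slope, 0)
  expect_equal(cst$r_squared, 0)
  expect_error(linear_regression(rep(1, 4), 1:4),
               class = "sersquant_regression_error")

  set.seed(9)
  x <- log10(c(78, 156, 312, 625, 1250, 2500, 5000))
  y <- 100 * x - 40 + stats::rnorm(7, 0, 5)
  fit <- linear_regression(x, y)
  # independent normal-equations oracle
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  expect_equal(fit$slope, slope, tolerance = 1e-12)
  expect_equal(fit$intercept, intercept, tolerance = 1e-12)
  expect_equal(fit$r_squared, stats::cor(x, y)^2, tolerance = 1e-12)
})

test_that("noise-free log-linear plates are recovered exactly by all methods", {
  cfg <- noiseless_config()
  plate <- generate_plate(make_default_design(cfg), cfg, seed = 1)
  for (m in c("total_population", "qi_sample", "cdf")) {
    fit <- sers_calibration(plate, method = m, k = 10)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  }
  # analytic slope of the averaging methods: beta times the signature's
  # response gain (hand Lorentzian evaluation)
  w <- seq(cfg$wavenumber_start, cfg$wavenumber_end, by = cfg$wavenumber_step)
  gain <- oracle_signature_value(w[which.min(abs(w - 792))], cfg$analyte_bands) -
    oracle_signature_value(w[which.min(abs(w - 723))], cfg$analyte_bands)
  fit_tp <- sers_calibration(plate, method = "total_population")
  expect_equal(fit_tp$slope, cfg$beta * gain, tolerance = 1e-9)
})

test_that("qi_sample with k = population size coincides with total_population", {
  plate <- small_plate(seed = 14)
  pop <- n_spectra(plate$maps[[1]])
  f_total <- sers_calibration(plate, "total_population")
  f_qi <- sers_calibration(plate, "qi_sample", k = pop)
  expect_equal(f_qi$responses$response, f_total$responses$response,
               tolerance = 1e-12)
  expect_equal(f_qi$slope, f_total$slope, tolerance = 1e-12)
})

test_that("degenerate plates are rejected", {
  cfg <- generator_config(raster_lines = 3, raster_per_line = 3,
                          concentrations = c(100),
                          replicate_wells_per_sample = 2)
  plate <- generate_plate(make_default_design(cfg), cfg, seed = 2)
  expect_error(sers_calibration(plate, "total_population"),
               class = "sersquant_regression_error")
})

test_that("CDF-method responses are raised by the smallest data point", {
  plate <- small_plate(seed = 23)
  fit <- sers_calibration(plate, "cdf")
  all_vals <- c(fit$model$response, fit$responses$response)
  # shift rule: every value was increased by |min| of the raw values
  raw <- all_vals - fit$shift
  expect_equal(fit$shift, abs(min(raw)), tolerance = 1e-9)
  expect_true(all(all_vals >= -1e-9))

  # when raw responses go negative (a distribution below the blank's),
  # the shift lands the smallest data point exactly at zero
  w <- seq(700, 850)
  peak <- as.numeric(abs(w - 792) <= 2)
  mk_map <- function(id, amps)
    spectral_map(id, w, outer(peak, amps),
                 data.frame(line = 1, position = seq_along(amps)))
  cfg <- generator_config(concentrations = c(100, 50),
                          replicate_wells_per_sample = 1)
  design <- make_default_design(cfg)
  hand_plate <- structure(list(
    design = design,
    maps = list(A1 = mk_map("A1", seq(1, 2, length.out = 50)),
                A2 = mk_map("A2", seq(0.5, 1, length.out = 50)),
                A3 = mk_map("A3", seq(10, 20, length.out = 50))),
    config = NULL, seed = NULL), class = "sers_plate")
  fit2 <- sers_calibration(hand_plate, "cdf")
  expect_gt(fit2$shift, 0)
  vals2 <- c(fit2$model$response, fit2$responses$response)
  expect_equal(min(vals2), 0, tolerance = 1e-9)
})

test_that("blank subtraction leaves calibration slopes unchanged", {
  plate <- small_plate(seed = 31)
  sub <- blank_subtract(plate)
  # the blank's own mean spectrum maps to (numerically) zero
  blank_ids <- plate$design$well_id[plate$design$is_blank]
  bm <- mean_spectrum(sub$maps[blank_ids])
  expect_equal(max(abs(bm$intensities)), 0, tolerance = 1e-9)

  # total population: algebraically exact (constant offset cancels)
  f0 <- sers_calibration(plate, "total_population")
  f1 <- sers_calibration(sub, "total_population")
  expect_equal(f1$slope, f0$slope, tolerance = 1e-9)
  expect_equal(f1$r_squared, f0$r_squared, tolerance = 1e-9)

  # qi sample: ranking is shift-invariant, so slopes agree
  g0 <- sers_calibration(plate, "qi_sample", k = 10)
  g1 <- sers_calibration(sub, "qi_sample", k = 10)
  expect_equal(g1$slope, g0$slope, tolerance = 1e-6)
})

test_that("calibration objects support the standard model interface", {
  plate <- small_plate(seed = 40)
  fit <- sers_calibration(plate, "qi_sample", k = 10)
  expect_s3_class(fit, "sers_calibration")
  expect_named(coef(fit), c("intercept", "slope"))
  expect_equal(unname(predict(fit, 1000)),
               fit$intercept + fit$slope * 3, tolerance = 1e-12)
  expect_length(residuals(fit), nrow(fit$model))
  expect_equal(residuals(fit),
               fit$model$response - predict(fit, fit$model$concentration),
               tolerance = 1e-12)
  s <- summary(fit)
  expect_s3_class(s, "summary.sers_calibration")
  expect_equal(nrow(s$per_concentration),
               length(unique(plate$design$concentration)))
  expect_output(print(fit), "qi_sample")
  expect_error(predict(fit, -5), class = "sersquant_argument_error")
})
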