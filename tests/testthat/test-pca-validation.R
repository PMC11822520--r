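test_that("truncation keeps the inclusive window and is idempotent", {
  s <- sers_spectrum(seq(400, 1800), seq_along(seq(400, 1800)))
  t1 <- truncate_spectrum(s)
  expect_equal(range(t1$wavenumbers), c(586, 1710))
  t2 <- truncate_spectrum(t1)
  expect_identical(t2, t1)
  expect_error(truncate_spectrum(s, lo = 1000, hi = 900),
               class = "sersquant_range_error")
  expect_error(truncate_spectrum(s, lo = 5000, hi = 6000),
               class = "sersquant_range_error")
})

test_that("IarPLS reproduces a peak-free smooth baseline", {
  w <- seq(586, 1710)
  x <- seq_along(w)
  smooth <- 200 + 0.1 * x - 6e-5 * x^2
  r <- iarpls_baseline(sers_spectrum(w, smooth))
  expect_lt(max(abs(r$baseline$intensities - smooth)), 1)
  # flat input: baseline equals input, corrected ~ 0
  f <- iarpls_baseline(sers_spectrum(w, rep(7, length(w))))
  expect_lt(max(abs(f$baseline$intensities - 7)), 1e-6)
  expect_lt(max(abs(f$corrected$intensities)), 1e-6)
  expect_true(f$converged)
  expect_error(iarpls_baseline(sers_spectrum(1:5, rep(1, 5))),
               class = "sersquant_argument_error")
})

test_that("IarPLS separates narrow peaks from a quadratic baseline", {
  w <- seq(586, 1710)
  x <- seq_along(w)
  base <- 300 + 0.15 * x - 9e-5 * x^2
  peaks <- 200 / (1 + ((w - 800) / 5)^2) + 150 / (1 + ((w - 1100) / 6)^2) +
    180 / (1 + ((w - 1500) / 5)^2)
  r <- iarpls_baseline(sers_spectrum(w, base + peaks))
  rmse <- sqrt(mean((r$baseline$intensities - base)^2))
  expect_lt(rmse, 0.01 * 200)  # < 1% of the tallest peak
  # corrected spectrum keeps the known peak positions
  expect_equal(which.max(r$corrected$intensities), which.max(peaks))
  ord <- order(r$corrected$intensities, decreasing = TRUE)
  expect_true(all(c(which(w == 800), which(w == 1100), which(w == 1500))
                  %in% ord[1:60]))
})

test_that("PCA scores separate a one-direction class difference", {
  w <- seq(600, 700)
  sig <- exp(-0.5 * ((w - 650) / 5)^2)
  mk <- function(a) sers_spectrum(w, a * sig)
  class_a <- lapply(c(0, 0.1, 0.2), mk)
  class_b <- lapply(c(5, 5.1, 5.2), mk)
  pca <- run_pca(class_a, class_b)
  # all variance lies along the single spectral direction
  expect_equal(pca$explained[1], 1, tolerance = 1e-9)
  expect_true(sum(pca$explained) <= 1 + 1e-12)
  expect_equal(pca$scores$class, rep(c("blank", "analyte"), each = 3))

  # order invariance up to sign: reversing inputs gives the same spread
  pca2 <- run_pca(rev(class_a), rev(class_b))
  expect_equal(sort(abs(pca2$scores$PC1)), sort(abs(pca$scores$PC1)),
               tolerance = 1e-9)

  # degenerate: identical spectra in both classes
  same <- lapply(1:3, function(i) mk(1))
  expect_error(run_pca(same, same), class = "sersquant_degeneracy_error")
  expect_error(run_pca(class_a[1:2], class_b),
               class = "sersquant_argument_error")
})

test_that("confidence ellipses follow the chi-square geometry", {
  # cloud with exactly unit covariance: boundary is a circle of radius
  # sqrt(chi^2 quantile)
  pts <- sqrt(3 / 2) * rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  e <- confidence_ellipsoid(pts, level = 0.95)
  expect_equal(unname(e$center), c(0, 0))
  radii <- sqrt(rowSums(e$boundary^2))
  expect_equal(radii, rep(sqrt(stats::qchisq(0.95, 2)), length(radii)),
               tolerance = 1e-9)

  # translation moves the center, not the shape
  e2 <- confidence_ellipsoid(sweep(pts, 2, c(-3, 4), `+`), level = 0.95)
  expect_equal(unname(e2$center), c(-3, 4))
  expect_equal(e2$shape, e$shape)

  # higher level -> larger ellipse (monotone boundary radius)
  e99 <- confidence_ellipsoid(pts, level = 0.99)
  expect_true(all(sqrt(rowSums((e99$boundary - rep(e99$center, each = 360))^2)) >
                  sqrt(rowSums((e$boundary - rep(e$center, each = 360))^2))))

  expect_error(confidence_ellipsoid(pts[1:2, ]),
               class = "sersquant_argument_error")
  # singular covariance
  degen <- rbind(c(0, 0), c(1, 0), c(2, 0))
  expect_error(confidence_ellipsoid(degen),
               class = "sersquant_degeneracy_error")
})

test_that("ellipse overlap is decided on strict interiors", {
  e1 <- ellipsoid(c(0, 0), diag(2), 1)
  expect_true(ellipsoids_overlap(e1, e1))
  # far apart
  e2 <- ellipsoid(c(200, 0), diag(2), 1)
  expect_false(ellipsoids_overlap(e1, e2))
  # tangent-separated pair: unit circles with centers 2 + eps apart
  e3 <- ellipsoid(c(2 + 1e-9, 0), diag(2), 1)
  expect_false(ellipsoids_overlap(e1, e3))
  # clearly intersecting pair
  e4 <- ellipsoid(c(1.5, 0), diag(2), 1)
  expect_true(ellipsoids_overlap(e1, e4))
  # containment (one inside the other) counts as overlap
  e5 <- ellipsoid(c(0, 0), diag(2), 25)
  expect_true(ellipsoids_overlap(e1, e5))
})

test_that("validate_loq assembles the class comparison end to end", {
  cfg <- generator_config(raster_lines = 10, raster_per_line = 10,
                          concentrations = twofold_series(5000, 3),
                          replicate_wells_per_sample = 4,
                          hotspot_fraction = 0.3, beta = 400)
  plate <- generate_plate(make_default_design(cfg), cfg, seed = 3)
  v <- validate_loq(plate, "qi_sample", k = 10)
  expect_s3_class(v, "loq_validation")
  expect_equal(v$concentration, 1250)
  expect_equal(nrow(v$pca$scores), 8)  # 4 blank + 4 lowest wells
  expect_length(v$ellipsoids, 2)
  expect_type(v$overlap, "logical")
  expect_output(print(v), "LOQ validation")
})
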