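test_that("plate design assigns samples to wells with correct indices", {
  cfg <- generator_config()
  d <- make_default_design(cfg)
  expect_s3_class(d, "plate_design")
  expect_equal(nrow(d), 40)  # 8 samples x 5 replicate wells
  expect_equal(sum(d$is_blank), 5)
  # twofold series bottoms out at 78 ng/mL after integer truncation
  expect_equal(sort(unique(d$concentration[!d$is_blank])),
               c(78, 156, 312, 625, 1250, 2500, 5000))
  # concentration index: 0 for the highest concentration, 7 for the blank
  expect_equal(unique(d$conc_index[d$concentration == 5000]), 0L)
  expect_equal(unique(d$conc_index[d$is_blank]), 7L)
  expect_true(all(table(d$sample_id) == 5))

  # minimal design: 2 concentrations + blank, single replicate
  cfg1 <- generator_config(concentrations = c(100, 50),
                           replicate_wells_per_sample = 1)
  expect_equal(nrow(make_default_design(cfg1)), 3)

  # capacity error when samples x replicates exceed the layout
  expect_error(make_default_design(cfg, rows = 2, cols = 2),
               class = "sersquant_capacity_error")
})

test_that("config invariants are enforced", {
  expect_error(generator_config(wavenumber_start = 1800, wavenumber_end = 400),
               class = "sersquant_config_error")
  expect_error(generator_config(hotspot_fraction = 1.5),
               class = "sersquant_config_error")
  expect_error(generator_config(noise_sd = -1),
               class = "sersquant_config_error")
  expect_error(generator_config(concentrations = c(100, 200)),
               class = "sersquant_config_error")
})

test_that("amplitude sampling follows the hotspot mixture law", {
  cfg <- generator_config(amplitude_law = "exponential")
  # blank and pi = 0 always give zero amplitude
  expect_equal(sample_analyte_amplitude(0, cfg, 10), numeric(10))
  cfg0 <- generator_config(hotspot_fraction = 0)
  set.seed(1)
  expect_equal(sample_analyte_amplitude(5000, cfg0, 10), numeric(10))

  # Monte-Carlo oracle: mean of 1e5 draws within 3 standard errors of
  # pi * mu(c) for the pure exponential law
  set.seed(101)
  cc <- 1250
  mu <- cfg$beta * log10(cc / cfg$c_ref)
  draws <- sample_analyte_amplitude(cc, cfg, 1e5)
  pi_ <- cfg$hotspot_fraction
  se <- sqrt((2 * pi_ * mu^2 - (pi_ * mu)^2) / 1e5)
  expect_lt(abs(mean(draws) - pi_ * mu), 3 * se)

  # nonzero amplitudes match the configured exponential (KS, alpha=0.01)
  set.seed(202)
  d2 <- sample_analyte_amplitude(cc, cfg, 1e4)
  nz <- d2[d2 > 0]
  expect_gt(suppressWarnings(
    stats::ks.test(nz, "pexp", rate = 1 / mu)$p.value), 0.01)

  # distribution mean is exactly linear in log10(c)
  concs <- c(100, 1000, 10000)
  mus <- vapply(concs, amplitude_mean, numeric(1), config = cfg)
  expect_equal(diff(mus) / diff(log10(concs)), rep(cfg$beta, 2))
})

test_that("generated spectra follow the band + amplitude + noise model", {
  # no background, no noise, forced zero amplitude -> all-zero intensities
  cfg <- generator_config(hotspot_fraction = 0, noise_sd = 0,
                          background_scale_sd = 0,
                          background_bands = data.frame(center = numeric(),
                                                        width = numeric(),
                                                        height = numeric()))
  s <- generate_spectrum(500, cfg)
  expect_equal(s$intensities, numeric(length(s$wavenumbers)))

  # deterministic unit amplitude: intensity at the band center equals
  # background there plus the amplitude
  cfg2 <- generator_config(hotspot_fraction = 1, noise_sd = 0,
                           background_scale_sd = 0,
                           amplitude_law = "deterministic",
                           analyte_bands = data.frame(center = 792, width = 6,
                                                      height = 1))
  s2 <- generate_spectrum(5000, cfg2)
  i792 <- nearest_index(s2$wavenumbers, 792)
  amp <- amplitude_mean(5000, cfg2)
  expect_equal(s2$intensities[i792],
               background_profile(s2$wavenumbers, cfg2)[i792] + amp)

  # determinism under a fixed seed
  set.seed(7); a <- generate_spectrum(1000, generator_config())
  set.seed(7); b <- generate_spectrum(1000, generator_config())
  expect_identical(a, b)
})

test_that("plate generation conserves counts and is reproducible", {
  cfg <- generator_config(raster_lines = 2, raster_per_line = 3,
                          concentrations = c(100, 50),
                          replicate_wells_per_sample = 1)
  plate <- generate_plate(make_default_design(cfg), cfg, seed = 5)
  expect_equal(length(plate$maps), 3)
  expect_true(all(vapply(plate$maps, n_spectra, integer(1)) == 6))

  plate2 <- generate_plate(make_default_design(cfg), cfg, seed = 5)
  expect_identical(plate$maps, plate2$maps)

  # raster coordinates enumerate the full line x position grid
  co <- plate$maps[[1]]$coords
  expect_equal(nrow(unique(co)), 6)
  expect_equal(range(co$line), c(1, 2))
  expect_equal(range(co$position), c(1, 3))
})
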