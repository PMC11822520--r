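# Small-scale generator configurations used across the unit tests.
# The default (paper-scale) configuration is exercised in
# test-acceptance.R; unit tests use reduced rasters for speed.

small_config <- function(...) {
  generator_config(raster_lines = 8, raster_per_line = 8,
                   concentrations = twofold_series(5000, 5),
                   replicate_wells_per_sample = 3, ...)
}

# noise-free, every spectrum a hotspot with deterministic amplitude
# mu(c): responses are exactly linear in log10 concentration
noiseless_config <- function(...) {
  generator_config(raster_lines = 5, raster_per_line = 5,
                   concentrations = twofold_series(5000, 5),
                   replicate_wells_per_sample = 3,
                   hotspot_fraction = 1, amplitude_law = "deterministic",
                   noise_sd = 0, background_scale_sd = 0, ...)
}

small_plate <- function(seed = 42, cfg = small_config()) {
  generate_plate(make_default_design(cfg), cfg, seed = seed)
}

# independent hand oracle for the quality index: explicit index loops
oracle_qi <- function(wavenumbers, intensities, peaks, n) {
  s <- numeric(nrow(peaks))
  wm <- function(center) {
    i <- which.min(abs(wavenumbers - center))
    idx <- max(1, i - n):min(length(wavenumbers), i + n)
    tot <- 0
    for (j in idx) tot <- tot + intensities[j]
    tot / length(idx)
  }
  for (kk in seq_len(nrow(peaks)))
    s[kk] <- wm(peaks$p[kk]) - (wm(peaks$b1[kk]) + wm(peaks$b2[kk])) / 2
  if (any(s <= 0)) 0 else prod(s)^(1 / nrow(peaks))
}

# hand Lorentzian / Gaussian band evaluation (kept independent of the
# package's internals) for analytic-expectation oracles
oracle_signature_value <- function(w, bands, shape = c("lorentzian", "gaussian")) {
  shape <- match.arg(shape)
  val <- 0
  for (i in seq_len(nrow(bands))) {
    u <- (w - bands$center[i]) / bands$width[i]
    val <- val + if (shape == "lorentzian") bands$height[i] / (1 + u^2)
                 else bands$height[i] * exp(-0.5 * u^2)
  }
  val
}
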