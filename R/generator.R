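#' Twofold dilution series, reported as truncated integers
#'
#' @param top Highest concentration (ng/mL).
#' @param n Number of concentrations.
#' @return Numeric vector of length `n`, strictly decreasing: `top / 2^k`
#'   truncated toward zero, matching how serial dilutions are reported.
#' @examples
#' twofold_series(5000, 7)  # 5000 2500 1250 625 312 156 78
#' @export
twofold_series <- function(top = 5000, n = 7) {
  trunc(top / 2^(seq_len(n) - 1))
}

default_background_bands <- function() {
  # broad plasma-like humps (Gaussian) plus the sharp 807 cm^-1
  # interferent reported in matrix blanks; the 758 band keeps the
  # 723-792 region locally balanced so the blank's quality index is
  # set by the interferent and noise, as a real matrix blank's is
  data.frame(
    center = c(620, 758, 807,  960, 1003, 1270, 1450, 1660),
    width  = c( 40,  60,  10,   25,   20,   90,   60,   40),
    height = c(200, 150,  60,   80,  100,  180,  150,  120)
  )
}

default_analyte_bands <- function() {
  # FTC signature: ring-breathing 792 cm^-1 dominant, weaker bands at
  # 1586 and 1672 cm^-1; heights relative to unit amplitude at 792
  data.frame(
    center = c(792, 1586, 1672),
    width  = c(  6,    8,    8),
    height = c(1.0, 0.35, 0.30)
  )
}

#' Configuration of the synthetic SERS plate generator
#'
#' Describes the stated world the generator emulates: a raster-scanned
#' well plate of dried plasma samples on a SERS substrate, where a small
#' fraction of map positions ("hotspots") carry analyte signal whose
#' amplitude across spectra is exponentially distributed, on top of a
#' congested plasma background and additive detector noise.
#'
#' The expected nonzero analyte amplitude at concentration `c` (ng/mL)
#' is `mu(c) = beta * log10(c / c_ref)`, clipped at zero, so that
#' calibration responses are linear in log10 concentration by
#' construction. A custom `mu_fun` may replace this mean model.
#'
#' @param wavenumber_start,wavenumber_end,wavenumber_step Wavenumber axis
#'   (cm^-1); defaults 400-1800 at 1 cm^-1.
#' @param raster_lines,raster_per_line Raster geometry; defaults 42 lines
#'   of 43 spectra (1806 spectra per well).
#' @param concentrations Analyte concentrations (ng/mL), strictly
#'   decreasing and positive; default a seven-point twofold series from
#'   5000 ng/mL (bottom 78 ng/mL). A matrix blank is always appended by
#'   [make_default_design()].
#' @param replicate_wells_per_sample Wells per sample; default 5.
#' @param hotspot_fraction Probability `pi` that a spectrum carries any
#'   analyte signal; default 0.25 (most map positions see none).
#' @param amplitude_law `"exponential"`, `"exponential_plus_normal"`
#'   (default: exponential with a minor pseudo-normal component, as seen
#'   in plasma quality-index histograms), or `"deterministic"`
#'   (amplitude exactly `mu(c)`; for noise-free recovery studies).
#' @param beta Amplitude scale in intensity counts per decade of
#'   concentration; default 50.
#' @param c_ref Reference concentration (ng/mL) where `mu` reaches zero;
#'   default 39, half the lowest default concentration.
#' @param normal_mean,normal_sd,normal_weight Pseudo-normal mixture
#'   component (counts / counts / mixing probability), used only by the
#'   `exponential_plus_normal` law; defaults 40 / 15 / 0.1.
#' @param mu_fun Optional function of concentration replacing the default
#'   log-linear mean model (must return a nonnegative scalar).
#' @param background_bands Data frame `center, width, height` of Gaussian
#'   background bands (cm^-1 / cm^-1 / counts); the default congested
#'   plasma background includes the 807 cm^-1 interferent.
#' @param analyte_bands Data frame of Lorentzian analyte bands; heights
#'   are relative to unit amplitude (default FTC signature at
#'   792 / 1586 / 1672 cm^-1).
#' @param noise_sd Additive Gaussian noise standard deviation (counts);
#'   default 20.
#' @param background_scale_sd Coefficient of variation of the
#'   per-spectrum multiplicative background scale (lognormal, mean 1);
#'   default 0.15. Models the spectrum-to-spectrum heterogeneity of the
#'   congested plasma/SERS background that local baseline subtraction
#'   removes but raw peak intensities retain. Set to 0 for a fixed
#'   background.
#' @return An object of class `"generator_config"` (validated list).
#' @export
generator_config <- function(wavenumber_start = 400,
                             wavenumber_end = 1800,
                             wavenumber_step = 1,
                             raster_lines = 42,
                             raster_per_line = 43,
                             concentrations = twofold_series(5000, 7),
                             replicate_wells_per_sample = 5,
                             hotspot_fraction = 0.25,
                             amplitude_law = c("exponential_plus_normal",
                                               "exponential",
                                               "deterministic"),
                             beta = 50,
                             c_ref = 39,
                             normal_mean = 40,
                             normal_sd = 15,
                             normal_weight = 0.1,
                             mu_fun = NULL,
                             background_bands = default_background_bands(),
                             analyte_bands = default_analyte_bands(),
                             noise_sd = 20,
                             background_scale_sd = 0.15) {
  amplitude_law <- match.arg(amplitude_law)
  cfg <- list(wavenumber_start = wavenumber_start,
              wavenumber_end = wavenumber_end,
              wavenumber_step = wavenumber_step,
              raster_lines = as.integer(raster_lines),
              raster_per_line = as.integer(raster_per_line),
              concentrations = as.numeric(concentrations),
              replicate_wells_per_sample = as.integer(replicate_wells_per_sample),
              hotspot_fraction = hotspot_fraction,
              amplitude_law = amplitude_law,
              beta = beta, c_ref = c_ref,
              normal_mean = normal_mean, normal_sd = normal_sd,
              normal_weight = normal_weight,
              mu_fun = mu_fun,
              background_bands = background_bands,
              analyte_bands = analyte_bands,
              noise_sd = noise_sd,
              background_scale_sd = background_scale_sd)
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  with(cfg, {
    if (!(wavenumber_start < wavenumber_end))
      stop_sq("wavenumber_start must be < wavenumber_end", "sersquant_config_error")
    if (wavenumber_step <= 0)
      stop_sq("wavenumber_step must be positive", "sersquant_config_error")
    if (raster_lines < 1L || raster_per_line < 1L)
      stop_sq("raster dimensions must be at least 1", "sersquant_config_error")
    if (hotspot_fraction < 0 || hotspot_fraction > 1)
      stop_sq("hotspot_fraction must lie in [0, 1]", "sersquant_config_error")
    if (beta < 0) stop_sq("beta must be nonnegative", "sersquant_config_error")
    if (noise_sd < 0) stop_sq("noise_sd must be nonnegative", "sersquant_config_error")
    if (background_scale_sd < 0)
      stop_sq("background_scale_sd must be nonnegative", "sersquant_config_error")
    if (any(concentrations <= 0) || any(diff(concentrations) >= 0))
      stop_sq("concentrations must be strictly decreasing and positive",
              "sersquant_config_error")
    for (bands in list(background_bands, analyte_bands))
      if (nrow(bands) > 0 && any(bands$width <= 0))
        stop_sq("all band widths must be positive", "sersquant_config_error")
    if (!is.null(mu_fun) && !is.function(mu_fun))
      stop_sq("mu_fun must be a function", "sersquant_config_error")
  })
  structure(cfg, class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(paste0("<generator_config> axis %g-%g cm^-1 step %g; raster %d x %d;\n",
                     "  %d concentrations (%g-%g ng/mL) x %d wells; pi=%g, law=%s,\n",
                     "  beta=%g counts/decade (c_ref=%g), noise_sd=%g\n"),
              x$wavenumber_start, x$wavenumber_end, x$wavenumber_step,
              x$raster_lines, x$raster_per_line,
              length(x$concentrations), max(x$concentrations),
              min(x$concentrations), x$replicate_wells_per_sample,
              x$hotspot_fraction, x$amplitude_law, x$beta, x$c_ref, x$noise_sd))
  invisible(x)
}

config_axis <- function(cfg) {
  seq(cfg$wavenumber_start, cfg$wavenumber_end, by = cfg$wavenumber_step)
}

#' Expected nonzero analyte amplitude at a concentration
#'
#' @param concentration Concentration in ng/mL (0 means blank).
#' @param config A [generator_config()].
#' @return `mu(c)`, nonnegative; 0 for the blank.
#' @export
amplitude_mean <- function(concentration, config) {
  if (concentration <= 0) return(0)
  if (!is.null(config$mu_fun)) {
    mu <- config$mu_fun(concentration)
  } else {
    mu <- config$beta * log10(concentration / config$c_ref)
  }
  max(0, mu)
}

#' Draw analyte peak amplitudes for map spectra
#'
#' With probability `1 - pi` a spectrum falls outside a hotspot and
#' carries zero analyte amplitude; otherwise the amplitude is drawn from
#' the configured law with mean `mu(c)`. The blank (`concentration = 0`)
#' always returns 0. Draws use R's global RNG stream.
#'
#' @param concentration Concentration in ng/mL, `>= 0`.
#' @param config A [generator_config()].
#' @param n Number of draws.
#' @return Numeric vector of `n` nonnegative amplitudes.
#' @export
sample_analyte_amplitude <- function(concentration, config, n = 1) {
  if (concentration < 0)
    stop_sq("concentration must be nonnegative", "sersquant_config_error")
  mu <- amplitude_mean(concentration, config)
  if (concentration == 0 || mu == 0 || config$hotspot_fraction == 0)
    return(numeric(n))
  amp <- numeric(n)
  hot <- stats::runif(n) < config$hotspot_fraction
  nh <- sum(hot)
  if (nh == 0) return(amp)
  draw <- switch(config$amplitude_law,
    exponential = stats::rexp(nh, rate = 1 / mu),
    deterministic = rep(mu, nh),
    exponential_plus_normal = {
      from_normal <- stats::runif(nh) < config$normal_weight
      d <- stats::rexp(nh, rate = 1 / mu)
      nn <- sum(from_normal)
      if (nn > 0)
        d[from_normal] <- pmax(0, stats::rnorm(nn, config$normal_mean,
                                               config$normal_sd))
      d
    },
    stop_sq(sprintf("unknown amplitude law '%s'", config$amplitude_law),
            "sersquant_config_error"))
  amp[hot] <- draw
  amp
}

background_scales <- function(n, config) {
  cv <- config$background_scale_sd
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)  # mean exactly 1
}

gaussian_band <- function(w, center, width, height) {
  height * exp(-0.5 * ((w - center) / width)^2)
}

lorentzian_band <- function(w, center, width, height) {
  height / (1 + ((w - center) / width)^2)
}

#' Evaluate the background profile on a wavenumber axis
#' @param wavenumbers Axis (cm^-1).
#' @param config A [generator_config()].
#' @return Numeric vector of background intensities (counts).
#' @export
background_profile <- function(wavenumbers, config) {
  bg <- numeric(length(wavenumbers))
  b <- config$background_bands
  if (nrow(b) > 0)
    for (i in seq_len(nrow(b)))
      bg <- bg + gaussian_band(wavenumbers, b$center[i], b$width[i], b$height[i])
  bg
}

#' Evaluate the unit-amplitude analyte signature on a wavenumber axis
#' @param wavenumbers Axis (cm^-1).
#' @param config A [generator_config()].
#' @return Numeric vector; multiply by an amplitude to get the analyte
#'   contribution to a spectrum.
#' @export
analyte_signature <- function(wavenumbers, config) {
  sig <- numeric(length(wavenumbers))
  b <- config$analyte_bands
  if (nrow(b) > 0)
    for (i in seq_len(nrow(b)))
      sig <- sig + lorentzian_band(wavenumbers, b$center[i], b$width[i], b$height[i])
  sig
}

#' Generate one synthetic SERS spectrum
#'
#' Background bands + analyte amplitude x signature + Gaussian noise.
#'
#' @param concentration Concentration in ng/mL (0 for blank).
#' @param config A [generator_config()].
#' @return A [sers_spectrum()].
#' @export
generate_spectrum <- function(concentration, config) {
  w <- config_axis(config)
  amp <- sample_analyte_amplitude(concentration, config, 1)
  y <- background_scales(1, config) * background_profile(w, config) +
    amp * analyte_signature(w, config)
  if (config$noise_sd > 0) y <- y + stats::rnorm(length(w), 0, config$noise_sd)
  sers_spectrum(w, y)
}

#' Plate layout: wells, samples and concentration indices
#'
#' Assigns each sample (seven descending concentrations plus a matrix
#' blank by default) to `replicate_wells_per_sample` consecutive wells
#' of a rows x cols plate. The concentration index `n` is 0 for the
#' highest concentration and `n_samples - 1` for the blank.
#'
#' @param config A [generator_config()].
#' @param rows,cols Plate dimensions; default 8 x 5.
#' @return A data.frame of class `"plate_design"` with columns
#'   `well_id, row, col, sample_id, concentration, conc_index, is_blank`
#'   (blank coded as `concentration = 0`).
#' @examples
#' d <- make_default_design(generator_config())
#' nrow(d)                 # 40 wells
#' min(d$concentration[!d$is_blank])  # 78
#' @export
make_default_design <- function(config, rows = 8, cols = 5) {
  conc <- c(config$concentrations, 0)  # blank appended
  reps <- config$replicate_wells_per_sample
  n_samples <- length(conc)
  if (n_samples * reps > rows * cols)
    stop_sq(sprintf("layout capacity %d < %d samples x %d replicates",
                    rows * cols, n_samples, reps),
            "sersquant_capacity_error")
  n_wells <- n_samples * reps
  well_row <- ((seq_len(n_wells) - 1L) %/% cols) + 1L
  well_col <- ((seq_len(n_wells) - 1L) %% cols) + 1L
  sample_idx <- rep(seq_len(n_samples), each = reps)
  d <- data.frame(
    well_id = paste0(LETTERS[well_row], well_col),
    row = well_row, col = well_col,
    sample_id = ifelse(conc[sample_idx] > 0,
                       paste0("c", conc[sample_idx]), "blank"),
    concentration = conc[sample_idx],
    conc_index = sample_idx - 1L,
    is_blank = conc[sample_idx] == 0,
    stringsAsFactors = FALSE
  )
  attr(d, "replicate_wells") <- reps
  attr(d, "rows") <- rows
  attr(d, "cols") <- cols
  class(d) <- c("plate_design", "data.frame")
  d
}

#' Generate the spectral map of one well
#'
#' @param concentration Concentration in ng/mL (0 for blank).
#' @param config A [generator_config()].
#' @param well_id Well label.
#' @return A [spectral_map()] with `raster_lines * raster_per_line`
#'   spectra.
#' @export
generate_map <- function(concentration, config, well_id = "A1") {
  w <- config_axis(config)
  n <- config$raster_lines * config$raster_per_line
  amp <- sample_analyte_amplitude(concentration, config, n)
  y <- outer(background_profile(w, config), background_scales(n, config))
  nz <- amp > 0
  if (any(nz))
    y[, nz] <- y[, nz] + outer(analyte_signature(w, config), amp[nz])
  if (config$noise_sd > 0)
    y <- y + matrix(stats::rnorm(length(w) * n, 0, config$noise_sd),
                    nrow = length(w))
  coords <- data.frame(
    line = rep(seq_len(config$raster_lines), each = config$raster_per_line),
    position = rep(seq_len(config$raster_per_line), config$raster_lines)
  )
  spectral_map(well_id, w, y, coords)
}

#' Generate a full synthetic plate
#'
#' One spectral map per well of the design, reproducible under a fixed
#' seed. With the default configuration this yields 1806 spectra per
#' well and 72,240 per plate.
#'
#' @param design A [make_default_design()] layout.
#' @param config A [generator_config()].
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `"sers_plate"`: list with the `design`,
#'   a named list `maps` (one [spectral_map()] per well) and the
#'   `config` used.
#' @export
generate_plate <- function(design, config, seed = NULL) {
  if (!inherits(design, "plate_design"))
    stop_sq("design must be a plate_design", "sersquant_config_error")
  if (!is.null(seed)) set.seed(seed)
  maps <- vector("list", nrow(design))
  names(maps) <- design$well_id
  for (i in seq_len(nrow(design)))
    maps[[i]] <- generate_map(design$concentration[i], config,
                              well_id = design$well_id[i])
  structure(list(design = design, maps = maps, config = config, seed = seed),
            class = "sers_plate")
}

#' @export
print.sers_plate <- function(x, ...) {
  per_well <- vapply(x$maps, n_spectra, integer(1))
  cat(sprintf("<sers_plate> %d wells, %d spectra total (%s per well)\n",
              length(x$maps), sum(per_well),
              paste(unique(per_well), collapse = "/")))
  invisible(x)
}
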