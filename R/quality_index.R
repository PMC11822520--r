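#' Quality-index configuration
#'
#' The quality index of a spectrum is computed from the mean intensity
#' in a window about a peak position `p` minus the mean of the window
#' means about two baseline positions `b1`, `b2`. For `t > 1` peaks the
#' per-peak terms are combined geometrically (product raised to `1/t`).
#'
#' @param peaks Data frame with columns `p`, `b1`, `b2` (cm^-1), one row
#'   per peak. Default: the 792 cm^-1 FTC ring-breathing peak with both
#'   baselines at the 723 cm^-1 trough.
#' @param n Half-width of the averaging window in grid points on each
#'   side of the nearest grid point (window is clipped at axis edges);
#'   default 2.
#' @return An object of class `"qi_config"`.
#' @export
qi_config <- function(peaks = data.frame(p = 792, b1 = 723, b2 = 723),
                      n = 2) {
  if (!is.data.frame(peaks) || !all(c("p", "b1", "b2") %in% names(peaks)))
    stop_sq("peaks must be a data.frame with columns p, b1, b2",
            "sersquant_config_error")
  if (nrow(peaks) < 1)
    stop_sq("at least one peak required", "sersquant_config_error")
  if (n < 0) stop_sq("window half-width n must be >= 0", "sersquant_config_error")
  structure(list(peaks = peaks, n = as.integer(n), t = nrow(peaks)),
            class = "qi_config")
}

#' @export
print.qi_config <- function(x, ...) {
  cat(sprintf("<qi_config> t=%d peak(s), window half-width n=%d\n", x$t, x$n))
  for (i in seq_len(nrow(x$peaks)))
    cat(sprintf("  p=%g cm^-1, baselines %g / %g cm^-1\n",
                x$peaks$p[i], x$peaks$b1[i], x$peaks$b2[i]))
  invisible(x)
}

window_indices <- function(wavenumbers, center, n) {
  i <- nearest_index(wavenumbers, center)
  seq(max(1L, i - n), min(length(wavenumbers), i + n))
}

#' Mean intensity in a window about a position
#'
#' Averages the intensity at the grid point nearest to `center` and its
#' `n` neighbours on each side (clipped at the axis edges).
#'
#' @param spectrum A [sers_spectrum()].
#' @param center Window center in cm^-1 (must lie on the axis range).
#' @param n Half-width in grid points.
#' @return Mean intensity (counts).
#' @export
window_mean <- function(spectrum, center, n) {
  idx <- window_indices(spectrum$wavenumbers, center, n)
  mean(spectrum$intensities[idx])
}

#' Quality index of one spectrum
#'
#' For each configured peak `k`, `s_k` is the window mean at the peak
#' minus the mean of the two baseline window means. The quality index is
#' `(prod(s_k))^(1/t)` when every `s_k` is positive, and 0 otherwise
#' (negative indices are defined as 0). For a single peak this reduces
#' to the baseline-subtracted peak average clipped at zero.
#'
#' @param spectrum A [sers_spectrum()].
#' @param cfg A [qi_config()].
#' @return Nonnegative scalar quality index.
#' @export
compute_qi <- function(spectrum, cfg = qi_config()) {
  s <- vapply(seq_len(cfg$t), function(k) {
    window_mean(spectrum, cfg$peaks$p[k], cfg$n) -
      mean(c(window_mean(spectrum, cfg$peaks$b1[k], cfg$n),
             window_mean(spectrum, cfg$peaks$b2[k], cfg$n)))
  }, numeric(1))
  if (any(s <= 0)) 0 else prod(s)^(1 / cfg$t)
}

#' Quality indices of every spectrum in a map
#'
#' Vectorised over the map's shared wavenumber axis; returns one value
#' per spectrum in raster order.
#'
#' @param map A [spectral_map()].
#' @param cfg A [qi_config()].
#' @return Numeric vector, `n_spectra(map)` long, all entries `>= 0`.
#' @export
compute_qi_map <- function(map, cfg = qi_config()) {
  w <- map$wavenumbers
  s <- matrix(NA_real_, nrow = cfg$t, ncol = ncol(map$intensities))
  for (k in seq_len(cfg$t)) {
    pm <- colMeans(map$intensities[window_indices(w, cfg$peaks$p[k], cfg$n), ,
                                   drop = FALSE])
    b1 <- colMeans(map$intensities[window_indices(w, cfg$peaks$b1[k], cfg$n), ,
                                   drop = FALSE])
    b2 <- colMeans(map$intensities[window_indices(w, cfg$peaks$b2[k], cfg$n), ,
                                   drop = FALSE])
    s[k, ] <- pm - (b1 + b2) / 2
  }
  qi <- ifelse(apply(s <= 0, 2, any), 0,
               apply(s, 2, prod)^(1 / cfg$t))
  as.numeric(qi)
}
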