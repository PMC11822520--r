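#' @keywords internal
stop_sq <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "sersquant_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1))
  ))
}

#' Construct a single SERS spectrum
#'
#' The atomic measurement of a spectral map: a strictly ascending
#' wavenumber axis (cm^-1) with one intensity value (detector counts,
#' arbitrary units) per grid point.
#'
#' @param wavenumbers Numeric vector of wavenumbers in cm^-1, strictly
#'   ascending.
#' @param intensities Numeric vector of intensities, same length as
#'   `wavenumbers`, all finite.
#' @return An object of class `"sers_spectrum"`: a list with elements
#'   `wavenumbers` and `intensities`.
#' @examples
#' s <- sers_spectrum(seq(400, 1800), rnorm(1401))
#' s
#' @export
sers_spectrum <- function(wavenumbers, intensities) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) != length(intensities))
    stop_sq("wavenumbers and intensities must have equal length",
            "sersquant_format_error")
  if (length(wavenumbers) < 1L)
    stop_sq("a spectrum needs at least one grid point", "sersquant_format_error")
  if (any(diff(wavenumbers) <= 0))
    stop_sq("wavenumber axis must be strictly ascending", "sersquant_format_error")
  if (!all(is.finite(intensities)))
    stop_sq("intensities must all be finite", "sersquant_format_error")
  structure(list(wavenumbers = wavenumbers, intensities = intensities),
            class = "sers_spectrum")
}

#' @export
print.sers_spectrum <- function(x, ...) {
  cat(sprintf("<sers_spectrum> %d points, %.2f-%.2f cm^-1\n",
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

#' Construct a spectral map (all spectra of one well)
#'
#' Holds every spectrum acquired over one sample well by a raster scan,
#' on a single shared wavenumber axis. Intensities are stored as a
#' matrix with one row per wavenumber grid point and one column per
#' spectrum, in raster acquisition order.
#'
#' @param well_id Character scalar identifying the well (e.g. `"A1"`).
#' @param wavenumbers Shared wavenumber axis (cm^-1), strictly ascending.
#' @param intensities Numeric matrix, `length(wavenumbers)` rows, one
#'   column per spectrum.
#' @param coords Data frame with integer columns `line` and `position`,
#'   one row per spectrum (raster coordinates).
#' @return An object of class `"spectral_map"`.
#' @export
spectral_map <- function(well_id, wavenumbers, intensities, coords) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.matrix(intensities)
  if (any(diff(wavenumbers) <= 0))
    stop_sq("wavenumber axis must be strictly ascending", "sersquant_format_error")
  if (nrow(intensities) != length(wavenumbers))
    stop_sq("intensity matrix rows must match the wavenumber axis",
            "sersquant_format_error")
  if (!is.data.frame(coords) || !all(c("line", "position") %in% names(coords)))
    stop_sq("coords must be a data.frame with columns line, position",
            "sersquant_format_error")
  if (nrow(coords) != ncol(intensities))
    stop_sq("one coordinate row per spectrum required", "sersquant_format_error")
  structure(list(well_id = as.character(well_id),
                 wavenumbers = wavenumbers,
                 intensities = intensities,
                 coords = coords),
            class = "spectral_map")
}

#' @export
print.spectral_map <- function(x, ...) {
  cat(sprintf("<spectral_map> well %s: %d spectra x %d points (%.0f-%.0f cm^-1)\n",
              x$well_id, ncol(x$intensities), nrow(x$intensities),
              min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

#' Number of spectra in a spectral map
#' @param map A `spectral_map`.
#' @return Integer count of spectra.
#' @export
n_spectra <- function(map) ncol(map$intensities)

#' Extract one spectrum from a map
#' @param map A `spectral_map`.
#' @param i Spectrum index in raster order.
#' @return A `sers_spectrum`.
#' @export
map_spectrum <- function(map, i) {
  sers_spectrum(map$wavenumbers, map$intensities[, i])
}

#' Index of the grid point nearest to a wavenumber
#'
#' Ties are broken toward the lower wavenumber.
#'
#' @param wavenumbers Ascending numeric axis.
#' @param center Target position in cm^-1; must lie within the axis range.
#' @return Integer index.
#' @export
nearest_index <- function(wavenumbers, center) {
  if (center < wavenumbers[1] || center > wavenumbers[length(wavenumbers)])
    stop_sq(sprintf("position %.2f cm^-1 outside axis range [%.2f, %.2f]",
                    center, wavenumbers[1], wavenumbers[length(wavenumbers)]),
            "sersquant_range_error")
  which.min(abs(wavenumbers - center))
}
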