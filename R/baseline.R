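#' Truncate a spectrum to a wavenumber window
#'
#' Retains grid points with `lo <= w <= hi` (inclusive). Defaults match
#' the preprocessing window used before PCA validation.
#'
#' @param spectrum A [sers_spectrum()].
#' @param lo,hi Window bounds in cm^-1; defaults 585.48 and 1710.01.
#' @return A truncated [sers_spectrum()].
#' @export
truncate_spectrum <- function(spectrum, lo = 585.48, hi = 1710.01) {
  if (lo > hi)
    stop_sq("truncation window has lo > hi", "sersquant_range_error")
  keep <- spectrum$wavenumbers >= lo & spectrum$wavenumbers <= hi
  if (!any(keep))
    stop_sq("truncation window contains no grid points",
            "sersquant_range_error")
  sers_spectrum(spectrum$wavenumbers[keep], spectrum$intensities[keep])
}

#' Baseline configuration for IarPLS correction
#'
#' @param lambda Smoothness penalty weight of the Whittaker smoother;
#'   default 1e5 (larger gives a stiffer baseline).
#' @param max_iterations Iteration cap; default 50.
#' @param tolerance Relative weight-change norm for convergence;
#'   default 1e-3.
#' @return An object of class `"baseline_config"`.
#' @export
baseline_config <- function(lambda = 1e5, max_iterations = 50,
                            tolerance = 1e-3) {
  if (lambda <= 0) stop_sq("lambda must be positive", "sersquant_config_error")
  if (max_iterations < 1)
    stop_sq("max_iterations must be at least 1", "sersquant_config_error")
  if (tolerance <= 0)
    stop_sq("tolerance must be positive", "sersquant_config_error")
  structure(list(lambda = lambda, max_iterations = max_iterations,
                 tolerance = tolerance),
            class = "baseline_config")
}

#' IarPLS baseline correction
#'
#' Improved asymmetrically reweighted penalized least squares: a
#' Whittaker smoother (second-difference penalty `lambda`) is solved
#' for the baseline under weights that are updated by an asymmetric
#' logistic rule on the residuals `d = y - z`, scaled by the standard
#' deviation of the negative residuals, with iteration-indexed
#' sharpening. Points far above the baseline (peaks) lose weight;
#' points at or below it keep weight near one, so the smooth curve
#' settles under the peaks.
#'
#' @param spectrum A [sers_spectrum()] (at least 10 points).
#' @param cfg A [baseline_config()].
#' @return List with `baseline` and `corrected` (both
#'   [sers_spectrum()]), `iterations`, and `converged` (FALSE flags a
#'   run that hit `max_iterations`; the result is still returned).
#' @export
iarpls_baseline <- function(spectrum, cfg = baseline_config()) {
  y <- spectrum$intensities
  n <- length(y)
  if (n < 10)
    stop_sq("IarPLS needs at least 10 points", "sersquant_argument_error")
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  P <- cfg$lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  converged <- FALSE
  iter <- 0L
  z <- y
  for (iter in seq_len(cfg$max_iterations)) {
    z <- as.numeric(Matrix::solve(P + Matrix::Diagonal(n, w), w * y))
    d <- y - z
    neg <- d[d < 0]
    if (length(neg) < 2 || stats::sd(neg) < .Machine$double.eps^0.5 * max(1, max(abs(y)))) {
      converged <- TRUE
      break
    }
    s <- stats::sd(neg)
    expo <- pmin(2 * iter * (d - 2 * s) / s, 500)
    w_new <- 1 / (1 + exp(expo))
    if (sqrt(sum((w_new - w)^2)) / sqrt(sum(w^2)) < cfg$tolerance) {
      w <- w_new
      converged <- TRUE
      break
    }
    w <- w_new
  }
  if (!converged)
    z <- as.numeric(Matrix::solve(P + Matrix::Diagonal(n, w), w * y))
  list(baseline = sers_spectrum(spectrum$wavenumbers, z),
       corrected = sers_spectrum(spectrum$wavenumbers, y - z),
       iterations = iter, converged = converged)
}
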