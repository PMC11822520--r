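#' Empirical CDF of quality-index values
#'
#' Nonzero values are sorted ascending; index `i = 1..m` is assigned
#' from the lowest value up and each index is divided by the highest
#' index, so the terminal probability is exactly 1. The abscissa is
#' `log10` of the value. Tied values keep duplicate abscissae with
#' distinct probabilities. The `raw_intensity` metric applies the same
#' construction to baseline-uncorrected peak intensities (nonpositive
#' values removed).
#'
#' @param values Numeric vector of quality indices (or raw intensities).
#' @param metric `"qi"` (default) or `"raw_intensity"`; recorded on the
#'   result.
#' @param source Free-text provenance label (e.g. a well id or
#'   `"pooled"`).
#' @return An object of class `"empirical_cdf"`: list with `x`
#'   (log10 values, nondecreasing), `probability` (strictly increasing,
#'   ending at 1), `metric`, `source`.
#' @export
build_cdf <- function(values, metric = c("qi", "raw_intensity"),
                      source = "") {
  metric <- match.arg(metric)
  v <- values[is.finite(values) & values > 0]
  if (length(v) == 0)
    stop_sq("no nonzero values: cannot build an empirical CDF",
            "sersquant_empty_cdf_error")
  v <- sort(v)
  structure(list(x = log10(v),
                 probability = seq_along(v) / length(v),
                 metric = metric, source = source),
            class = "empirical_cdf")
}

#' Model CDF pooled over replicate wells
#'
#' Values from all replicates of one concentration are pooled into a
#' single array, then sorted, indexed and divided exactly as in
#' [build_cdf()], so the model CDF describes the quality-index
#' distribution of the whole concentration rather than a single well.
#'
#' @param value_sets List of numeric vectors, one per replicate well.
#' @param metric,source As in [build_cdf()].
#' @return An `"empirical_cdf"`.
#' @export
build_model_cdf <- function(value_sets, metric = c("qi", "raw_intensity"),
                            source = "pooled") {
  build_cdf(unlist(value_sets, use.names = FALSE), metric = metric,
            source = source)
}

#' @export
print.empirical_cdf <- function(x, ...) {
  cat(sprintf("<empirical_cdf> %d points (%s%s), x in [%.3f, %.3f]\n",
              length(x$x), x$metric,
              if (nzchar(x$source)) paste0(", ", x$source) else "",
              min(x$x), max(x$x)))
  invisible(x)
}

#' Fourth-order polynomial fit to a CDF segment
#'
#' Fits `x = f(probability)` by least squares over the CDF points whose
#' probability lies in `prob_range` (default 0.6-0.9, the segment that
#' carries the most calibration information), then evaluates the
#' polynomial at `n_fit` evenly spaced probabilities across the range so
#' that fits of different CDFs share one probability grid.
#'
#' @param cdf An [build_cdf()] result.
#' @param prob_range Inclusive probability range; default `c(0.6, 0.9)`.
#' @param degree Polynomial degree; default 4.
#' @param n_fit Number of evaluation points; default 500.
#' @return An object of class `"cdf_poly_fit"`: list with `coefficients`
#'   (raw polynomial, increasing powers), `prob_range`, `probabilities`
#'   (length `n_fit`), `x` (fitted values).
#' @export
fit_cdf_poly <- function(cdf, prob_range = c(0.6, 0.9), degree = 4,
                         n_fit = 500) {
  sel <- cdf$probability >= prob_range[1] & cdf$probability <= prob_range[2]
  if (sum(sel) < degree + 1)
    stop_sq(sprintf("only %d CDF points in probability range [%g, %g]; need %d",
                    sum(sel), prob_range[1], prob_range[2], degree + 1),
            "sersquant_fit_error")
  p <- cdf$probability[sel]
  x <- cdf$x[sel]
  # center the probability axis for conditioning; store raw coefficients
  pc <- p - mean(prob_range)
  X <- outer(pc, 0:degree, `^`)
  beta <- qr.coef(qr(X), x)
  beta[is.na(beta)] <- 0
  pgrid <- seq(prob_range[1], prob_range[2], length.out = n_fit)
  xgrid <- drop(outer(pgrid - mean(prob_range), 0:degree, `^`) %*% beta)
  structure(list(coefficients = beta, center = mean(prob_range),
                 prob_range = prob_range, probabilities = pgrid, x = xgrid),
            class = "cdf_poly_fit")
}

#' @export
print.cdf_poly_fit <- function(x, ...) {
  cat(sprintf("<cdf_poly_fit> degree %d on probability [%g, %g], %d fit points\n",
              length(x$coefficients) - 1, x$prob_range[1], x$prob_range[2],
              length(x$probabilities)))
  invisible(x)
}

#' Summed pointwise CDF difference (calibration response of the CDF
#' method)
#'
#' Sums, over the matched probability grid of two polynomial CDF fits,
#' the difference between the quality-index value (intensity units,
#' i.e. `10^x` of the fitted log10 abscissa) of a concentration's CDF
#' and that of the reference (blank) CDF. Differencing in intensity
#' units makes the response linear in the analyte amplitude scale, so
#' a log-linear amplitude model yields a calibration line in
#' log concentration.
#'
#' @param fit_n Fit for the concentration of interest.
#' @param fit_ref Reference fit (the blank's model CDF).
#' @return Scalar sum of the pointwise differences (intensity units).
#' @export
sigma_delta_qcdf <- function(fit_n, fit_ref) {
  if (length(fit_n$probabilities) != length(fit_ref$probabilities) ||
      max(abs(fit_n$probabilities - fit_ref$probabilities)) > 1e-12)
    stop_sq("CDF fits do not share a probability grid",
            "sersquant_argument_error")
  sum(10^fit_n$x - 10^fit_ref$x)
}
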