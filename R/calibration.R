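#' Pointwise mean spectrum
#'
#' Averages all spectra of a map, a list of maps (pooled, weighted by
#' spectrum count), or a list of spectra sharing one axis.
#'
#' @param x A [spectral_map()], a list of maps, or a list of
#'   [sers_spectrum()] objects.
#' @return A [sers_spectrum()].
#' @export
mean_spectrum <- function(x) {
  if (inherits(x, "spectral_map"))
    return(sers_spectrum(x$wavenumbers, rowMeans(x$intensities)))
  if (inherits(x, "sers_spectrum")) return(x)
  if (!is.list(x) || length(x) == 0)
    stop_sq("mean_spectrum needs at least one spectrum",
            "sersquant_argument_error")
  if (inherits(x[[1]], "spectral_map")) {
    w <- x[[1]]$wavenumbers
    total <- numeric(length(w))
    n <- 0L
    for (m in x) {
      if (length(m$wavenumbers) != length(w) ||
          max(abs(m$wavenumbers - w)) > 0)
        stop_sq("maps do not share a wavenumber axis",
                "sersquant_argument_error")
      total <- total + rowSums(m$intensities)
      n <- n + ncol(m$intensities)
    }
    return(sers_spectrum(w, total / n))
  }
  w <- x[[1]]$wavenumbers
  total <- numeric(length(w))
  for (s in x) {
    if (length(s$wavenumbers) != length(w) ||
        max(abs(s$wavenumbers - w)) > 0)
      stop_sq("spectra do not share a wavenumber axis",
              "sersquant_argument_error")
    total <- total + s$intensities
  }
  sers_spectrum(w, total / length(x))
}

#' Peak-minus-trough calibration response of a spectrum
#'
#' The intensity at the grid point nearest the analyte peak minus the
#' intensity at the grid point nearest the baseline trough
#' (default 792 and 723 cm^-1). May be negative.
#'
#' @param spectrum A [sers_spectrum()].
#' @param peak,baseline Positions in cm^-1.
#' @return Scalar intensity difference.
#' @export
peak_response <- function(spectrum, peak = 792, baseline = 723) {
  spectrum$intensities[nearest_index(spectrum$wavenumbers, peak)] -
    spectrum$intensities[nearest_index(spectrum$wavenumbers, baseline)]
}

#' Select the spectra with the largest quality indices
#'
#' Ties are broken by raster order (earlier spectra first).
#'
#' @param map A [spectral_map()].
#' @param qi Quality-index vector for the map (see [compute_qi_map()]).
#' @param k Number of spectra to keep; default 20.
#' @return A [spectral_map()] containing the selected spectra, ordered
#'   by decreasing quality index.
#' @export
select_top_k_by_qi <- function(map, qi, k = 20) {
  m <- n_spectra(map)
  if (length(qi) != m)
    stop_sq("qi vector length must equal the spectrum count",
            "sersquant_argument_error")
  if (k <= 0 || k > m)
    stop_sq(sprintf("k must lie in 1..%d", m), "sersquant_argument_error")
  idx <- order(-qi, seq_along(qi))[seq_len(k)]
  spectral_map(map$well_id, map$wavenumbers,
               map$intensities[, idx, drop = FALSE],
               map$coords[idx, , drop = FALSE])
}

#' Ordinary least-squares line with R-squared
#'
#' @param x Predictor (log10 concentration).
#' @param y Response.
#' @return List with `slope`, `intercept`, `r_squared` (squared Pearson
#'   correlation; 0 by convention when `y` is constant).
#' @export
linear_regression <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop_sq("need at least two (x, y) pairs", "sersquant_regression_error")
  if (length(unique(x)) < 2)
    stop_sq("predictor is constant: regression undefined",
            "sersquant_regression_error")
  fit <- stats::lm(y ~ x)
  if (stats::var(y) == 0)
    return(list(slope = 0, intercept = mean(y), r_squared = 0, lm = fit))
  r <- stats::cor(x, y)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r^2, lm = fit)
}

#' Subtract the pooled matrix-blank mean spectrum from a plate
#'
#' The mean spectrum over all blank wells is subtracted pointwise from
#' every spectrum of every well (blanks included), mirroring the
#' background-subtraction robustness check of the calibration methods.
#'
#' @param plate A `sers_plate`.
#' @return A new `sers_plate` with subtracted intensities.
#' @export
blank_subtract <- function(plate) {
  blank_wells <- plate$design$well_id[plate$design$is_blank]
  if (length(blank_wells) == 0)
    stop_sq("plate has no blank wells", "sersquant_argument_error")
  blank_mean <- mean_spectrum(plate$maps[blank_wells])
  maps <- lapply(plate$maps, function(m) {
    if (length(m$wavenumbers) != length(blank_mean$wavenumbers))
      stop_sq("axis mismatch between map and blank mean",
              "sersquant_argument_error")
    spectral_map(m$well_id, m$wavenumbers,
                 m$intensities - blank_mean$intensities, m$coords)
  })
  structure(list(design = plate$design, maps = maps,
                 config = plate$config, seed = plate$seed),
            class = "sers_plate")
}

#' Fit a SERS calibration curve from a mapped plate
#'
#' Builds the calibration response of every well and regresses the
#' per-concentration values against `log10(concentration)` by one of
#' three strategies:
#'
#' \describe{
#'   \item{`total_population`}{each well's response is the peak-minus-
#'     trough intensity (default 792 - 723 cm^-1) of the mean of all
#'     its spectra; the regression uses the per-concentration mean of
#'     the replicate responses.}
#'   \item{`qi_sample`}{as above, but each well is represented by the
#'     mean of its `k` (default 20) highest-quality-index spectra, so
#'     spectra without analyte signal do not dilute the average.}
#'   \item{`cdf`}{each concentration's pooled nonzero quality indices
#'     form a model CDF; a fourth-order polynomial fitted over
#'     probabilities 0.6-0.9 is evaluated on a common 500-point grid,
#'     and the response is the summed pointwise difference from the
#'     blank's model CDF fit. Per-well CDFs give the replicate scatter.
#'     All values are raised by the absolute value of the smallest
#'     data point before regression.}
#' }
#'
#' The blank (concentration 0) is never part of the regression; for the
#' CDF method it serves as the reference distribution.
#'
#' @param plate A `sers_plate` (see [generate_plate()] / [read_plate()]).
#' @param method `"total_population"`, `"qi_sample"` or `"cdf"`.
#' @param qi_cfg A [qi_config()]; used by `qi_sample` and `cdf`.
#' @param k Spectra retained per well by `qi_sample`; default 20.
#' @param metric CDF metric: `"qi"` (default) or `"raw_intensity"`
#'   (raw peak intensities, the degraded variant).
#' @param response_peak,response_baseline Positions (cm^-1) of the
#'   intensity-difference response; defaults 792 and 723.
#' @param prob_range,n_fit CDF fit controls; see [fit_cdf_poly()].
#' @return An object of class `"sers_calibration"` with components
#'   `method`, `responses` (per-well data frame), `model` (per-
#'   concentration data frame used for the regression), `slope`,
#'   `intercept`, `r_squared`, `shift` (CDF positive shift, else 0),
#'   and the fitted `lm`. Supports `print`, `summary`, `coef`,
#'   `predict`, `plot` and `residuals`.
#' @examples
#' cfg <- generator_config(raster_lines = 6, raster_per_line = 6,
#'                         concentrations = twofold_series(5000, 4),
#'                         replicate_wells_per_sample = 2)
#' plate <- generate_plate(make_default_design(cfg), cfg, seed = 1)
#' fit <- sers_calibration(plate, method = "total_population")
#' coef(fit)
#' @export
sers_calibration <- function(plate,
                             method = c("total_population", "qi_sample", "cdf"),
                             qi_cfg = qi_config(), k = 20,
                             metric = c("qi", "raw_intensity"),
                             response_peak = 792, response_baseline = 723,
                             prob_range = c(0.6, 0.9), n_fit = 500) {
  method <- match.arg(method)
  metric <- match.arg(metric)
  design <- plate$design
  if (sum(!design$is_blank) == 0)
    stop_sq("plate contains no analyte concentrations",
            "sersquant_regression_error")
  if (length(unique(design$concentration[!design$is_blank])) < 2)
    stop_sq("need at least two distinct concentrations for a calibration",
            "sersquant_regression_error")

  if (method == "cdf") {
    res <- cdf_responses(plate, qi_cfg, metric, response_peak,
                         prob_range, n_fit)
  } else {
    well_response <- function(m) {
      if (method == "qi_sample") {
        qi <- compute_qi_map(m, qi_cfg)
        m <- select_top_k_by_qi(m, qi, k = min(k, n_spectra(m)))
      }
      peak_response(mean_spectrum(m), response_peak, response_baseline)
    }
    responses <- data.frame(
      well_id = design$well_id,
      concentration = design$concentration,
      conc_index = design$conc_index,
      response = vapply(design$well_id,
                        function(wid) well_response(plate$maps[[wid]]),
                        numeric(1)),
      row.names = NULL
    )
    model <- stats::aggregate(response ~ concentration + conc_index,
                              data = responses[!design$is_blank, ],
                              FUN = mean)
    res <- list(responses = responses, model = model, shift = 0)
  }

  model <- res$model[order(-res$model$concentration), ]
  reg <- linear_regression(log10(model$concentration), model$response)
  structure(list(method = method,
                 responses = res$responses,
                 model = model,
                 slope = reg$slope, intercept = reg$intercept,
                 r_squared = reg$r_squared,
                 shift = res$shift,
                 k = if (method == "qi_sample") k else NA_integer_,
                 metric = if (method == "cdf") metric else NA_character_,
                 qi_cfg = qi_cfg,
                 lm = reg$lm,
                 call = match.call()),
            class = "sers_calibration")
}

# CDF-method responses: model CDF per concentration vs the blank model
# CDF, per-well CDFs as replicate scatter, joint positive shift.
cdf_responses <- function(plate, qi_cfg, metric, response_peak,
                          prob_range, n_fit) {
  design <- plate$design
  if (!any(design$is_blank))
    stop_sq("the CDF method needs a blank sample as reference",
            "sersquant_argument_error")
  well_values <- lapply(design$well_id, function(wid) {
    m <- plate$maps[[wid]]
    if (metric == "qi") compute_qi_map(m, qi_cfg)
    else m$intensities[nearest_index(m$wavenumbers, response_peak), ]
  })
  names(well_values) <- design$well_id

  fit_of <- function(values_list, source)
    fit_cdf_poly(build_model_cdf(values_list, metric = metric,
                                 source = source),
                 prob_range = prob_range, n_fit = n_fit)

  blank_fit <- fit_of(well_values[design$well_id[design$is_blank]], "blank")

  concs <- unique(design$concentration[!design$is_blank])
  concs <- sort(concs, decreasing = TRUE)
  model_vals <- vapply(concs, function(cc) {
    wids <- design$well_id[design$concentration == cc]
    sigma_delta_qcdf(fit_of(well_values[wids], paste0("c", cc)), blank_fit)
  }, numeric(1))

  nb <- design[!design$is_blank, ]
  rep_vals <- vapply(nb$well_id, function(wid) {
    f <- fit_cdf_poly(build_cdf(well_values[[wid]], metric = metric,
                                source = wid),
                      prob_range = prob_range, n_fit = n_fit)
    sigma_delta_qcdf(f, blank_fit)
  }, numeric(1))

  shift <- abs(min(c(model_vals, rep_vals)))
  responses <- data.frame(well_id = nb$well_id,
                          concentration = nb$concentration,
                          conc_index = nb$conc_index,
                          response = rep_vals + shift,
                          row.names = NULL)
  model <- data.frame(concentration = concs,
                      conc_index = vapply(concs, function(cc)
                        design$conc_index[design$concentration == cc][1],
                        integer(1)),
                      response = model_vals + shift)
  list(responses = responses, model = model, shift = shift)
}

#' @export
print.sers_calibration <- function(x, ...) {
  cat(sprintf("SERS calibration curve (%s method)\n", x$method))
  cat(sprintf("  response ~ log10(concentration [ng/mL]), %d concentrations\n",
              nrow(x$model)))
  cat(sprintf("  slope = %.4f, intercept = %.4f, R^2 = %.4f\n",
              x$slope, x$intercept, x$r_squared))
  if (x$method == "cdf")
    cat(sprintf("  positive shift applied: %.4f (metric: %s)\n",
                x$shift, x$metric))
  invisible(x)
}

#' @export
coef.sers_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.sers_calibration <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) conc <- object$model$concentration
  else if (is.data.frame(newdata)) conc <- newdata$concentration
  else conc <- newdata
  if (any(conc <= 0))
    stop_sq("predictions require positive concentrations",
            "sersquant_argument_error")
  object$intercept + object$slope * log10(conc)
}

#' @export
residuals.sers_calibration <- function(object, ...) {
  object$model$response - predict(object, object$model$concentration)
}

#' @export
summary.sers_calibration <- function(object, ...) {
  per_conc <- do.call(rbind, lapply(split(object$responses,
                                          object$responses$concentration),
    function(d) data.frame(concentration = d$concentration[1],
                           n = nrow(d),
                           mean = mean(d$response),
                           sd = stats::sd(d$response),
                           rsd = stats::sd(d$response) / mean(d$response))))
  per_conc <- per_conc[order(-per_conc$concentration), ]
  rownames(per_conc) <- NULL
  structure(list(calibration = object, per_concentration = per_conc),
            class = "summary.sers_calibration")
}

#' @export
print.summary.sers_calibration <- function(x, ...) {
  print(x$calibration)
  cat("\nPer-concentration replicate responses:\n")
  print(x$per_concentration, digits = 4)
  invisible(x)
}

#' @export
plot.sers_calibration <- function(x, ...) {
  pos <- x$responses$concentration > 0
  lx <- log10(x$responses$concentration[pos])
  graphics::plot(lx, x$responses$response[pos],
                 xlab = "log10 concentration (ng/mL)",
                 ylab = "calibration response", pch = 1,
                 main = sprintf("%s method: slope %.1f, R^2 %.3f",
                                x$method, x$slope, x$r_squared), ...)
  graphics::points(log10(x$model$concentration), x$model$response,
                   pch = 19, col = "red")
  graphics::abline(a = x$intercept, b = x$slope, col = "red")
  invisible(x)
}
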