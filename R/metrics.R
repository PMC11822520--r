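#' Aggregate replicate calibration experiments
#'
#' Averages slopes and R-squared values across experiments, and averages
#' the replicate responses position-wise (well `r` of every experiment
#' is averaged into one value), so a design with five replicate wells
#' yields five experiment-averaged values per concentration.
#'
#' @param curves List of [sers_calibration()] fits of the same method on
#'   identical designs (one per experiment).
#' @return List with `method`, `n_experiments`, `mean_slope`,
#'   `mean_r_squared`, and `responses` (per-well data frame of
#'   experiment-averaged responses).
#' @export
aggregate_experiments <- function(curves) {
  if (length(curves) < 1)
    stop_sq("need at least one experiment", "sersquant_argument_error")
  method <- curves[[1]]$method
  ref <- curves[[1]]$responses[, c("well_id", "concentration")]
  for (cv in curves) {
    if (cv$method != method)
      stop_sq("all experiments must use the same method",
              "sersquant_argument_error")
    if (!identical(cv$responses$well_id, ref$well_id) ||
        !identical(cv$responses$concentration, ref$concentration))
      stop_sq("experiments must share an identical plate design",
              "sersquant_argument_error")
  }
  resp <- rowMeans(vapply(curves, function(cv) cv$responses$response,
                          numeric(nrow(ref))))
  list(method = method,
       n_experiments = length(curves),
       mean_slope = mean(vapply(curves, `[[`, numeric(1), "slope")),
       mean_r_squared = mean(vapply(curves, `[[`, numeric(1), "r_squared")),
       responses = data.frame(ref, response = resp, row.names = NULL))
}

#' Relative standard deviation of replicate responses per concentration
#'
#' Sample standard deviation divided by the mean of the (experiment-
#' averaged) replicate responses at each concentration.
#'
#' @param responses Data frame with columns `concentration`, `response`
#'   (e.g. from [aggregate_experiments()]); the blank
#'   (concentration 0) is excluded.
#' @return Data frame `concentration`, `rsd`, sorted by decreasing
#'   concentration.
#' @export
rsd_per_concentration <- function(responses) {
  d <- responses[responses$concentration > 0, ]
  out <- do.call(rbind, lapply(split(d, d$concentration), function(g) {
    if (nrow(g) < 2)
      stop_sq("RSD needs at least two replicates per concentration",
              "sersquant_argument_error")
    m <- mean(g$response)
    if (m == 0)
      stop_sq(sprintf("zero mean response at %g ng/mL: RSD undefined",
                      g$concentration[1]), "sersquant_undefined_rsd_error")
    data.frame(concentration = g$concentration[1],
               rsd = stats::sd(g$response) / m)
  }))
  out <- out[order(-out$concentration), ]
  rownames(out) <- NULL
  out
}

#' Signal-to-noise as the reciprocal relative standard deviation
#'
#' @param rsd Numeric vector of RSD values, `> 0`. A zero RSD yields
#'   `Inf` with a warning (perfect replicates).
#' @return `1 / rsd`.
#' @export
sn_per_concentration <- function(rsd) {
  if (any(rsd < 0))
    stop_sq("RSD must be nonnegative", "sersquant_argument_error")
  if (any(rsd == 0))
    warning("zero RSD: reporting infinite S/N")
  1 / rsd
}

#' Compare the quantification methods across replicate experiments
#'
#' Builds the three comparison tables: mean slope and mean R-squared per
#' method, per-concentration RSD per method, and per-concentration S/N
#' (reciprocal RSD) per method, with winner flags (largest slope,
#' largest R-squared, smallest RSD, largest S/N per row).
#'
#' @param curves_by_method Named list; each element is a list of
#'   [sers_calibration()] fits (one per experiment) for one method.
#' @return An object of class `"sers_comparison"` with components
#'   `summary` (slope/R-squared table), `rsd`, `sn` (concentration by
#'   method data frames), and `winners`.
#' @export
compare_methods <- function(curves_by_method) {
  if (length(curves_by_method) < 1 || is.null(names(curves_by_method)))
    stop_sq("curves_by_method must be a named list of experiment lists",
            "sersquant_argument_error")
  aggs <- lapply(curves_by_method, aggregate_experiments)
  methods <- names(aggs)

  summary_tbl <- data.frame(
    method = methods,
    mean_slope = vapply(aggs, `[[`, numeric(1), "mean_slope"),
    mean_r_squared = vapply(aggs, `[[`, numeric(1), "mean_r_squared"),
    row.names = NULL
  )
  rsd_list <- lapply(aggs, function(a) rsd_per_concentration(a$responses))
  conc <- rsd_list[[1]]$concentration
  rsd_tbl <- data.frame(concentration = conc)
  for (m in methods) rsd_tbl[[m]] <- rsd_list[[m]]$rsd
  sn_tbl <- data.frame(concentration = conc)
  for (m in methods) sn_tbl[[m]] <- sn_per_concentration(rsd_tbl[[m]])

  pick <- function(vals, fun) methods[fun(vals)]
  winners <- list(
    slope = pick(summary_tbl$mean_slope, which.max),
    r_squared = pick(summary_tbl$mean_r_squared, which.max),
    rsd = vapply(seq_along(conc), function(i)
      pick(as.numeric(rsd_tbl[i, methods]), which.min), character(1)),
    sn = vapply(seq_along(conc), function(i)
      pick(as.numeric(sn_tbl[i, methods]), which.max), character(1))
  )
  structure(list(summary = summary_tbl, rsd = rsd_tbl, sn = sn_tbl,
                 winners = winners,
                 n_experiments = aggs[[1]]$n_experiments),
            class = "sers_comparison")
}

#' @export
print.sers_comparison <- function(x, ...) {
  cat(sprintf("Method comparison over %d replicate experiment(s)\n\n",
              x$n_experiments))
  cat("Mean slope and R^2 per method:\n")
  print(x$summary, digits = 4)
  cat(sprintf("\n(largest slope: %s; largest R^2: %s)\n",
              x$winners$slope, x$winners$r_squared))
  cat("\nRSD per concentration:\n")
  print(x$rsd, digits = 3)
  cat("\nS/N per concentration (reciprocal RSD):\n")
  print(x$sn, digits = 3)
  invisible(x)
}
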