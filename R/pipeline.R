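#' Run the full quantification workflow end to end
#'
#' For each replicate experiment: generate a synthetic plate (seed
#' `seed + experiment - 1`), compute quality indices, and fit the
#' requested calibration methods. Experiments are then aggregated into
#' the method-comparison tables, and (optionally) the lowest
#' concentration is validated against the blank by PCA on the first
#' experiment's plate. Rerunning with the same configuration and seed
#' reproduces identical results.
#'
#' @param config A [generator_config()].
#' @param qi_cfg A [qi_config()].
#' @param methods Subset of
#'   `c("total_population", "qi_sample", "cdf")`.
#' @param n_experiments Number of replicate experiments; default 3.
#' @param seed Base integer seed.
#' @param k Spectra per well for the quality-index sample method.
#' @param validate Run the PCA limit-of-quantification check on the
#'   first experiment; default `TRUE`.
#' @param out_dir Optional output directory; when given, per-method
#'   response tables, the comparison tables, the validation verdict, a
#'   run manifest and a plain-text log are written there.
#' @return An object of class `"sers_run"`: `curves` (method ->
#'   experiment list of [sers_calibration()]), `comparison`
#'   ([compare_methods()] result), `loq` (list of [validate_loq()]
#'   results or `NULL`), `seeds`, `log`.
#' @export
run_pipeline <- function(config = generator_config(),
                         qi_cfg = qi_config(),
                         methods = c("total_population", "qi_sample", "cdf"),
                         n_experiments = 3, seed = 1, k = 20,
                         validate = TRUE, out_dir = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (n_experiments < 1)
    stop_sq("n_experiments must be at least 1", "sersquant_config_error")
  design <- make_default_design(config)
  seeds <- seed + seq_len(n_experiments) - 1L
  curves <- stats::setNames(
    lapply(methods, function(m) vector("list", n_experiments)), methods)
  loq <- NULL
  log_lines <- c(sprintf("run: %d experiment(s), methods [%s], base seed %d",
                         n_experiments, paste(methods, collapse = ", "), seed))

  for (i in seq_len(n_experiments)) {
    plate <- generate_plate(design, config, seed = seeds[i])
    n_total <- sum(vapply(plate$maps, n_spectra, integer(1)))
    qi_nonzero <- mean(vapply(plate$maps, function(m)
      mean(compute_qi_map(m, qi_cfg) > 0), numeric(1)))
    log_lines <- c(log_lines, sprintf(
      "experiment %d (seed %d): %d wells, %d spectra, nonzero-Qi fraction %.3f",
      i, seeds[i], length(plate$maps), n_total, qi_nonzero))
    for (m in methods) {
      cv <- sers_calibration(plate, method = m, qi_cfg = qi_cfg, k = k)
      curves[[m]][[i]] <- cv
      log_lines <- c(log_lines, sprintf(
        "  %s: slope %.3f, intercept %.3f, R^2 %.4f",
        m, cv$slope, cv$intercept, cv$r_squared))
    }
    if (validate && i == 1L) {
      loq <- lapply(c(qi_sample = "qi_sample",
                      total_population = "total_population"),
                    function(m) validate_loq(plate, method = m,
                                             qi_cfg = qi_cfg, k = k))
      for (m in names(loq))
        log_lines <- c(log_lines, sprintf(
          "  loq (%s): blank vs %g ng/mL ellipses %s",
          m, loq[[m]]$concentration,
          if (loq[[m]]$overlap) "overlap" else "disjoint"))
    }
    rm(plate)
  }

  comparison <- compare_methods(curves)
  run <- structure(list(curves = curves, comparison = comparison, loq = loq,
                        seeds = seeds, config = config, qi_cfg = qi_cfg,
                        log = log_lines),
                   class = "sers_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (m in names(run$curves)) {
    resp <- do.call(rbind, lapply(seq_along(run$curves[[m]]), function(i)
      cbind(experiment = i, run$curves[[m]][[i]]$responses)))
    utils::write.csv(resp, file.path(out_dir, paste0("responses_", m, ".csv")),
                     row.names = FALSE)
    fits <- do.call(rbind, lapply(seq_along(run$curves[[m]]), function(i) {
      cv <- run$curves[[m]][[i]]
      data.frame(experiment = i, slope = cv$slope, intercept = cv$intercept,
                 r_squared = cv$r_squared, shift = cv$shift)
    }))
    utils::write.csv(fits, file.path(out_dir, paste0("fits_", m, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(run$comparison$summary,
                   file.path(out_dir, "comparison_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(run$comparison$rsd, file.path(out_dir, "comparison_rsd.csv"),
                   row.names = FALSE)
  utils::write.csv(run$comparison$sn, file.path(out_dir, "comparison_sn.csv"),
                   row.names = FALSE)
  if (!is.null(run$loq)) {
    verdict <- vapply(names(run$loq), function(m) sprintf(
      "%s: blank vs %g ng/mL -> %s", m, run$loq[[m]]$concentration,
      if (run$loq[[m]]$overlap) "overlap" else "disjoint"), character(1))
    writeLines(verdict, file.path(out_dir, "loq_verdict.txt"))
  }
  manifest <- list(seeds = run$seeds,
                   methods = names(run$curves),
                   config = run$config[setdiff(names(run$config),
                                               c("mu_fun", "background_bands",
                                                 "analyte_bands"))])
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(run$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.sers_run <- function(x, ...) {
  cat("SERS quantification run\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n\n")
  print(x$comparison)
  if (!is.null(x$loq)) {
    cat("\n")
    for (m in names(x$loq)) print(x$loq[[m]])
  }
  invisible(x)
}
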