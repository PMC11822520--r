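#' PCA of two spectrum classes
#'
#' Pools the spectra of two classes (typically the matrix blank and the
#' lowest analyte concentration, after truncation and baseline
#' correction), mean-centers, and extracts the first two principal
#' components. Each component is oriented so its largest-magnitude
#' loading is positive, for reproducibility.
#'
#' @param class_a,class_b Lists of [sers_spectrum()] objects sharing one
#'   axis (each at least 3 spectra).
#' @param labels Character vector of two class labels.
#' @return An object of class `"sers_pca"`: `scores` data frame
#'   (`PC1`, `PC2`, `class`), `explained` (two explained-variance
#'   ratios), `rotation`.
#' @export
run_pca <- function(class_a, class_b, labels = c("blank", "analyte")) {
  if (length(class_a) < 3 || length(class_b) < 3)
    stop_sq("each class needs at least 3 spectra", "sersquant_argument_error")
  spectra <- c(class_a, class_b)
  w <- spectra[[1]]$wavenumbers
  X <- t(vapply(spectra, function(s) {
    if (length(s$wavenumbers) != length(w) || max(abs(s$wavenumbers - w)) > 0)
      stop_sq("spectra do not share a common truncated axis",
              "sersquant_argument_error")
    s$intensities
  }, numeric(length(w))))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  total_var <- sum(pc$sdev^2)
  if (total_var <= .Machine$double.eps * max(1, sum(abs(X))))
    stop_sq("pooled spectra have no variance: PCA degenerate",
            "sersquant_degeneracy_error")
  n_pc <- min(2L, length(pc$sdev))
  scores <- pc$x[, seq_len(n_pc), drop = FALSE]
  rotation <- pc$rotation[, seq_len(n_pc), drop = FALSE]
  for (j in seq_len(n_pc)) {
    sgn <- sign(rotation[which.max(abs(rotation[, j])), j])
    if (sgn < 0) {
      rotation[, j] <- -rotation[, j]
      scores[, j] <- -scores[, j]
    }
  }
  if (n_pc < 2L) {  # rank-1 data: PC2 carries exactly zero variance
    scores <- cbind(scores, 0)
    rotation <- cbind(rotation, 0)
  }
  explained <- c(pc$sdev[1]^2, if (length(pc$sdev) > 1) pc$sdev[2]^2 else 0) /
    total_var
  structure(list(
    scores = data.frame(PC1 = scores[, 1], PC2 = scores[, 2],
                        class = rep(labels, c(length(class_a),
                                              length(class_b)))),
    explained = explained,
    rotation = rotation),
    class = "sers_pca")
}

#' @export
print.sers_pca <- function(x, ...) {
  cat(sprintf("<sers_pca> %d scores; explained variance %.1f%% / %.1f%%\n",
              nrow(x$scores), 100 * x$explained[1], 100 * x$explained[2]))
  invisible(x)
}

#' Construct a 2-D ellipsoid from center and shape
#'
#' Low-level geometric constructor; [confidence_ellipsoid()] builds one
#' from PCA scores.
#'
#' @param center Length-2 numeric center.
#' @param shape 2x2 symmetric positive-definite matrix (covariance).
#' @param radius2 Squared Mahalanobis radius of the boundary.
#' @param label Class label.
#' @param n_boundary Number of boundary points sampled; default 360.
#' @return An object of class `"sers_ellipsoid"`.
#' @export
ellipsoid <- function(center, shape, radius2, label = "",
                      n_boundary = 360) {
  shape <- (shape + t(shape)) / 2
  ev <- eigen(shape, symmetric = TRUE)
  if (any(ev$values <= 0))
    stop_sq("ellipsoid shape matrix must be positive definite",
            "sersquant_degeneracy_error")
  theta <- seq(0, 2 * pi, length.out = n_boundary + 1)[-(n_boundary + 1)]
  B <- ev$vectors %*% diag(sqrt(ev$values))
  boundary <- t(center + sqrt(radius2) * B %*% rbind(cos(theta), sin(theta)))
  structure(list(label = label, center = center, shape = shape,
                 radius2 = radius2, boundary = boundary),
            class = "sers_ellipsoid")
}

#' 95% confidence ellipse of a 2-D score cloud
#'
#' Ellipse centered at the class mean with axes from the score
#' covariance scaled by the chi-square quantile (2 degrees of freedom)
#' at the requested level.
#'
#' @param scores Matrix or data frame of 2-D scores (at least 3 rows;
#'   columns `PC1`, `PC2` or the first two columns).
#' @param level Confidence level; default 0.95.
#' @param label Class label attached to the result.
#' @return A [ellipsoid()] of class `"sers_ellipsoid"`.
#' @export
confidence_ellipsoid <- function(scores, level = 0.95, label = "") {
  S <- as.matrix(scores)[, 1:2, drop = FALSE]
  storage.mode(S) <- "double"
  if (nrow(S) < 3)
    stop_sq("need at least 3 score points", "sersquant_argument_error")
  ellipsoid(colMeans(S), stats::cov(S), stats::qchisq(level, df = 2),
            label = label)
}

#' @export
print.sers_ellipsoid <- function(x, ...) {
  cat(sprintf("<sers_ellipsoid>%s center (%.3g, %.3g), radius^2 %.3g\n",
              if (nzchar(x$label)) paste0(" ", x$label) else "", x$center[1],
              x$center[2], x$radius2))
  invisible(x)
}

inside_ellipsoid <- function(points, e) {
  stats::mahalanobis(points, e$center, e$shape) < e$radius2
}

#' Do two ellipses overlap?
#'
#' TRUE iff the strict interiors intersect, decided by mutual
#' center-containment plus dense boundary sampling (each boundary point
#' of one ellipse tested for strict containment in the other).
#'
#' @param e1,e2 Objects from [confidence_ellipsoid()] / [ellipsoid()].
#' @return Logical.
#' @export
ellipsoids_overlap <- function(e1, e2) {
  any(inside_ellipsoid(rbind(e1$center), e2)) ||
    any(inside_ellipsoid(rbind(e2$center), e1)) ||
    any(inside_ellipsoid(e1$boundary, e2)) ||
    any(inside_ellipsoid(e2$boundary, e1))
}

#' Confirm the limit of quantification by PCA class separation
#'
#' Collects the spectra each calibration method would average for the
#' matrix blank and the lowest analyte concentration (per-well mean
#' spectra for the total-population method; per-well means of the top-k
#' quality-index spectra for the quality-index sample method),
#' truncates them to the analysis window, applies IarPLS baseline
#' correction, runs PCA, and tests whether the two classes' 95%
#' confidence ellipses overlap. Disjoint ellipses support quantifying
#' at that concentration.
#'
#' @param plate A `sers_plate` with a blank sample.
#' @param method `"qi_sample"` or `"total_population"`.
#' @param qi_cfg A [qi_config()]; used by `qi_sample`.
#' @param k Spectra per well for `qi_sample`; default 20.
#' @param lo,hi Truncation window (cm^-1); defaults 585.48 / 1710.01.
#' @param baseline_cfg A [baseline_config()].
#' @param level Ellipse confidence level; default 0.95.
#' @return An object of class `"loq_validation"`: `method`, `pca`
#'   ([run_pca()] result), `ellipsoids` (list of two), `overlap`
#'   (logical; FALSE means the lowest concentration is distinguishable
#'   from the blank), `concentration` (the lowest concentration
#'   tested).
#' @export
validate_loq <- function(plate, method = c("qi_sample", "total_population"),
                         qi_cfg = qi_config(), k = 20,
                         lo = 585.48, hi = 1710.01,
                         baseline_cfg = baseline_config(), level = 0.95) {
  method <- match.arg(method)
  design <- plate$design
  if (!any(design$is_blank))
    stop_sq("plate has no blank wells", "sersquant_argument_error")
  lowest <- min(design$concentration[!design$is_blank])
  class_wells <- list(blank = design$well_id[design$is_blank],
                      lowest = design$well_id[design$concentration == lowest])
  class_spectra <- lapply(class_wells, function(wids) {
    lapply(wids, function(wid) {
      m <- plate$maps[[wid]]
      if (method == "qi_sample") {
        qi <- compute_qi_map(m, qi_cfg)
        m <- select_top_k_by_qi(m, qi, k = min(k, n_spectra(m)))
      }
      s <- truncate_spectrum(mean_spectrum(m), lo = lo, hi = hi)
      iarpls_baseline(s, baseline_cfg)$corrected
    })
  })
  labels <- c("blank", sprintf("%g ng/mL", lowest))
  pca <- run_pca(class_spectra$blank, class_spectra$lowest, labels = labels)
  ells <- lapply(labels, function(lb) {
    sc <- pca$scores[pca$scores$class == lb, c("PC1", "PC2")]
    confidence_ellipsoid(sc, level = level, label = lb)
  })
  structure(list(method = method, concentration = lowest, pca = pca,
                 ellipsoids = ells,
                 overlap = ellipsoids_overlap(ells[[1]], ells[[2]]),
                 level = level),
            class = "loq_validation")
}

#' @export
print.loq_validation <- function(x, ...) {
  cat(sprintf("LOQ validation (%s method): blank vs %g ng/mL\n",
              x$method, x$concentration))
  cat(sprintf("  explained variance: PC1 %.1f%%, PC2 %.1f%%\n",
              100 * x$pca$explained[1], 100 * x$pca$explained[2]))
  cat(sprintf("  %.0f%% confidence ellipses %s\n", 100 * x$level,
              if (x$overlap) "OVERLAP (classes not distinguishable)"
              else "are DISJOINT (classes distinguishable)"))
  invisible(x)
}

#' @export
plot.loq_validation <- function(x, ...) {
  sc <- x$pca$scores
  cls <- unique(sc$class)
  cols <- c("blue", "red")
  graphics::plot(sc$PC1, sc$PC2,
                 col = cols[match(sc$class, cls)], pch = 19,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$pca$explained[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$pca$explained[2]),
                 main = sprintf("%s method: ellipses %s", x$method,
                                if (x$overlap) "overlap" else "disjoint"),
                 ...)
  for (i in seq_along(x$ellipsoids))
    graphics::lines(rbind(x$ellipsoids[[i]]$boundary,
                          x$ellipsoids[[i]]$boundary[1, ]), col = cols[i])
  graphics::legend("topright", legend = cls, col = cols, pch = 19, bty = "n")
  invisible(x)
}
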