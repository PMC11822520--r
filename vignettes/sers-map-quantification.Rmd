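---
title: "Quantifying analytes from SERS spectral maps: methods and design"
author: "sersquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying analytes from SERS spectral maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sersquant)
```

## The problem

Surface-enhanced Raman spectroscopy (SERS) on dried sample wells is
spatially heterogeneous: enhancement is concentrated in sparse
"hotspots", so a raster scan across one well yields hundreds to
thousands of spectra ranging from pure background to very strong
analyte signal. A conventional calibration averages everything and
lets the many empty spectra dilute the response. `sersquant`
implements and compares three ways of turning a mapped well plate into
a calibration curve against `log10` concentration, plus the
preprocessing and validation steps around them:

1. **Total population**: average all spectra of a well, take the
   peak-minus-trough intensity response.
2. **Quality-index (Q_i) sample**: score every spectrum with a
   figure of merit, average only the top-`k` spectra per well
   (default `k = 20`), same response.
3. **CDF method**: model the distribution of all nonzero Q_i values of
   a concentration with an empirical cumulative distribution function
   and regress a summed distance from the blank's distribution.

The driving application is therapeutic drug monitoring of the
antiretroviral emtricitabine (FTC) in plasma, whose SERS signature has
its dominant ring-breathing band at 792 cm^-1 with a trough at
723 cm^-1 and secondary bands at 1586 and 1672 cm^-1. Nothing in the
package is specific to that analyte: peak positions are configuration.

## The data model

* `sers_spectrum`: one strictly ascending wavenumber axis (cm^-1) plus
  intensities (detector counts).
* `spectral_map`: all spectra of one well (shared axis, intensity
  matrix in raster order with line/position coordinates).
* `plate_design`: wells mapped to samples. The default layout is an
  8 x 5 plate holding seven twofold concentrations from 5000 ng/mL
  down to 78 ng/mL (integer truncation) plus a matrix blank, five
  replicate wells each. Concentration index `n` runs from 0 (highest)
  to 7 (blank).
* The default raster is 42 lines x 43 positions = 1806 spectra per
  well, 72,240 per plate.

Maps round-trip through a columnar CSV dialect (wavenumber column plus
one column per spectrum, headers carrying raster coordinates), plates
through a JSON manifest; gzip is handled transparently.

## The synthetic-data world

No instrument data ships with the package; every downstream stage is
exercised against a generator whose defaults are a single, fixed
statement of the world being emulated:

* **Hotspot sparsity.** Each spectrum independently carries analyte
  signal with probability `hotspot_fraction` (default 0.25): most map
  positions see little or none, which is exactly why the three methods
  differ.
* **Amplitude law.** Nonzero amplitudes are exponential with mean
  `mu(c) = beta * log10(c / c_ref)` (clipped at zero), by default with
  a minor pseudo-normal admixture (10%, mean 40, sd 15 counts) of the
  kind plasma matrices add on top of the exponential hotspot
  statistics. `beta = 50` counts per decade and `c_ref = 39` ng/mL
  (half the lowest plate concentration, so the lowest concentration
  retains positive expected signal). The log-linear mean makes the
  generator's ground truth match the calibration model, enabling exact
  parameter-recovery tests. A `deterministic` law (amplitude exactly
  `mu(c)`) supports noise-free recovery studies, and `mu_fun` lets a
  user substitute any mean model.
* **Bands.** The analyte signature is Lorentzian (792 cm^-1 dominant,
  1586/1672 cm^-1 weaker); the background is a congested set of broad
  Gaussian humps plus a sharp interferent at 807 cm^-1 near the
  analyte peak. The 723-792 cm^-1 region of the background is locally
  balanced so the matrix blank's quality index is governed by the
  interferent and noise — a matrix blank with real (nonzero) signal
  structure, as plasma blanks show, which is what makes the blank's
  reference CDF constructible.
* **Noise and background variability.** Additive Gaussian noise
  (sd 20 counts) plus a per-spectrum multiplicative background scale
  (lognormal, mean 1, cv 0.15). The latter models the
  spectrum-to-spectrum heterogeneity of the matrix background; it is
  removed by the quality index's local baseline subtraction but
  retained by raw peak intensities, which is the structural reason
  raw-intensity CDFs calibrate worse than Q_i CDFs.
* **The wavenumber axis** defaults to 400-1800 cm^-1 at 1 cm^-1.

What the generator deliberately does **not** emulate: spatially
correlated drying ("coffee-ring") patterns — hotspot draws are i.i.d.
across the raster; electromagnetic enhancement physics; instrument
drift; and well-to-well chemistry differences beyond the background
scale law. A green test on this world therefore establishes that the
statistical machinery behaves as designed under heterogeneous hotspot
statistics — not that any particular instrument will achieve a given
slope or limit of quantification.

```{r generator, eval = FALSE}
cfg <- generator_config()          # the default world
design <- make_default_design(cfg) # 40 wells: 7 concentrations + blank
plate <- generate_plate(design, cfg, seed = 1)
```

## The quality index

For each configured peak `p` with baselines `b1`, `b2`, the index of a
spectrum is the mean intensity in a window of `n` grid points on each
side of the point nearest `p`, minus the mean of the two baseline
window means. With `t` peaks the per-peak terms are combined as a
geometric mean (product raised to `1/t`); any nonpositive term forces
the index to 0, and negative indices are defined as 0. The defaults
are the single 792 cm^-1 peak with both baselines at 723 cm^-1 and
`n = 2`.

Numerical conventions: the grid point nearest a position is found by
minimum absolute distance with ties broken toward the lower
wavenumber; windows are clipped at the axis edges; `b1 = b2` is
allowed (the baseline mean then equals that single window mean). The
index is shift-invariant (adding a constant to a spectrum) and, for a
single peak, scale-equivariant — both properties are tested against a
brute-force loop oracle.

The multi-peak combination is a design choice: a per-peak-balanced
figure of merit that reduces exactly to baseline-subtracted peak
intensity for `t = 1`, the only case the driving experiments exercise.
Zeroing on any nonpositive term avoids fractional powers of negative
numbers.

## Calibration methods

`sers_calibration(plate, method = ...)` is the central fitting
function; it returns an object with `print`, `summary`, `coef`,
`predict`, `plot` and `residuals` methods. All three methods regress
per-concentration responses on `log10(concentration)`; the blank is
never a regression point (its log concentration is undefined) — it
serves as the CDF reference and as the PCA comparison class.

**Total population.** One response per well: the 792 − 723 cm^-1
intensity difference of the well's mean spectrum. The regression is
fitted to the per-concentration means of the five replicate responses.

**Q_i sample.** Identical, except each well is represented by the mean
of its `k = 20` highest-Q_i spectra (ties broken by raster order).
With `k` equal to the population size this reproduces the total
population method exactly — a tested coincidence.

**CDF method.** For each well, the nonzero Q_i values are sorted
ascending; index `i = 1..m` divided by `m` gives the probability, and
the abscissa is `log10 Q_i` (tied values keep duplicate abscissae).
Pooling all five replicates of a concentration the same way gives the
concentration's *model CDF*. A fourth-order polynomial
`x = f(probability)` is fitted over the probability window 0.6-0.9 —
the segment that carries the most concentration information and is
well approximated by a quartic — and evaluated at 500 evenly spaced
probabilities, so every fit shares one grid. The calibration response
of concentration `n` is the summed pointwise difference

    Sigma-Delta-QCDF(n) = sum over the 500 matched probabilities of
                          [ Q_n(p) - Q_blank(p) ]

between the populated fits of the concentration and of the blank,
taken in intensity units (`10^x`). Differencing in intensity units is
a deliberate design choice: it makes the response linear in the
analyte amplitude scale, so the log-linear amplitude world yields an
exactly linear calibration (the package's noise-free recovery test:
the response reduces to `500 * mu(c) * gain`), and it puts the CDF
slope on the same intensity footing as the other two methods. Summing
`log10` differences instead would make exact log-linear calibration
impossible for any amplitude law that keeps the averaging methods
linear, and compresses the method's sensitivity below the Q_i sample
method's in every realistic regime — the opposite of how the method
behaves.

Replicate-level responses (one per well, each well's own CDF against
the blank *model* CDF) provide the scatter; following the source
procedure every data point is then increased by the absolute value of
the smallest data point. When responses dip negative this lands the
minimum at exactly zero; when all are positive it simply doubles the
minimum — the rule is applied literally, and the regression slope and
R^2 are unaffected either way. The regression uses the shifted model
values.

The `metric = "raw_intensity"` variant builds the CDFs from raw
792 cm^-1 intensities (nonpositive values removed) instead of Q_i —
the degraded comparison showing why local baseline subtraction
matters.

**Blank subtraction.** `blank_subtract()` removes the pooled blank
mean spectrum from every spectrum. For the total-population method the
slope is unchanged by exact algebra (a constant response offset
cancels); for the Q_i sample method the Q_i ranking is shift-invariant
so selection, and hence the slope, is preserved (up to ties at the
clipping boundary). Both invariances are tested.

## Replicate aggregation and comparison metrics

Experiments (default three, seeded `seed`, `seed + 1`, `seed + 2`) are
aggregated by averaging slopes and R^2 across experiments and
averaging replicate responses position-wise (well `r` of every
experiment becomes one value), yielding five experiment-averaged
values per concentration. Per concentration the relative standard
deviation is the sample (n − 1) standard deviation divided by the
mean, and the signal-to-noise ratio is its exact reciprocal —
`S/N * RSD = 1` cell-wise by construction (a zero RSD reports `Inf`
with a warning). `compare_methods()` assembles the slope/R^2, RSD and
S/N tables with per-row winner flags; the min-RSD winner always equals
the max-S/N winner.

## Baseline correction and PCA validation of the LOQ

`validate_loq()` asks whether the lowest concentration is
statistically distinguishable from the matrix blank, using the same
spectra each calibration method would average (per-well means for the
total population method, per-well top-`k` means for the Q_i sample
method — five spectra per class). Each spectrum is truncated to
585.48-1710.01 cm^-1 and baseline-corrected by IarPLS before PCA.

**IarPLS.** A Whittaker smoother with second-difference penalty
`lambda` is solved for the baseline `z` under weights `w`; the weights
are then updated by an asymmetric logistic rule on the residuals
`d = y − z`, scaled by the standard deviation `s` of the negative
residuals and sharpened with the iteration index `i`:
`w = 1 / (1 + exp(2 i (d − 2 s) / s))`. Points far above the baseline
(peaks) lose weight; points at or below keep weight near one.
Iteration stops when the relative weight-change norm falls below the
tolerance, when fewer than two negative residuals remain (a perfect
fit), or at the iteration cap — the latter flags `converged = FALSE`
on the result rather than failing. Defaults `lambda = 1e5`, 50
iterations, tolerance `1e-3` suit the default axis; none of these is
fixed by the driving study, so they are exposed in
`baseline_config()`. The linear system is solved sparsely (banded
penalty) via the Matrix package. On the package's synthetic fixture
(gentle quadratic baseline + three narrow Lorentzians, noise-free) the
baseline is recovered with RMSE below 1% of the tallest peak and peak
positions are preserved.

**PCA and ellipses.** Pooled, mean-centered PCA (via `prcomp`) returns
the first two score columns, each component oriented so its
largest-magnitude loading is positive. Rank-1 inputs are allowed (PC2
is identically zero, the first explained-variance ratio is 1); inputs
with no variance at all are a degeneracy error. Each class's 95%
confidence ellipse is centered at the class mean with shape from the
score covariance scaled by the chi-square quantile at 2 degrees of
freedom. Overlap is decided geometrically — mutual center containment
plus dense (360-point) boundary sampling with strict interior tests —
matching the visual criterion of the source figures rather than a
formal hypothesis test.

In the default world (and more sharply in a "low-signal" regime with
sparser hotspots of stronger amplitude, hotspot fraction 0.1 and
`beta = 150`), the Q_i sample classes separate at 78 ng/mL while the
total-population classes do not: averaging 1806 spectra of which a
handful carry signal buries the class difference in noise, while
top-20 sampling concentrates it. That contrast is the package's
qualitative LOQ result, and it is computed fresh by the test suite —
nothing about a particular real instrument follows from it.

## Numerical choices and degenerate inputs

* Polynomial CDF fits center the probability axis before building the
  Vandermonde matrix (conditioning); fits with fewer than five
  in-range points are an error; mismatched fit grids cannot be
  differenced.
* An all-zero Q_i vector cannot form a CDF (error); the blank must be
  present for the CDF method.
* Regression needs two distinct concentrations; a constant response
  returns slope 0 with R^2 = 0 by convention.
* Quality-index windows clip at axis edges; positions outside the
  axis range are errors.
* All randomness flows through R's global RNG; `generate_plate()` and
  `run_pipeline()` take explicit seeds and are bit-reproducible.

## Limitations

* Slope comparisons across methods mix response units (intensity
  counts for the averaging methods, summed CDF differences for the
  CDF method); the ordering of sensitivities is therefore a statement
  about a signal regime, not a universal constant.
* The generator's amplitude scale, noise level and background are a
  stated world; absolute slopes, RSDs and S/N values are not
  predictions for any instrument.
* No formal LOD/LOQ estimator (3-sigma style) is provided; the LOQ
  criterion is PCA separability.
* Multivariate calibration (PLS/MLR) and spectral deconvolution are
  out of scope.
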