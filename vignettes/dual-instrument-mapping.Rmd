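---
title: "Dual-instrument geostatistical mapping: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-instrument geostatistical mapping: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duokrig)
```

## The problem

Soil surveys of potentially toxic trace elements (Cu, Pb) at mine sites face a
resolution/accuracy trade-off. Laboratory assays (ICP--AES after acid
digestion) are accurate but so costly that only a handful of stations get
sampled; portable XRF reads hundreds of stations in the field but runs high
and noisy, albeit almost perfectly linearly related to the lab values
(calibration R^2^ near 0.99). `duokrig` implements the four standard mapping
strategies for such surveys and the machinery to compare them:

1. **Sparse accurate only** — ordinary kriging (OK) of the lab assays.
2. **Dense biased only** — OK of the field assays, left on their own scale.
3. **Calibration fusion** — regress lab on field values at the co-located
   stations, map every field reading through the fitted line, merge with the
   lab data (lab wins where both exist within a co-location tolerance),
   then OK.
4. **Co-kriging (CK)** — lab values as the primary variable, field values as
   the secondary, under a linear model of coregionalization (LMC).

## Model

Each assay $z(x_i)$ is a realization of a random function $Z(x)$. The spatial
structure is summarized by the semivariogram
$\gamma(h) = \frac{1}{2N(h)}\sum [z(x_i) - z(x_i+h)]^2$ over pairs in a
distance (and optionally direction) class. A theoretical model — Gaussian by
default, spherical and exponential available — is fitted by pair-count
weighted least squares. Geometric anisotropy rotates the lag into a
major/minor frame (azimuth clockwise from north) and scales by the two ranges
to an isotropic effective distance; the *practical range* convention is used
(the Gaussian form is $c_0 + c\,(1 - e^{-3h_e^2})$, reaching ~95% of the sill
at the stated range). $\gamma(0) = 0$ exactly: the nugget is a discontinuity
for $h > 0$, so kriging interpolates the data exactly.

OK predicts $z^* = \sum_i \lambda_i z_i$ with $\sum\lambda_i = 1$
(unbiasedness), solving the semivariance system with one Lagrange multiplier.
Ordinary CK adds secondary weights $k_j$ with $\sum k_j = 0$ and needs the
two direct variograms plus a cross-variogram sharing the same basic
structures; validity requires $|c_{12}| \le \sqrt{c_{11} c_{22}}$ per
structure (checked by `check_lmc()`). Because the feasible set of the CK
minimization contains the OK solution ($k = 0$), a valid secondary variable
can only reduce the kriging variance — asserted as a test invariant.

Concentrations are strongly right-skewed, so kriging operates on natural logs
whenever the adjusted Fisher--Pearson skewness exceeds 1 (`skewness_screen()`,
overridable). Back-transforms:

* `naive_exp`, $\exp(z^*)$ — a median-type estimate, kept as the
  `krige_lognormal()` default for map display because it is stable and exact
  at data points;
* `unbiased`, $\exp(z^* + \sigma^2_{OK}/2 - \psi)$ — the classical
  lognormal-kriging estimator of the conditional mean.

For *validation*, the pipeline defaults to `unbiased`. This was a deliberate
reversal after a measured failure mode: the naive back-transform
under-predicts on the original scale by roughly $e^{-\sigma^2/2}$, and when
the dense instrument is biased high by a factor near that shrinkage, the two
errors cancel and RMSE comparisons systematically *flatter the biased
instrument*. The GIS workflows this package emulates back-transform
approximately unbiasedly, so scoring follows that convention.

## Tunable parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| grid `cell_size` | 5 | m | typical DEM spacing for 1:5000 mine-site mapping |
| variogram model | gaussian | — | strong short-range continuity of contamination plumes |
| lag binning | span/(2·12) | m | half-span cutoff, 12 lags; beyond-cutoff pairs dropped |
| angular tolerance | ±22.5 | deg | directional variography without starving bins |
| co-location tolerance | 0.5 | m | survey station re-occupation accuracy |
| skewness threshold | 1.0 | — | log-transform trigger |
| calibration floor | 1 | mg/kg | calibrated values must stay positive for logs |

## Numerical choices

Gaussian variograms produce notoriously ill-conditioned kriging matrices.
Four safeguards are applied, all documented here because they alter results
only in degenerate corners: (i) fitted ranges are bounded by twice the
observed lag span (beyond-support ranges are unidentifiable); (ii) nuggets
used by the pipeline are floored at 1% of the partial sill; (iii) the
semivariance block is normalized to unit scale before the dense solve
(weights are invariant; multiplier and variance are rescaled), which matters
when raw-scale sills of order 10^6^ meet unit constraint rows; (iv) a
one-shot escalating ridge (10^-8^–10^-4^ relative) rescues systems that are
singular to machine precision, with a warning. The fitted cross-sill is
capped at 0.97 of the Cauchy--Schwarz bound: at full correlation with
co-located stations the CK matrix loses rank. Duplicate coordinates within
1 nm are an error, not silently merged. Kriging variances in
[-10^-6^·scale, 0) are clamped to zero.

The LMC fitted from data is primary-led: the sparse primary's isotropic fit
sets the shared range, the secondary's sills are re-estimated at that range
by weighted *linear* least squares (the model is linear in nugget and sill
once the range is fixed), and the cross-sill comes from a one-parameter WLS
fit to the experimental cross-variogram of the co-located pairs. This
mirrors how a primary-variable-led workflow actually proceeds — and it is
deliberately *not* optimal: the sparse primary variography limits the whole
model, which is the structural reason CK underperforms calibration fusion
when the primary set is small.

## What the synthetic generator emulates — and what it does not

`scenario_config()` states a world: a lognormal concentration field —
deterministic hotspot trend (Gaussian-decay point sources standing in for
waste piles and pit heads) plus a stationary Gaussian random field in log
space with a Gaussian variogram (nugget 0.4, partial sill 1.3, ranges
70/35 m, azimuth 115°, copied from the dense-survey variography of the
motivating study) — sampled by a campaign of 100 secondary stations, 12
primary stations co-located with 12 of them, and 11 primary-instrument
validation stations. The primary instrument is unbiased with 5% lognormal
noise; the secondary reads `1.5·truth + 10` with proportional noise of 20%
(the stated measurement error of 2-minute field-XRF readings), yielding
co-located calibration R^2^ ≈ 0.99.

The bias slope deserves honesty: the study that motivates the defaults never
published its calibration coefficients, only R^2^ and the direction of the
bias. The slope was therefore calibrated to the *qualitative* regime that
study reports — the biased dense instrument must be bad enough that fusing
it with accurate data clearly helps (strategy 3 beats 2), yet still more
informative than twelve accurate points alone (2 beats 1 on average).
Measured across bias slopes, both properties hold jointly in expectation in
a window around 1.5; far below it the bias becomes negligible, far above it
the dense instrument becomes the worst input. Outside that qualitative
anchoring the value is arbitrary, and per-replicate rankings remain noisy —
which is why the replicated comparison is run at hundreds of replicates, not
one.

One finding of the replicated comparison deserves emphasis: calibration
fusion (3) separates *robustly* from the single-instrument strategies (1 and
2), but only *narrowly* from co-kriging (4) — at 300 replicates their win
counts differ by a handful either way depending on the random stream. This
is not a defect of the study design: when the secondary variable is almost
exactly proportional to the primary, ordinary co-kriging implicitly performs
the calibration through the cross-structure, so the two data-fusion routes
are nearly statistically equivalent. The practical arguments for fusion are
its simplicity and its robustness to LMC misspecification, not a large
accuracy margin.

The generator does **not** emulate: terrain-driven transport (real plumes
follow drainage, not ellipses), spatially structured instrument error,
censoring at detection limits, or preferential sampling of hotspots. A green
ranking test therefore establishes that the *pipeline* reproduces the
expected ordering in the stated world, not that the ordering holds for any
real survey.

The random field is realized by exact Cholesky factorization of the grid
covariance (limited to 4096 cells); the factor is cached in
`field_simulator()` so replicate studies pay it once.

## Design decisions taken where the design was open

* **Sill convention**: parameter tables in the wild rarely say whether
  "sill" includes the nugget. `variogram_from_config()` takes
  `sill_is_total` (default `TRUE`) instead of guessing.
* **Cross-nugget reported as "N/A"** is read as zero, not as missing.
* **Regression direction** for calibration is primary-on-secondary (inverse
  calibration): the line is used to predict lab-equivalent values from field
  readings. OLS is the default; Deming regression is available but
  non-default since the calibration's purpose is prediction, not structural
  slope estimation.
* **Validation at exact coordinates**, not nearest grid cell, avoiding
  raster discretization error in the comparison.
* **No per-fold variogram refitting** in leave-one-out cross-validation: one
  parameter set describes one map. A refit-per-fold variant would mix model
  selection into prediction error.
* **ME sign**: observed − predicted, so positive mean error means
  underestimation.
* **Global kriging neighborhood** by default (n ≤ ~120 in the intended
  regime); a nearest-n option exists for larger sets.

## Known limitations

* The unbiased lognormal back-transform can overshoot where the kriging
  variance is large (sparse data, Gaussian model); maps meant for display
  may prefer the naive transform — this is exactly the trade-off the two
  options expose.
* Anisotropy azimuths must be supplied (or fitted with the azimuth fixed);
  there is no automatic anisotropy-direction search.
* The LMC is restricted to one basic structure plus nugget; nested
  structures are out of scope.
* Cross-variography requires co-located pairs; displaced-pair (pseudo)
  cross-variograms are not implemented.
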