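---
title: "Methods: integrated log-Gaussian Cox models for presence-only data fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated log-Gaussian Cox models for presence-only data fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`lgcpfuse` fits species distribution models that fuse two presence-only
data streams with different observation processes:

* a **structured stream** ("nest"): locations recorded by targeted
  monitoring, treated as a direct realization of the latent point process;
* an **opportunistic stream** ("ebird"): volunteer sightings with effort
  metadata, treated as a *thinned* realization of the same process.

The latent process is an inhomogeneous space-time Poisson point process
with log-Gaussian intensity (a log-Gaussian Cox process):

$$\lambda(s, t) = \exp\!\Big(\textstyle\sum_i \beta_i X_i(s, t) + u(s, t)\Big),$$

where $X(s,t)$ are standardized ecological covariates (some static, some
annual) and $u(s,t)$ is a mean-zero Gaussian random field absorbing
unmeasured covariates and residual spatiotemporal autocorrelation. The
opportunistic stream has intensity $\lambda(s,t)\,b(s)$ with log-linear
thinning

$$\log b(s) = \delta_0 + \textstyle\sum_j \delta_j Z_j(s),$$

where $Z(s)$ holds site-accessibility covariates (road density) and
per-checklist effort marks (log distance, log duration). All fixed
effects get independent Gaussian priors with precision 0.001; the field
hyperparameters get a penalized-complexity (PC) prior.

## The latent field

$u$ is a Matérn field with smoothness $\nu = 1$, approximated by the SPDE
finite-difference discretization on a regular lattice: the precision is
$Q \propto (\kappa^2 C + G)^\top C^{-1} (\kappa^2 C + G)$ with lumped mass
$C$, the 5-point Neumann stiffness $G$, and $\kappa = \sqrt{8}/\rho$. The
*nominal range* $\rho$ is the distance at which correlation falls to
roughly 0.1 (the exact Matérn-1 value at $\rho$ is ~0.14, inside the
calibration tolerance used by the tests). Instead of an analytic variance
formula we rescale $Q$ so the **measured** marginal variance at the
central cell equals $\sigma^2$; Neumann boundaries then inflate variance
near the edge, which we accept and document — calibration checks use
interior cells only.

Years are coupled by a stationary AR1 process with coefficient $\phi$:
the space-time precision is the Kronecker product of the unit-variance
tridiagonal AR1 precision with the spatial precision, so the stationary
marginal variance is $\sigma^2$ in every year.

A triangulated mesh, the usual choice in INLA-based analyses, is replaced
here by this regular lattice: the asymptotics are the same, the
engineering is far simpler, and the test surface (correlation at the
nominal range, marginal sd, AR1 lag correlation) validates fidelity
directly. A `field_coarsen` factor lets the field live on a lattice
coarser than the data grid (bilinear projection to data locations) to
keep desk-scale runtime; `rho` must be at least twice the *coarse* cell
size to be resolvable.

## Likelihood and quadrature

Point process likelihoods are approximated by downweighted Poisson
regression (DWPR): presence points and background ("quadrature") points
each carry an areal weight $w_i$, the response is $y_i = z_i / w_i$, and
the weighted Poisson likelihood $\sum_i w_i (y_i \eta_i - e^{\eta_i})$
converges to the point process likelihood as quadrature density grows.

Two construction choices matter and are worth stating plainly:

* **Weights.** With uniform weights $|A|/n_t$ per year, presences (which
  cluster in high-intensity cells) distort the integral estimate, and at
  desk-scale quadrature sizes this measurably attenuates coefficients —
  we observed slope-type coefficients shrunk by ~2x at 20k points,
  converging only near the 200k points used in large published analyses.
  The default is therefore Berman-Turner **counting weights**: all scheme
  points in a grid cell-year share that cell's area. Per-year weights
  still sum exactly to $|A|$. Uniform weighting remains available
  (`weighting = "uniform"`).
* **Placement.** `type = "random"` scatters uniform background points
  (the classical construction); `type = "grid"` (default in the
  integrated fit) places one deterministic point per cell-year center,
  which makes the integral *exact* for intensities that are piecewise
  constant at the analysis resolution — precisely what the synthetic
  generator produces and what a 30 m covariate stack supports.

## Variable and scale selection

Each candidate covariate can be summarized at six spatial scales (the
pixel, its 8 neighbors, and radii of 90/150/300/750 m) via a moving
window (mean, or sd for slope roughness). Scale selection fits univariate
unpenalized DWPRs per scale and keeps the smallest-CV-RMSE scale (ties to
the smaller scale). The multivariable model is then selected by an
L1-penalized DWPR implemented in-house (IRLS with coordinate descent,
intercept unpenalized, 1e-8 coefficient tolerance); `glmnet` is used only
as an independent oracle in the test suite.

CV losses: per held-out row the presence score is
$\hat p_i = 1 - \exp(-\hat\lambda_i w_i)$ (the model's probability of at
least one point in the row's tile), RMSE compares $\hat p$ with the 0/1
presence indicator, and AUC ranks presences against background. The
penalty is chosen by the **one-standard-error rule** (largest penalty
within one fold-SE of the minimum RMSE): the exact CV minimizer
consistently retained several pure-noise covariates in simulation (a
well-known property of min-rule CV), while the 1-SE rule removes them
while keeping the true signal; `rule = "min"` is available.

## Inference

Fitting is MAP plus nested Laplace approximation (empirical-Bayes
flavored), not full INLA:

* **Inner loop.** Newton optimization of $(\beta, \delta, u)$ on the
  penalized joint log-posterior, with the sparse Hessian
  $A^\top W A + \mathrm{blockdiag}(\tau I, Q)$ solved by Cholesky
  factorization; step halving guards monotonicity; convergence at
  gradient norm $10^{-6}$ (relative).
* **Outer loop.** Nelder-Mead maximization of the Laplace-approximate
  marginal posterior of $(\log\rho, \log\sigma,
  \mathrm{logit}((\phi+1)/2))$ with the PC prior on $(\rho, \sigma)$ and
  three seeded restarts. Hyperparameters may instead be fixed
  (`hyper = field_params(...)`) for conditional, empirical-Bayes fits —
  the mode used by the recovery harness and the bootstrap.

Credible intervals are Gaussian-approximation quantiles (2.5/50/97.5) at
the joint mode, from the fixed-effect block of the inverse Hessian
(which marginalizes over the field). Simulation shows these intervals
are mildly anti-conservative for the roughest covariates (z-score sd
~1.5 for pixel-scale slope/NDVI at ~2,000 points), while coverage still
clears the 80% acceptance bar; users should treat borderline effects on
pixel-scale covariates with corresponding caution.

**Identifiability of effort effects.** Effort marks exist only for
observed checklists; quadrature rows carry the mark mean. With that
construction the likelihood contains almost no information about effort
coefficients — their estimates hug zero with wide intervals. We keep
them in the design deliberately: published integrated analyses report
exactly this signature (credible intervals overlapping zero for effort
terms), and the Hessian-condition diagnostic (`fixed_cov_condition`)
flags such flat directions. Spatial accessibility (road density), which
varies over the domain, is well identified, and the simulation harness
checks its sign and magnitude.

## Synthetic worlds

`make_landscape()` builds a seeded landscape with the statistical
structure the analysis assumes: smooth GMRF-derived elevation (slope by
Horn's method), seeded lakes/roads/settlements/trees with exact Euclidean
distance layers, road density in a disc (5 km in real landscapes; capped
at 15% of the domain diameter on toy domains so the layer varies), a crop
mask, and annual water/vegetation layers driven by an AR1-persistent
latent field mapped to their natural ranges.

`truth_spec()` fixes true coefficients. Signs follow the effect
directions reported for breeding shorebirds in prairie-wetland systems
(water +, water² −, vegetation +, distance to lake −, slope −, crop −,
road density + on the observation side); magnitudes are moderated to
order 0.3-1.5 on the standardized scale because field-scale magnitudes
(e.g. −9.4 for the exponential lake distance) concentrate all intensity
in a handful of cells on a 64x64 toy landscape. Intercepts are calibrated analytically so expected totals hit
the stated sample sizes (~2,000 structured and ~300 opportunistic points
over 5 years in the default world), accounting for the field's lognormal
mean factor $e^{\sigma^2/2}$. Field defaults: range 240 m (8 cells), sd
0.5, persistence 0.9 — the high-persistence regime reported for this
system. Effort marks are log-normal (log-mean log 1.2 km / log 1.0 h, log-sd
0.5), a config-exposed convenience, not a claim about real checklists.

Point placement is per-cell Poisson counts with uniform jitter — exact
for piecewise-constant intensity. Because the generated world *is*
piecewise constant, the estimator's covariate sampling should match:
`sample_method = "nearest"` evaluates designs at the containing cell and
is used throughout the synthetic harness, while `"bilinear"` (default)
suits real GPS points on coarser rasters. A green recovery test
establishes correctness of the estimator against this stated world; it
does not establish robustness to misregistration, positional error, or
non-Poisson clustering, which real data exhibit.

## Prediction, thresholding, abundance

Annual surfaces are $\hat\lambda = \exp(X\hat\beta + \hat u)\cdot$cell
area with training standardization constants replayed; the field mode is
year-specific, or averaged over fitted years (required for out-of-range
years). Suitability thresholds maximize the Symmetric Extremal Dependence
Index over midpoints of sorted unique scores (ties to the larger, more
conservative threshold; rates clamped at $10^{-6}$ so perfect
classification stays finite; the background class is the quadrature
scheme). Relative abundance is the sum of strictly suprathreshold cell
values per year. Bootstrap intervals resample presence points with
replacement within stream and year and refit only the modes with
hyperparameters held fixed — a *conditional* bootstrap chosen for
desk-scale runtime; the default 10,000 replicates is config-reducible.

## Validation

Temporal block CV uses inclusive year periods; spatial block CV tiles the
extent with square blocks dealt round-robin to folds after ordering by
presence count (equal block counts, balanced presences, seeded
tie-breaks). Block sizes can be suggested from the data as the median
effective range (3x the exponential range parameter) of Cressie-weighted
semivariogram fits to the continuous layers. Held-out metrics score
held-out presences against held-out background cell-years, always with
the averaged field (held-out structure has no year-specific field
information); fold metrics pool by held-out rows. The buffered evaluator
scores each checklist by the maximum predicted cell within its
effort-distance disc, acknowledging traveling-checklist positional
uncertainty. The stream ablation refits with and without the
opportunistic stream on identical folds.

## Numerical choices and degenerate inputs

* Grid cells are half-open; a point on a shared edge belongs to the cell
  of higher index in x and y; the grid's bottom edge is closed.
* Distance binarization maps the exact threshold to 1 (the rules are
  stated with strict inequalities; the measure-zero case must be fixed).
* Checklist filters: distance < 5 km and duration < 5 h strict, at most
  10 observers inclusive, start time in [05:00, 21:00] inclusive;
  incomplete checklists are retained (all rows are presence records).
* Standardization uses the sample (n-1) sd; zero-variance columns error
  with the offending name.
* Constant surfaces: SEDI thresholding errors (no discrimination);
  min-max normalization warns and returns zeros.
* Missing covariates drop the affected rows with a logged count.
* Rasters are exchanged as ESRI ASCII grids; GeoTIFF is unsupported in
  this build because no GDAL-backed R reader is available, and `.tif`
  paths fail with a clear message. Configs are JSON for the same reason
  (no YAML parser in the dependency set).

## Known limitations

* Laplace intervals are approximate; no MCMC check is provided.
* The lattice field inherits Neumann boundary variance inflation.
* The conditional bootstrap understates hyperparameter uncertainty.
* Effort-mark coefficients are structurally weakly identified (above).
* No reprojection or CRS handling: coordinates are planar meters.
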