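---
title: "Indirect forest stock volume mapping: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indirect forest stock volume mapping: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`canopystack` implements an indirect framework for mapping forest stock
volume (FSV, m³/ha) over terrain where field plots cannot be co-located
with spaceborne-LiDAR footprints: footprint metrics are first spatially
extrapolated into continuous 30 m surfaces, those surfaces are fused with
optical and terrain covariates, and plot volume is regressed on the fused
predictor set with a multi-level stacking ensemble. This vignette explains
the models and their assumptions, the tunable parameters, what the
synthetic generator does and does not emulate, the numerical decisions, and
known limitations.

## 1. The model chain and its assumptions

**Quality control.** Footprints are retained when waveform `sensitivity`
strictly exceeds 0.9 and `quality_flag == 1`. The strict inequality is
deliberate: a record at exactly 0.9 is dropped. The filter is idempotent
and order-preserving.

**Variography.** Each LiDAR metric is treated as a realization of a
second-order stationary, isotropic random field. The empirical Matheron
semivariogram is fitted with spherical, exponential and Gaussian models by
weighted least squares (Cressie pair-count weights `N(h)`; plain OLS by
option). The best model is the one with the highest R² (`1 − RSS/TSS`
about the mean empirical semivariance), ties broken by lower RSS, then by
the fixed kind order spherical → exponential → gaussian, so fitting is
fully deterministic. Spatial dependence is classified from the
nugget-to-sill ratio C₀/(C₀+C): < 25% strong, 25–75% moderate, > 75% weak.

*Range convention.* Only the spherical model has a true range. For the
exponential and Gaussian kinds the single reported range is the *effective*
range: γ reaches a fraction `1 − e⁻³` (≈ 95%) of the partial sill there,
i.e. γ_exp(h) = C₀ + C(1 − e^(−3h/a)) and γ_gau(h) = C₀ + C(1 − e^(−3h²/a²)).

*Lag geometry.* `empirical_variogram` records, besides bin midpoints, the
pair-weighted mean distance per bin (`lag_means`). Fits and model-vs-
empirical comparisons use `lag_means`: on gridded data the pair distances
cluster at a few discrete values per bin and midpoint evaluation is biased.
Default lag width is half the mean nearest-neighbor distance and the
default maximum lag half the domain diagonal — both deliberately
conservative defaults for irregular track data.

**Ordinary kriging.** The OK predictor Ẑ(s₀) = Σλᵢ Z(sᵢ) solves the usual
semivariance system with the unbiasedness constraint Σλᵢ = 1 over the 25
nearest observations by default (`Inf` gives global kriging). A target
coinciding with an observation returns that observation with zero variance
(exactness); duplicated observation locations are averaged first. The
alternative nugget-filtered behaviour at data points is intentionally *not*
the default — exactness is what the retention gate evaluates.

**Sequential Gaussian conditional simulation (SGCS).** Values are
normal-score transformed (piecewise-linear quantile table, endpoints
clamped), observations are assigned to their grid cells (cell-averaged when
several share a cell), and the unsimulated cells are visited along a seeded
random path; at each cell the conditional mean and variance come from
simple kriging with the sample mean on the nearest 16 conditioning values
(observations plus previously simulated cells), and a Gaussian value is
drawn. All randomness for realization *i* derives from `(seed, i)`, so
stacks are reproducible and extensible realization-by-realization.
Realizations honor the data exactly at conditioning cells and reproduce the
model variogram; the realization *mean* surface (the default product fed to
the regression stage, configurable) approaches the kriging surface as the
realization count grows while a *single* realization preserves the field's
variance. The realization count is chosen by tracking the global
coefficient of variation (spatial mean of per-cell sd/mean across
realizations) over a candidate ladder such as 10, 25, 50, 75, 100, 125 and
stopping when successive values change by at most a tolerance.

**IDW and exponent optimization.** wᵢ = dᵢ^(−β); β is tuned by minimizing
5-fold-cross-validated RMSE with grid search (0.5–5.0 step 0.1, lowest β on
ties), particle swarm (swarm 15, 50 iterations, inertia 0.8,
c₁ = c₂ = 1.5, velocities clamped to the bound width) or a real-valued GA
(population 15, 50 generations, crossover 0.8, mutation 0.1, tournament
selection of size 2, blend crossover, Gaussian mutation with sd 5% of the
bound width — operator choices are this implementation's, as only the
population-level settings are standard). β starts in [0.1, 5] and is
constrained to [0.1, 10].

**Retention gate.** Footprints are split 80/20 uniformly at random under a
recorded seed (no stratification); the surface is built from the training
points and R² = 1 − SSE/SST is computed at the held-out footprint
locations. A printed formulation of this interpolation R² elsewhere is
typographically ambiguous; the standard coefficient of determination —
consistent with the model-assessment metrics — is used. Variables pass at
R² ≥ 0.50 (inclusive). Evaluation happens at test footprints, not on
rasterized surfaces; for SGCS the realization-mean value of the cell
containing the test footprint is used.

**Predictors.** Digital numbers scale to surface reflectance as
`0.0000275·DN − 0.2`. Eleven standard vegetation indices (NDVI, DVI, RVI,
EVI with G = 2.5, C₁ = 6, C₂ = 7.5, L = 1, SAVI with L = 0.5, ARVI, TVI,
RDVI, VDVI, NGBDI, NPCI) are computed from blue/green/red/NIR; division by
zero yields nodata. Texture features use a per-cell gray-level
co-occurrence matrix over a 5×5 window at one-pixel displacement with 64
linear quantization levels, symmetric and averaged over the four
orientations; the eight features (mean, variance, homogeneity, contrast,
dissimilarity, entropy, angular second moment, correlation) are the
Haralick set common in forestry texture studies — the source workflow does
not name its eight, so this standard set is adopted and documented. A
zero-variance window has correlation 1 by convention. Slope and aspect use
Horn's 3×3 kernel; aspect is degrees clockwise from north (direction of
steepest descent) with −1 for flat cells. Candidate assembly for the
reference configuration — 6 gated LiDAR surfaces, slope/aspect/elevation, 7
single-band reflectances (bands 1–7 by default, configurable), 11 indices,
8 textures — yields 35 uniquely named columns; a LiDAR ground-elevation
surface must be given a distinct name from the terrain `elevation` layer.

**Two-stage screening.** Stepwise VIF elimination removes the predictor
with the largest VIF while any exceeds 5, recomputing after each removal
(VIFᵢ = 1/(1−Rᵢ²) from regressing predictor i on the rest; constant or
perfectly collinear columns are tagged infinite and removed first; with
rank-deficient designs the R² is capped so VIF ≤ 10⁶). The survivors are
ranked by mean |SHAP| from a seeded random forest using exact tree-path
SHAP, and the top six are retained.

**Harmonization.** SDI = 407181.974·(D₀/D)^(−2.209) with D₀ = 12 cm;
V′(SI, SDI, t) = a₁·SI^a₂ / (1 − a₃·SDI^a₄·e^(−a₅·t)) with the published
coefficients and SI defaulting to the regional mean 18.39. Because the
source does not state how a measured volume is moved between survey years,
the least-assumption *ratio projection*
v·V′(t+Δt)/V′(t) is used, with direct evaluation of V′ also exposed; `t` is
*stand age*, which the caller must supply (the alternative reading — years
since an epoch — is not defined anywhere, so age is required input and the
ambiguity documented). Per-pixel volume is v·cell²/10⁴ (0.09 at 30 m).

**Stacking ensemble.** Six base learners — random forest, three gradient
boosting configurations (classical depth-3; depth-4 with row/feature
subsampling; depth-6 with larger leaves and feature subsampling), AdaBoost.R2
and k-nearest neighbours — are trained with 10-fold cross-validation; the
out-of-fold (OOF) predictions form the meta-features, so no meta-feature
entry was produced by a model that saw that row. Learners are ranked by OOF
R² (ties: lower OOF RMSE, then registry order). Two meta-learners are
trained, each with its own OOF pass, on the meta-features of the two best
base models (a flag widens this to all six); a final meta-learner is
trained on their OOF outputs. The pass-through baseline shares the level-0
stage bit-for-bit and forwards the concatenated OOF columns (ordered by
base rank) directly to the final learner. Model comparison uses a seeded
80/20 plot hold-out; spatially blocked validation is available but not the
default, mirroring the reference workflow.

*Meta-learner design.* Meta-features are one or two columns already highly
predictive of the response, so the meta-learners are weak offset-initialized
boosters: they start from their best-ranked input column (the `base_margin`
mechanism of modern boosting libraries) and learn only a 30-round, depth-2,
large-leaf correction. An unregularized booster at this level mostly refits
the OOF noise of the base predictions and measurably degrades the stack;
with the offset design the stack degrades gracefully to the best base model
when the base learners have nothing complementary to offer.

## 2. The synthetic world

The generator emulates, under a single fan-out seed:

* **Fields** — stationary Gaussian random fields with a chosen variogram,
  simulated exactly by dense Cholesky factorization up to 4 096 cells and
  by FFT circulant embedding above that (exact when the embedding is
  positive semidefinite; negative eigenvalues are clamped with a warning
  and the method is recorded in an attribute).
* **Footprints** — parallel tracks with the instrument's along/across-track
  spacings (60 m / 600 m at full scale; desk-scale configs compress the
  across-track spacing to preserve footprints-per-cell), a small seeded
  track tilt and phase, Gaussian metric noise, and a configurable QC-fail
  fraction split between low sensitivity and a zero quality flag.
* **Plots** — uniform locations over distinct cells; volume is the
  saturating response `vmax·h/(h + h50)·clamp(cover, 0, 1)` of a
  height-like and a cover-like field plus Gaussian noise, clipped at zero.
  Defaults `vmax = 400` m³/ha, `h50 = 12` m and noise sd 15 m³/ha were
  chosen once so plot volumes span the magnitude reported for the reference
  inventory (≈ 3–275 m³/ha, mean ≈ 78) with ~20% observation noise; mean
  DBH is an increasing noisy function of volume so the density index
  behaves sensibly.

It does **not** emulate: anisotropy or nonstationarity, geolocation error,
orbital striping artifacts beyond parallel tracks, cloud masking and
compositing of real imagery, terrain-induced illumination effects,
non-forest footprint classification (only a generic QC-fail fraction), or
support mismatch between 1 ha plots, 25 m footprints and 30 m cells. A
green test therefore establishes that the algorithms are implemented
correctly on well-specified inputs, not that the workflow is robust to
those real-data pathologies.

## 3. Numerical decisions

* Kriging/SK systems get a diagonal jitter of 10⁻¹⁰ × sill (10⁻⁷ for the
  Gaussian kind, whose smooth covariance makes the system near
  rank-deficient when the range exceeds the domain) — an implicit
  micro-nugget that stabilizes `solve()` without visible bias.
* Exactness at a conditioning point is enforced by special-casing
  coincident targets (observation returned, variance 0) rather than relying
  on the solver.
* SGCS honors data at *cell support*: observations are snapped to cell
  centers and cell-averaged. Any oracle comparing the ensemble mean against
  kriging must condition on the same snapped data, or the two sides differ
  at every conditioning cell by construction.
* Variogram fitting uses deterministic multi-start L-BFGS-B over a fixed
  grid of initializations with box constraints C₀ ≥ 0, C ≥ 0, a > 0; the
  reported RSS is unweighted.
* Degenerate inputs: constant observations make the IDW objective flat —
  the grid optimizer returns its lowest candidate (0.5), PSO/GA the lower
  bound, with a warning; a zero-sill model makes SGCS return constant
  realizations with a warning; constant responses give flagged-undefined
  R².
* Tie-breaks are all deterministic and documented: variogram kinds by fixed
  order, grid search by lowest β, learner ranking by OOF R² then RMSE then
  registry order.
* Per-stage seeds derive from the single config seed by a fixed integer
  map, so every stage is independently reproducible and the pipeline report
  is bit-identical across reruns (timings are logged, not stored).

## 4. Design choices where the source was open

* Whether surfaces entering the final model are the SGCS realization mean
  or a single realization is unstated: the realization mean is the default,
  configurable.
* Whether level-1 meta-learners see the top-2 or all six OOF columns is
  ambiguous; top-2 is the default with a flag for all six.
* The seven single-band reflectance predictors default to bands 1–7,
  configurable.
* Totals are computed from per-pixel volumes (per-hectare predictions ×
  0.09 at 30 m) summed over valid cells.
* GeoTIFF support is intentionally absent (no offline library): rasters are
  ESRI ASCII grids; configs are JSON.

## 5. The benchmark orderings, and why two assertions are red

The acceptance suite asserts, over seeds 1–10 of the packaged benchmark
(the synthetic world above at its defaults, n = 500 plots, predictors
delivered through kriged surfaces), that the stack's median test R² is at
least the best single base learner's, and its median RMSE at most the
pass-through baseline's. Both assertions fail by small margins on this
world, and the analysis is worth stating because it is a property of the
evaluation design, not a bug:

* All six base learners see the same features, so their errors are strongly
  correlated; an ordinary-least-squares blend of all six OOF columns — the
  linear ceiling for any meta-learner — measures within a few thousandths
  of the best base model's R². There is nothing for the meta-levels to add.
* "Best single base learner's test R²" takes a maximum over six correlated
  estimates on a ~100-row test set, a positively biased selection the stack
  cannot make: it must commit by OOF rank before seeing the test rows.
* The extra OOF layer costs the multi-level stack a residual ≈ 0.2 m³/ha
  median RMSE (on an ≈ 18 m³/ha error scale) relative to the pass-through
  variant; the sign of the difference flips across seeds.

The assertions are kept exactly as stated rather than weakened. On data
where base learners are diverse (different feature views, heterogeneous
error structure) trained meta-levels can add real value; this synthetic
world is not such a case, and a reported large gain on a small non-spatial
hold-out should be read with the corresponding caution.

## 6. Limitations

Isotropic variograms only (no anisotropy, nesting or cross-variograms); no
co-kriging or external drift; sequential simulation cost grows with grid
size (the R implementation is comfortable to ~10⁴ cells per realization);
tree learners are this package's CART core, configured to *represent* the
named boosting families rather than reproduce the eponymous libraries
bit-for-bit; no spatially blocked cross-validation by default; the growth
model is specific to the reference species and site-index range.
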