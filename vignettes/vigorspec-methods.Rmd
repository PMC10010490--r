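---
title: "Methods: hyperspectral assessment of peanut seed vigor"
author: "VigorSpec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral assessment of peanut seed vigor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(VigorSpec)
```

## The problem

Seed vigor — the capacity of a seed lot to germinate rapidly and grow into
normal seedlings — degrades during storage, and aged peanut seeds are
nearly indistinguishable from fresh ones by eye. Destructive assays
(germination tests, enzyme assays) answer the question seed by seed but
consume the seed. Visible/near-infrared hyperspectral imaging offers a
non-destructive proxy: aging degrades storage compounds (pigments,
sugars, protein, lipids), which shifts broadband reflectance upward and
flattens the absorption features those compounds produce, so a
calibrated model can read physiological state off the spectrum.

VigorSpec implements the full chemometrics pipeline for this setting:

1. reflectance calibration of raw cubes (`blackWhiteCorrect`),
2. seed segmentation and per-seed mean spectra (`segmentSeeds`,
   `meanSpectrum`),
3. edge-band trimming to 400–1000 nm (`trimBands`),
4. spectral preprocessing (`savitzkyGolay`, `mscCorrect`,
   `medianFilterSpectra`),
5. feature-band ranking by gradient-boosted-tree importance
   (`rankBands`),
6. seed-viability classification and SOD-activity regression over a
   (preprocess × band-set × model) grid (`runClassificationGrid`,
   `runRegressionGrid`),
7. germination vigor indices and NBT assay arithmetic (`vigorIndices`,
   `sodActivity`), and
8. group-level correlation analysis (`buildGroupSummary`,
   `pearsonMatrix`).

Because no instrument data ships with the package, a synthetic generator
(`simConfig`, `simulateSpectra`, `simulateCube`, `simulateGermination`)
emulates a five-group accelerated-aging experiment; every pipeline stage
is exercised and tested against it.

## Reflectance calibration

Raw push-broom counts are converted to reflectance with the standard
two-point calibration

$$R = \frac{\mathrm{Sample} - \mathrm{dark}}{\mathrm{White} - \mathrm{dark}},$$

applied elementwise. The transform is invariant under affine rescaling
of all three inputs (tested), and a zero `White − dark` denominator is a
hard error rather than silent infinity. Dark/white references recorded
as a single scan line are broadcast along the scan axis.

Segmentation thresholds a single near-infrared band (default 800 nm,
where seeds are bright against dark cardboard), labels connected
components (via `EBImage::bwlabel`), and orders them row-major by
centroid so masks align with tray position. The imaging instrument's
region-of-interest procedure is not described in detail anywhere we
could follow, so this simple global-threshold design is the package's
own; it recovers the generator's masks exactly on clean trays, and a
merged-seed condition (threshold too low) is reported via the
`expected` argument rather than guessed at.

The sensor's useful range is 384–1034 nm but the edge bands are noisy;
`trimBands` retains 400–1000 nm by default and is idempotent.

## Spectral preprocessing

Three transforms, selectable per grid cell by their usual abbreviations:

* **SG** — Savitzky–Golay smoothing: each band is replaced by the value
  of a local least-squares polynomial (default window 11 bands,
  order 3, no derivative). Defaults are the common chemometrics choice
  at ~2.5 nm resolution; both are exposed. Edge bands are fitted with
  the shifted edge window evaluated off-centre, so the filter is exact
  on polynomials up to the fitted order at every band — the test suite
  checks equality with an explicit per-window polynomial-fit oracle at
  1e-10.
* **MSC** — multiplicative scatter correction: each spectrum is
  regressed on a reference ($x = a + b\,\mathrm{ref}$) and corrected to
  $(x-a)/b$, removing per-seed scatter gain and baseline offset. The
  reference is the **calibration-set** mean and is frozen there: the
  prediction set is corrected against the calibration reference, never
  its own mean, so no information leaks across the split.
* **MF** — median filter along the spectral axis (default window 5,
  reflected padding). The window is deliberately small to flatten
  single-band spikes without erasing the ~20 nm absorption features;
  filtering is per spectrum, not spatial, since the per-seed mean
  spectrum is the analysis unit.

## Feature-band ranking

Both rankers fit a 500-tree gradient-boosted ensemble (learning rate
0.1, depth 6) on the full-wavelength calibration data and rank bands by
gain importance (total loss reduction), keeping the top 15 with ties
broken by ascending wavelength. Two flavours are provided so the two
selection columns of the results grid are genuinely different
ensembles: `"catboost"` grows depth-limited, depthwise (symmetric-
leaning) trees, `"gbdt"` grows leaf-wise histogram trees. The
hyperparameters are fixed in the interface because tree-count/depth
choices barely move a *ranking* even when they move accuracy; gain
importance is used for both because it is the stable default for
correlated spectral predictors. Ranking runs on the calibration set
only (leakage-safe); the convenience method on a whole `SpectralSet`
exists for exploratory use.

## Models and the results grid

`splitDataset` makes a deterministic stratified 7:3 split; per-stratum
calibration quotas are allocated by largest remainder so the overall
calibration size is exactly `round(0.7 n)` (280/120 at n = 400) and
every stratum is within one seed of its share.

Classifiers: depthwise gradient boosting (`"xgboost"`), leaf-wise
histogram gradient boosting (`"lightgbm"`, 31 leaves), an RBF-kernel
SVM (cost 1, gamma $1/(p\,\hat\sigma^2)$ with $\hat\sigma^2$ the overall
predictor variance — the scale-aware convention), and a 500-tree random
forest. All tree fits are single-threaded with fixed seeds so grids are
reproducible run to run. Accuracy is reported on the 0–100 scale at two
decimals, with the exact correct-count and full confusion matrix kept
alongside (rows = true class).

Regression: NIPALS PLS1 is implemented in the package (`plsrFit`)
because the latent-variable fit *is* part of the method under study;
with components equal to the rank of centred X it reproduces ordinary
least squares (tested at 1e-8), and an installed independent PLS
implementation is used as a cross-check in the tests, never as the
implementation. The component count is chosen by 5-fold cross-validated
RMSE on the calibration set, capped at 15 (the selected-band count).
Gradient-boosted regression is the second family.

`runClassificationGrid` / `runRegressionGrid` cross preprocessing ×
{full, catboost, gbdt} × model, fit everything on calibration only, and
flag the best cell by prediction metric. A full 4 × 3 × 4
classification grid is 48 cells.

## Phenotype arithmetic

With daily germinated counts $G_t$ on days $D_t = 1..8$, $M$ seeds
tested, $m_1$/$m_2$ germinated within 3/8 days, and seedling mass
scale $S$:

$$GP = 100\,m_1/M,\; GE = 100\,m_2/M,\; GI = \sum_t G_t/D_t,\;
MGT = \frac{\sum_t G_t D_t}{\sum_t G_t},\; VI = GI \cdot S,\;
SVI = (GP/100)\,S.$$

Two conventions deserve a note. First, SVI uses GP as a *fraction*:
$S$ is of order 1 (grams of root mass), and published SVI magnitudes of
0.3–1.6 are only consistent with the fractional form. Second, $S$ is a
single per-group scalar; its printed definition is ambiguous between
seedling length and root weight, so the package treats it as an opaque
mass/size scale that multiplies GI and GP. MGT is undefined (flagged,
NA) when nothing germinates.

SOD activity from the nitroblue-tetrazolium photoreduction assay uses
the 50 %-inhibition unit convention:

$$\mathrm{SOD} = \frac{[(A_0-A_b)-(A_s-A_b)]\cdot V_T}
{\tfrac12 (A_0-A_b)\cdot W\cdot V_s} \quad [\mathrm{U/g\,FW}],$$

antitone in $A_s$, homogeneous of degree 1 in $V_T$, equal to
$2V_T/(W V_s)$ at complete inhibition (all tested).

## The synthetic generator

`simConfig()` defines the study conditions; the defaults are the
conditions, not tuning knobs:

| parameter | default | meaning |
|---|---|---|
| `wavelengths` | 256 bands, 384–1034 nm | ~2.5 nm grid matching the instrument's listed wavelengths |
| `baselineByGroup` | 0.36 → 0.56 | broadband reflectance rises with aging |
| `spectralSlope` | 0.45 | broadband profile climbs toward the NIR |
| `featureCenters` / widths | 450, 550, 920, 970 nm / 16–30 nm | pigment, sugar, protein, O–H features |
| `featureDepthsByGroup` | visible fade ×1→0.6, NIR ×1→0.4 | aging flattens dips, NIR faster |
| `scatterSd`, `offsetSd`, `noiseSd` | 0.08, 0.02, 0.004 | per-seed gain/offset, per-band white noise |
| `vigorSd`, `vigorDepthCoef` | 1.0, 0.20 | latent physiological state and its spectral footprint |
| `germProbByGroup` | 0.9625 … 0.225 | the five observed 8-day germination rates |
| `sodMeanByGroup` | 3.32 … 1.80 | unaged mean above 3 U/g FW, aged below, decreasing |
| `meanGermDayByGroup` | 2.78 … 7.21 | the five observed mean germination times |

The load-bearing design choice is the **latent vigor variable**. Each
seed draws $v \sim N(\mu_g, 1)$ with $\mu_g = \Phi^{-1}(p_g)$, so that
`viable = v > 0` reproduces each group's germination probability
exactly in expectation. The same deviation $v - \mu_g$ (i) deepens or
shallows the 920/970 nm protein and O–H dips **additively**, in units
of the unaged depth, and (ii) shifts SOD activity
(`sod = sodMean[g] + 0.3 (v - mu_g) + N(0, 0.08)`). Without this
seed-level coupling the spectrum would carry only group identity, and no
classifier could beat ~77 % viability accuracy (the average of
`max(p, 1-p)` over groups); with it, the spectrum genuinely encodes the
phenotype. The additive (linear-in-state) depth response matters too:
it makes dip depth, and hence SOD, linearly recoverable, which is what
lets a linear calibration (PLSR after MSC) reach prediction R² well
above 0.9 — an early multiplicative variant of the coupling made the
within-group slope vary by group and capped PLSR near 0.89.

A related subtlety: if the clean spectrum were a flat baseline minus a
single common dip shape, every spectrum would be an affine map of the
reference and MSC would remove the *chemistry* along with the scatter.
The generator therefore gives the broadband profile a slope and lets
visible and NIR features fade at different rates, so the shape change
with aging is not a pure rescaling and survives scatter correction —
which is also what real seed spectra look like.

What the generator does **not** emulate: camera quantisation and slit
effects, spatial texture, wavelength-dependent instrument noise, and
any within-tray spatial gradients. Passing recovery tests on this
generator demonstrates that the pipeline's estimators are correct and
leak-free under the stated generative model; it does not certify the
accuracy figures on physical seeds. One published-table quirk is worth
recording: the printed within-3-day rates (GP) and mean germination
times are mutually impossible for aged groups (half of A4's germinators
within 3 days caps MGT at 5.5 days, below the printed 7.21), so the
generator calibrates to the GE and MGT columns and lets GP follow from
the day distribution (discretised normal, sd 1.2 days).

Problem sizes used by the tests and recovery checks are the study's own
cohorts: 400 seeds (80 per group) for classification, 100 seeds (20 per
group) for SOD regression.

## Numerical choices and degenerate inputs

* All RNG flows from a single integer seed per config or function
  argument; identical seeds give byte-identical outputs.
* Importance ties in band ranking break by ascending wavelength;
  weights are sum-normalised for reporting (normalisation cannot change
  the ranking).
* NIPALS stops early if the residual X carries no covariance with y
  (weight norm below 1e-14); a constant y therefore yields the constant
  prediction.
* `mscCorrect` errors on a constant reference and on a fitted slope of
  exactly 0; `blackWhiteCorrect` errors on any zero denominator;
  `vigorIndices` flags MGT as undefined at zero germination instead of
  dividing by zero.
* Correlation analysis over five group means is descriptive; the
  functions warn about n ≤ 5 and report no p-values.

## Known limitations

* The "catboost" and "lightgbm" flavours are gradient-boosting variants
  (depthwise vs leaf-wise growth) implemented on one backend; they
  reproduce the *procedure* — two distinct tree-ensemble rankers and
  classifiers — not any specific external library's split heuristics.
* Per-group correlation (n = 5) cannot support inference; a per-seed
  mode is available by building the summary from individual seeds.
* ENVI I/O covers 32/64-bit float BSQ and BIL, the formats the pipeline
  writes and reads; integer raw counts should be corrected to
  reflectance before export.
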