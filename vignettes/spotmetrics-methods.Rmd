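---
title: "Methods: quantifying coat spot patterns, their inheritance, and their fitness consequences"
author: "spotmetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying coat spot patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotmetrics)
```

This vignette is the package's own account of its methods: the models and
procedures, their assumptions, the tunable parameters and why their
defaults are what they are, the numerical conventions, and the design
choices that were genuinely open. The pipeline has five stages — spot
extraction, trait measurement, similarity statistics, phenotype
clustering, and survival modelling — plus a synthetic-data module that
emulates every input with known ground truth.

## The measurement problem and giraffe units

Coat photographs differ in resolution, camera distance, and animal size,
so raw pixel measurements are not comparable between animals or between
photographs of the same animal. All measurements are therefore made inside
a manually defined *analysis rectangle* on the flank and expressed in
giraffe units (GU), with 1 GU equal to the rectangle height in pixels
(`analysis_rect()`). A spot of area 0.04 GU² is the same biological size
whether the photograph is 2 or 20 megapixels. The scale-invariance is
approximate, not exact — discretisation effects shrink as resolution grows
— and is tested: re-rendering the same scene at 1x and 2x resolution
changes the retained spot count not at all and trait means by under 3%.

Rectangle coordinates are 0-based and half-open with y increasing
downward; conversion to R's 1-based matrix indexing happens once, in the
I/O layer.

## Extraction chain

`extract_spots()` runs: Rec. 601 luminance greyscale (`round(0.299R +
0.587G + 0.114B)`); a linear contrast stretch mapping the tail quantiles
to 0 and 255 (`enhance_contrast()`, default `saturated_fraction = 0.007`,
i.e. 0.35% of pixels saturated per tail — the default behaviour of the
image-analysis tools practitioners use for this task; the exact value is
configuration, not inference); the isodata (iterated intermeans) automatic
threshold, whose fixed point `t = round((mean(levels <= t) + mean(levels >
t))/2)` is verified in tests against a brute-force scan of all 255
candidate thresholds; binarisation with the *darker* phase as foreground,
because spots are darker than the coat ground; 8-connected component
labelling (two blobs touching only diagonally are one particle, the usual
particle-analysis semantics); and two filters — any component owning a
pixel on the rectangle border is removed (incomplete spots would bias
shape statistics), and any component below `min_area_gu2 = 1e-5` GU² is
removed as a speckle. Filtering is idempotent and fully logged.

Labelling is implemented on the pixel adjacency graph (igraph connected
components) for speed, and is tested for exact equality against a naive
flood-fill oracle on hundreds of random masks.

## Shape descriptors and their conventions

Per spot, `measure_spots()` reports area, perimeter, fitted-ellipse major
and minor axes and angle, circularity, maximum caliper (Feret diameter)
and Feret angle, aspect ratio, roundness and solidity. The conventions
matter, because circularity and solidity inherit them:

* **Perimeter** is the Moore-neighbour boundary chain length; straight
  steps count 1 px and diagonal steps `sqrt(2)` px; an isolated pixel
  counts 4 px. This estimator is exact for axis-aligned rectangles (a
  10x10 px square gives exactly 36 px) but overestimates smooth contours
  by up to ~5%, which bounds the circularity of a large digitised circle
  near 0.9. Because downstream shape statistics may prefer an unbiased
  estimator, `trace_perimeter(method = "smoothed")` applies the
  Vossepoel–Smeulders corner-count correction (`0.980 n_straight +
  1.406 n_diagonal − 0.091 n_corner`), accurate to well under 1% on smooth
  contours; the chain estimator remains the default and the choice is
  exposed in `measure_spots(perimeter_method=)`.
* **Ellipse fit** uses second central moments of the pixel centers with
  the 1/12 per-pixel variance term (so single-pixel and collinear
  components stay non-degenerate), then rescales the axes so the ellipse
  area `pi*major*minor/4` equals the pixel area. A deliberate consequence:
  `roundness = 4A/(pi*major^2)` equals `1/aspect_ratio` *exactly*, which
  the suite asserts at 1e-9. The printed roundness formula in the
  field's tool documentation is dimensionally garbled; the standard form
  above matches its stated gloss ("the inverse of aspect ratio").
* **Angles** (ellipse and Feret) are degrees in [0, 180), measured
  counterclockwise from the image x-axis after flipping y to the
  mathematical orientation.
* **Feret diameter** is the maximum pairwise distance over pixel
  *centers*, computed on the convex hull and verified exactly against a
  brute-force pairwise oracle. Centers (not pixel corners) are used
  because the caliper of two pixels at offsets (3, 4) should be the
  3-4-5 hypotenuse, 5 px; a corner-point set would give sqrt(41).
* **Solidity** divides pixel area by the area of the convex hull over
  pixel *corners*, so thin components have positive hull area; a plus
  sign of five unit squares scores exactly 5/7.
* **Circularity and roundness are capped at 1**: coarse rasters can
  overshoot the analytic bound.
* **Mode shade** is the most frequent packed 24-bit value `65536r + 256g
  + b` over the whole colour rectangle (not spot pixels only), ties
  broken toward the smaller packed value. It is a crude colour summary
  and is excluded from the multivariate analyses below.

`aggregate_profile()` takes arithmetic means over retained spots —
including the angular traits, which follows the source tooling's
convention rather than circular statistics; with spot orientations spread
over [0, 180) the mean angle is a weak trait, and its repeatability should
be interpreted accordingly.

## Repeatability

`repeatability()` estimates the intraclass correlation from a one-way
ANOVA: `R = (MS_A − MS_W) / (MS_A + (k0 − 1) MS_W)`, with `k0` the
unbalanced-design group-size coefficient; negative point estimates are
truncated to 0, the p-value is the ANOVA F test, and the SE is a seeded
parametric bootstrap (default 1000 replicates) under the fitted variance
components. This is the same estimand as the mixed-model estimators used
for such data in Gaussian one-way designs, but fully specified and
dependency-free. R is invariant to affine transforms of the trait (tested
at 1e-9).

## Mother–offspring similarity and heritability

`po_regression()` regresses the calf value on the mother value by OLS,
unstandardised. Under single-parent–offspring regression the expected
slope is half the additive-genetic fraction, so `h2 = 2*slope` and
`SE(h2) = 2*SE` — an exact bookkeeping identity, asserted as such. The
method cannot separate additive genetics from maternal or shared
environmental effects; it is the appropriate estimator when only
mother–offspring dyads are known. With eleven single-trait tests the
Bonferroni-adjusted level is `bonferroni_alpha(0.05, 11)` = 0.05/11,
reported rounded to 0.0045. Diagnostics (`regression_diagnostics()`) are a
Shapiro–Wilk test of residual normality and the non-constant-variance
score test (squared standardised residuals regressed on fitted values,
chi-square with 1 df), hand-implemented in a few lines and cross-checked
against the car package's implementation in the suite; both are verified
to produce uniform p-values under the null and to detect variance growing
with the mean.

## Phenotype clustering

The ten measured traits (colour excluded) are z-scored (`standardize_traits()`,
n−1 denominator) and summarised by PCA (`trait_pca()`), implemented as an
eigendecomposition of the correlation matrix; loading vectors are
sign-flipped so each dimension's largest-magnitude loading is positive
(signs are otherwise arbitrary), and `contribution = 100 * loading^2`.
Scores reproduce the standardised data exactly at full rank, and the
eigenvalues agree with `prcomp(scale = TRUE)` at 1e-8.

K-means phenotype groups (`kmeans_fit()`) take the best of `n_restarts =
50` seeded Lloyd runs by total within-cluster SS, retrying on empty
clusters; on toy sets the solution equals the brute-force best assignment.
The number of groups is chosen by the gap statistic (`gap_statistic()`):
`B` reference sets drawn uniformly over each feature's observed range
(the simplest published reference, deterministic given the seed),
`gap_k = mean_b log W*_kb − log W_k`, `s_k = sd_b(log W*) sqrt(1 + 1/B)`,
and the chosen k is the smallest with `gap_k >= gap_{k+1} − s_{k+1}`. The
full curve is always returned because real data can be ambiguous between
several k; the pipeline configuration can force a k (e.g. 3 or 4) for the
survival analysis, and `lump_groups()` merges overlapping groups with
centers recomputed as merged means (within-SS can only grow under
coarsening, which is asserted).

## Robust-design survival

`fit_rd()` fits the robust-design capture–mark–recapture model by maximum
likelihood. The hidden state of each animal at each primary occasion is
one of {alive inside, alive outside, dead}; between occasions the animal
survives with seasonal apparent survival S (logit-linear in age A =
seasons since first capture, plus optional group factors and windowed
trait covariates), and conditional on survival moves inside/outside with
the temporary-emigration probabilities gamma'' (inside to outside) and
gamma' (outside stays outside). Within a primary occasion, inside animals
are detected at each secondary event with p (before their first capture of
that occasion) or c (after); outside and dead animals are never detected.
The likelihood conditions on the first capture (all simulated and
parsed individuals enter as neonates, age 0) and is computed by a
vectorised forward pass. Two exact oracles pin it down: on a small
schedule the probabilities of all post-release histories sum to 1 at
1e-10, and with one secondary event and no emigration it reduces to the
closed-form Cormack–Jolly–Seber likelihood at 1e-8.

Numerical choices: logit link throughout; BFGS from a zero-initialised
coefficient vector plus 5 seeded jittered restarts (relative tolerance
1e-9, 500 iterations); SEs from the inverse Hessian at the optimum; AICc
with effective sample size equal to the number of individual histories
(configurable to events — the orderings at these scales are insensitive to
the choice); AICc ties broken by smaller K in `model_table()`. Covariates
are z-scored before fitting (configurable) for optimiser conditioning;
quadratic covariate models include the linear term (standard polynomial
nesting), and the covariate enters only for intervals whose starting age
falls in the chosen window ("first_season" = age 0, "first_year" = ages
0–2, "first_3yr" = ages 0–8). An optional overdispersion factor
`c_hat > 1` converts AICc to QAICc and inflates variances; it is off by
default.

One genuinely open design point deserves note. With both emigration
parameters free (Markovian emigration) and constant detection, the model
has a weak-identifiability ridge: the MLE can drift to S near 1 with
gamma' near 1, re-explaining mortality as permanent absence, with a
likelihood at least as good. This is a property of the model, not of the
implementation (the normalisation and CJS oracles are exact). The package
therefore exposes the standard constraint `share_gamma = TRUE`
(gamma' = gamma'', random emigration), under which survival, emigration
and detection separate cleanly — simulation recovery tests show
first-season S recovered within 0.03 at roughly 2,000 histories — and the
unconstrained parameterisation remains available for model sets that need
it. Inference utilities follow the standard multimodel toolkit: Akaike
weights `exp(−Δ/2)` normalised, model-averaged real-scale estimates with
Burnham–Anderson unconditional variances, likelihood-ratio tests for
nested pairs (nesting is checked by term containment per parameter
block), and per-covariate significance read from whether the 95% beta CI
excludes zero.

## The synthetic-data module

`gen_coat_image()` renders dark elliptical blobs on a lighter ground.
Geometry is sampled in GU space (so a seed fixes the scene at any
resolution): lognormal equivalent radii (default mean 0.07 GU, CV 0.25),
fixed aspect ratio (default 1.7, the scale of real spot elongation),
uniform orientation, and boundary roughness implemented as radial
perturbation of the boundary polygon by smoothed random harmonics with
amplitude `roughness x minor semi-axis` — chosen because it directly
modulates solidity and circularity the way tortuous, incised spot edges
do. Ground truth per spot is the closed-form ellipse area and numerically
integrated perimeter (or polygon area and length when roughened, on a
720-gon whose discretisation error is far below the tolerances tested).
Illumination gradient and Gaussian pixel noise stress the contrast
stretch and threshold. Overlapping blobs merge into one raster component
(raster semantics); the truth table flags merged and edge-touching spots
so recovery tests exclude them, and `edge_margin_gu` can keep centers
interior. The default spot count (15) and radius give ~20% dark cover —
sparser than a real giraffe coat, a deliberate simplification because the
generator places spots independently (no spatial inhibition), and denser
packing would merge most components. What passing tests show is therefore
that the *measurement chain* is faithful on blob imagery with known
geometry; they do not certify performance on photographs with perspective
distortion, occlusion, dappled lighting or fur texture, none of which the
generator emulates.

`gen_po_pairs()` draws mothers from the stated normal and calves with the
stated regression slope and matched marginal variance. `gen_repeat_measurements()`
splits total variance into individual and residual components at the
stated repeatability. `gen_clustered_traits()` builds spherical unit-SD
clusters whose centers sit a stated number of SDs apart.
`gen_encounter_histories()` simulates the full state process under a
survey schedule (the default study design: 13 primary occasions of two
events, 26 survey events, 20 neonates entering per occasion for ~250
retained histories), retaining only individuals first detected during
their birth occasion — matching a study design in which all marked calves
are first photographed as neonates.

## Pipeline and reproducibility

`run_traits()` and `run_full()` execute the stages from one configuration
(YAML or list; `pipeline_config()` documents the defaults) into an output
directory. Every CSV carries the seed and a configuration hash in header
comments; a manifest of MD5 hashes is written at the end, and rerunning
the same configuration reproduces every output byte-for-byte (tested).
Stage seeds are derived from the single global seed by a stable hash, so
stages are reproducible independently. Encounter histories are exchanged
in a MARK-style `.inp` dialect (history string, frequency, numeric
covariate columns, `/* */` comments) with exact write/read round-tripping.

Default problem sizes in the shipped tests are desk scale, chosen to
exercise each property at the smallest size where it is expected to hold:
2,000+ histories for survival recovery, 3–10 seeds per detection or
selection property, 31 pairs for study-scale heritability behaviour, and
rectangles of 200–600 px height for imaging. The acceptance script's
quantities (the heritability conversions and analytic circularity) are
deterministic closed forms and independent of scale.

## Known limitations

* The mean of angular traits is arithmetic, not circular (see above).
* The chain-code perimeter is biased upward on smooth boundaries; use the
  smoothed estimator when absolute circularity levels matter.
* JPEG photographs must be converted to PNG or TIFF first; no reader for
  JPEG is bundled.
* PO regression cannot separate genetic, maternal and shared-environment
  similarity; the heritability it reports is an upper-bound-style
  estimate of the additive fraction.
* Apparent survival absorbs permanent emigration; the model cannot
  distinguish the two, and the unconstrained Markovian-emigration
  parameterisation can be weakly identified (see `share_gamma`).
* Goodness-of-fit testing of encounter histories (contingency-table
  tests, overdispersion estimation) is out of scope; `c_hat` accepts an
  externally estimated value.
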