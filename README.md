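# spotmetrics

Objective quantification of complex mammal coat spot patterns from
photographs, and downstream evolutionary analysis: trait measurement,
measurement repeatability, mother–offspring heritability, phenotype
clustering, and juvenile-survival modelling by capture–mark–recapture.

The package was built around the biology of Masai giraffes, whose torso
spots vary from nearly round with smooth edges to strongly elliptical with
incised, lobate boundaries. Those patterns are individually unique and
stable through life, which makes them usable both as biometric markers and
as heritable quantitative traits whose fitness consequences (neonate
camouflage against visually hunting predators) can be measured in the wild.
Everything is driven by synthetic data with known ground truth, so the full
pipeline runs and is tested without any field data; real photographs plug
into the same functions.

## What it computes

**Trait measurement.** A photograph is cropped to a manually defined
*analysis rectangle* on the flank; all lengths are expressed in giraffe
units (GU), where 1 GU = the rectangle height in pixels, making
measurements approximately invariant to image resolution and animal size.
The extraction chain is: 8-bit greyscale (Rec. 601 weights), linear
contrast stretch, automatic isodata (iterated intermeans) threshold,
binarisation with spots as the dark phase, 8-connected particle labelling,
then removal of edge-cut spots and of speckles with area < 1e-5 GU².
Eleven per-animal traits are computed (10 measurements plus colour): number
of spots and the means of spot area, perimeter, fitted-ellipse angle,
circularity `4πA/P²` (1 for a perfect circle), maximum caliper (Feret
diameter), Feret angle, aspect ratio, roundness `4A/(πM²)` (the inverse of
aspect ratio), solidity `A / convex hull area` (tortuousness), and the mode
shade `65536·r + 256·g + b` of the colour rectangle.

**Similarity statistics.** Measurement repeatability R is the one-way ANOVA
intraclass correlation with a parametric-bootstrap SE. Heritability uses
single-parent (mother–offspring) regression: `h² = 2·b` where `b` is the
OLS slope of calf on mother, with Bonferroni control (α/m; 0.05/11 =
0.0045 for the eleven traits) and residual diagnostics (Shapiro–Wilk,
non-constant-variance score test).

**Phenotypes.** PCA of the ten z-scored measured traits (correlation
matrix), k-means coat-pattern phenotype groups, gap-statistic selection of
the number of groups (uniform reference, one-SE rule, full curve returned),
and lumping of overlapping groups.

**Survival.** Pollock robust-design capture–mark–recapture: two closed
secondary events inside each 4-month primary occasion. The full model is
`{S(A), γ′(A), γ″(A), c(t), p(t)}` on the logit scale: apparent survival S
with a linear age trend A, Markovian temporary emigration γ′/γ″ (optionally
constrained equal), time-dependent first capture p and recapture c. The
likelihood conditions on first capture and marginalises the hidden states
{alive inside, alive outside, dead}. Phenotype groups enter S as factors
(additive or interacting with age), spot traits as linear or quadratic
covariates restricted to an age window (first season, first year, first
three years). Models are ranked by AICc, compared by Akaike weights and
likelihood-ratio tests, and estimates are model-averaged with unconditional
variances.

## Worked example

```r
library(spotmetrics)

## 1. render a synthetic coat and measure its spot traits
params  <- coat_scene_params(n_spots = 15, mean_radius_gu = 0.07, seed = 7,
                             noise_sd = 5, edge_margin_gu = 0.1)
scene   <- gen_coat_image(params)
ex      <- extract_spots(scene$image, scene$rect)
profile <- aggregate_profile(measure_spots(ex$spot_map), ex$color_rect)
round(as.data.frame(profile)[1:10], 3)
#>   number  area perimeter  angle circularity max_caliper feret_angle
#> 1      8 0.035     0.709 64.684        0.75       0.246       57.31
#>   aspect_ratio roundness solidity
#> 1        1.648     0.621    0.918
```

Eight spots survived the edge and speckle filters; mean spot area is
0.035 GU², mean circularity 0.75 (fairly round), mean solidity 0.92
(smooth edges — the scene's boundary roughness is mild).

```r
## 2. mother-offspring heritability of a trait
pairs <- gen_po_pairs(n_pairs = 31, po_slope = 0.52, seed = 7)
po_regression(pairs, trait = "circularity")
#> Parent-offspring regression [circularity] (n = 31 pairs)
#>   slope = 0.5252 (SE 0.1076), F(1,29) = 23.827, p = 3.528e-05
#>   heritability h2 = 2 x slope = 1.0504 (SE 0.2152)
```

The generator was told the true mother–calf slope (0.52); at the study's
sample size of 31 pairs the fitted slope is 0.525, and the implied
heritability is twice that. The p-value sits well below the
Bonferroni-adjusted level `bonferroni_alpha(0.05, 11)` = 0.0045.

```r
## 3. robust-design survival from simulated encounter histories
eh  <- gen_encounter_histories(cmr_sim_design(seed = 3))   # 13 x 2 = 26 events
fit <- fit_rd(eh, S = ~ A, share_gamma = TRUE, n_restarts = 1)
rd_real(fit, "S", data.frame(A = 0:2))
#>   estimate    se   lcl   ucl
#> 1    0.862 0.019 0.820 0.895
#> 2    0.861 0.016 0.828 0.889
#> 3    0.861 0.014 0.832 0.885
```

Estimated seasonal apparent survival for ages 0–2 seasons is ~0.86, which
matches the simulated truth (logit⁻¹(1.735) = 0.85 at age 0). `model_table()`,
`akaike_weights()`, `model_average()` and `covariate_effect_models()` carry
the analysis through model selection and trait-effect estimation, and
`run_full()` executes the entire pipeline from a single seeded
configuration with a hashed output manifest.

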