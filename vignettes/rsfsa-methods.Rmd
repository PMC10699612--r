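---
title: "Random-subset feature selection for presence-background habitat models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-subset feature selection for presence-background habitat models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(rsfsa)
```

## The problem

Species distribution models for urban-adapted birds such as the Red-crowned
Parrot face two coupled difficulties. First, coarse categorical land-cover
maps miss the fine-grained vegetation structure (scattered urban
greenspaces, palm clusters, heterogeneous canopy) that actually drives
where the birds live, so the useful predictors have to be *derived* from
high-resolution multiband imagery — and there are hundreds of plausible
derivations. Second, once hundreds of candidate predictors exist, choosing
a defensible handful for a presence-background model is itself a modelling
problem: stepwise or single-ranking selection ignores synergies between
variables and invites overfitting.

This package implements a complete treatment of both halves:

1. a **feature factory** that turns two dates of red/green/blue/NIR imagery
   plus elevation into seven families of 9.5 m raster predictors
   (raw spectral indices, multitemporal differences, preferred-range
   percent cover, grey-level co-occurrence textures, and their
   compositions), and
2. **RSFSA-CV**, a three-stage cross-validated random-subset
   feature-selection algorithm that screens thousands of decorrelated
   subsets of those predictors with a MaxEnt-style model, ranks variables
   by a weighted combination of permutation importance and frequency, and
   assembles a max-TSS-calibrated binary consensus ensemble (core and
   semi-core habitat maps).

Because occurrence data of this kind are typically withheld from public
release, the package ships a seeded synthetic-scene generator whose
planted "truth" makes the entire pipeline testable end to end.

## The presence-background model

The occurrence density over the landscape is modelled as a Gibbs
distribution over a basis expansion $f(x)$ of the predictors,

$$p_\beta(x) \;=\; \frac{e^{\beta^\top f(x)}}{\sum_{z \in B} e^{\beta^\top f(z)}},$$

normalized over the background sample $B$ — the classical maximum-entropy
(MaxEnt) formulation. Fitting maximizes the l1-penalized presence
log-likelihood; we solve it through the standard equivalence with a
weighted logistic regression (presence weight 1, background weight 100)
using coordinate descent (`glmnet`). The basis contains linear and
quadratic terms plus forward/reverse hinge terms at background quantile
knots, echoing MaxEnt's default feature classes; `model_spec()` exposes
the classes, knot count and penalty.

Predictions come in three scales: `link` (the linear predictor), `raw`
(the background-normalized density, which sums to 1 over the training
background — an invariant the tests assert), and `cloglog`,

$$\mathrm{cloglog}(x) = 1 - \exp\!\big(-e^{H}\,\mathrm{raw}(x)\big),$$

where $H$ is the entropy of the fitted background distribution — the
entropy-calibrated transform modern MaxEnt uses for a
probability-of-presence-like score in $(0,1)$.

Evaluation statistics are implemented in-package and checked against
brute-force oracles: Mann–Whitney rank AUC with half-weight ties
(`rank_auc()`), the maximum true skill statistic with its calibrating
threshold (`max_tss()`, scanning midpoints of adjacent unique scores and
returning the lowest maximizer), the background-normalized
sample-size-corrected AIC (`aicc_bg()`, with $k$ = nonzero coefficients
after shrinkage and $n$ = presence count), and permutation importance
(mean drop in background AUC when one variable is shuffled, normalized to
sum to 100 across the model's variables).

Two AUC variants recur throughout: **AUC_psa** uses pseudoabsence points
as the absence class; **AUC_bgp** uses background *plus presence* points
as absences (the conventional presence-background evaluation, in which the
presences appear on both sides).

## The feature families

All layers share one 9.5 m grid (row 1 = north, pixel-centre coordinates,
planar projected metres). Seven families:

| family | construction | naming example |
|---|---|---|
| topography | elevation resampled to grid | `elevation` |
| raw index | Table of band-arithmetic indices | `bndvi08` |
| multitemporal difference | date-2 minus date-1, simple and normalized | `deltgrn10_08`, `ndeltgrn10_08` |
| percent cover of preferred raw range | presence-range binarize, then focal % | `bnd08_70_990` |
| raw index texture | focal GLCM statistics | `bnd082c990` |
| texture of binary preferred range | GLCM of the 0/1 mask | `bnd082m31070` |
| percent cover of preferred texture range | range-binarized texture, focal % | `ndv102e99pc70` |

The five indices are NDVI, BNDVI, GBNDVI, GRNDI and SARVI, each with the
fixed $10^{-5}$ denominator stabilizer (so a zero-vegetation pixel yields
a finite value); SARVI uses $RB = R - y(B - R)$ with $y = 1$, $L = 0.5$.
Two SARVI parenthesizations circulate in print; the package evaluates the
standard form $(1+L)(NIR - RB)/(NIR + RB + L)$ and exposes
`sarvi_params(literal = TRUE)` for the alternative reading, so the two can
be compared explicitly. The blue-dependent indices (BNDVI, GBNDVI, SARVI)
exist only for the date with a blue band. The normalized multitemporal
difference $(a-b)/(a+b)$ receives the same $10^{-5}$ stabilizer for
finiteness. A generic `signed_power_transform()`
($\mathrm{sign}(v)\,|v|^p$, rank-preserving) covers the occasional
non-linear stretch applied to selected rasters; its exponent is a
configuration value (default 2) because no canonical value exists.

**Preferred ranges.** For the range-based families, the central
$p\%$ interval of a predictor's values at *withheld* presence points
(percentiles $50 \pm p/2$, inclusive linear interpolation — R `quantile`
type 7, the spreadsheet convention; the convention matters at small $n$)
defines "preferred"; the raster is binarized (closed interval, ties
preferred) and percent cover is computed in 310 m and 990 m focal windows
(9.61 and 98.01 ha). Raw-value ranges default to 50% and 70%; texture
ranges to 70/80/85/90%. Ranges must come from the 20% presence partition
withheld from model fitting so that range estimation and model training
stay independent.

**GLCM textures.** Second-order mean, variance, contrast and entropy of
the grey-level co-occurrence matrix in a focal window. Quantization is
equal-interval over the layer's *global* range (16 levels by default, 2
for binary inputs) so texture values are comparable across a scene; pairs
are accumulated over the four unit-distance directions symmetrically, and
entropy uses the natural logarithm (the Haralick convention; the base is a
config option). The sliding-window kernel (C++) updates the co-occurrence
histogram incrementally along each row, so a 105-pixel window costs
$O(\text{window height})$ per pixel rather than $O(\text{window}^2)$.

**Windows and edges.** Map-unit windows convert to the nearest odd pixel
count (310 m → 33 px, 990 m → 105 px at 9.5 m), so every window has a
centre pixel. Focal operations truncate windows at raster edges and flag
the output (`edge_mode = "truncate"`); the intended full-window workflow
computes on a 1 km-buffered extent and crops the buffer afterwards
(`crop_margin()`). The percent-cover denominator counts valid pixels, so
the two modes agree wherever full windows exist.

## Occurrence handling

The point-handling rules, in order: (1) drop records with reported
positional accuracy worse than 100 m (boundary inclusive); (2) randomly
withhold 20% of presences for preferred-range estimation; (3) spatially
thin the remaining modelling presences so no two are closer than 100 m
(seeded random visiting order, greedy acceptance — the rule specifies the
outcome, one random survivor per cluster, not the algorithm); (4) generate
10,000 background points at ≥ 100 m spacing and an equal pseudoabsence set
additionally excluded within 200 m of any presence. Distances are planar
Euclidean, appropriate to a projected CRS. The `extract_swd()` step reads
each feature at the containing pixel and drops (and counts) rows touching
nodata, yielding the samples-with-data table all model fitting consumes.

## RSFSA-CV

Candidate subsets must be internally decorrelated: no pair with
$|r| \ge 0.5$ (Pearson, computed over presence+background rows; 0.5 is
deliberately stricter than the usual 0.7). Subsets are drawn by seeded
random greedy construction with bounded retries, and every emitted subset
satisfies the constraint exactly — a property the tests verify over
10,000 draws.

Each subset is evaluated by re-randomized cross-validation: the presence
and pseudoabsence sets are split into train/test shares (75/25 by
default, 3 re-randomizations in the screening stages), the model is
fitted on training presences against the full background, and three
criteria are recorded: test AUC_psa (accuracy), AUC_psa_diff =
train − test AUC (overfitting), and AICc_bg over all presences
(complexity/information).

* **Stage 1** screens 250 random subsets per size (sizes 1–10) and picks
  the optimal size — the lowest size that already yields high-performing
  models. We operationalize "lowest sufficient" as the smallest
  size whose top-10 models beat 10 random evaluated subsets (Welch's
  t-test, α = 0.05) *and* lie within one pooled standard deviation of the
  best size's top-10 mean (a plateau rule), under whichever criterion
  (AUC_psa or AICc_bg) separates top from random more sharply (larger
  mean |t| across sizes). If no size reaches significance the best-mean
  size is returned with a fallback flag.
* **Stage 2** runs three independent replicates of ~3,000 subsets of the
  chosen size, ranks each replicate by the stage-1 criterion, and keeps
  the top 250 (each compared against an equal random cohort with Welch's
  t-test, recorded per replicate — running the test per replicate rather
  than pooled keeps the replicates independent).
* **Stage 3** draws 4 subsets at random from each replicate's top list —
  12 models from the 750 pooled — refits each on the full data and
  evaluates it with 10-fold cross-validation, producing the full metric
  suite (AUC_psa, AUC_bgp, AUC_psa_diff, AICc_bg, TSS_psa, TSS_bg) and
  each member's max-TSS_psa calibration threshold. Random draw (not
  top-4) is the documented default because the ensemble is meant to
  represent the population of top models, not its extreme order
  statistics; `stage3_random = FALSE` gives the deterministic
  alternative.

**Variable ranking.** Every stage-2 top model is refitted on the full
presence+background data and its permutation importances computed. Per
variable: frequency of appearance across all top models, and mean
importance over its appearances; both min-max normalized and combined as
$0.6\,\text{importance} + 0.4\,\text{frequency}$ (importance carries more
weight as the more informative signal), ranked descending with ties broken
by importance then name. Correlation groups are then assigned by walking
the ranking: each ungrouped variable seeds a new group and every variable
correlated with the seed at $|r| \ge 0.5$ joins it, so a variable bridging
two seeds appears in both groups.

**Seeding.** All randomness flows from one master seed through named
substreams (scene, points, subset draws, CV splits, stage-3 draw,
permutations), so a fixed seed reproduces the entire run byte-for-byte —
`run_pipeline()` writes identical ledgers across repeated runs — while any
single stage can be re-run in isolation.

## Consensus ensembles and maps

Each of the 12 members predicts a cloglog suitability raster and is
calibrated to binary presence/absence at its own max-TSS_psa threshold.
The pixelwise sum of the 12 binaries is the frequency-of-consensus map;
the **core** mask is 100% agreement (all 12), the **semi-core** mask is
at least half ($\lceil n/2 \rceil$, i.e. ≥ 6 of 12 — ceiling so that "50%
or greater" holds for odd ensembles too). Areal extents are pixel counts
times the nominal 90.25 m² pixel area (no geodesic correction; the grids
are projected metres), and land-cover composition reports the percentage
of each LULC class inside a mask (summing to 100 exactly).

## The synthetic scene generator

`generate_scene()` emulates exactly the statistical structure the
analysis assumes and nothing more: each band is separably box-smoothed
Gaussian white noise (three passes ≈ Gaussian kernel) rescaled to the
0–255 digital-number range; date-2 bands are date-1 plus an independent
smoothed change field (`change_sd`, default 10 DN); date 2 has no blue
band; elevation is a smooth ramp-plus-noise surface spanning 1–70 m (a
low-relief coastal plain). The planted truth is a cloglog suitability
surface over standardized driver features — by default the 310 m entropy
texture of date-2 NDVI plus elevation, weights 2 and 1.5, intercept −2 —
chosen so that "does the selection find the true drivers?" is a
meaningful recovery question targeting the texture family the method
centres on. Presences are drawn without replacement at pixel centres with
probability proportional to suitability (avoiding duplicate coordinates
that thinning would immediately delete), and the LULC layer
quantile-slices a smoothed field into equal-area classes.

What the generator deliberately does *not* emulate: radiometric realism
of aerial imagery, observation-protocol artefacts of community-science
data, spatial sampling bias, and real land-cover geometry. Passing
recovery tests therefore demonstrates the *algorithmic* correctness of
the selection machinery under known truth, not field performance on real
occurrence data.

## Desk-scale study conditions

The documented fixture is a 200 × 200 scene (1.9 km side, 3.61 km²) with
a 26-feature catalog spanning all seven families
(`fixture_features()`), ~150 modelling presences (250 sampled, 20%
withheld, thinned), and 1,000 background / 1,000 pseudoabsence points.
Three densities scale with the extent: points are spaced ≥ 30 m (not
100 m — a thousand points at 100 m spacing cannot pack into 3.61 km²),
pseudoabsences are excluded within 100 m of presences (not 200 m), and
presences are thinned at 50 m. The selection runs sizes 1–5 × 100 subsets
in stage 1, 3 × 300 subsets keeping the top 50 in stage 2, and 4 draws
per replicate in stage 3. One full run takes about a minute on a single
core; the bundled acceptance script repeats it over five master seeds.

```{r, eval = FALSE}
study <- prepare_study(seed = 1)
result <- run_rsfsa(study$swd,
                    rsfsa_config(sizes = 1:5, stage1_subsets_per_size = 100,
                                 stage2_subsets = 300, stage2_top = 50),
                    seed = 1)
glance(result)
maps <- build_ensemble_maps(result$ensemble, study$stack, lulc = study$lulc)
autoplot(maps)
```

## Numerical choices and degenerate inputs

* `quantize_integer()` scales by the largest power of ten keeping the
  largest absolute value within 7 digits; already-integer layers pass
  through unchanged; the scale is recorded in the layer name and as an
  attribute so the float layer is recoverable.
* Constant features are dropped from fits with a warning (never
  silently); an all-constant design yields a flagged uniform model;
  near-separation (|coefficient| > 50) warns.
* The subset sampler errors on exhaustion of distinct admissible subsets
  by default; the screening stages pass `allow_fewer = TRUE` and warn,
  since a desk-scale catalog cannot supply 100 distinct single-feature
  subsets.
* AICc is undefined (NA with a warning) when presences ≤ parameters + 1.
* GLCM windows with no valid pair (all-nodata neighbourhoods) yield
  nodata; `0 log 0 = 0` in entropy.
* Ties at preferred-range bounds count as preferred; ties in TSS
  maximization resolve to the lowest threshold; AUC ties count one half.
* The screening model default is linear+quadratic (`rsfsa_config()`)
  while `model_spec()` defaults to linear+quadratic+hinge: subset
  screening fits thousands of small models where the leaner basis is the
  appropriate complexity control; the richer basis remains available for
  final models.

## Limitations

* Raster I/O is the plain-text ESRI ASCII grid (readable by GDAL, ArcGIS
  and QGIS); GeoTIFF and CRS-aware reprojection are out of scope —
  `align_to_grid()` handles affine nearest/bilinear resampling only.
* The printed family counts of the full 199-feature catalog are not
  hard-coded: families whose exact membership is a judgment call (which
  index rasters feed percent-cover families, which texture ranges are
  used) are configuration-driven with documented defaults; the
  unambiguous counts (topography 1, multitemporal 4, 6 rasters × 4
  textures × 2 windows = 48) fall out of the enumeration and are asserted
  in tests.
* Exact numeric parity with any particular MaxEnt release is a non-goal;
  the model is the standard penalized Gibbs formulation, not a wrapper.
* Parallel scheduling is out of scope; a full-scale run (250 × 10 +
  3 × 3,000 subsets) is embarrassingly parallel over subsets if needed.
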