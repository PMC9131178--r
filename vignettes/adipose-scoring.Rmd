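---
title: "Adipose scoring of H&E slides: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adipose scoring of H&E slides: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the score

Adipose tissue in the colorectal tumor microenvironment carries prognostic
information, but scoring it by eye on whole-slide H&E images is slow and
subjective. histoadi automates the measurement as a tile-classification
problem. A slide is cut into non-overlapping 224 x 224 pixel tiles at a
working resolution of 0.5 microns per pixel, tiles that are mostly glass
are discarded, the remaining tiles are each assigned one of nine colorectal
tissue classes (ADI adipose, BACK background, DEB debris, LYM lymphocyte
aggregates, MUC mucus, MUS smooth muscle, NORM normal mucosa, STR stroma,
TUM tumor epithelium), and the patient's adipose score is the fraction of
classified tiles labeled ADI:

$$\mathrm{ADI} = \frac{n_{\mathrm{ADI}}}{n_{\mathrm{classified}}}.$$

A patient whose slide yields 1,000 classified tiles of which 200 are
labeled adipose scores ADI = 0.2. The score is then dichotomized and
evaluated as a prognostic marker for overall survival, and connected to
transcriptome data through gene-set enrichment.

## Tiling and background removal

`tile_slide()` conceptually rescales the slide by `mpp / target_mpp`
(bilinear interpolation, via EBImage) and covers the rescaled image with a
0-based, row-major grid of non-overlapping squares; partial tiles at the
right and bottom edges are dropped, never padded. Each tile is pooled to a
single pixel by global averaging; the gray value is the unweighted mean of
the three pooled channel means. A tile is background iff this gray value
strictly exceeds the threshold (default 200 on the 0--255 scale), so a
tile at exactly 200 is kept. Counts are conserved by construction:
`kept + removed = total` for every slide.

Two points were genuinely open and are settled as follows. The gray value
could have been a luminance-weighted combination; we use the unweighted
mean because the pooled "RGB gray" is not otherwise defined, and the
filter's behavior near the threshold is dominated by glass-vs-tissue
contrast, not channel weighting. And the filter is applied *after*
rescaling to the working resolution, so that the decision is made on the
same pixels the classifier sees.

Color normalization (`normalize_tile()`) is the per-channel affine map
`(x/255 - mean)/sd`. Its statistics default to values computed from a
fixed batch of synthetic training tiles; externally supplied statistics
are accepted. The reference classifier consumes raw 8-bit tiles (its
features are defined on the 0--255 scale), so `tile_slide()` attaches
normalized copies only on request — normalization matters when plugging in
CNN-style models trained on normalized inputs.

## Classification

The deployed quantity is only the per-tile argmax label, so the
classifier is an interface: anything that maps a 224 x 224 x 3 tile to a
nine-probability vector. Labels are the class of maximum probability with
ties broken toward the lowest class index (so a degenerate uniform vector
yields ADI); the tie-break is arbitrary but documented and deterministic.

The shipped reference classifier is deliberately desk-scale: 11 summary
features per tile (channel means and standard deviations, white-pixel
fraction, dark-blob count, edge density, gradient-orientation share, and
gray-level co-occurrence contrast) feeding a multinomial logistic
regression (`nnet::multinom`), with a stratified 20% holdout reporting
accuracy. It is a stand-in with the same contract as a transfer-learned
deep CNN, adequate for the separable synthetic textures; it is *not*
expected to transfer to real H&E tiles, where learned features are
necessary. `load_classifier()` accepts serialized coefficients so an
externally trained model can be swapped in behind the same interface.

## The synthetic-data generator

Every stage is testable without restricted slide archives because the
generator emits data *with ground truth attached*:

* **Tiles** (`simulate_tile()`): parametric textures — discs, ellipses,
  rings, oriented stripes, speckle — on stained base colors. Adipose tiles
  are large white vacuoles with thin pink rims; background is
  near-uniform near-white; lymphocytes are dense small dark-blue dots;
  tumor is crowded dark-purple ellipses; stroma and muscle are pink fiber
  textures at roughly orthogonal orientations; normal mucosa shows gland
  rings; mucus a pale blue wash; debris heavy pink-gray speckle. Base
  colors are chosen so every foreground class pools to a gray value
  safely below 200 and BACK safely above, making the background filter
  behave as it does on tissue. Textures are parametric primitives, not
  learned: the goal is class separability for a desk-scale classifier,
  not histological realism.
* **Slides** (`simulate_slide()`): mosaics whose per-class tile counts
  follow largest-remainder apportionment of the requested fractions, so
  realized compositions are *exactly* predictable (error at most one tile
  per class); the ground-truth label grid is returned and stored in the
  PNG sidecar.
* **Cohorts** (`simulate_cohort()`): ADI ~ Beta(2, 4) (mean 1/3, mass on
  both sides of the default cutpoint); event times exponential with a
  hazard that steps by `exp(log HR)` above the true cutpoint, independent
  exponential censoring. The step model mirrors the dichotomized use of
  the score; a continuous linear effect is available (`effect =
  "linear"`) but off by default. Defaults — 600 patients, true HR 2 at
  cutpoint 0.25, baseline hazard 0.1 events/month, censoring rate
  0.03/month — describe a mid-sized retrospective cohort with a strong
  but realistic effect.
* **Expression** (`simulate_expression()`): Gaussian baseline (sd 1) with
  a constant mean shift (+2 by default) added to the genes of chosen sets
  in high-ADI samples.

All generators are bitwise reproducible: each draws from a single RNG
stream seeded from its own seed argument, sub-seeds for per-tile streams are
derived deterministically from the index, and the caller's RNG state is
restored afterwards.

What passing tests on these data do and do not show: they validate the
*procedures* — counting, filtering, estimation, testing — under known
truth. They do not show that the reference classifier, or any particular
cutpoint or hazard ratio, generalizes to real cohorts; stain variation,
scanner artifacts, pen marks and intermediate tissue morphologies are all
absent from the simulation by design.

## Survival analysis from first principles

The survival stack is authored in the package rather than delegated, so
that every formula is visible and testable against independent oracles:

* **Kaplan-Meier** (`km_curve()`): product-limit
  `S(t) = prod(1 - d_i/n_i)` over distinct event times; subjects censored
  exactly at an event time remain in the risk set at that time.
* **Log-rank** (`logrank_test()`): observed-minus-expected events in one
  group under the per-time hypergeometric null,
  `chi2 = (sum(O-E))^2 / sum(V)`, df 1. The implementation is an
  O(n log n) vectorized accumulation; the test suite checks it to 1e-12
  against a naive per-time loop.
* **Cox** (`cox_fit()`): univariate partial likelihood by Newton-Raphson,
  Efron tie handling by default (Breslow by flag; identical without
  ties). Convergence at |step| < 1e-8 or 50 iterations; the covariate is
  centered for numerical stability; early steps are damped to |step| <= 5.
  Monotone likelihood (perfect separation) is detected by |beta| > 15 and
  flagged `converged = FALSE` rather than returned silently. CIs are Wald:
  `exp(beta +/- 1.96 se)`.
* **Cutpoint** (`find_cutpoint()`): maximally selected standardized
  log-rank statistic `|O-E|/sqrt(V)` over candidate thresholds at
  midpoints between consecutive distinct scores, with both groups
  required to hold at least `minprop` (default 0.1, the conventional
  choice) of the cohort; ties break toward the lower threshold.
* **Median split** (`median_split()`): high iff score > median, so
  subjects at exactly the median go low — a documented, deterministic
  rule.

`stratify_survival()` composes these per (sub)cohort. Both stratification
methods are provided because the source procedure names both in one
breath; cutpoint search is the default and the choice is recorded in the
result object. Subgroups with fewer than 2 events in a group are flagged
unreliable. Multivariable adjustment, competing risks and
proportional-hazards diagnostics are out of scope.

## Enrichment

`ssgsea_scores()` implements the rank-ECDF form of single-sample GSEA:
genes ranked by expression descending (ties broken by gene identifier,
for determinism), enrichment score = sum over the ordered list of
(weighted in-set ECDF - out-of-set ECDF), with in-set weights
`rank^alpha`, alpha 0.25. Scores are reported unnormalized by default;
`normalize = TRUE` divides by the overall max-min range. Because only
ranks enter, any strictly monotone within-sample transform leaves scores
unchanged — a property the tests exercise directly.

`gsea_preranked()` is the classical weighted running sum (maximum
deviation from zero) with significance by *gene-label* permutation — the
standard convention for preranked input, chosen because phenotype
permutation is undefined once the input is a single ranked list. The
permutation p-value uses the add-one rule, `(1 + #{|ES*| >= |ES|}) /
(1 + n_perm)`, so it is never exactly zero; 1,000 permutations by
default.

`compare_groups()` compares pathway (or immune-score) rows between
high- and low-ADI samples: Welch's t by default, Mann-Whitney U by flag,
BH adjustment across rows, stars at 0.05/0.01/0.001. The named "limma
test" of the source procedure is under-specified; moderated-variance
shrinkage is deliberately not reimplemented, and Welch is the default as
the closest well-defined two-sample test. Exact Mann-Whitney p-values are
used when there are no ties.

## Scoring decisions

The score denominator includes *all* classified tiles, including any the
model itself labels BACK — this matches the reference worked example, in
which the denominator is simply the patient's slice count; `drop_back =
TRUE` excludes model-labeled background instead. Patients with several
slides are pooled by *counts*, not by averaging per-slide proportions, so
slides weigh by their tile numbers and pooling equals scoring the
concatenated prediction stream. A slide with zero classified tiles has no
score: `NA`, never 0. For body-mass-index comparisons the convention
`BMI > 25` vs `<= 25` is retained from the source analysis even though it
corresponds to the overweight rather than the WHO obesity threshold.

## Problem sizes and numerical choices

The test suite validates the estimators at sizes chosen to make the
statistical properties visible while remaining comfortable on a single
CPU: classifier accuracy on 200 tiles per class; Cox recovery at n = 250,
1,000 and 4,000; null calibration of the log-rank test and of GSEA
permutation p-values over 500 replicate simulations (permutations scaled
to 200 per replicate); cutpoint recovery at n = 600 with a hazard ratio
of 3. Oracle agreement (Kaplan-Meier, log-rank, ssGSEA, Mann-Whitney) is
required to 1e-12; agreement between the package's Cox fit and an
independent implementation to 1e-7.

## Known limitations

* The reference classifier is a stand-in for a trained CNN; its accuracy
  statements apply to the synthetic textures only.
* Single-resolution raster slides; no pyramid traversal, stain
  deconvolution or artifact detection.
* Univariate survival modelling only.
* ssGSEA scores are not calibrated across set sizes (no NES); group
  comparison has no variance moderation.
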