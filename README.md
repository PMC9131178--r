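# histoadi

Adipose tissue scoring of H&E whole-slide images, with survival and
gene-set enrichment analysis — and a synthetic-data generator that makes
the whole pipeline testable with known ground truth.

## What it does and for whom

Pathologists and computational-pathology researchers who want a
quantitative, reproducible measure of adipose content in colorectal
cancer H&E sections can use histoadi to:

1. **Tile** a slide into non-overlapping 224 × 224 px tiles at a working
   resolution of 0.5 µm/pixel, dropping background tiles whose
   global-average gray value exceeds 200 (strict inequality: a tile at
   exactly 200 is kept);
2. **Classify** each kept tile into one of nine tissue classes — ADI
   (adipose), BACK, DEB, LYM, MUC, MUS, NORM, STR, TUM — by argmax over a
   pluggable classifier's probability vector (a desk-scale reference
   classifier ships with the package; externally trained models plug in
   behind the same interface);
3. **Score** each patient by the adipose fraction of classified tiles,

   `ADI = n_ADI / n_classified`

   (a patient with 1,000 classified tiles of which 200 are labeled
   adipose scores ADI = 0.2);
4. **Stratify** patients into high- and low-ADI groups — maximally
   selected log-rank cutpoint by default, median split as an
   alternative — and compare overall survival with Kaplan–Meier curves,
   the log-rank test and a univariate Cox model (Efron ties, Wald CIs),
   all implemented from first principles;
5. **Enrich**: connect the score to transcriptome data with single-sample
   GSEA (rank-ECDF form, α = 0.25), preranked GSEA (1,000 gene-label
   permutations, add-one p-values), and high-vs-low group comparisons
   (Welch or Mann–Whitney, BH-adjusted).

Because real slide cohorts (public tumor archives, hospital collections)
are restricted or impractically large,
the package includes generators for nine-class texture tiles, mosaic
slides with exact known composition, survival cohorts with a planted
hazard ratio, and expression matrices with planted gene-set shifts —
every downstream stage is validated against this ground truth.

## Worked example

```r
library(histoadi)

# A synthetic slide with known composition: 20% adipose
sl <- simulate_slide(10, 10, c(ADI = 0.2, TUM = 0.6, STR = 0.2),
                     seed = 1, slide_id = "demo")
tiles <- tile_slide(sl$slide)
tiling_report(tiles)
#>   slide_id total removed  kept
#> 1 demo       100       0   100

model <- fit_tissue_classifier(simulate_tile_features(30, seed = 1), seed = 1)
model
#> <tissue_classifier: multinomial logit on 11 features, 216 training tiles,
#>  held-out accuracy 1.000>

preds <- classify_tiles(tiles, model)
adi_score(slide_composition(preds))
#> [1] 0.2

# A cohort whose hazard doubles above ADI 0.25
coh <- simulate_cohort(400, true_log_hr = log(2), seed = 42)
res <- stratify_survival(coh)   # maximally selected cutpoint
res
#> ADI survival stratification (cutpoint, cutpoint 0.247)
#>   n: low 149 / high 251; events: 111 / 222
#>   log-rank p = 1.575e-09; HR = 2.066 (95% CI 1.626-2.627)
```

The pipeline recovers the planted truth: the slide's adipose fraction
(0.2) exactly, the hazard-step location (0.247 vs the true 0.25) and the
hazard ratio (2.07 vs the true 2). `autoplot(res)` draws the group KM
curves; `tidy()`/`glance()` return the numbers as tibbles;
`run_pipeline()` orchestrates the whole chain from a config list or YAML
file (see `simulate_study()` for a one-call synthetic input set).

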