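# adipoindex

Adipocyte morphometry and the blubber **adipocyte index (AI)** — an
image-analysis and statistics toolkit for assessing the adiposity
(energetic reserves) of marine mammals from histological sections of
blubber biopsies.

## The problem and who this is for

Blubber stores energy as triglyceride in lipid-filled adipocytes embedded
in a darker-staining matrix (the intervacuolar space). Since adipocyte
*number* is fixed in adulthood, energy gain and loss show up as changes in
adipocyte *size*. Sections of shallow biopsy samples therefore carry a
nondestructive morphometric signal of body condition — more robust than
the lipid-percent assays usually run on the same biopsies, which suffer
badly from lipid loss during sampling. This package is for ecophysiology
and population-health groups who want to run that measurement chain end
to end, and to validate every stage against synthetic tissue with known
ground truth.

Given a thresholded image with adipocyte pixel fraction *a*, the package
reports

    AI = total area / adipocyte area = 1/a  =  1 + (intervacuolar/adipocyte)

so AI ≥ 1, with 1 meaning a fully lipid-filled field and larger values
meaning leaner tissue. The per-cell route measures each complete
adipocyte under a circular model: a cell of *n* pixels at *c* µm/px has
equivalent diameter d = 2·sqrt(n·c²/π) and area π(d/2)² = n·c².

The statistical layer implements the full two-cohort comparison battery:
Shapiro–Wilk, Levene, a 2.2 × IQR outlier screen, VIF, pooled-variance
t-tests (log10 AI), Pearson correlations, and binary logistic regression
of migration cohort (early = 0, late = 1) with backward likelihood-ratio
selection, Nagelkerke R² and Hosmer–Lemeshow goodness of fit.

## Worked example

```r
library(adipoindex)

## synthetic tissue with exact ground truth
res <- generate_tissue_image(tissue_spec(seed = 7))
res$truth
#> <ground_truth> 254 cells, intervacuolar fraction 0.444, true AI 1.7971

## segment, measure, and compute the AI
seg <- segment_image(res$image, threshold = 128)
seg$measurements
#> <cell_measurements> 213 cells (213 complete), mean complete-cell area 1014.77 um2
seg$ai
#> <adipocyte_index> 1.8016 (total_over_adipocyte), adipocyte fraction 0.555

## a two-cohort metrics table under the study conditions, and the battery
tab <- generate_cohort_table(cohort_table_spec(seed = 7))
analyze_metrics_table(tab)
#> Correlations:
#>   area_ai: r = -0.825 (n = 83, p = 8.94e-22)
#>   area_lipid: r = 0.333 (n = 77, p = 0.00313)
#>   ai_lipid: r = -0.322 (n = 139, p = 0.000112)
#>
#> <model_battery>
#>   A: n = 77, final predictors: ai + lipid_percent, Nagelkerke R2 = 0.391
#>   B: n = 139, final predictors: ai + lipid_percent, Nagelkerke R2 = 0.353
#>   C: n = 77, final predictors: adipocyte_area_um2, Nagelkerke R2 = 0.252
#>   D: n = 83, final predictors: ai, Nagelkerke R2 = 0.380
#>   E: n = 77, final predictors: adipocyte_area_um2, Nagelkerke R2 = 0.252
#>   F: n = 77, final predictors: ai, Nagelkerke R2 = 0.342
#>   G: n = 77, final predictors: lipid_percent, Nagelkerke R2 = 0.000
```

Reading the output: the noisy synthetic image's AI (1.8016) recovers the
generator's ground truth (1.7971) to within the noise tolerance, and on a
noise-free image the recovery is exact. In the simulated cohort table the
AI correlates strongly and negatively with adipocyte area (r = −0.83;
they measure the same underlying cell size from opposite directions),
lipid percent correlates only weakly with either, and the logistic
battery picks AI — never lipid percent alone — as the informative
predictor of migration cohort. The listwise-deletion subset sizes (77,
139, 83) fall directly out of the generator's per-metric missingness
pattern.

A command-line wrapper covers the same pipeline for shell use:

```sh
adipo=$(Rscript -e 'cat(system.file("exec","adipo.R",package="adipoindex"))')
Rscript $adipo simulate --image --seed 9 --out sim     # image + ground truth
Rscript $adipo segment --images sim --threshold 128 --um-per-px 0.65 --out seg
Rscript $adipo simulate --table --seed 9 --out tab
Rscript $adipo stats --table tab/metrics.csv --out report
```

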