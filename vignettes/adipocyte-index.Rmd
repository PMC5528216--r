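---
title: "The blubber adipocyte index: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The blubber adipocyte index: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adipoindex)
```

## The biological problem

Blubber — the subcutaneous adipose tissue of marine mammals — stores energy
as triglyceride inside lipid-filled adipocytes embedded in a matrix of
collagen, vessels and other cells (the *intervacuolar space*). Because
adipocyte number is essentially fixed in adulthood, changes in stored
energy show up as changes in adipocyte *size*. Histological sections of
shallow biopsy samples therefore carry a morphometric signal of adiposity
that is more robust than the lipid-percent assays commonly run on the same
biopsies, which are notoriously sensitive to lipid loss during sampling
and handling.

This package implements two measurement routes on stained (H&E) blubber
sections, and the statistical battery used to compare them:

1. **Per-cell area.** Adipocytes are segmented, incomplete (border) cells
   discarded, and each cell's cross-sectional area measured under a
   circular cell model. The per-sample statistic is the mean area of at
   least 100 complete cells.
2. **Adipocyte index (AI).** A single thresholding of a sufficiently
   large image partitions it into adipocyte and intervacuolar area. With
   adipocyte pixel fraction $a$, the package reports
   $\mathrm{AI} = 1/a$ (total area over adipocyte area) by default.
   Higher AI means relatively more matrix, i.e. leaner tissue.

## The AI definition

The AI is often described loosely as "the ratio of intervacuolar to
adipocyte area". Taken literally that is $(1-a)/a$, which is below 1 for
any adipocyte-dominated image; observed field values, however, are bounded
below by exactly 1 (an image with no visible matrix scores 1). The only
definition consistent with that bound is

$$\mathrm{AI}_{\text{total}} = \frac{\text{total area}}{\text{adipocyte area}}
  = \frac{1}{a} = 1 + \frac{1-a}{a},$$

so `compute_adipocyte_index()` defaults to the total-over-adipocyte form
and also offers the strict ratio. The strict value is computed as
$1/a - 1$ so that the identity $\mathrm{AI}_{\text{total}} =
1 + \mathrm{AI}_{\text{strict}}$ holds *exactly* in floating point; every
result records which definition produced it. The AI is a pure fraction:
it is invariant to image rescaling and to the µm/pixel calibration.

## Intensity conventions and thresholds

Image files store intensities in light-is-high form (0 = black). The
densitometric convention used for stained sections is the opposite:
0 = white, maximum = black. All thresholds in this package are expressed
on that dark-is-high scale, and `binarize()` resolves the convention of
whatever image it is given, recording both the raw and converted threshold
in the mask's provenance. A pixel at or beyond the threshold on the dark
side is intervacuolar; everything else is adipocyte.

The default 16-bit threshold is 65,527 — a conservative near-black cut
under which only strongly stained pixels count as matrix. Its 8-bit
equivalent is derived by proportional scaling (65,527/65,535 → 254.97,
rounded to 255, i.e. only pure black). In practice the operator tunes the
threshold once per staining batch so that darkened pixels cover the
intervacuolar space without encroaching on adipocyte area, then holds it
fixed across the whole sample set; `segment_image()` takes the threshold
as an argument precisely so a pipeline can enforce that constancy.

Two validity gates apply to the AI. First, the image must cover at least
167,687.3336 µm² — smaller fields make the two-phase ratio unstable to
local tissue heterogeneity. Second, because field protocols select
adipocyte-dominated images, images whose adipocyte fraction falls below
0.5 are QC-flagged and excluded from AI reporting by default (both gates
can be overridden with `force = TRUE`).

## Per-cell measurement

Adipocyte pixels are labelled as 8-connected components (the matrix phase
is implicitly 4-connected, the standard duality that avoids checkerboard
ambiguity); the labeler is a small two-pass union-find in C++. Cells
touching the image border are removed, as are labels below a 20 px debris
floor (a stand-in for the manual curation of nuclei and specks). The
equivalent diameter of a cell with $n$ pixels at calibration $c$ µm/px is
$d = 2\sqrt{n c^2 / \pi}$ and the reported area is $\pi (d/2)^2$,
identically $n c^2$. The circular model is recorded in the measurement
object so an alternative diameter estimator (e.g. Feret) could be swapped
in without changing the contract. Whether the original field protocol used
an equivalent-circle or caliper diameter is not documented; the
equivalent-circle choice is the default here.

Merged cell pairs can optionally be split by seeded watershed: seeds are
local maxima of the Euclidean distance transform, thinned to a minimum
separation of half the median equivalent diameter, then grown through the
mask (`EBImage::propagate`). This is off by default, mirroring protocols
in which clusters are corrected manually.

The per-sample mean refuses to report on fewer than 100 complete cells
(configurable), the count at which per-sample area estimates are known to
stabilise; the error carries the observed count so pipelines can log it.

## Derived quantities

* Spherical volume: $r = \sqrt{A/\pi}$, $V = \tfrac{4}{3}\pi r^3$,
  converted at $10^6$ µm³ per nl (the constant is `UM3_PER_NL` in the
  code). Note that treating the measured cross-section as an equatorial
  section overestimates the volume of the *average* cell, since sections
  do not all pass through cell centres; volumes are reported for
  comparison between cohorts, not as absolute cell sizes.
* Cohort summaries report n, geometric mean, arithmetic mean and range
  per metric per cohort, excluding missing values metric-wise.
* Percent reductions are reported separately for arithmetic means,
  geometric means, and volumes — never blended into a single "size"
  number, because the three transforms do not commute.

## The statistical battery

The screens and tests mirror the standard workflow for two-cohort
morphometric comparisons: Shapiro–Wilk normality per metric (AI is also
screened after log10, the scale on which it is approximately normal),
classical mean-centred Levene for homogeneity of variances (median
centring available), a conservative 2.2 × IQR outlier screen with
type-7 (linear interpolation) quartiles, and VIF as a collinearity check.
Cohort comparisons use the pooled-variance Student t-test (Welch
available), with log10 applied to AI only; AI enters the logistic models
untransformed, since normality is not a prerequisite there.

Binary logistic regression codes the response early = 0, late = 1. Fits
are maximum likelihood via IRLS (`stats::glm`), standard errors from the
inverse observed information, odds ratios $e^B$ with 95% Wald intervals
$e^{B \pm 1.959964\,\mathrm{SE}}$. Non-convergence and separation are
detected and flagged distinctly. Missing data are handled by listwise
deletion per model, never imputation — subset sizes are part of the
scientific record.

Backward likelihood-ratio selection starts from the full model and
repeatedly removes the predictor with the largest likelihood-ratio
removal p-value while that p-value is at least `p_out`. The default
`p_out = 0.10` is the conventional default of mainstream statistical
software; it is configurable. The trace records every step.

Model fit is summarised by Nagelkerke's $R^2$ (Cox–Snell
$1 - e^{2(LL_0 - LL_1)/n}$ rescaled by its maximum $1 - e^{2 LL_0/n}$) and
the Hosmer–Lemeshow chi-square over 10 groups of ranked fitted
probabilities (ties kept together; degenerate bins merged with a warning;
df = groups − 2). A fitted log-likelihood below the null model's raises an
error rather than a negative $R^2$, since it can only signal a fitting
bug. For near-separated fits the binning can degenerate below three
groups; the battery then reports the diagnostic as undefined rather than
failing.

### The seven-model battery

`run_model_battery()` fits the standard comparison set: A = area + AI +
lipid, B = AI + lipid, C = lipid + area, D = area + AI, and the univariate
E = area, F = AI, G = lipid. Models A–D use backward-LR selection on their
own listwise subsets. The univariate models E–G are *forced-entry* fits
evaluated on the complete-case subset (records with all three metrics):
this keeps the three measures comparable on identical samples, and is the
only reading consistent with published batteries of this design in which
all three univariate models share one n even though each metric alone
covers a different number of samples. (Under backward LR a non-significant
univariate predictor would simply be removed, leaving nothing to report.)

## The synthetic-histology generator

Ground truth for the image pipeline comes from a disc-packing generator.
Cell radii are lognormal (default median 14.5 µm, log-SD 0.25, giving a
median cell area near 660 µm²); discs are placed by random sequential
adsorption, largest first, with centre-to-centre clearance of at least
the sum of radii plus a matrix gap (default 2 µm). Cells are rendered at
the bright (lipid) pole and matrix at the dark pole of an 8- or 16-bit
light-is-high scale; Gaussian intensity noise and dark specks (a nuclei
mimic, Poisson per 1,000 µm²) are added afterwards and truncated to the
bit-depth range. The ground truth — label mask, per-cell rasterized areas,
intervacuolar fraction, true AI — is taken from the noise-free rendering,
so on a noise-free image the pipeline must recover it *exactly*, and does
(this is asserted in the test suite).

Two design points deserve emphasis:

* **Packing density.** Random sequential adsorption of discs saturates
  near an area fraction of 0.6 even with largest-first polydisperse
  placement — well below the space-filling density of real adipose
  tissue, where polygonal cells leave only thin matrix septa. The default
  target fraction is 0.58 (rendered ≈ 0.55 after border clipping), which
  yields synthetic AI values around 1.8: inside the plausible field range
  but at its lean end. Synthetic images therefore stress the
  *segmentation* machinery faithfully (intensity structure, border
  effects, specks, noise), not the marginal distribution of field AI
  values. A packer that cannot reach its target raises an error naming
  the achieved fraction rather than silently under-delivering.
* **What the image generator does not emulate.** Staining gradients,
  out-of-focus blur, vascular and fibroblast structure, elliptical or
  polygonal cell outlines (an equal-area elliptical perturbation is
  available behind a flag, default off), and 3-D sectioning effects.
  Passing tests on synthetic images show the measurement chain is
  correct, not that thresholds tuned here transfer to any particular
  staining batch.

The cohort-table generator supplies ground truth for the statistics. It
draws the three metrics from a Gaussian copula (so cross-metric Pearson
and rank correlations are controlled without distorting marginal ranges)
with per-cohort marginals: normal area, log10-normal AI floored at its
theoretical minimum of 1, and normal lipid percent clamped to (0.5, 100].
Its defaults are the targeted study's conditions: 98 early / 105 late
samples; early/late area means 792.10/597.65 µm² with SDs of roughly a
quarter of the printed ranges (200/126); AI cohort geometric means
1.30/1.55 (pooling to ≈ 1.42; the per-cohort split is not printed anywhere
and was chosen once); lipid means equal across cohorts (42, SD 16, whose
geometric mean ≈ 39.3) so that lipid percent is uninformative about
cohort; copula correlations (−0.784, 0.388, −0.468) applied within
cohort; and a missingness pattern derived exactly from the published
per-metric counts (AI always observed; area on 42/41 samples; lipid on
38/101; 36 early and all 41 late area samples also carry lipid), which
makes the listwise-deletion subsets come out at exactly 83 (area + AI),
139 (AI + lipid) and 77 (all three). Because the copula is applied within
cohort, *pooled* correlations also absorb the cohort mean shifts and the
attenuation from the clamped lipid marginal; the generator's correlation
contract is therefore tested at equal cohort means.

## Numerical choices

* IRLS convergence: relative deviance change < 10⁻⁸, at most 100
  iterations; separation flagged from the fitted-probability warning or a
  coefficient norm above 10⁴.
* Wald intervals use z = 1.959964.
* Quartiles use linear interpolation (type 7); this is stated because
  outlier flags near the fence depend on it.
* Rasterization uses pixel-centre membership; a rasterized disc's area
  differs from $\pi r^2$ by at most a one-pixel perimeter band, which is
  why ground-truth areas are defined from the rendered mask, not the
  analytic discs.
* RGB input converts to grayscale with Rec. 601 luminance weights
  (0.299, 0.587, 0.114), recorded in provenance; colour input can be
  refused outright.
* Every generator call consumes a single seeded RNG stream
  (`withr::with_seed`), so equal seeds give bit-identical images, tables
  and downstream reports.

## Problem sizes used in the test suite

The suite validates the statistical machinery at deliberately modest
sizes chosen for statistical resolution: copula calibration at n = 10,000,
null-mean checks at n = 5,000 per cohort, logistic parameter recovery at
n = 5,000, selection behaviour over 200 replicates of n = 500, and
Hosmer–Lemeshow calibration over 100 replicates of n = 1,000. Image-level
checks use the default 1024 × 1024 px field plus smaller constructed
fixtures.

## Known limitations

* Disc packing cannot reach real adipose densities (above), so synthetic
  AI marginals sit high; cohort-level statistical structure is supplied
  by the table generator instead.
* The watershed de-clusterer is a geometric stand-in for expert manual
  correction and will over-split strongly elongated merged regions.
* JPEG input is not supported (TIFF/PNG only); the 8-bit threshold
  convention still applies to 8-bit files.
* Whole-body extrapolations of blubber lipid loss are out of scope: they
  require empirical tissue-mass data external to histology.
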