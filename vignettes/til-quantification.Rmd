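---
title: "Automated TIL quantification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated TIL quantification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Tumor-infiltrating lymphocytes (TILs) reflect the host immune response inside
a tumor and carry prognostic information in esophagogastric cancers. The
conventional readout — a pathologist's semi-quantitative grade on a
haematoxylin–eosin (H&E) section — is subjective and labour-intensive.
`tilquant` implements an automated, quantitative readout: it detects every
nucleus in a section image, classifies each as cancer cell, lymphocyte, or
stromal cell, and reports the TIL proportion

$$\pi \;=\; 100 \cdot \frac{n_{\text{lymphocyte}}}{n_{\text{cancer}} +
n_{\text{lymphocyte}} + n_{\text{stroma}}}\ [\%],$$

which then enters cohort comparisons and survival models as an ordinary
quantitative biomarker.

## Nucleus detection

**Colour model.** H&E stains nuclei dark (haematoxylin, basophilic) against a
pink eosin background. The image is converted to CIELAB (sRGB primaries, D65
white); nuclear signal is concentrated in low lightness $L$. Two grayscale
channels are derived:

- *Thresholding channel* (`to_nucleus_grayscale`): each slide's $L$ channel is
  standardised by its own mean and standard deviation, negated so nuclei score
  high, and affinely rescaled to $[0,1]$. Standardising per slide makes the
  threshold robust to staining intensity differences between sections.
- *Feature channel* (`nucleus_intensity`): the absolute complement of
  lightness, $(100 - L)/100$. Intensity and texture features use this fixed
  scale so that a nucleus's measured darkness does not depend on what else is
  on the slide. (A slide containing only pale nuclei would otherwise stretch
  its own contrast until those nuclei looked as dark as lymphocytes —
  composition-dependent features would follow.)

**Threshold.** Otsu's criterion: the histogram (256 right-open bins on
$[0,1]$) is scanned over all interior bin boundaries and the boundary
maximising the between-class variance $\sigma_B^2(t) = w_0 w_1 (\mu_0 -
\mu_1)^2$ is chosen; ties break to the lowest boundary, so the result is
deterministic. A constant image has no threshold and raises a degenerate-image
error. The threshold is estimated once per slide, on the full image: a 100th
of a section frequently contains no nuclei at all, and a per-tile threshold
would split pure background noise into spurious foreground there. Tiles are
still *segmented* independently (opening, watershed) and merged at their
offsets.

**Morphology and watershed.** The binary mask (`gray > t*`) is opened with a
disk of radius `opening_radius_px` (default 1 px), removing speckle.
Touching nuclei are separated by a marker-controlled watershed: seeds are the
h-maxima of the exact Euclidean distance transform (prominence threshold
`hmax_suppression`, default 2 px, computed by morphological reconstruction),
and flooding runs on the negated distance transform with 8-connectivity.
Two equal disks of radius 8 whose centres are 12 px apart are cut within
2 px of their midline; maxima whose saddle is within 2 px of their height are
merged, which prevents boundary-noise lumps on large cancer nuclei from
splitting them. Regions below `min_nucleus_area_px` (default 9 px, below any
plausible lymphocyte at this scale) are discarded and labels are relabelled
contiguously.

**Tiling.** Whole sections are processed as a 10 × 10 grid ("100 equal
parts"): tile extents use floor division with the remainder appended to the
last row/column, so reassembly is exact. A nucleus cut by a tile boundary
appears as one fragment per tile; fragments whose labels touch across a
boundary are grouped and only the largest is kept. This slightly truncates
boundary nuclei (they remain matched at IoU ≥ 0.5 in validation) and, rarely,
suppresses one of two genuinely distinct nuclei that touch exactly at a
boundary — an accepted cost of tile independence.

**Blank slides.** A slide whose lightness standard deviation falls below
`min_contrast` (default 4 L-units) is treated as unstained/background and
yields an empty label map rather than hallucinated nuclei; downstream
quantification then raises an undefined-proportion error.

## The 43-feature vector

The classifier consumes a fixed, ordered, versioned registry of 43 features
per nucleus (`feature_registry()`): 12 shape (area, Crofton perimeter,
moment-based major/minor axis, eccentricity, solidity against the pixel-count
convex hull, extent, circularity, convex area, orientation, equivalent
diameter, boundary roughness), 12 intensity on the absolute nucleus-intensity
channel (moments, order statistics, integrated intensity, contrast against a
2-px dilated ring), 13 grey-level co-occurrence statistics (32 levels, four
symmetric unit offsets averaged, background masked to the region median), 3
neighbourhood (neighbour count within 50 px, nearest-neighbour distance,
local density) and 3 boundary Sobel-gradient summaries. The perimeter
estimator is a four-direction Crofton intercept count (within 10% of the
polygon boundary length on the shapes used here); second moments carry a 1/12
pixel-extent correction so thin regions keep finite axes. For an isolated
nucleus the nearest-neighbour distance is set to the image diagonal — a
documented sentinel rather than an infinity.

Only a handful of these features are canonical in the field; the registry as
a whole is this package's fixed contract: all 43 are computed for every
nucleus, in a stable order, and training files (`f01..f43`) must match it. A
column-mapping shim in `read_training_set()` adapts external tables whose
feature names differ. Shape and texture features are invariant to translation
and (orientation excepted) to 90° rotations, which the tests enforce.

## Classification and its three validations

A support-vector machine with RBF kernel (cost 1, kernel width 1/43) is
fitted on features standardised by training-set statistics; any supervised
classifier meeting the accuracy contracts could stand behind the same
interface. Per-cancer-type training sets reflect genuine cytomorphological
differences between AEGJ, GAC and ESCC.

Validation follows three routes: (1) stratified 10-fold cross-validation
within each training set (fold assignment seeded; pooled held-out accuracy);
(2) concordance of automated per-sample class proportions with manual counts
(Pearson by default, Spearman switchable); (3) a Jonckheere–Terpstra trend
test of quantified TIL% across ordered manual infiltration grades. The JT
statistic is the sum of pairwise Mann–Whitney counts; for pooled n ≤ 12 the
p-value comes from full enumeration of assignments, otherwise from a normal
approximation with tie-corrected variance and a 0.5 continuity correction —
with the correction the approximation stays within 0.02 of the exact tail on
untied samples of this size, without it the gap reaches 0.15.

## Synthetic data: what it does and does not emulate

`generate_slide()` renders the three nucleus morphologies the classifier must
separate — cancer nuclei with radius 8–16 px, low-order harmonic boundary
perturbation (≤ 8% of radius) and ±15% multiplicative intra-nuclear texture;
lymphocytes as uniform dark disks of radius 3–5 px; stromal nuclei as
ellipses with axis ratio 3–5 — over an eosin-pink background with additive
Gaussian noise (σ = 0.02) and 0.8 px blur. Placement is rejection sampling
with a 1000-retry cap (failure raises an error); a configurable fraction of
nuclei is deliberately placed touching a neighbour to exercise the watershed.
Colours and geometry are calibrated in pixels, matching a magnification at
which lymphocytes span a few pixels; no physical µm scale is asserted.

What it does **not** emulate: staining gradients and batch effects, nuclear
chromatin structure, overlapping translucent nuclei, tissue folds, necrosis,
mitoses, out-of-focus regions. Passing the end-to-end accuracy contracts on
these images demonstrates that the pipeline's geometry, thresholding,
splitting, features and classifier compose correctly — not that the
classifier would reach the same accuracy on real H&E sections, where the
per-cancer training sets and pathologist labels carry the burden.

`generate_cohort()` draws TIL% from a log-normal (meanlog = log 4.82,
sdlog = 1.314, right-truncated at 100), calibrated to a heavily right-skewed
cohort with median 4.82% and IQR 1.90–11.18; binary covariates are
Bernoulli(0.5); event times are exponential with rate
$\lambda_0 \exp(\beta_{\text{TIL}}\,\pi + \sum_j \beta_j x_j)$
(default baseline 0.25/year, β per TIL point log 0.965) with independent
exponential censoring (0.1/year, giving roughly two-thirds observed deaths).
The proportional-hazards structure is exact by construction, so Cox fits are
a parameter-recovery exercise: 50 replicates of n = 2000 recover a pooled HR
within [0.96, 0.97] with ~95% Wald CI coverage.

## Statistical conventions

- Kruskal–Wallis: tie-corrected H; exact permutation p for pooled n ≤ 12
  (the chi-square approximation is not reliable to 0.02 at such sizes),
  chi-square with g − 1 df otherwise.
- Wilcoxon rank-sum: exact when min(n) ≤ 8 without ties; tie-corrected
  normal approximation without continuity correction otherwise (so identical
  samples give p = 1 exactly).
- Chi-square: Pearson, no Yates correction (the published demographic tables
  are larger than 2 × 2).
- Bonferroni: min(1, m·p); the default family is the three pairwise
  cancer-type comparisons.
- Linear models: OLS on complete cases with stated reference levels;
  standardised coefficients Beta = B · SD(x)/SD(y); CIs as B ± 1.96·SE.
  Rank-deficient designs raise an error naming the offending terms.
- Survival: OS in years from diagnosis to death or last follow-up; KM median
  is the earliest time with S(t) ≤ 0.5 (NA if never reached); median TIL
  split sends ties to the low group; Cox uses Efron ties (year-resolution
  follow-up makes ties common) with Newton iterations to a 1e-9 gradient
  tolerance; Wald CIs.

## Problem sizes

The shipped validation runs use sizes chosen to finish in minutes on one
CPU while keeping Monte-Carlo error far from the acceptance margins: one
1000 × 1000 px slide with 200 nuclei for end-to-end accuracy, training sets
of 150 nuclei per class from 500 × 500 px slides, 100 random histograms for
the Otsu oracle, 1000 replicates for test calibrations, and 50 × 2000
patients for hazard-ratio recovery.

## Known limitations

- The exclusion flow and case-registry helpers reproduce selection
  arithmetic; they do not model image quality itself.
- The JT exact path enumerates up to 12 observations; larger samples use the
  corrected normal approximation.
- Fragment suppression at tile boundaries truncates boundary nuclei instead
  of stitching them; stitching would require cross-tile label merging that
  the tile-independent design deliberately avoids.
- The simulators' defaults are fixed study conditions, not fitting targets;
  they should be changed only to model a different study.
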