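# tilquant

Automated quantification of tumor-infiltrating lymphocytes (TILs) in
haematoxylin–eosin (H&E) stained tumor section images, with the downstream
cohort statistics and survival models used to evaluate the TIL proportion as
a prognostic biomarker in esophagogastric cancers (AEGJ, GAC, ESCC).

TILs are usually graded semi-quantitatively by pathologists, which is
subjective and costly. `tilquant` implements a fully automated alternative:

1. **Segmentation** — the RGB section is transformed to CIELAB, converted to a
   nucleus-signal grayscale (haematoxylin-dark nuclei score high), thresholded
   with Otsu's between-class-variance criterion, cleaned by morphological
   opening, and touching nuclei are split by a marker-controlled watershed
   seeded from h-maxima of the Euclidean distance transform. Whole sections
   are processed in 100 equal tiles and merged.
2. **Feature extraction** — each detected nucleus gets a fixed, versioned
   43-feature vector: 12 shape, 12 intensity, 13 grey-level co-occurrence
   texture, 3 neighbourhood and 3 boundary-gradient features.
3. **Classification** — a support-vector machine (RBF kernel) trained on a
   per-cancer-type labelled cellular training set assigns each nucleus to
   cancer cell, lymphocyte, or stromal cell.
4. **TIL proportion** — for a slide with class counts
   (n_cancer, n_lymph, n_stroma),

   π = 100 · n_lymph / (n_cancer + n_lymph + n_stroma)  [%].

5. **Cohort analysis** — Kruskal–Wallis / Wilcoxon / chi-square comparisons,
   Bonferroni correction, Spearman correlation, multivariable linear models
   with standardised coefficients, a Jonckheere–Terpstra trend test for
   agreement with ordered manual grades, median-split Kaplan–Meier curves with
   log-rank tests, and univariable/multivariable Cox proportional-hazards
   models with TIL% as a quantitative covariate (Efron ties;
   HR = exp(β) per TIL percentage point with Wald 95% CI).

Because real cohort images and patient data cannot be redistributed, the
package ships first-class simulators: `generate_slide()` renders H&E-like
sections with three nucleus morphologies (large textured cancer nuclei, small
round dark lymphocytes, elongated stromal nuclei) and exact ground truth, and
`generate_cohort()` draws survival data from an exponential
proportional-hazards model whose log-hazard is linear in TIL%. Every stage of
the pipeline is validated end-to-end against this ground truth.

## Worked example

```r
library(tilquant)

## train a cell classifier on a labelled synthetic training set
ts    <- generate_training_set(n_per_class = 150, seed = 5)
model <- train_classifier(ts, seed = 1)
cross_validate(ts, k = 10, seed = 1)
#> Cross-validation (AEGJ, 10-fold, n = 450)
#>   overall accuracy: 100.00%

## quantify a synthetic slide with known ground truth
sl  <- generate_slide(slide_spec(n_nuclei = 200,
                                 class_fractions = c(0.5, 0.2, 0.3),
                                 seed = 7))
res <- quantify_slide(sl$image, model, slide_id = "demo")
res
#> Slide 'demo': 202 cells (95 cancer, 39 lymphocyte, 68 stroma)
#>   TIL proportion: 19.31%
sl$truth$til_proportion   # 19.5 -- estimate within 0.2 percentage points

## survival: median split, log-rank, Cox HR per TIL percentage point
co  <- generate_cohort(cohort_spec(n_patients = 750, seed = 12))
grp <- median_split(co$til)
log_rank(grp$assignment, co$time, co$event)
#> Log-rank test
#>   X2 = 22.95, df = 1, p = 1.663e-06
cox_fit(co[, c("til", "sex_man")], co$time, co$event)
#> Cox proportional-hazards fit (efron ties): n = 750, events = 475
#>   til        HR 0.965 (95% CI 0.955-0.974), p = 3.27e-12
#>   sex_man    HR 1.177 (95% CI 0.982-1.413), p = 0.0786
```

The fitted hazard ratio of 0.965 per TIL percentage point recovers the
simulator's default truth: each additional point of lymphocyte infiltration
lowers the hazard of death by 3.5%.

## Package layout

- `R/synthetic-slide.R`, `R/synthetic-cohort.R` — simulators with ground truth
- `R/colorspace.R`, `R/segmentation.R`, `src/imageops.cpp` — nucleus detection
- `R/features.R` — the 43-feature registry and extraction
- `R/classification.R`, `R/jonckheere.R` — classifier training and validation
- `R/til.R`, `R/evaluate.R` — TIL proportion, median split, accuracy metrics
- `R/cohort-stats.R`, `R/survival.R` — cohort statistics and survival models
- `R/io.R`, `R/run-all.R` — file formats, exclusion flow, configuration,
  end-to-end driver
- `vignettes/til-quantification.Rmd` — methods and design notes
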