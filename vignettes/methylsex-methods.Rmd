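---
title: "Sex and karyotype classification from methylation beta values: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex and karyotype classification from methylation beta values: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylSex)
```

## The problem

Public methylation-array datasets (Illumina 450K and EPIC) frequently lack
sex annotations or carry mislabelled ones, and many uploads provide only
text tables of beta values or signal intensities — no raw IDATs. Most
sex-check tools need raw intensities; methylSex works from beta values
alone, so it applies to the text-only majority of public data. Beyond a
binary sex check it places each sample on two continuous axes — an
X-chromosome dosage axis and a Y-chromosome presence axis — which turns the
sex check into a four-way karyotype classifier that also detects the common
sex chromosome aneuploidies, 45,XO (Turner syndrome) and 47,XXY
(Klinefelter syndrome).

## Why methylation separates the karyotypes

In two-X cells, one X copy is silenced by X-chromosome inactivation and
hypermethylated. A ChrX probe therefore averages an active (low-methylation)
and an inactive (high-methylation) allele in females, giving mid-range betas
(roughly 0.2–0.8), while males' single active X yields betas below ~0.2. A
minority of ChrX probes sit in genes that escape inactivation (e.g. *Xist*)
and show the opposite, male-higher pattern. ChrY probes are hypermethylated
(beta > ~0.6) when a Y is present; without a Y the ChrY signal is background
and cross-hybridisation, centred near beta 0.35 (sd ~0.07) with raw
intensities around a tenth of male levels. X dosage and Y presence are thus
independently readable, and their four combinations map to 46,XX, 46,XY,
45,XO and 47,XXY.

## The pipeline

1. **Beta computation.** From methylated (M) and unmethylated (U)
   intensities, `beta = M / (M + U + 100)`. The +100 offset keeps betas
   strictly below 1 and stabilizes low-intensity probes. Missing M or U
   yields a missing beta; readers map textual sentinels ("NA", "null",
   blanks) to missing values, never to 0.
2. **Sample QC.** Samples with *more than* 10% missing probe values are
   excluded (strict inequality: exactly 10% is retained). An advisory
   density check (`flag_abnormal_density`) warns about samples whose beta
   density is not bimodal, but never drops them automatically — silent
   removal hides data problems and cannot be reproduced.
3. **Imputation.** Missing cells are replaced by the probe's mean across
   the samples of the dataset being processed — at prediction time as well
   as training time, so prediction never needs training data beyond the
   model file. Probes missing everywhere are dropped with a warning.
4. **Per-sample autosomal Z-scoring.** Every probe value of a sample is
   centered and scaled by the mean and standard deviation of that sample's
   *autosomal* betas. The statistic is sex-independent by construction, and
   per-sample, so a sample's Z-scores never depend on which other samples
   are in the batch — single-sample prediction is exact, not approximate.
   The standard deviation uses the population convention (divide by n);
   the choice is recorded in the model file because it changes Z-values at
   small probe counts.
5. **Probe selection (training).** A pooled-variance (Student's) two-sample
   t-test compares female and male *raw* betas per probe; selection requires
   Bonferroni-corrected p < 0.01 (m = probes actually tested) AND
   |mean(female) − mean(male)| > 0.2. Selection runs on raw betas while the
   PCA runs on Z-scores: the effect-size threshold is only interpretable on
   the beta scale, and this asymmetry is deliberate. Training draws a
   sex-balanced subset first (equal numbers per sex, seeded) so the test is
   not biased by unequal group sizes. Autosomal probes that pass are
   reported but excluded from the model — the classifier uses
   sex-chromosome probes only.
6. **Axis fitting.** Two separate principal component analyses: one on the
   Z-scores of selected ChrX probes, one on selected ChrY probes. Probes
   are mean-centered but not variance-scaled (covariance PCA): per-sample
   scaling already happened in the Z-score step, and per-probe scaling
   would double-standardize. The first component of each PCA carries
   essentially all between-sex variance (≥ 0.9, typically ~0.98 on X). Each
   axis is oriented so that on the training data females score higher on
   the X axis and males higher on the Y axis; the orientation sign is
   stored in the model.
7. **Prediction.** Scores are centered projections:
   `x_score = sign * sum(loadings * (z - center))`, a pure matrix
   multiplication against the stored coefficients. The quadrant of
   (x_score, y_score) gives the call: (+, −) 46,XX female; (−, +) 46,XY
   male; (−, −) 45,XO; (+, +) 47,XXY. Aneuploid calls get
   `predicted_sex = "aneuploid"` rather than a forced binary — coercion
   would corrupt downstream QC. A labelled sample is a mismatch only when
   a *binary* prediction contradicts its label.

## Numerical and boundary choices

- **Decision boundaries at 0.** No numeric cutoffs are inherited from
  anywhere: centering each axis on the training means puts the between-sex
  midline near the origin, so 0 is the natural boundary. Exact zeros
  (measure-zero in practice) break toward 45,XO, i.e. toward flagging
  rather than a confident binary call. Samples within 5% of the training
  separation of either axis are annotated `near_boundary` — potential
  low-level mosaics deserving inspection, not confident calls.
- **Missing model probes at prediction.** EPIC/450K exports routinely drop
  probes. The projection rescales the partial sum by
  (total probes / available probes) — a mean-equivalence contract — up to
  20% missing per axis; beyond that the error names the axis.
- **Degenerate inputs.** A sample with constant autosomal betas (sd 0)
  cannot be Z-scored and is a named error. A probe with identical values in
  both sexes gets t = 0, p = 1; zero pooled variance with different means
  gets p = 0. Model files are re-validated on read (unit-norm loadings to
  1e-10, disjoint X/Y probe sets, schema version), so hand-edited weights
  cannot silently corrupt predictions.
- **Full-precision serialization.** Model files print floats with 17
  significant digits, which round-trips IEEE doubles exactly; write → read
  reproduces the model bit for bit, and identical inputs produce
  byte-identical files.

## The synthetic cohort generator

`generate_cohort()` emulates the distributional geometry the classifier
relies on, with ground-truth karyotypes for recovery testing:

- Two-X states (46,XX; 47,XXY) draw ChrX probe means uniformly from the
  noise-adjusted interior of \[0.2, 0.8\] (so realized betas land in the
  stated interval); one-X states (46,XY; 45,XO) draw below 0.2. A fixed 7%
  of ChrX probes act as inactivation-escape probes with the opposite,
  male-higher pattern — this fraction follows the observed share of
  male-higher probes among sex-associated ChrX sites (~6.6%), not the
  larger gene-level escape figure in the literature.
- Y-present states draw ChrY means above 0.6; Y-absent states draw each
  ChrY beta from Normal(0.35, 0.07) truncated to \[0, 1\] — the background
  statistics observed on cross-reactive ChrY probes, adopted here for all
  Y-absent probes as a documented modeling choice.
- Autosomal betas are a two-component bimodal mixture (peaks near 0.1 and
  0.9) identical across karyotypes; only the per-sample autosomal mean and
  sd enter the method, so peak placement is what matters, not empirical
  450K densities.
- Per-cell Gaussian noise (sd 0.03) is added and values are clipped to
  \[0, 0.99\]; 0.99 is the beta ceiling T/(T+100) at array-scale total
  intensities (T ~ 10^4), which keeps every generated beta exactly
  invertible into plausible M/U intensity tables
  (`generate_intensity_tables`, which also scales Y-absent ChrY totals to
  ~11% of Y-present totals to mimic background signal).
- Default probe counts — 2000 autosomal, 400 ChrX, 60 ChrY — scale down a
  shared 450K/EPIC panel while preserving the roughly 14:1 X:Y ratio of
  sex-associated sites; cohort sizes in the test-suite runs (200 samples;
  one 857-sample mislabel scenario; 20 replicate seeds) are desk-scale
  choices that keep the full suite under a minute while exercising every
  contract.

**What passing tests do and do not show.** The generator reproduces
first-order beta regimes per chromosome class, not probe-level correlation
structure, batch effects, cell-composition shifts or cross-tissue
variation. Perfect recovery on synthetic cohorts demonstrates that the
pipeline's machinery is correct (selection, normalization, projection,
quadrant logic, serialization); it does not by itself establish accuracy on
real arrays, which depends on training with real cohorts at full probe
resolution.

## Known limitations

- Binary IDAT parsing is out of scope; inputs are text tables of
  intensities or betas. No background, dye-bias or between-array
  normalization is applied — the method deliberately uses none.
- Detection p-values are not used; probes below detection enter as ordinary
  values unless exported as missing.
- Mosaic fractions are not estimated; near-boundary annotation is the only
  mosaicism signal.
- The quadrant boundary at exactly 0 and the 5% near-boundary band are this
  package's documented conventions for an otherwise unspecified decision
  rule.

## A worked run

```{r example}
set.seed(1)
train <- generate_cohort(generator_config(
  n_samples = 200,
  karyotype_proportions = c(`46XX` = 0.5, `46XY` = 0.5,
                            `45XO` = 0, `47XXY` = 0),
  seed = 7))
model <- train_sex_model(train$beta, train$sheet, train$annotation, seed = 7)
model

cohort <- generate_cohort(generator_config(n_samples = 200, seed = 42))
preds <- estimate_sex(cohort$beta, cohort$annotation, model, cohort$sheet)
table(predicted = preds$karyotype, truth = cohort$truth$karyotype)
```
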