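---
title: "Class-selective fusion of two-view SVM classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Class-selective fusion of two-view SVM classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viewfuse)
```

## The problem

Histopathological screening for epithelial dysplasia in oral lesions is a
binary decision — presence (`P`) versus absence (`A`) of dysplasia — made on
H&E-stained image patches. Two features of the task shape this package.
First, clinical datasets are imbalanced: dysplastic and carcinoma lesions
outnumber non-dysplastic leukoplakia roughly 3:1 (about 76% presence), and
under that imbalance a single unweighted classifier drifts toward the
majority class. Second, the two classes are visible at different scales:
presence shows in fine-grained local morphology (irregular nuclei, abnormal
tissue architecture), while absence shows in diffuse, global tissue
organization. A feature representation tuned to one scale therefore tends
to produce a classifier specialized for one class — sensitive but
unspecific, or the reverse.

`viewfuse` operationalizes the resulting strategy: train one linear SVM per
feature *view* (a local, presence-sensitive view and a global,
absence-sensitive view) and merge their decisions with an explicit
class-selection rule set, rather than reweighting classes or stacking.

## The fusion rule

Let `CP` be the classifier on the presence-sensitive view and `CA` the one
on the absence-sensitive view. Each emits a label and complementary
calibrated scores `mu(P) + mu(A) = 1`. For a test sample:

| case | condition | fused label |
|------|-----------|-------------|
| a | `CP = P` and `CA = P` | `P` (consensus) |
| b | `CP = A` and `CA = A` | `A` (consensus) |
| c | `CP = P`, `CA = A`, `mu(A|CA) > mu(P|CP)` | `A` |
| d | `CP = P`, `CA = A`, `mu(A|CA) < mu(P|CP)` | `P` |

Rules (c) and (d) resolve conflicting evidence by comparing each
classifier's confidence in its own call. Two situations the four rules do
not determine are **policy parameters** rather than silent choices
([fusion_policy()]):

* **Score ties** in the conflict case default to `P` (`prefer_P`): in this
  clinical setting a false negative — a missed dysplastic lesion — is the
  costlier error. The same convention puts a calibrated score of exactly
  0.5 on the `P` side of the per-classifier threshold.
* **The reverse disagreement** `CP = A, CA = P` (each specialist voting
  *against* its specialty) is not covered by (a)–(d). The default
  `confidence_vote` extends the conflict rules' own principle symmetrically:
  the classifier with the larger own-class confidence wins. The alternative
  `prefer_specialist` lets `CP` decide `P`-membership outright (outcome
  `A`). In practice the case is rare: the decision log (`rule_fired`)
  reports how often each rule fired.
* **The fused ROC score** for a rule-based (discrete) fuser is likewise a
  construction choice; the default takes the winning classifier's
  presence score (`selected_classifier`), with `average` exposed for
  sensitivity analysis.

## Why calibrated scores

The conflict rules compare scores *across two different SVMs*, and raw SVM
margins are not on a common scale. Each classifier therefore carries a
Platt-style sigmoid `score_P = plogis(a + b * margin)` fitted on
*out-of-sample* margins from an internal seeded stratified 3-fold split of
its training data (fitting the sigmoid on resubstitution margins would
overstate confidence on separable folds). Platt's target smoothing keeps
the logistic fit finite when the internal folds are separable, and the
slope is clamped to a small positive floor (`1e-8`) so that the
margin-to-score map is strictly increasing even in signal-free fits. A
`score_mode = "margin"` switch replaces the fitted sigmoid with a fixed
unit-slope logistic squashing for sensitivity analysis.

Two further numerical choices in the per-view classifier: features are
z-scored per feature with the standardizer fitted on training rows only
(zero-variance features pass through with scale 1 rather than erroring),
and the SVM regularization constant defaults to `C = 1`, exposed in the
interface since no principled value is implied by the method itself.

## The synthetic generator

Real H&E patches and pretrained deep backbones are deliberately outside the
test loop: the generator ([generate_synthetic()]) reproduces the
*statistical structure* the pipeline assumes, so every downstream module is
testable in seconds without any download.

Each view draws class-conditional spherical Gaussians. The total
standardized separation `delta` is spread over the signal axes (a quarter
of each view's dimensions by default), so class separability is controlled
independently of dimension. A view *favors* a class by giving it a tighter
covariance: linear separation alone cannot yield a sensitivity/specificity
asymmetry at a symmetric threshold, but a sharply concentrated favored
class rarely spills across the boundary while the diffuse class does. The
tightening must be strong to matter, because an unweighted soft-margin SVM
under 3:1 imbalance shifts its boundary toward the minority class;
[asymmetry_preset()] uses `favored_sd_scale = exp(-strength)` (about 0.14
at the default `strength = 2`), which realizes both asymmetries —
view-1 classifier more sensitive, view-2 classifier more specific — with
margins comfortably above 0.02 at the default sizes, and collapses
continuously to the symmetric null as `strength` tends to 0. At
`delta = 0` the default configuration has no variance asymmetry at all, so
cross-validated balanced accuracy sits at chance; this matters because a
variance-asymmetric "null" would still be linearly exploitable (a
hyperplane threshold between equal-mean Gaussians of unequal variance
reaches balanced accuracy near 0.58).

Default sample sizes are 180 presence / 57 absence — the imbalanced setting
the package targets — with view dimensions 64 and 48, large enough to
exercise high-dimensional behavior while keeping a 20-replicate, 5-fold
study under ten seconds. What the generator does **not** emulate: feature
correlations within and between views beyond label-conditional
independence, heavy tails, staining artifacts, batch effects, or any image
content. Passing tests on synthetic data therefore validate the *pipeline
mechanics and the fusion mechanism*, not performance on real slides.

## Evaluation choices

Stratified k-fold assignment shuffles within class with a seeded RNG and
deals round-robin — the simplest scheme under which per-fold class counts
differ by at most one. With 180 `P` / 57 `A` and `k = 5` every fold has
exactly 36 `P` and 11–12 `A`. All per-fold fits (standardizer, SVM,
calibration) see training rows only; the test suite verifies that held-out
decisions are bit-identical to a from-scratch refit without the test rows.

AUC uses the Mann–Whitney rank statistic with half-credit for ties
(mid-ranks), documented because the fused score stream contains many
duplicated values. Metrics with a zero denominator (e.g. precision in a
fold with no positive predictions) are flagged and excluded from that
metric's cross-fold aggregate with a warning, never silently coerced to 0.
Aggregates use the sample standard deviation (n − 1), the usual convention
of comparative cross-validation tables. Balanced accuracy is computed as
`(SEN + SPE)/2` exactly, and specificity is always reported directly rather
than back-derived from balanced accuracy.

## A worked run

```{r run}
ds <- generate_synthetic(asymmetry_preset(3, 2, n_P = 180, n_A = 57, seed = 1))
summarize_manifest(ds$manifest)
report <- cross_validate(ds$manifest, ds$view1, ds$view2, k = 5, seed = 1)
report
table(report$decisions$rule_fired)
```

The view-1 classifier (`CP`) is near-perfectly sensitive but unspecific;
the view-2 classifier (`CA`) trades sensitivity for specificity; the fusion
keeps `CP`'s sensitivity while recovering most of `CA`'s specificity, so
its balanced accuracy is at least that of either specialist.

## Deep feature backends

The intended real-data views are a frozen CNN's global-average-pool layer
(local texture; 1536-dim) and a frozen vision transformer's pre-softmax
1000-unit head (global context). Both are *frozen extractors*: no
fine-tuning, no augmentation, no dropout at extraction time, so extraction
is deterministic. This package declares those backends
([backend_spec()]) but does not bundle weights or a deep-learning runtime;
calling them raises a configuration error distinct from data errors.
Precomputed feature matrices are accepted as delimited text
([read_feature_view()]), which is the expected route for real data. The
built-in `toy` backend (per-channel means/variances plus 4×4 luminance
block means) exists so the image path is exercised end to end.

## Known limitations

* The fusion rule is the class-selection rule set only; weighted averaging
  and stacking are out of scope by design.
* No cost-sensitive weighting or resampling: the fusion itself is the
  imbalance mechanism under study.
* Conclusions from the synthetic study transfer to real data only insofar
  as the two real views are in fact complementary specialists; the package
  measures, but cannot guarantee, that premise (compare the per-view
  sensitivity/specificity in any report).
* Binary labels only; the three raw categories exist solely to feed the
  merging rule, and merging carcinoma into "presence of dysplasia" is a
  labeling convention of the source data, not a pathological claim.
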