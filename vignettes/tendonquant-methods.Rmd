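---
title: "Quantifying tendon structure in B-mode ultrasound: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tendon structure in B-mode ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tendonquant)
```

## The problem

B-mode ultrasound is the workhorse modality for tendon assessment, but the
reading is subjective: an expert grades structural change on an ordinal 0-3
scale, and agreement between (or within) readers is imperfect. This package
implements a quantitative counterpart: a fixed 51-variable descriptor of
the image computed over five analyst-chosen regions of interest, and the
statistical machinery to measure whether those variables are reliable
across repeated readings and able to predict the expert's grade.

Two design commitments run through everything:

* **Determinism.** Every operation is a pure function of its inputs and
  configuration. The same image, ROI set and `tq_config()` give a
  bit-identical descriptor; all generators are pure functions of their seed.
* **No silent repair.** Invalid inputs are rejected; quantities that are
  mathematically undefined on an input (GLCM correlation of a constant
  region, convexity of an empty segmentation, width ratio with a pinched
  outline) come back as flagged `NA`, are excluded pairwise from
  reliability computations, and are never coerced to 0 or 1.

## The descriptor

### Texture (quality and the two edge ROIs, 13 variables each)

Pixels are first quantized to `Ng` gray levels by
`floor(v * Ng / 256)`. The default `Ng = 32` is a compromise: co-occurrence
matrices on the small ROIs typical of tendon work (a few thousand pixels)
are noisy at 256 levels and blind at 8; 32 keeps the matrix well populated
without erasing echotexture differences. It is configurable from 2 to 256.

The **gray-level co-occurrence matrix** counts ordered pixel pairs at
distance 1 along the four canonical orientations (0°, 45°, 90°, 135°),
symmetrizes each count matrix by adding its transpose, normalizes, and
averages the four. Averaging orientations makes the features balanced with
respect to rotation of the speckle pattern; distance 1 probes the finest
(speckle-cell) scale. From `p(i, j)` we take the six classical Haralick
statistics: contrast, sum average, sum-of-squares variance, difference
variance, correlation and the inverse difference moment
`Σ p(i,j) / (1 + (i−j)²)`. Correlation divides by the marginal standard
deviations and is therefore undefined on a constant region — flagged, not
zeroed.

The **gray-level difference statistics** histogram pools the absolute
differences `|v(x) − v(x+δ)|` over the four unit displacements
`(0,1), (1,1), (1,0), (1,−1)`. Pooling the *pair set* (rather than
computing features per displacement and averaging) was chosen because the
Table-of-variables contract has one value per feature and pooling is the
more sample-efficient estimator on small ROIs. Homogeneity, contrast,
angular second moment, entropy (natural log, zero bins skipped) and mean
follow.

The **Haar statistics** are the mean and population variance of the pooled
absolute detail coefficients of a one-level 2×2 block transform
(orthonormal scaling, divisor 2). Three choices deserve a note:

* only the three *detail* bands enter — approximation-band statistics would
  duplicate plain mean intensity, and the motivation for the wavelet is
  gradients and abrupt transitions;
* the transform runs on the **raw 8-bit region**, not the quantized one:
  gradient magnitudes do not need a reduced alphabet, and quantizing first
  would discard exactly the fine amplitude information this feature is
  meant to capture (GLCM/GLDS, by contrast, are definitionally alphabet
  statistics);
* odd trailing rows/columns are truncated, not padded — padding invents
  border gradients.

### Morphology (5 variables)

The tendon outline arrives as a simple polygon. It is cut at its leftmost
and rightmost vertices (ties broken toward smaller y) into an upper and a
lower border chain; vertical "cap" edges at the ends are shed, and each
chain must be x-monotone or the polygon is rejected. At 100 equally spaced
stations across the common x-range the vertical distance between linearly
interpolated borders gives the width profile; features are its max, min,
mean, population standard deviation (the parallelism measure — 0 means
perfectly parallel borders) and max/min ratio.

Width is measured **vertically** (along image columns), not perpendicular
to a fitted axis: the scanning protocol for longitudinal tendon views
aligns the probe with the tendon, so columns approximate the perpendicular,
and the vertical measure is deterministic and easy to validate against a
ray-casting oracle. The population (not sample) SD is used because the
stations are a deterministic grid, not a random sample. 100 stations keep
the discretization error of the summary statistics below 1% for smooth
borders (they converge as stations grow).

Convexity — polygon area over convex-hull area, both by the shoelace
formula — is computed and reported, but **outside** the canonical
51-variable vector: the morphology block of the variable table has exactly
five entries, and 13+13+13+5+7 = 51 only without it. It travels as an
auxiliary value.

### Bone (7 variables)

Bone reflects strongly, so the bone interface is segmented by intensity
thresholding, Otsu's method by default (parameter-free; a fixed threshold
is available and is what the phantom ground-truth tests use). One
numerical subtlety: with well-separated modes the between-class variance is
exactly flat across the empty histogram stretch between them, and "the"
argmax is the whole plateau. We return the plateau midpoint (the ImageJ
convention); returning the left edge would put the cut at the brightest
background value.

Components are 8-connected (speckle makes bone fragments
diagonal-contiguous; 4-connectivity over-counts), and components smaller
than `min_fragment_px = 5` are removed — without a floor, isolated speckle
pixels make the fragment count meaningless. Area is the foreground pixel
count; perimeter is the summed outer-contour arc length from Moore
neighbor tracing with diagonal steps weighted √2 (pixel-edge counting
overestimates smooth boundaries); convexity is area over the hull area of
the foreground pixels' corner points, so a filled rectangle scores exactly
1. An empty segmentation yields zero area and perimeter and a flagged
undefined convexity.

The three bone texture values are computed on the **raw ROI**, not the
binary mask (a mask has degenerate texture) and not the thresholded
sub-region (which would make texture depend on the segmentation). Bone
"homogeneity" is `Σ p/(1+|i−j|)` — deliberately a different formula from
the texture ROIs' inverse difference moment `Σ p/(1+(i−j)²)`, because the
variable table names them differently and both conventions exist in the
texture literature.

## The statistical pipeline

### Reliability

For the ordinal grades: Cohen's kappa with quadratic disagreement weights
`w_ij = ((i−j)/(k−1))²` ("squared-weighted"); undefined when both sessions
are constant. For quantitative variables: the three classical
single-measure ICCs from the two-way mean-squares decomposition. The
screening rule discards variables whose ICC falls below 0.75 (or is
undefined). The underlying reliability study did not state which ICC form
drives the rule, so the package defaults to **two-way absolute agreement**,
ICC(A,1) — same rater, same tool, repeated sessions: agreement, not mere
consistency, is the quantity of interest — and always reports all three
forms so the choice is auditable (`icc_form` switches it). Kendall's W uses
midranks and the standard tie correction. Missing (flagged) values are
removed pairwise, with `n_used` reported; a minimum of 3 complete pairs is
required.

### Prediction

Each retained variable enters, alone, a random-intercept logistic model
`logit P(Y_ij = 1 | x_ij, u_j) = β₀ + β₁ x_ij + u_j`, `u_j ~ N(0, σ²)`,
fitted by maximum marginal likelihood (`lme4::glmer`; Laplace by default,
adaptive Gauss–Hermite via `nagq`). Single-term fixed effects only: the
pilot-scale designs this targets cannot support more parameters. Both
reading sessions contribute observations `i` within subject `j`. Two
dichotomizations of the grade are analyzed: Y1 (any change, grade > 0) and
Y3 (severe change, grade = 3). A response observed in one class only is
reported as "model not created" — fitting it would be meaningless — while
the other response proceeds normally.

Cross-validation leaves out one *subject* (all their observations) at a
time; held-out subjects are predicted with the fixed effects alone,
`p = plogis(β₀ + β₁x)` — the random effect of an unseen subject is its
prior mean 0, and empirical-Bayes shrinkage of the held-out subject is
deliberately not offered because it would leak the held-out labels.
Covariates stay on their raw scale so β₁ is per unit of the feature. A
training fold that loses a response class falls back to the fold
prevalence; a fold whose optimizer fails (e.g. complete separation) falls
back to the fixed-effects-only logistic fit; both are flagged in the
result. The ROC is built on the pooled cross-validated probabilities, the
AUC is the midrank Mann–Whitney statistic, and the highest-AUC model per
ROI and response is selected with deterministic tie-breaks (larger Wald
ratio, then variable name).

### A known bias, kept visible

One acceptance property asserts that the cross-validated AUC under a null
covariate is 0.5 ± 0.05. That assertion is **left failing on purpose**.
Pooled-ROC leave-one-subject-out cross-validation is pessimistically
biased under a pure null: the coefficients refitted without subject j
anti-correlate with j's realized labels — remove a subject with many
positives and the training prevalence (hence the refitted intercept, and,
through accidental alignment, the slope) drops — so across folds the
pooled scores rank subjects *against* their outcomes. On this package's
generator the null AUC concentrates around 0.42 and can fall far lower; an
implementation-independent leave-one-subject-out `glm` oracle reproduces
the same distribution, so the bias is intrinsic to the specified procedure
(pooled CV probabilities into one ROC), not an implementation defect.
Practically this means small-sample pooled-CV AUCs near 0.5 should be read
as "no signal", and mildly below 0.5 as noise, not as anti-prediction. The
monotonicity property (AUC non-decreasing in the generating effect size)
and the leakage metamorphic test (altering held-out labels leaves held-out
predictions unchanged) both hold.

## The synthetic world

Because no clinical images are distributed, the package ships generators
whose defaults *are* the stated test conditions.

**Phantom images** (`generate_phantom()`): a 128×192 scene with a dim
background (mean gray 28), an echogenic tendon band across rows at 18-60%
of the image height (mean 115) carrying a sinusoidal fibrillar stripe
pattern (period 6 px, relative amplitude 0.35), and a bright bone band
(mean 235, thickness 8) under the tendon, split by `n_gaps` anechoic gaps
— the ground truth for the fragment count. Speckle is multiplicative with
a unit-mean Rayleigh envelope (the first-order model of fully developed
B-mode speckle, coefficient of variation ≈ 0.52). Inside the organized
tendon band the envelope is damped to `0.55 + 0.45·E` — healthy tendon
scatters partly *coherently* from aligned fibrils, which is what gives it
its regular, relatively smooth fibrillar appearance. Tendinopathic lesions
are disks that lose that coherent component (fully developed speckle
again) and are mildly hypoechoic (darkening 0.35 by default). This matters:
a lesion modeled as darkening alone would *increase* measured GLDS
homogeneity — darker regions compress into fewer gray levels — whereas real
echotexture disruption is rougher, not merely dimmer. With the coherence
model, adding lesions lowers homogeneity and raises contrast, as the
end-to-end tests require. What the phantom does **not** emulate: the
system point-spread function (speckle here is white, real speckle is
laterally correlated), attenuation and time-gain compensation, refraction
and shadowing, anisotropy of the fibrillar echoes, or probe pressure
effects. A green phantom test therefore establishes algorithmic
correctness on a controlled image model, not clinical performance.

**Statistical generators**: `generate_glmm_dataset()` draws from exactly
the random-intercept logistic model above (defaults: 200 subjects × 4
observations, β₀ = −1, β₁ = 1.5, σ = 1, x ~ N(0,1)), plus ordinal grades
from rank-based quantile cuts of the linear predictor at 40/70/90% — all
four grades get non-trivial mass, so the Y1/Y3 dichotomizations and the
degenerate-class guard are all exercised. `generate_rating_pairs()` makes
two-session ordinal data with uniform marginals where session 2 repeats
session 1 with probability `a` and is otherwise redrawn from the *other
three* grades; the expected quadratic-weighted kappa is then exactly
`1 − (4/3)(1 − a)`, so `a = 0.25` is exact independence and `a = 1` perfect
agreement. `generate_paired_measurements()` is the two-variance-component
normal model whose consistency ICC is `σ_b²/(σ_b² + σ_e²)`.

## Degenerate inputs, tie-breaks, tolerances

* GLCM/GLDS require at least one valid pixel pair; orientations with no
  pairs are dropped from the angle average (error if none remain).
* Matrix normalization is exact to 1e−9 and symmetry is exact (tested).
* Otsu on a single-gray-level region is flagged degenerate: zero
  fragments, `NA` threshold.
* The seed-fixed test oracles compare at 1e−10 to 1e−12; stochastic
  calibration tests use the bands their generating models justify.
* Model selection breaks AUC ties by the larger `|β₁|/se`, then variable
  name, so reports are reproducible across runs and platforms.

## Limitations

ROIs must be supplied (no automatic border detection or bone finding, by
design — the workflow quantifies the analyst's regions). DICOM is out of
scope; images arrive as 8-bit PNG. Reliability covers two sessions of one
rater (the test-retest design), not multi-rater panels, and no confidence
intervals are attached to the point coefficients the screening rule uses.
The prediction stage is deliberately restricted to single-covariate models
with random intercepts — no random slopes, no multivariable models, no
probability calibration. And the synthetic world, while sufficient to
verify every algorithm against independent oracles, is not a substitute
for clinical validation.
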