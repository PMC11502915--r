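---
title: "Methods: a desk-scale chest-radiograph CAD pipeline and its evaluation statistics"
author: "cxrcad authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a desk-scale chest-radiograph CAD pipeline and its evaluation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and intent

`cxrcad` re-implements, at desk scale, the complete architecture of a
computer-aided detection (CAD) system for chest radiographs together with
the statistical machinery used to evaluate such a device: standalone
performance (ROC/sensitivity/specificity with case-bootstrap confidence
intervals, localization IoU) and a multi-reader multi-case (MRMC)
crossover reader study (DBM jackknife pseudovalue analysis, DeLong tests,
miss-rate reduction, read-time analysis). Because clinical images and
trained production weights are proprietary, the package ships a
first-class synthetic phantom generator and a simulated expert labeler
panel, so that every stage — from pixel input to the final mixed-effects
F test — is runnable and testable end to end on any machine.

The package does **not** attempt to reproduce clinical performance
numbers that depend on proprietary data (e.g. a standalone overall AUC
near 0.98). What it reproduces is the *method*: identical interfaces,
identical statistics, identical decision rules, validated against
independent oracles and on synthetic data whose ground truth is known
exactly.

# The model

## Case-level problem

An input *case* consists of 1 or 2 grayscale radiographs. The device
emits, for each of 8 clinical categories (Cardiac, Mediastinum/Hila,
Lungs, Pleura, Bones, Soft Tissues, Hardware, Other), (1) a binary
abnormality-present determination and (2) a set of bounding boxes around
suspicious regions.

## Label model: beta-binomial k-of-n likelihood

Training labels come from panels of experts: for a case and category,
$k$ of $n$ independent readers called the category abnormal ($n$ varies
per case). The classification head therefore outputs, per category, the
parameters $(\alpha, \beta)$ of a beta-binomial distribution

$$P(k \mid n, \alpha, \beta) = \binom{n}{k}
\frac{B(k+\alpha,\, n-k+\beta)}{B(\alpha, \beta)},$$

i.e. a Binomial whose success probability is Beta$(\alpha,\beta)$
distributed. This models the observed spread of annotator agreement
instead of forcing a single binary target. The training loss term is the
negative log-likelihood, computed in log-gamma space
(`betaBinomialNLL()`), and at inference time the posterior mean
$\alpha/(\alpha+\beta)$ is the continuous score
(`pointEstimate()`). Positivity of $(\alpha,\beta)$ is enforced by
`softplus(x) + 1e-4`; softplus avoids the overflow pathologies of an
exponential link and the small floor keeps the Beta away from its
degenerate corners.

## Network architecture

Each radiograph passes through a convolutional encoder (3×3
convolutions + ReLU with 2× max-pooling between stages). The final
stage's spatial maps are the *penultimate feature maps*; they feed a 1×1
convolutional localization head with a sigmoid, one probability map per
category per image. A global spatial pooling of the same maps gives the
per-image feature vector; a shared fully connected projection lifts it to
the case feature dimension, and the 1–2 projected vectors are collapsed
by elementwise maximum into one case embedding — a multiple-instance
pooling that is order-invariant and coordinate-wise monotone in the
evidence of either image. A final fully connected layer maps the case
embedding to the 8 × 2 beta-binomial parameters.

Two profiles are configured. The `"test"` profile (default) is a
4-stage encoder on 64 × 80 inputs (8-16-32-32 channels, 32-dim image
features, 64-dim case embedding, 8 × 10 localization maps) that trains on
one CPU in minutes. The `"deployed"` profile mirrors the production geometry
(800 × 1024 inputs, 512-dim image features, 1024-dim case embedding); its
encoder is a plain convolutional chain reproducing the deployed
interface, not the residual wiring of a production backbone. The global
pooling is elementwise **max** by default: with small high-contrast
abnormalities, average pooling dilutes a localized signal over the whole
map, which measurably slows learning at this scale; max pooling keeps it.
`global_pool = "avg"` restores mean pooling.

The localization-map resolution and its upsampling to pixel space are
not dictated by the underlying design; the head operates at the
penultimate stride (8 for the test profile) and `upsampleMap()` lifts
maps with bilinear (default) or nearest-neighbour interpolation.

## Training

`trainModel()` minimizes, per case,

$$\mathcal{L} = \sum_{c=1}^{8} \left[ w^{loc}_c\,
\mathrm{BCE}_c + w^{cls}_c\, \mathrm{NLL}_c \right]$$

where BCE is the across-radiograph average per-pixel binary
cross-entropy between predicted and ground-truth maps (boxes rasterized
at map resolution; a cell is positive when ≥ 25% covered), and NLL is the
beta-binomial term. Both weights default to 1 per category — the
weighting is exposed in configuration because no canonical values exist —
and the BCE clipping epsilon is 1e-7. Optimization is AdamW
(decoupled weight decay; defaults lr 5e-3, wd 1e-4) on randomized
batches of cases (default 64 per batch; the epoch remainder is kept).
Augmentation (random rotation ±10°, horizontal/vertical flips, gamma,
contrast, ≥ 90%-area crops) applies geometric transforms identically to
the truth masks and intensity transforms to the image only.

After each epoch the across-category mean AUC of posterior-mean scores
on a tuning set is computed (categories with a single class are excluded
with a warning); training stops when no improvement has occurred within
the patience window (default 10 epochs) and the best-epoch weights are
returned, so the reported checkpoint never has a tuning AUC below the
best seen. All gradients are exact (hand-derived backward passes through
the conv/pool/max-instance/softplus/likelihood chain) and are verified
against finite differences in the test suite. A single configuration
seed fans out deterministically to weight initialization, shuffling and
augmentation, so identical configurations reproduce identical histories
on CPU.

## Post-processing and operating points

Decision thresholds are calibrated per category on a tuning set to
*equalize sensitivity and specificity*: candidate thresholds are the
midpoints of adjacent sorted unique scores (plus sentinels), the
candidate minimizing $|\mathrm{sens} - \mathrm{spec}|$ is chosen, ties
broken toward higher sensitivity, and the result is frozen
(`calibrateThresholds()`, serialized with a calibration fingerprint). A
score **on or above** the threshold yields "present" — the boundary is
inclusive. Box extraction binarizes the upsampled probability map at a
per-category map threshold, labels 4-connected components
(EBImage), drops components below 0.05% of the image area (speckle
suppression; configurable) and returns each surviving component's tight
bounding box with the maximum map probability as its score. Map
thresholds are calibrated by maximizing mean tuning-set IoU over a grid —
the calibration procedure is a package choice, recorded in the operating
points' fingerprint. No component merging or box-count limiting is
performed. A "present" determination with an empty box list is allowed
but warned about.

# The synthetic data generator

The generator is the package's study population, not a test fixture,
and its defaults are fixed study conditions:

* **Phantoms.** Background = smoothed Gaussian random field (amplitude
  0.04) over a coarse thorax-like intensity gradient (bright
  mediastinal column, mild cranio-caudal fade) on 100 × 125 grids.
  Abnormalities are high-contrast parametric shapes, one characteristic
  family per category — bright/dark elliptical blobs (Cardiac/Lungs),
  bright/dark annuli (Mediastinum/Hila, Hardware), bright diagonal and
  dark horizontal bands (Pleura, Bones), fine/coarse checkered patches
  (Soft Tissues, Other) — with contrast magnitudes 0.45–0.50 and texture
  periods chosen to survive the downscale to the 64 × 80 test-profile
  input. The design goal is learnability at desk scale with a small CNN,
  not radiographic realism.
* **Prevalences** default to the per-category reference-positive rates
  of a large multi-site testing population (Cardiac 0.316 … Other
  0.083); the probability of a 2-image case is 0.45, matching an average
  of ~1.45 radiographs per case. Patient sex and age-group frequencies
  follow the same population.
* **Labeler panel.** Each of $n$ simulated experts (default 3) calls a
  truly positive category with probability `sensitivity` (default 0.90)
  and a truly negative one with probability `1 - specificity` (default
  0.97); these rates were chosen once as realistic for a trained expert
  panel. Positive labelers on true positives emit the truth box jittered
  by up to 10% shift/scale, exercising IoU < 1 paths. The reference
  standard is the strict majority ($k > n/2$): at least two of three for
  $n = 3$; ties on even panels are negative (the conservative reading,
  since only $n = 3$ has a canonical rule).
* **Reader studies.** `generateReaderStudy()` simulates the crossover
  design (per reader, a stratified random half of cases aided in session
  1, the complement in session 2). Confidence scores follow a binormal
  latent model: separation $\delta_{cond} = \sqrt{2}\,\Phi^{-1}(AUC_{cond})$
  plus a reader skill effect (sd 0.15) and a case difficulty effect (sd
  0.5) shared across readers and conditions — inducing the reader and
  case random-effect structure MRMC methods assume — then mapped
  monotonically to the 0–100 scale. Default AUC targets are 0.773
  unaided and 0.874 aided; setting them equal gives an exact null
  design. Read times are log-normal with condition-specific medians
  (radiologists 69.5/67.5 s unaided/aided, non-radiologists 107/98.5 s)
  and reader effects.

What the generator does **not** emulate: anatomical structure,
scanner/site heterogeneity, label correlations between categories,
reading-order effects, or the long tail of rare abnormalities. Passing
tests therefore demonstrate the correctness of the pipeline and the
statistical machinery under a controlled data-generating process — they
do not certify performance on real radiographs.

# Evaluation statistics

* `rocAuc()` is the tie-aware normalized Mann–Whitney statistic
  (trapezoidal AUC); "overall" metrics pool all (case, category) pairs
  (micro-averaging), and overall sensitivity/specificity apply the
  per-category frozen thresholds before pooling the determinations (the
  pooling convention is stated, since either convention is defensible).
* `bootstrapCI()` resamples whole cases (the 8 category observations of
  a case move together, preserving within-case correlation), with the
  percentile interval over m = 1000 replicates by default; degenerate
  one-class replicates are skipped with a 20% cap.
* `summedIoU()` reports the set-semantics IoU (pixel regions covered by
  the union of each side's boxes) as the headline number — summing raw
  box areas would double-count overlapping boxes within one side — and
  exposes the raw summed-area variant for transparency. Only true
  positives are aggregated.
* `subsetSensitivity()` computes stratified sensitivity/AUC with case
  bootstrap and suppresses strata with 20 cases or fewer (strata must be
  observed on *over* 20 cases to be analyzed).

# MRMC statistics

`dbmAnalysis()` computes each reader's micro-averaged AUC per condition,
case-jackknife pseudovalues $Y_c = n\,\widehat{AUC} - (n-1)\,
\widehat{AUC}_{(-c)}$ (an $O(n \log n)$ placement-count implementation,
verified against naive recomputation), and the three-factor pseudovalue
ANOVA with condition fixed and readers and cases random. The treatment
F statistic uses the Hillis denominator $MS_{TR} + \max(MS_{TC} -
MS_{TRC}, 0)$ with its matching denominator degrees of freedom — the
standard modern choice, since the original formulation's denominator can
go negative — and `df = "dbm"` restores the original with Satterthwaite
df. The 95% CI of the LS-mean difference uses $\pm t_{ddf}\sqrt{2\,
MS_{den}/(rc)}$. Jackknife replicates that lose a class compute the
pseudovalue on the reduced set with a warning.

`delongTest()` implements the placement-value covariance estimate for
paired AUCs and reports an unadjusted two-sided p; multiplicity
correction (e.g. Bonferroni at 0.05/2 when both conditions are tested)
belongs to the caller, keeping the primitive pure. `readTimeTest()`
averages log read times per reader before the paired t-test — pairing at
the reader level matches df = readers − 1 (17 for 18 non-radiologists, 5
for 6 radiologists); the reported $t$ relates to an F-style presentation
by $t^2 = F(1, df)$. `missRateReduction()` is
$100\,[(1-s_u) - (1-s_a)]/(1-s_u)$.

# Problem sizes, seeds and numerical choices

The package's own validation runs use these sizes, chosen as the
smallest scales at which each property is meaningfully exercised:

* End-to-end learnability: 500 training / 150 tuning phantom cases,
  category-balanced prevalence 0.25 (mirroring the enrichment used in
  clinical test sets to guarantee positives per category), test-profile
  model, ≤ 30 epochs, patience 10, batch 16, lr 5e-3, augmentation off
  for this check (augmentation correctness is tested separately; the
  check targets the architecture/optimizer, and an unaugmented run
  isolates that). Expected outcome: across-category mean tuning AUC
  above 0.9.
* Likelihood oracle: ≥ 200-point $(\alpha,\beta,n,k)$ grid against
  numerical integration at 1e-8.
* Type-I error: 500 null reader studies (6 readers × 80 cases — the
  smallest design at which the three-way ANOVA is well conditioned);
  the empirical rejection rate of DBM and DeLong at $\alpha=0.05$ should
  sit inside the binomial 95% band around 0.05. Power: 200 replicates of
  the full 24-reader × 238-case design with a planted ΔAUC = 0.10,
  expected detection in well over 90%.
* All randomness flows from a single seed through a documented
  linear-congruential splitting scheme (`childSeed`), keeping every
  derived seed a valid 32-bit integer.

Numerical conventions: boxes and crops are 0-based half-open
$[r_0,r_1)\times[c_0,c_1)$ everywhere; padding is symmetric with the
extra pixel on the right/bottom; image resampling uses explicit
triangle-filter weight matrices (anti-aliased on downscale, plain
bilinear on upscale) so a constant image is reproduced exactly and
standardization is idempotent at target size; the minimum-resolution
gate ("over 1440 pixels") is interpreted as image *height* — the
resize reference axis — and is configurable.

# Known limitations

* The deployed-profile encoder reproduces the production interface (input
  geometry, feature dimensions) but not a residual backbone; training at
  that scale is out of scope.
* The phantom generator's shape families make the 8 categories almost
  perfectly separable given enough data; it cannot probe the
  hard-abnormality regime.
* The beta-binomial head is fit per category independently; no
  between-category correlation is modeled.
* The DBM implementation covers the balanced two-condition crossover
  design used here; arbitrary missingness or unbalanced designs are not
  supported.
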