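---
title: "From limb-worn IMU signals to a motor maturity score: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From limb-worn IMU signals to a motor maturity score: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`infantmotor` implements a complete analysis stack for infant movement
recordings made with a four-sensor limb-worn inertial wearable (tri-axial
accelerometer in m/s², tri-axial gyroscope in deg/s, nominal 52 Hz per
sensor). The stack covers:

1. a **synthetic-data generator** producing ground-truth state sequences,
   realistic 24-channel signals, multi-rater annotations and age cohorts;
2. **preprocessing** from raw packets to 2.3-s analysis frames;
3. **multi-rater annotation handling** — compounded confusion matrices,
   Fleiss' kappa, per-class metrics, and iterative annotation refinement
   (IAR);
4. a **dual-track convolutional sequence classifier** (posture, movement)
   and a binary **active-carrying detector** (ACD);
5. **contrastive predictive coding** (CPC/InfoNCE) pretraining for
   label-free verification of latent signal structure;
6. the **BIMS score** — an age-normative Gaussian-likelihood maturity
   index — with LOSO evaluation and recording-length robustness;
7. the **evaluation statistics layer** (Bland–Altman, monthly-change
   slopes, correlation tests, a ten-test battery for comparing dependent
   overlapping correlations, quadratic trajectories, transition rates).

Because clinical recordings of infants are restricted data, the generator
is a first-class, tested component: every downstream stage is validated
against simulator ground truth.

# The synthetic-data generator

## State sequences

Per-second labels are generated on three parallel tracks:

* **posture** — supine, prone, side (left/right), crawl posture, sitting,
  standing;
* **movement** — a graded quality within the posture: still, proto
  (general activity), elementary (developing pattern), fluent (mature
  pattern), plus pivot, roll and transition intermediates;
* **carrying** — independent, passive/active support, passive/active
  carry.

Age-dependent occupancy follows logistic and bell trajectories chosen to
reproduce the canonical developmental shapes: prone and supine decline,
standing and fluent movement rise steeply after the first year, and crawl
posture is bell-shaped around 10 months. The curves are relative weights
normalized to a prior at the recording's age (`age_priors()`).

The sequence generator is semi-Markov with a twist: rather than drawing
segment states i.i.d., each posture class receives a **time budget** equal
to its prior share of the recording, the budget is cut into dwell segments
with negative-binomial lengths (mean 12 s, size 10 — roughly 5 posture
transitions/min, matching the high transition rates typical of freely
playing infants), and segment order is shuffled. Occupancy therefore
converges to the prior by construction while transition-rate statistics
remain meaningful. Movement is drawn semi-Markov (mean dwell 4 s) within
each posture segment from the age prior restricted to the posture's
permitted movements — the generator never emits, e.g., fluent walking
while supine. Carrying is an independent layer (mean dwell 25 s).

## Signals

Each posture maps to a fixed per-sensor gravity orientation
(`posture_orientations()`); the convention is arbitrary but documented,
and what matters is that the 4-sensor pattern differs between postures so
that posture is physically recoverable from static acceleration — the same
property the garment's real sensor placement provides. Movement classes
map to overlapping oscillation-amplitude tiers (still < proto <
elementary < fluent) with class-specific frequency bands; the overlap is
deliberate, reproducing the empirically easier posture / harder movement
classification structure. Gyroscope channels carry a per-sensor constant
bias drawn uniformly from ±3 deg/s plus the oscillation; active carrying
adds a common-mode low-frequency component across all sensors (adult
locomotion). Packets get Gaussian timestamp jitter (SD 2 ms) and random
drops (p = 0.01). With all noise zeroed and still movement, the
accelerometer reads exactly gravity and the gyroscope exactly its bias —
an identity the tests exploit.

## Raters and cohorts

Simulated annotators implement the two dominant disagreement modes of
video annotation: Gaussian jitter of segment boundaries (SD 0.3 s) and
per-second label confusion. The default confusion levels (posture accuracy
0.985, movement 0.85, carrying 0.97) were set so that three simulated
raters reproduce the published agreement regime for this kind of
annotation — Fleiss' kappa ≈ 0.95 for posture and ≈ 0.6 for movement.

`generate_age_cohort()` draws recording-level feature vectors directly:
each simplex block (posture; conditional movement per posture) is
Dirichlet-distributed around the age-dependent mean trajectory with total
concentration 100 by default — enough scatter that recordings of the same
age differ visibly, while the age signal (several percentage points per
month for the fast-moving categories) dominates.

What the generator does **not** emulate: biomechanically realistic limb
kinematics, sensor saturation and drift, behavioral idiosyncrasies
(bottom-shuffling, atypical repertoires), or clinical conditions. Passing
tests therefore demonstrate that the pipeline's machinery is correct and
learnable, not that real-world classification accuracy will match.

# Preprocessing

The pipeline (`preprocess_recording()`) is: linear interpolation of
packets onto the ideal 52 Hz base, gyroscope bias removal, a seven-tap
running median filter, and framing into 120-sample (2.3 s) frames with 50%
overlap (hop 60). Choices made where the procedure was open:

* **Common time base** — origin at the latest sensor start, end at the
  earliest sensor end, so all 24 channels are defined everywhere; no
  extrapolation beyond a sensor's packet span.
* **Gyroscope bias estimate** — per-channel median over the lowest-motion
  decile of 1-s windows (motion ranked by summed gyroscope variance).
  Stillness-based medians are robust to movement content and recover the
  simulator's true bias to well under 0.1 deg/s at default noise.
* **Median filter edges** — reflect padding: length-preserving, no phase
  shift, constants unchanged. The filter runs after interpolation.
* **Frame convention** — half-open sample intervals, 0-based starts;
  frame centre times join frames to per-second annotations.

# Annotations, agreement and IAR

Frame labels are assigned per rater by plurality time share within the
frame interval, ties broken by a fixed per-track priority order (main
categories before intermediates) so the mapping is deterministic. Frames
with more than half their interval outside the annotation span are
excluded. Rater labels compound into per-frame distributions, majority
hard labels and ambiguity flags.

Two chance-corrected agreement forms are provided and named distinctly:
standard **multi-rater Fleiss' kappa** on item × category counts
(`fleiss_kappa_counts()`), and the **two-rater specialization** computed
from a (compounded) confusion matrix, used for pairwise and
human-vs-algorithm comparisons. Class-specific kappas collapse the matrix
one-vs-rest. Metrics of empty classes are reported as undefined (`NA`),
never zero.

IAR (`iar_refine()`) keeps consensus frames one-hot and re-targets
contested frames as `(1 − α) · rater distribution + α · classifier
posterior`, renormalized, iterating train → refine until fewer than 1% of
frames change or 3 iterations. α = 0.5 weights human raters and the
(internally consistent) classifier equally; the form captures the
procedure's intent with the stopping rule made explicit.

# The classifier

The architecture contract is: 120 × 24 input, a 160-dimensional frame
latent, and per-track softmax output. Within that contract the stack is:
three strided 1-D convolutions (widths 7/5/3, strides 3/2/2, channels
32/48/64, leaky-ReLU), global average pooling, and a dense projection to
the latent; then four same-padded temporal convolutions over the frame
sequence (width 3, dilations 1/2/4/8, 64 channels) and a linear softmax
head. Posture, movement and carrying are separate models sharing the
architecture. All layers, the ADAM optimizer (lr 1e-4, β₁ 0.9, β₂ 0.999,
ε 1e-8) and the weighted cross-entropy loss are implemented in base R
matrix algebra; gradients are verified against numerical differentiation
in the test suite.

Training uses batches of 100 consecutive frames, inverse-frequency class
weights normalized to mean 1, **sample dropout** (each time sample zeroed
across all channels with p = 0.3) and **sensor dropout** (one sensor's six
channels zeroed with p = 0.3 per batch element), an 80/20 frame-level
train/validation split, and selection of the epoch with the best
validation unweighted-average F1. A frame-level split within a temporal
model admits mild leakage between neighbouring frames; the recording-level
cross-validation (`crossvalidate_tenfold()`, subjects never split across
folds) is the honest generalization measure and is asserted in tests.

The default profile (200 epochs, lr 1e-4) suits full-size corpora. The
test suite uses a scaled-down profile — cohorts of ten 10-minute
recordings, ≤ 30 epochs, lr 1e-3 — because at a few thousand ADAM steps a
larger step size is needed to converge; on the generator's separable
posture signatures this reaches held-out kappa above 0.9 in minutes on one
CPU.

The ACD collapses the five carrying classes to binary active-carry vs
rest, trains the same architecture, and is evaluated leave-one-subject-out;
`acd_filter()` masks active-carry frames from all distribution analyses.

# CPC

The CPC encoder is architecturally identical to the supervised encoder
with a 128-dimensional latent; a GRU (hidden size 128) summarizes the
latent history into a context; a linear head predicts the latent 5 frames
(≈ 5.8 s) ahead; and the InfoNCE loss scores the true future against 10
negatives under a dot-product similarity (temperature 1). Negatives are
drawn uniformly per time step from the same recording, excluding the
positive, and resampled each epoch. A single prediction head at exactly
k = 5 is used rather than heads at all distances 1…k. Projection weights
initialize near zero so an untrained model scores at the analytic chance
baseline `ln(1 + 10) ≈ 2.398`. The GRU's backward pass is, like the rest,
hand-implemented and numerically gradient-checked. CPC uses ADAM at
lr 1e-3 (no learning rate is canonical for this component; 1e-3 is the
customary ADAM default and converges in a handful of epochs on simulator
data).

# BIMS

Recording-level features are the fused posture distribution (left/right
side merged; 6 values) and, for each fused posture, the conditional fused
movement distribution (pivot/roll merged; 7 values each) over
ACD-retained frames — 48 features. Conditional blocks of postures never
observed are flagged unsupported and **masked out of the likelihood**
rather than penalized: a never-standing 5-month-old should not be scored
on standing-conditional movement.

The normative model fits diagonal Gaussians at 1-month bin centres from 4
to 16 inclusive (13 bins; the lower bound is included for symmetry with
the upper). Bins use recordings within ±1 month; bins short of 3 members
absorb the nearest-age recordings (ties toward the younger); ages above 16
pool into the 16 bin; per-feature SDs are floored at 1e-4. Prediction
computes per-bin log-likelihoods **including the normalization constant**
(so bins with tighter variances are properly favoured; the
constant-free alternative would change weights whenever σ varies across
bins), stabilizes by max-log subtraction, normalizes to weights, and
averages the bin centres. The score rescales linearly:
`BIMS = (predicted_age − 4) × 100 / 12`, anchored at 0 (4 months) and 100
(16 months and beyond). Because the prediction is a convex combination of
bin centres, BIMS is bounded in [0, 100] for any input.

Evaluation is leave-one-subject-out (all of a subject's recordings held
out together). Length robustness draws random-start subsegments (10–100
min) from ≥ 120-min recordings, recomputes distributions per segment and
summarizes the absolute age error per length; the error stabilizes once
segments exceed about an hour. The AIMS predictor reuses the same
machinery with bins over the clinical AIMS score.

# Evaluation statistics

* **Bland–Altman**: error = predicted − annotated, one-sample two-tailed
  t-test with df = n − 1, ±2 SD band, optional monthly-change overlay.
  (A fixed df of n − 2 appears in some published uses of this analysis;
  the one-sample test's df = n − 1 is used here.)
* **Monthly change Δ**: OLS slope of fraction vs age, reported in
  percentage points per month; meaningful only for monotone categories.
* **Correlations**: Pearson (t transform) and Spearman; Spearman p-values
  use the exact small-sample null distribution without ties (delegated to
  `stats::cor.test`, which enumerates it exactly in that regime) and the
  t approximation otherwise.
* **cocor battery**: all ten classical tests for comparing two dependent
  overlapping correlations (Pearson–Filon, Hotelling, Williams, Olkin,
  Dunn–Clark, Hendrickson–Stanley–Hills, Steiger, Meng–Rosenthal–Rubin,
  Hittner–May–Silver, and Zou's interval), each implemented from its
  primary published formula. Correctness is established by construction
  plus simulation: under a trivariate-normal null at n = 100 (asymptotic
  tests need a moderate n) each test's type-I error over 2000 replicates
  falls within ±0.02 of the nominal α = 0.05, and Zou's interval agrees
  with Dunn–Clark's decision.
* **Transition rates**: label changes between consecutive *retained*
  frames per analyzed minute; a masked gap never counts as a transition.

# Numerical choices and degenerate inputs

Softmax and InfoNCE computations subtract row maxima before
exponentiation; likelihoods live in log space. Ties in plurality labelling
and majority voting resolve by fixed priority orders; equidistant bin-fill
candidates resolve toward the younger recording. Degenerate inputs fail
loudly: empty retained frame sets, single-class training targets,
all-single-category agreement tables, zero-variance correlations and
non-PSD correlation triples all raise errors rather than returning
defaults.

# Problem sizes in the test suite

The suite runs entirely on one CPU: classifier learnability uses ten
10-minute recordings (≈ 5200 frames) and 20 epochs; CPC uses three
4-minute recordings and 8 epochs; BIMS recovery uses a 60-recording
cohort and six 125-minute label sequences at 100 robustness iterations;
statistical calibration uses 2000 null replicates. These sizes were chosen
as the smallest at which each property is comfortably demonstrated.

# Known limitations

The generator's orientation table and amplitude tiers are conventions, not
biomechanics; classifier accuracies on simulated data bound nothing about
clinical data. The frame-level validation split can leak temporal context
(see above). The Fleiss/Cohen two-rater forms differ slightly in their
chance term on unbalanced data; both are exposed. BIMS inherits the
ceiling of the description scheme: ages beyond 16 months are
indistinguishable by design, and the score is only as good as the
classifier distributions feeding it.
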