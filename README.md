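# infantmotor

Analytics for infant motor development measured with a multi-sensor
wearable. Infants wearing a jumpsuit with four limb-mounted inertial
sensors (tri-axial accelerometer + gyroscope, 52 Hz) are recorded during
spontaneous play; the package turns those raw packet streams into
second-by-second posture and movement classifications and, from a
recording's aggregated category distributions, an age-normative **motor
maturity score (BIMS)** on a 0–100 scale. It is aimed at researchers in
infant neurodevelopment and wearable human-activity recognition who need
the full pipeline — or any stage of it — reproducible and testable without
access to restricted clinical recordings.

## What's inside

* **Synthetic data** — a semi-Markov generator for posture / movement /
  carrying state sequences with age-dependent occupancy trajectories,
  posture-dependent gravity signatures, movement-dependent oscillation
  dynamics, multi-rater annotation noise, and Dirichlet age cohorts.
* **Preprocessing** — packet-to-frame pipeline: linear interpolation onto
  the ideal 52 Hz base, gyroscope bias removal, seven-tap median filter,
  2.3-s (120-sample) frames with 50% overlap.
* **Agreement** — compounded confusion matrices, multi-rater Fleiss'
  kappa and its two-rater form, per-class recall/precision/F1/kappa, and
  iterative annotation refinement (IAR) of contested frame labels.
* **Classifier** — a dual-module convolutional network (frame encoder to
  a 160-d latent; dilated temporal convolutions to per-track softmax),
  trained with ADAM, inverse-frequency class weights, sample/sensor
  dropout, and validation-F1 epoch selection; recording-level ten-fold
  cross-validation and a binary active-carrying detector (LOSO).
* **Self-supervision** — contrastive predictive coding with a GRU context
  model and InfoNCE loss (`k = 5` frames ≈ 5.8 s look-ahead, 10
  negatives) for label-free latent-structure checks.
* **BIMS** — age-binned diagonal-Gaussian normative models of the motor
  ability distributions; likelihood-weighted age prediction rescaled as
  `BIMS = (predicted_age − 4) × 100 / (16 − 4)`; LOSO evaluation,
  recording-length robustness, and an AIMS-score analogue.
* **Statistics** — Bland–Altman with zero-bias t-test, monthly-change
  slopes, Pearson/Spearman, quadratic trajectories, transition rates, and
  the ten-test battery for comparing dependent overlapping correlations.

The neural networks (convolutions, GRU, ADAM, backprop) are implemented
in base R matrix algebra and verified against numerical gradients in the
test suite.

## Worked example

```r
library(infantmotor)

cfg  <- sim_config(age_months = 10, duration_s = 600, seed = 42)
seq1 <- simulate_state_sequence(cfg)          # per-second ground truth
rec  <- synthesize_imu(seq1, cfg)             # 4 x 6-channel packet streams
frames <- preprocess_recording(rec)           # 518 x 120 x 24 frame array

ann <- simulate_raters(seq1, n_raters = 3, seed = 1)
fleiss_kappa(ann, "posture")                  # 0.944
fleiss_kappa(ann, "movement")                 # 0.591

mask <- seq1$carrying != "active_carry"       # carrying-filtered analysis
f    <- compute_distributions(seq1$posture, seq1$movement, mask)

cohort <- generate_age_cohort(60, c(4, 16), seed = 7)
fit    <- fit_age_bins(cohort)                # 13 Gaussian age bins, 4..16
p      <- predict_age(fit, f)
p$predicted_age                               # 10.0 months
p$bims                                        # 50.0

loso_evaluate(cohort)[c("pearson_r", "mae")]  # r = 0.992, MAE = 0.36 months

transition_rates(seq1$posture, seq1$movement, hop_s = 1, mask = mask)
# posture 4.4 / min, movement 15.0 / min
```

The ten-month-old simulated here spends most time sitting and in crawl
posture (30% and 26%), the raters agree almost perfectly on posture but
only moderately on movement — the structure the pipeline is built around —
and the recording's feature vector lands in the 10-month age bin, i.e. a
BIMS of 50 on the 0 (≤ 4 mo) to 100 (≥ 16 mo) maturity scale. On the
60-recording synthetic cohort, leave-one-subject-out age prediction tracks
true age with r = 0.99 and a mean absolute error of about a third of a
month.

A thin command-line wrapper is installed with the package
(`system.file("cli", "infantmotor", package = "infantmotor")`) with
`simulate`, `preprocess` and `agreement` subcommands.

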