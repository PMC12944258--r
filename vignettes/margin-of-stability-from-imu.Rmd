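---
title: "Estimating the margin of stability from wearable IMU signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the margin of stability from wearable IMU signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitmos)
```

## The problem

The margin of stability (MoS) quantifies dynamic balance during walking:
it is the horizontal distance between the boundary of the base of support
(BoS) and the *extrapolated* centre of mass (XCoM), the CoM position
advanced by its velocity scaled by the inverted-pendulum natural
frequency,

$$ x_{xcom} = x_{com} + \frac{\dot{x}_{com}}{\omega}, \qquad
   \omega = \sqrt{g / l}, $$

where $l$ is the CoM height above the ground. On a treadmill the belt
speed is added to the anterior CoM velocity before extrapolation. The
anterior MoS is the signed difference $x_{bos}^{(y)} - x_{xcom}^{(y)}$
(negative once the XCoM passes the forefoot boundary); the mediolateral
MoS is the absolute difference $|x_{bos}^{(x)} - x_{xcom}^{(x)}|$.
Because the anterior minimum occurs at heel contact and the mediolateral
minimum shortly after it, the per-step summary used throughout is the
*minimum* MoS within each step, a step running from one foot's heel
contact to the opposite foot's heel contact.

MoS is normally computed from optical motion capture, which confines it
to the laboratory. This package implements the alternative: estimating
per-step minimum MoS from one or two body-worn six-axis IMUs
(accelerometer + gyroscope) via principal motion analysis, and
quantifying which body placements carry the relevant information.

## Reference MoS from markers

Four markers suffice: bilateral anterior superior iliac spines (their
midpoint approximates the CoM) and bilateral forefoot markers (the
stance-side one defines the BoS boundary). Conventions chosen where
several readings were possible:

* **Pendulum length** $l$: the trial-mean vertical CoM coordinate, not
  the instantaneous height, so $\omega$ is one constant per trial.
* **Mediolateral BoS boundary**: the stance-foot forefoot marker's
  x-coordinate — the only lateral landmark available in this marker set.
* **Differentiation**: second-order central differences, one-sided at
  the ends, no smoothing filter by default; exact for locally quadratic
  trajectories.
* **Heel-contact detection**: on a treadmill the stance toe marker moves
  backwards with the belt, so heel contact is a local maximum of the toe
  marker's anterior coordinate. Peaks closer than a 0.3 s refractory
  window are pruned (highest kept) and left/right alternation is
  enforced.
* **Units**: SI internally; per-step labels are reported in millimetres.
  `g` is 9.81 m/s²; km/h converts to m/s by exactly 1/3.6.

## Principal motion analysis

Each step is resampled to 51 points covering 0–50% of the gait cycle
(support-foot heel contact to opposite heel contact) by linear
interpolation, and the six channels are concatenated into a length-306
predictor ($51 \times 6$); a second sensor appends another 306 entries.
With the $n \times d$ matrix $X$ and response $y$ (per-step minimum MoS)
column-centred, components $l = 1 \dots L$ are extracted by deflation:

$$ w_l = \frac{X_l^\top y_l}{|X_l^\top y_l|}, \quad
   c_l = X w_l, \quad
   p_l = \frac{X_l^\top c_l}{c_l^\top c_l}, \quad
   b_l = \frac{c_l^\top y_l}{c_l^\top c_l}, $$

with $X_{l+1} = X_l - c_l p_l^\top$, $y_{l+1} = y_l - b_l c_l$, and a
new (centred) sample predicted as
$\hat{y} = x^\top \sum_l b_l w_l + \bar{y}$.

One genuinely open design point: the score definition above takes $c_l$
from the **undeflated** centred $X$ even for $l \ge 2$, whereas standard
NIPALS PLS1 uses $c_l = X_l w_l$. The two coincide at $L = 1$, and the
prediction rule is self-consistent with the first form, which is
therefore the default (`variant = "as_printed"`); `variant = "nipals"`
provides the standard recursion (combined coefficients
$W (P^\top W)^{-1} b$) for comparison. Numerical choices: centring only,
no unit-variance scaling (raw sensor units enter the model); a $10^{-12}$
zero-norm threshold stops the deflation early on degenerate folds
instead of erroring, so cross-validation never aborts on an unlucky
split; $L$ is capped at $\min(n-1, d)$; all algebra in double precision.

A second, deliberately literal loop-based transcription of the same
recursion (`pma_fit_reference()`) ships in the package purely as a test
oracle; the suite requires agreement to $10^{-10}$ on random instances
and checks the $L=1$ limit against an independent NIPALS implementation
and against `mixOmics::pls`.

## Cross-validated evaluation

Model quality is assessed by stratified 10-fold cross-validation
repeated 5 times: within every (participant, speed) stratum samples are
shuffled and dealt round-robin to folds (from a random starting fold, so
no fold is systematically overfull), centring statistics are recomputed
inside every training fold, and held-out RMSE and Pearson correlation
are summarised as mean ± sd over the $k \times$ repetitions fold-level
values — the sd population is a documented package choice. The component
count $L$ is tuned over 1–10 by the same procedure, ties broken toward
the smaller count; selection is per (site set, direction, support foot)
unless a single global value is requested. `placement_grid()` runs this
machinery for every single site and every unordered pair (ten sites give
$10 + \binom{10}{2} = 55$ cells per support foot and direction), with
left- and right-support steps always analysed separately.

For descriptive interpretation, `categorize_mos()` bands a value against
a reference distribution: within one sd of the mean (or above) is
*typical*, between one and two sd below is *cautionary*, and more than
two sd below is *potentially high-risk* — only low values are flagged,
because smaller MoS means less stability. This is a statistical framing,
not a clinically validated classification.

## The synthetic gait generator

No public treadmill dataset accompanies this problem, so the package
ships a generator whose ground truth is known exactly. It emulates the
study conditions the package targets: eight participants × three belt
speeds (2.5/3.0/3.5 km/h) × 60 left- plus 60 right-stance steps retained
per speed after a 60 s warm-up is generated and discarded; markers at
200 Hz, ten IMUs at 100 Hz.

The kinematics are the simplest model whose MoS is available in closed
form: a constant-height CoM with a lateral sinusoid at stride frequency
(phased so the sway peaks toward the support side mid-stance) and a
small anterior bounce at step frequency; toe markers that travel
backwards at belt speed during stance from a per-step randomised reach
and swing forward linearly. Two per-step random deviations — the toe
reach at contact (sd 12 mm) and the lateral foot placement (sd 8 mm) —
are the sole drivers of step-to-step variation in the anterior and
mediolateral minimum MoS respectively. Cadence defaults (1.6/1.7/1.8 Hz
across the three speeds) and the toe-reach calibration place the
simulated label distributions in the ranges reported for healthy young
adults (anterior means falling from ≈ 40 mm to ≈ −15 mm across speeds,
mediolateral ≈ 77 mm), which keeps error magnitudes interpretable.

IMU channels are built in the estimator's own model class: a
step-phase-locked baseline (identical in every step, hence absorbed by
centring) plus linear mixtures of `n_latent` latent waveforms whose
per-step scores include the standardised reach and placement deviations,
plus white sensor noise (0.05 m/s², 0.02 rad/s). Site informativeness is
structural: lower-limb and sacral sites load fully on the MoS-coupled
latents, the xiphisternum at 0.4, and the skull vertex and left wrist at
zero — mirroring the finding that head and wrist motion reflect
individual style rather than stability. A separate latent-linear
generator (`generate_latent_dataset()`) draws directly from
$X = CP^\top + E$, $y = Cb + e$ for estimator-recovery studies.

Ground-truth labels are defined on the marker sampling grid using the
same central-difference convention as the analysis path (evaluated by
independent inline code in the generator): a continuous-time derivative
would differ from any discrete pipeline by far more than the 10⁻⁶ m
consistency budget, so the grid-sampled noiseless model *is* the truth.
The consistency test therefore genuinely exercises event handling,
support-foot bookkeeping, step segmentation and unit conversion, not the
differentiator. Determinism is per-trial: each (participant, speed)
trial draws from its own stream keyed by the configured seed, so trials
can be regenerated independently and bit-identically.

What the generator does **not** emulate: rigid-body/musculoskeletal
dynamics, soft-tissue artefact, marker occlusion or noise, gravity
components and axis misalignment in the IMU frames, realistic IMU noise
spectra, and between-participant anatomical variation beyond independent
random streams. Passing tests on this generator show the pipeline is
correct and well-calibrated under its stated assumptions — a linear
latent structure linking signals to labels — not that a given accuracy
will transfer to real recordings.

## Worked example

```{r example, eval = FALSE}
cfg <- gait_sim_config(n_participants = 2, steps_per_foot_per_speed = 30,
                       sites = c("sacral_crest", "right_knee", "skull_vertex"),
                       seed = 1)
samples <- simulate_step_samples(cfg, support = "left")
dm <- build_design_matrix(samples, c("sacral_crest", "right_knee"),
                          "mediolateral")
sel <- select_L(dm, 1:10, base_seed = 1)
cv <- cross_validate(dm, sel$best_L, base_seed = 1)
cv
```

## Problem sizes and limitations

The shipped tests and the acceptance script run the statistical studies
at desk scale — e.g. 20 replicates of the $n = 480$, $d = 306$ latent
recovery study, single-participant trials of 20–40 steps for pipeline
consistency and placement ranking, and `repetitions = 1` for the full
55-cell grid — sizes at which every calibration property is already
stable. Known limitations: the CoM is a pelvis-marker approximation, the
mediolateral BoS uses the forefoot marker for want of a lateral one,
heel contacts rely on a treadmill-specific peak detector, and the
estimator is linear — steps whose signal–label relation is strongly
nonlinear are outside its model class.
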