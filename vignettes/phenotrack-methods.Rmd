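---
title: "Methods: synthetic cohorts, tracking, behavioral features, survival models and the phenotypic clock"
author: "phenotrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic cohorts, tracking, behavioral features, survival models and the phenotypic clock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

phenotrack is a desk-scale re-creation of an automated phenotyping
platform for small swimming animals such as *Daphnia magna*: video
tracking of many animals at once, behavioral and morphological feature
extraction, lifespan modelling, and a "phenotypic clock" that predicts
an animal's apparent age from its behavior. Because the original
physical rig (tank, camera, lights, vibration motors) is out of scope,
the package ships a ground-truthed synthetic cohort generator that
stands in for the rig; every downstream stage is validated against the
generator's known truth. This vignette explains each model, the
parameters that matter, the numerical choices, and what the synthetic
validation does and does not establish about real recordings.

## The synthetic cohort generator

`cohort_config()` fixes the study conditions: a 25 fps monochrome
camera over a 400 x 300 px arena at 8 px/mm (50 x 37.5 mm of water),
animals of 2.5 mm baseline body length swimming at a 5 mm/s baseline
speed. Aging enters through two linear trends with defaults chosen to
mirror the qualitative biology — locomotion declines while the body
keeps growing: mean speed `max(0, 5 - 0.05 * age)` mm/s and body length
`2.5 + 0.02 * age` mm. Lifespans are drawn from a configurable hazard;
the default Gompertz `h(t) = a e^{bt}` with `a = 6e-4`, `b = 0.085`
gives a median of ~54 days, the scale typical of well-kept *D. magna*
cohorts.

Movement is a correlated random walk: per-frame wrapped-Gaussian
heading increments (`turn_sd = 0.35` rad) and log-normal multiplicative
speed jitter with mean exactly one (`speed_cv = 0.3`), so the empirical
mean speed converges to the configured value. Walls reflect, which
keeps trajectories in frame without boundary deaths; at a reflection
the within-frame path is folded, so displacement-based speed estimates
are biased a fraction of a percent low — the generator's commanded
per-frame speed is stored alongside the positions for exact checks.
With `territories = TRUE` each animal is confined to its own grid cell,
producing a guaranteed non-overlapping cohort for tracking-recovery
studies.

Stimuli follow the standard 2-minute protocol encoded by
`stimulus_schedule()`: weak light at 20–30 s, strong light at 40–50 s,
vibration at 70–80 s. Inside a window the speed is multiplied by
`stimulus_response_gain`; light windows additionally impose a vertical
drift (upward while on, downward for an equally long window after
light-off), emulating phototaxis toward an overhead light and sinking
after it. The magnitude of that drift is not quantified in the
literature we model, so it is an explicit free parameter
(`drift_speed`, default 2 mm/s) rather than an asserted value.

Each animal also carries a per-frame body *presentation* — transverse
(top view, near-circular) or sagittal (side view, elongated) — as a
two-state Markov chain with switch probability 0.02 per frame. A
Markov chain rather than an independent per-frame coin keeps
presentation switches rare enough that a linker with a size gate can
follow the animal through them, which matches how real animals roll
between presentations over fractions of a second, not per frame. The
aspect ratios (transverse 1.12, sagittal 4.5) were chosen once so the
two presentations cleanly straddle the published circularity
thresholds (see below) at the rendered blob sizes (about 20 px major
axis); smaller blobs make discrete circularity too noisy for any
threshold to separate.

`render_video()` draws each animal as a filled oriented ellipse, bright
on dark (the package's fixed polarity; `read_video_tiff(invert=)`
adapts recordings with the opposite polarity), composites static debris
blobs that persist across frames, and adds Gaussian pixel noise
(`noise_sd = 4` on the 8-bit scale). Overlaps composite by maximum
intensity. What the renderer does *not* emulate: molting and egg-sac
morphology, partial transparency, water-surface reflections, lighting
gradients, and compression artifacts. Passing the synthetic recovery
tests therefore shows the pipeline logic is correct and well
calibrated at realistic SNR; it does not certify performance on any
particular real rig.

## Tracking

The background model is the pixel-wise mean of every 25th frame
starting at frame 0 (0-based indexing throughout); at 25 fps that is
one frame per second, enough for swimming animals to decorrelate while
debris and corpses stay put and are removed by subtraction.
`segment_frame()` thresholds the absolute difference image — Otsu by
default with a fixed-value override, plus a floor (`min_threshold = 8`)
so an all-noise difference image yields nothing — labels connected
components, filters by area, and parameterizes each blob by centroid,
area, perimeter, ellipse-equivalent axes and circularity.

Circularity is `4 pi A / P^2`. On rasterized blobs the discrete
perimeter estimator (a boundary-pixel count) biases the raw value —
an ideal digital disc scores about 1.3 — so the package reports a
*normalized* circularity: the raw value divided by the raw circularity
of an ideal rasterized disc of equal area measured with the same
estimators (tabulated over radius and interpolated). A disc then maps
to ~1, and the published plane thresholds apply to this scale: above
0.92 the blob is a transverse presentation, below 0.58 sagittal, in
between unclassified and excluded from plane-specific size features.

Identity linking is framed as per-transition assignment: candidate
(track, detection) pairs must pass a positional gate
(`max_link_dist_px`, default 20) and a morphological gate (area ratio
within `[1/5, 5]`; the wide default deliberately admits transverse <->
sagittal presentation switches, whose area ratio is about 4). Among
feasible pairs the package solves the *minimum-total-distance
assignment exactly* (enumeration with pruning) whenever a frame has at
most 7 open tracks and 7 detections, falling back to a greedy
nearest-neighbour sweep on denser frames; ties break by smaller
distance, then smaller area difference, then lower detection index.
Exact assignment was chosen over plain greedy because greedy
shortest-edge-first is not globally optimal even on 2 x 2 crossings,
and the package's own oracle tests compare against exhaustive
enumeration. Unmatched detections open new tracks; a track unmatched
for more than `max_gap_frames` (5) frames closes — one animal may
therefore yield several trajectories, which is expected and handled
downstream by the duration filter. Tracks shorter than 10 s (duration
convention `(n_detections - 1)/fps`, so 251 detections at 25 fps is
exactly 10 s and is kept) are discarded, as are tracks whose net
start-to-end displacement falls below an optional floor (residual
non-moving gunk).

## Behavioral features

Positions are smoothed by a centered 3-point moving average before
differencing; edges use the truncated window. Because the truncated
edge distorts even perfectly uniform motion, the first and last
kinematic samples are reported `NA` and excluded from features. Speed
is mm/s (`px_per_mm` is required; the package standardizes all speed
features on physical units), angular velocity is the wrapped heading
difference times fps, and vertical velocity is sign-flipped so upward
(decreasing image y) is positive.

The ethogram is a fixed decision cascade per frame on speed in body
lengths per second (body length = per-track median major axis) and
angular velocity: Pause (<= 0.2 BL/s), else Spin (>= 2 pi rad/s), else
Turn (>= pi/2 rad/s), else FwdRun (>= 2 BL/s), FwdSlow (<= 1 BL/s),
else Fwd. The thresholds are configuration values calibrated on
synthetic cohorts — the cascade order resolves ties, and the six state
probabilities are frame fractions that always sum to one.

`natural_features()` yields the 21 natural-swimming features per
trajectory: mean/median/SD speed, mean/SD angular velocity, mean
absolute vertical velocity, mean vertical position (0–1, up = 1),
fraction of time in the upper half, net-to-gross displacement ratio,
transverse- and sagittal-plane areas (plane-classified frames only;
honest `NA` when a plane never occurs), major and minor axes, the six
ethogram probabilities, duration and path length.
`stimulus_features()` yields 12 more: per stimulus, the mean speed over
the 10 s before onset, the mean speed during the window, their ratio,
and the mean signed vertical velocity during the window. Window means
exclude a guard of `(window+1)/2` frames at each boundary because the
position smoothing blends the two regimes there; with the guard, a
clean step response is recovered exactly. The correlation matrix of a
feature table uses pairwise-complete Pearson correlations and reports
zero-variance columns as missing, never as zero.

## Survival

Census counting takes the median of per-frame detection counts over a
short clip and raises a curation flag whenever those counts disagree
(animals touching or overlapping) — the automated counter is designed
to be *curated*, not trusted blindly. Curation is a plain ledger file
whose overrides are applied with provenance retained. Census series
convert to per-animal records with the right-endpoint convention (a
death between censuses is recorded at the census where it is first
seen); survivors at study end are right-censored, and conversion
refuses increasing counts instead of silently repairing them.

Kaplan–Meier estimation and the two-group log-rank test are delegated
to the survival package; the median is the smallest time with
S(t) <= 0.5 and is reported as undefined (not a number) when the curve
never reaches 0.5. Parametric lifespan fitting covers seven families —
exponential, Weibull, gamma, generalized gamma, log-logistic,
log-normal, Gompertz — by maximum likelihood with right-censoring,
via flexsurv. Parameterizations are pinned because conventions vary:
Gompertz hazard `h(t) = rate * e^{shape t}` (so `rate` is the
generator's `a` and `shape` its `b`), and the generalized gamma in the
(mu, sigma, Q) form whose Q = 0 and Q = 1 limits are the log-normal
and Weibull. Model selection ranks by AIC (BIC also reported), ties
broken by family name; fits are fingerprinted by (n, sum of times, sum
of events) so ranking fits from different datasets is an error.

## The phenotypic clock

Longitudinal lifespan data are intrinsically imbalanced — old animals
are rare because most of the cohort has died — so the clock pipeline
combines age-stratified cross-validation with optional oversampling of
rare target regions.

*Stratified folds for a continuous target.* Ages are binned into
equal-width bins (default 5 days) and each bin's rows are dealt
round-robin into the folds, so every fold spans the whole age range.

*Imputation.* Missing cells are replaced by the mean of the feature in
the same age bin, falling back to the feature's global mean for an
empty bin; a feature missing everywhere is an error.

*SMOGN oversampling.* Rarity is defined by the target density:
relevance `1 - density(y)/max density`, rare above 0.8. Each rare row
spawns one synthetic row: interpolation toward a random one of its 5
nearest rare neighbours (standardized Euclidean distance) when that
neighbour is near (at or below the row's median k-neighbour distance),
Gaussian perturbation at `0.01 x feature SD` when it is distant.
Originals are never altered. These hyperparameters are configuration
defaults, not claims about the original method's settings.

*No leakage.* Within every fold, the imputer and the oversampler are
fitted on the training split only; the test suite verifies the
per-fold imputer means against independently recomputed training-only
means, and the final deployment model is refitted on all rows.

Five regressor families are wrapped behind one interface: LASSO and
elastic net (glmnet, lambda chosen by internal CV), random forest
(ranger, 300 trees), gradient boosting (xgboost, 150 rounds, learning
rate 0.1, depth 3, subsample 0.8) and RBF-SVM (e1071). Metrics are
pooled held-out R², adjusted R² `1 - (1 - R²)(n-1)/(n-p-1)` with p the
number of feature columns presented to the learner (stated explicitly
because resampling changes row counts but not p), and RMSE in days.

Feature importance is reported in *both* dialects, because "permutation
importance, i.e. the incremental error from excluding the feature"
conflates two procedures: (a) permuting the column under the fitted
model, (b) retraining without the column and re-measuring CV error.
They are returned separately and labelled; neither is asserted to be
the original implementation.

Phenotypic age is `predicted - chronological`; a healthier-than-
expected cohort scores negative deltas. The aging-rate summary is the
origin-forced regression slope `sum(xy)/sum(x^2)` of predicted on
chronological age with SE from the no-intercept residuals (the package
reports a standard error and labels it as such). A control cohort
should score near 1; the package's synthetic control calibration
requires the slope to land in [0.9, 1.1].

## Problem sizes and determinism

Every stochastic operation takes a seed through its config and is
bit-reproducible given it. The validation suite runs at deliberately
chosen sizes: tracking recovery on 20 animals for 60 s at 25 fps
(1,501 frames, 400 x 300 px), KM medians at n = 10,000, log-rank
type-I error over 2,000 null replicates of 50 vs 50, parametric
parameter recovery at n = 5,000 per family, and clock cohorts of a few
hundred trajectories over ages 5–60 days — large enough for 3-SEM
moment checks to be meaningful, small enough that the whole suite runs
on a laptop core. Generator-level moment checks use 3-SEM bounds;
end-to-end recovery through the rendered video uses a 2% tolerance,
which budgets the sampling error at those sizes plus the sub-percent
biases of the displacement estimator (centroid jitter, reflection
folding).

## Known limitations

- The renderer's realism gap (no molts, transparency or lighting
  gradients) means segmentation thresholds may need recalibration on
  real footage; all of them are exposed in `segmentation_params()`.
- Identity is not maintained through full occlusion; crossing animals
  may swap or split tracks, which the duration filter tolerates but
  does not repair.
- The linker's exact assignment is per frame transition, not a global
  multi-frame optimization.
- Lifespan likelihoods treat census-interval deaths as exact at the
  census date (right-endpoint convention), not interval-censored.
- The clock's regressors use small fixed hyperparameter defaults;
  serious applications should tune them through the exposed config.
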