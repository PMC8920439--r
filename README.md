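# phenotrack

Automated phenotyping of small swimming animals — *Daphnia magna* in
particular — from grayscale video to survival curves and a behavioral
"phenotypic clock", as a single R package. It is aimed at aging and
ecotoxicology labs that record many animals per tank and want, without
a commercial tracking suite:

1. **Tracking** — background subtraction (pixel-wise mean of every
   25th frame), blob segmentation, and frame-to-frame identity linking
   by minimum-cost assignment with positional and morphological gates;
   tracks shorter than 10 s are not counted as trajectories.
2. **Features** — per trajectory, 21 natural-swimming features
   (kinematics, morphology, vertical location, and a 6-state locomotor
   ethogram: FwdRun, Fwd, FwdSlow, Turn, Spin, Pause) plus 12
   stimulus-response features for the weak-light / strong-light /
   vibration protocol. Body presentation (top vs side view) is
   separated by normalized circularity `4\pi A/P^2` with thresholds
   0.92 and 0.58.
3. **Survival** — human-in-the-loop census counting, Kaplan–Meier
   curves, two-group log-rank tests, and maximum-likelihood fits of
   seven lifespan families (exponential, Weibull, gamma, generalized
   gamma, log-logistic, log-normal, Gompertz) ranked by AIC.
4. **Clock** — age-stratified 5-fold cross-validated regressors
   (LASSO, elastic net, random forest, gradient boosting, SVM) with
   age-group mean imputation and SMOGN oversampling of rare old ages;
   phenotypic age `= predicted − chronological`, permutation and
   refit feature importance, and origin-forced aging-rate slopes
   `\sum xy / \sum x^2`.
5. **Synthetic cohorts** — a ground-truthed generator (correlated
   random walks with age-dependent speed and size, rendered ellipse
   videos with debris and noise, parametric lifespans, feature-level
   intervention cohorts) that stands in for the physical rig so every
   stage is testable end to end.

## Worked example

Simulate a 20-animal, 60 s cohort, render it, track it, and extract
features:

```r
library(phenotrack)

cfg    <- cohort_config(n_animals = 20, duration_s = 60,
                        territories = TRUE, seed = 101)
truth  <- simulate_trajectories(cfg, age_days = 10)
video  <- render_video(truth, cfg)
det    <- segment_video(video, params = segmentation_params(min_area_px = 10))
tp     <- tracking_params()
tracks <- filter_tracks(link_tracks(det, tp), tp, cfg$fps)
length(unique(tracks$track_id))
#> [1] 24

fp    <- feature_params(px_per_mm = cfg$px_per_mm, fps = cfg$fps,
                        arena_h_px = cfg$arena_h_px)
feats <- extract_features(tracks, fp, age_days = 10)
round(mean(feats$mean_speed_mms), 2)
#> [1] 4.24
```

The 20 animals yield 24 trajectories — a tracked animal may split
into more than one trajectory, which is expected and handled by the
10 s duration filter. The configured mean speed at age 10 is
`5 − 0.05·10 = 4.5` mm/s; the feature value (4.24)
is a few percent lower because the 3-point position smoothing slightly
shortens a correlated random walk — with smoothing off
(`window = 1`) the estimate is unbiased.

Lifespans and model selection:

```r
rec  <- simulate_survival(cfg, 2000)     # Gompertz, median ~54 d
km   <- km_estimate(rec)
km$median_days
#> [1] 54.10263
fits <- fit_all_parametric(rec)
select_model(fits)[1:3, c("family", "aic", "delta_aic")]
#> # A tibble: 3 × 3
#>   family               aic delta_aic
#>   <chr>              <dbl>     <dbl>
#> 1 gompertz          16043.       0  
#> 2 generalized_gamma 16127.      83.7
#> 3 weibull           16364.     321. 
```

The fitted Gompertz ranks first on its own data, ahead of the
generalized gamma (which only approximates the Gompertz hazard shape).

Train a clock on a synthetic control cohort and score interventions:

```r
ctrl <- simulate_feature_cohort(ages = seq(5, 60, 5), n_per_age = 30,
                                attrition = TRUE, seed = 1)
m <- train_clock(dplyr::select(ctrl, -age_days, -condition), ctrl$age_days,
                 clock_config(model = "random_forest", oversample = "smogn"))
glance(m)
#> # A tibble: 1 × 6
#>   model             n     p    r2 adj_r2  rmse
#>   <chr>         <int> <int> <dbl>  <dbl> <dbl>
#> 1 random_forest   218    11 0.960  0.958  2.76

toxic <- simulate_feature_cohort(ages = seq(20, 60, 5), n_per_age = 25,
                                 shift_days = 10, condition = "toxic", seed = 2)
pa <- predict_phenotypic_age(m, dplyr::select(toxic, -age_days, -condition),
                             toxic$age_days, toxic$condition)
glance(pa)[, c("condition", "mean_delta", "slope")]
#> # A tibble: 1 × 3
#>   condition mean_delta slope
#>   <chr>          <dbl> <dbl>
#> 1 toxic           6.38  1.12
```

A cohort whose features were generated 10 days "older" than its
chronological age scores a positive mean phenotypic-age delta and an
aging-rate slope above 1, as it should.

`autoplot()` methods exist for KM fits, clock models and phenotypic-age
results; `plot_tracks()` and `plot_correlation()` cover trajectories
and feature correlation matrices. A thin command-line front end ships
at `inst/cli/phenotrack.R` with subcommands `simulate`, `track`,
`features`, `survive`, `clock` and `run`.

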