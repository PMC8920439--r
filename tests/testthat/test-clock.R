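test_that("imputation fills missing cells with age-group means", {
  X <- tibble::tibble(f1 = c(2, 4, NA, 10, NA), f2 = c(1, NA, 3, 4, 5))
  ages <- c(10, 11, 12, 30, 31) # bins of width 5: {10,11,12} and {30,31}
  out <- impute(X, ages, bin_width_days = 5)
  expect_equal(out$f1[3], 3) # mean of {2, 4}
  expect_equal(out$f1[5], 10) # only value in its group
  expect_equal(out$f2[2], 2) # mean of {1, 3}
  full <- tibble::tibble(a = 1:4, b = 4:1)
  expect_identical(impute(full, c(1, 1, 2, 2)), tibble::tibble(a = 1:4, b = 4:1))
  expect_error(impute(tibble::tibble(a = c(NA_real_, NA_real_)), c(1, 2)),
               "no observed values")
})

test_that("imputed values equal brute-force group means under random missingness", {
  set.seed(19)
  n <- 200
  ages <- sample(seq(5, 60, 5), n, replace = TRUE)
  X <- tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  Xm <- X
  for (cn in names(Xm)) Xm[[cn]][runif(n) < 0.25] <- NA
  out <- impute(Xm, ages, bin_width_days = 5)
  bins <- floor(ages / 5)
  for (cn in names(Xm)) {
    miss <- is.na(Xm[[cn]])
    expected <- as.numeric(tapply(Xm[[cn]], bins,
                                  function(v) mean(v, na.rm = TRUE))[
      as.character(bins[miss])])
    expected[is.na(expected)] <- mean(Xm[[cn]], na.rm = TRUE)
    expect_equal(out[[cn]][miss], expected)
    expect_equal(out[[cn]][!miss], Xm[[cn]][!miss]) # observed cells untouched
  }
})

test_that("SMOGN leaves a uniform-density target unchanged and is seeded", {
  set.seed(2)
  X <- tibble::tibble(a = rnorm(200), b = rnorm(200))
  y <- seq(0, 60, length.out = 200) # flat density: no rare region
  out <- resample_smogn(X, y, rel_threshold = 0.8, seed = 3)
  expect_equal(nrow(out$features), 200)
  expect_equal(out$target, y)
  # determinism on a genuinely rare-tailed target
  y2 <- c(rep(30, 180), seq(55, 60, length.out = 20))
  r1 <- resample_smogn(X, y2, seed = 5)
  r2 <- resample_smogn(X, y2, seed = 5)
  expect_identical(r1, r2)
  expect_gt(nrow(r1$features), 200) # rare rows were augmented
  expect_warning(resample_smogn(X[1, ], y2[1]), "fewer than 2")
})

test_that("SMOGN augments the depleted old-age bin with geometrically valid rows", {
  coh <- simulate_feature_cohort(ages = seq(5, 60, 5), n_per_age = 40,
                                 attrition = TRUE, seed = 23)
  X <- dplyr::select(coh, -age_days, -condition)
  y <- coh$age_days
  out <- resample_smogn(X, y, rel_threshold = 0.8, k = 5,
                        noise_scale = 0.01, seed = 7)
  old_pre <- sum(y >= 50)
  old_post <- sum(out$target >= 50)
  expect_gte(old_post, old_pre)
  expect_gt(nrow(out$features), nrow(X))
  expect_equal(out$features[seq_len(nrow(X)), ], tibble::as_tibble(X),
               ignore_attr = TRUE) # originals unaltered
  # every synthetic row lies on a segment between rare originals, up to
  # the configured noise
  dens <- density(y, n = 512)
  rel <- 1 - approx(dens$x, dens$y, xout = y, rule = 2)$y / max(dens$y)
  rare <- which(rel > 0.8)
  Xm <- as.matrix(X)
  sds <- apply(Xm, 2, sd)
  syn <- as.matrix(out$features)[out$synthetic, , drop = FALSE]
  for (s in seq_len(nrow(syn))) {
    v <- syn[s, ]
    ok <- FALSE
    for (i in rare) {
      # candidate interpolation parent: recover t from the first
      # non-degenerate coordinate, then check collinearity
      for (j in rare) {
        if (i == j) next
        dirv <- Xm[j, ] - Xm[i, ]
        nz <- which(abs(dirv) > 1e-9)[1]
        if (is.na(nz)) next
        tt <- (v[nz] - Xm[i, nz]) / dirv[nz]
        if (!is.finite(tt) || tt < -0.05 || tt > 1.05) next
        if (max(abs(Xm[i, ] + tt * dirv - v) / sds) < 0.05) { ok <- TRUE; break }
      }
      if (ok) break
      if (max(abs(v - Xm[i, ]) / sds) < 0.05) { ok <- TRUE; break } # noise variant
    }
    expect_true(ok)
  }
})

test_that("a feature equal to age yields near-perfect held-out accuracy", {
  set.seed(31)
  n <- 300
  ages <- rep(seq(5, 60, 5), length.out = n)
  X <- tibble::tibble(perfect = ages, junk1 = rnorm(n), junk2 = rnorm(n))
  m <- train_clock(X, ages, clock_config(model = "lasso", seed = 1))
  met <- m$metrics[m$metrics$split == "cv_heldout", ]
  expect_gte(met$adj_r2, 0.99)
  expect_lt(met$rmse, 1)
})

test_that("permuted labels give held-out R2 near zero", {
  set.seed(32)
  coh <- simulate_feature_cohort(ages = seq(5, 60, 5), n_per_age = 25, seed = 3)
  y_perm <- sample(coh$age_days)
  m <- train_clock(dplyr::select(coh, -age_days, -condition), y_perm,
                   clock_config(model = "random_forest", seed = 2))
  met <- m$metrics[m$metrics$split == "cv_heldout", ]
  expect_lt(abs(met$r2), 0.1)
})

test_that("fold preprocessing never sees held-out rows (leakage guard)", {
  set.seed(33)
  coh <- simulate_feature_cohort(ages = seq(5, 60, 5), n_per_age = 20,
                                 missing_rate = 0.15, seed = 4)
  X <- dplyr::select(coh, -age_days, -condition)
  cfg <- clock_config(model = "lasso", seed = 9)
  m <- train_clock(X, coh$age_days, cfg)
  # per-fold imputer means must equal means over the training split only,
  # recomputed here independently
  bins <- floor(coh$age_days / cfg$bin_width_days)
  for (f in seq_len(cfg$folds)) {
    tr_i <- which(m$folds != f)
    imp <- m$fold_imputers[[f]]
    for (cn in c("mean_speed_mms", "body_len_mm")) {
      expected <- tapply(X[[cn]][tr_i], bins[tr_i],
                         function(v) mean(v, na.rm = TRUE))
      expect_equal(imp$group_means[[cn]], expected)
    }
  }
  # metrics identical when held-out rows are perturbed AFTER the folds
  # and preprocessing are fixed: retrain on data where one test-fold row
  # carries an absurd value in a column the imputer would average if it
  # leaked; training metrics must not move
  X2 <- X
  test_rows <- which(m$folds == 1)
  X2$noise_1[test_rows[1]] <- 1e6
  m2 <- train_clock(X2, coh$age_days, cfg)
  imp1 <- m$fold_imputers[[1]]$group_means$noise_1
  imp2 <- m2$fold_imputers[[1]]$group_means$noise_1
  expect_equal(imp1, imp2) # fold-1 imputer blind to its test rows
})

test_that("training is deterministic under a fixed seed for every model family", {
  coh <- simulate_feature_cohort(ages = seq(10, 50, 10), n_per_age = 14,
                                 seed = 5)
  X <- dplyr::select(coh, -age_days, -condition)
  for (fam in c("lasso", "elastic_net", "random_forest", "gradient_boost",
                "svm")) {
    cfg <- clock_config(model = fam, folds = 3, seed = 11)
    m1 <- train_clock(X, coh$age_days, cfg)
    m2 <- train_clock(X, coh$age_days, cfg)
    expect_identical(m1$metrics, m2$metrics)
    expect_gt(m1$metrics$r2[1], 0.5) # every family learns the signal
  }
})

test_that("feature importance singles out the age-copy and ignores constants", {
  set.seed(35)
  n <- 250
  ages <- rep(seq(5, 60, 5), length.out = n)
  X <- tibble::tibble(perfect = ages + rnorm(n, 0, 1), junk1 = rnorm(n),
                      junk2 = rnorm(n), flat = 1)
  m <- train_clock(X, ages, clock_config(model = "random_forest", seed = 6))
  imp_perm <- feature_importance(m, X, ages, method = "permutation", seed = 1)
  expect_equal(imp_perm$feature[1], "perfect")
  expect_lt(abs(imp_perm$importance[imp_perm$feature == "flat"]), 1e-8)
  imp_refit <- feature_importance(m, X, ages, method = "refit")
  expect_equal(imp_refit$feature[1], "perfect")
  expect_lt(imp_refit$importance[imp_refit$feature == "flat"],
            0.2 * imp_refit$importance[1])
  # invariance to row order
  ord <- sample(n)
  imp_shuf <- feature_importance(m, X[ord, ], ages[ord],
                                 method = "permutation", seed = 1)
  expect_equal(dplyr::arrange(imp_shuf, feature)$importance,
               dplyr::arrange(imp_perm, feature)$importance,
               tolerance = 0.05)
})

test_that("phenotypic age deltas: arithmetic, sign under intervention", {
  set.seed(36)
  ctrl <- simulate_feature_cohort(ages = seq(5, 60, 5), n_per_age = 30,
                                  seed = 7)
  m <- train_clock(dplyr::select(ctrl, -age_days, -condition),
                   ctrl$age_days,
                   clock_config(model = "gradient_boost", seed = 8))
  # delta is exactly predicted - chronological
  pa <- predict_phenotypic_age(m, dplyr::select(ctrl, -age_days, -condition),
                               ctrl$age_days, ctrl$condition)
  expect_equal(pa$delta, pa$predicted - pa$chronological)
  # healthier cohort (young-type features at old chronological age):
  # negative mean delta; toxic cohort: positive
  healthy <- simulate_feature_cohort(ages = seq(20, 60, 5), n_per_age = 30,
                                     shift_days = -10,
                                     condition = "healthy", seed = 9)
  toxic <- simulate_feature_cohort(ages = seq(20, 60, 5), n_per_age = 30,
                                   shift_days = 10,
                                   condition = "toxic", seed = 10)
  ph <- predict_phenotypic_age(m, dplyr::select(healthy, -age_days, -condition),
                               healthy$age_days, healthy$condition)
  pt <- predict_phenotypic_age(m, dplyr::select(toxic, -age_days, -condition),
                               toxic$age_days, toxic$condition)
  expect_lt(glance(ph)$mean_delta, 0)
  expect_gt(glance(pt)$mean_delta, 0)
  expect_error(predict(m, dplyr::select(ctrl, -mean_speed_mms,
                                        -age_days, -condition)),
               "missing feature")
})

test_that("mean predicted age falls monotonically with intervention strength", {
  ctrl <- simulate_feature_cohort(ages = seq(10, 50, 10), n_per_age = 30,
                                  seed = 12)
  m <- train_clock(dplyr::select(ctrl, -age_days, -condition), ctrl$age_days,
                   clock_config(model = "random_forest", seed = 13))
  means <- sapply(c(0, -5, -10, -15), function(s) {
    coh <- simulate_feature_cohort(ages = 40, n_per_age = 80, shift_days = s,
                                   seed = 14)
    mean(predict(m, dplyr::select(coh, -age_days, -condition)))
  })
  expect_true(all(diff(means) < 0))
})

test_that("origin-forced slope matches the closed form sum(xy)/sum(x^2)", {
  expect_equal(aging_rate_slope(1:10, 1:10)$slope, 1.0)
  expect_equal(aging_rate_slope(2 * (1:10), 1:10)$slope, 2.0)
  ex <- aging_rate_slope(c(12, 19, 33), c(10, 20, 30))
  expect_equal(ex$slope, 1490 / 1400)
  expect_gt(ex$slope_se, 0)
  expect_error(aging_rate_slope(c(1, 2), c(0, 0)), "all zero")
})

test_that("a control cohort scores an origin-forced slope near one", {
  ctrl <- simulate_feature_cohort(ages = seq(5, 60, 5), n_per_age = 30,
                                  seed = 15)
  m <- train_clock(dplyr::select(ctrl, -age_days, -condition), ctrl$age_days,
                   clock_config(model = "random_forest", seed = 16))
  held <- simulate_feature_cohort(ages = seq(5, 60, 5), n_per_age = 20,
                                  seed = 99)
  pa <- predict_phenotypic_age(m, dplyr::select(held, -age_days, -condition),
                               held$age_days, held$condition)
  sl <- glance(pa)$slope
  expect_gt(sl, 0.9); expect_lt(sl, 1.1)
})
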