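#' Clock training configuration
#'
#' @param model regressor family: `"lasso"`, `"elastic_net"`,
#'   `"random_forest"`, `"gradient_boost"` or `"svm"`.
#' @param folds number of cross-validation folds (>= 2); ages are
#'   stratified into the folds so each is representative of the whole
#'   age range.
#' @param bin_width_days width of the equal-width age bins used for
#'   stratification (and for age-group imputation), days.
#' @param oversample `"none"` or `"smogn"` (rare-age oversampling on the
#'   training split of each fold).
#' @param smogn_rel_threshold relevance threshold above which a target
#'   value counts as rare (relevance = 1 - density/max density).
#' @param smogn_k nearest neighbours used for interpolation.
#' @param smogn_noise_scale Gaussian-noise scale, as a fraction of each
#'   feature's SD, used when a neighbour is distant.
#' @param hyper named list of per-model hyperparameter overrides
#'   (`num_trees`, `nrounds`, `eta`, `max_depth`, `cost`, ...).
#' @param seed integer seed controlling folding, oversampling and any
#'   stochastic learner.
#' @return a `clock_config` list.
#' @export
clock_config <- function(model = c("random_forest", "lasso", "elastic_net",
                                   "gradient_boost", "svm"),
                         folds = 5L,
                         bin_width_days = 5,
                         oversample = c("none", "smogn"),
                         smogn_rel_threshold = 0.8,
                         smogn_k = 5L,
                         smogn_noise_scale = 0.01,
                         hyper = list(),
                         seed = 1L) {
  model <- match.arg(model)
  oversample <- match.arg(oversample)
  stopifnot("folds must be >= 2" = folds >= 2,
            "bin_width_days must be > 0" = bin_width_days > 0)
  structure(list(model = model, folds = as.integer(folds),
                 bin_width_days = bin_width_days, oversample = oversample,
                 smogn_rel_threshold = smogn_rel_threshold,
                 smogn_k = as.integer(smogn_k),
                 smogn_noise_scale = smogn_noise_scale,
                 hyper = hyper, seed = as.integer(seed)),
            class = "clock_config")
}

age_bin <- function(ages, bin_width) floor(ages / bin_width)

# ---- imputation ------------------------------------------------------------

fit_imputer <- function(features, ages, bin_width) {
  X <- as_tibble(features)
  missing_everywhere <- names(X)[vapply(X, function(x) all(is.na(x)), logical(1))]
  if (length(missing_everywhere) > 0) {
    abort(paste0("impute: feature(s) with no observed values: ",
                 paste(missing_everywhere, collapse = ", ")))
  }
  bins <- age_bin(ages, bin_width)
  group_means <- lapply(X, function(x) {
    tapply(x, bins, function(v) mean(v, na.rm = TRUE))
  })
  global_means <- vapply(X, function(x) mean(x, na.rm = TRUE), numeric(1))
  list(group_means = group_means, global_means = global_means,
       bin_width = bin_width, features = names(X))
}

apply_imputer <- function(imputer, features, ages) {
  X <- as_tibble(features)
  bins <- as.character(age_bin(ages, imputer$bin_width))
  for (f in imputer$features) {
    x <- X[[f]]
    miss <- is.na(x)
    if (!any(miss)) next
    fill <- imputer$group_means[[f]][bins[miss]]
    fill[is.na(fill)] <- imputer$global_means[[f]] # unseen or empty age group
    x[miss] <- fill
    X[[f]] <- x
  }
  X
}

#' Impute missing feature values by age-group means
#'
#' Each missing cell is replaced by the mean of that feature among rows
#' in the same age group (equal-width bins of `bin_width_days`); an age
#' group with no observed value for the feature falls back to the
#' feature's global mean. A feature missing everywhere is an error.
#'
#' @param features feature tibble (numeric columns).
#' @param ages chronological age (days) for every row.
#' @param bin_width_days age-group width, days.
#' @return imputed feature tibble (same shape, no `NA`s).
#' @export
impute <- function(features, ages, bin_width_days = 5) {
  stopifnot(length(ages) == nrow(features), !any(is.na(ages)))
  imp <- fit_imputer(features, ages, bin_width_days)
  apply_imputer(imp, features, ages)
}

# ---- SMOGN oversampling ----------------------------------------------------

#' Oversample rare target regions (SMOGN)

#' Synthetic minority oversampling for regression with Gaussian noise.
#' Target rarity is defined by the target density: relevance(y) =
#' 1 - density(y)/max(density), and rows with relevance above the
#' threshold are rare. Each rare row spawns one synthetic row per
#' original: a random one of its `k` nearest rare neighbours (Euclidean
#' distance on standardized features) is chosen; if the neighbour is
#' near (distance at or below the median of the row's k-neighbour
#' distances) the synthetic row is a random interpolation between the
#' two rows (target interpolated with the same coefficient); if it is
#' distant, the row is perturbed with Gaussian noise of scale
#' `noise_scale * SD` per feature instead. Original rows are never
#' altered, so the output always contains the input.
#'
#' @param features numeric feature tibble/matrix (no missing values).
#' @param target numeric target (e.g. chronological age).
#' @param rel_threshold relevance threshold in (0, 1).
#' @param k nearest rare neighbours considered.
#' @param noise_scale Gaussian-noise scale, fraction of feature SD.
#' @param seed integer seed.
#' @return list with `features`, `target` (originals first, synthetic
#'   rows appended) and `synthetic` (logical marker).
#' @export
resample_smogn <- function(features, target, rel_threshold = 0.8, k = 5L,
                           noise_scale = 0.01, seed = 1L) {
  X <- as.matrix(as_tibble(features))
  y <- as.numeric(target)
  stopifnot(nrow(X) == length(y), !any(is.na(X)), !any(is.na(y)))
  n <- nrow(X)
  base <- list(features = as_tibble(as.data.frame(X)), target = y,
               synthetic = rep(FALSE, n))
  if (n < 2) {
    warn("resample_smogn: fewer than 2 rows; returning input unchanged")
    return(base)
  }
  dens <- density(y, n = 512)
  rel <- 1 - approx(dens$x, dens$y, xout = y, rule = 2)$y / max(dens$y)
  rare <- which(rel > rel_threshold)
  if (length(rare) < 2) return(base)

  sds <- apply(X, 2, sd); sds[sds == 0 | !is.finite(sds)] <- 1
  Z <- sweep(X, 2, sds, "/")
  withr::with_seed(as.integer(seed), {
    synth_X <- matrix(NA_real_, length(rare), ncol(X))
    synth_y <- numeric(length(rare))
    for (m in seq_along(rare)) {
      i <- rare[m]
      others <- setdiff(rare, i)
      d <- sqrt(colSums((t(Z[others, , drop = FALSE]) - Z[i, ])^2))
      kk <- min(k, length(others))
      nb <- others[order(d)[seq_len(kk)]]
      dk <- sort(d)[seq_len(kk)]
      pick <- sample.int(kk, 1)
      j <- nb[pick]
      if (dk[pick] <= median(dk)) {
        tt <- runif(1)
        synth_X[m, ] <- X[i, ] + tt * (X[j, ] - X[i, ])
        synth_y[m] <- y[i] + tt * (y[j] - y[i])
      } else {
        synth_X[m, ] <- X[i, ] + rnorm(ncol(X), 0, noise_scale) * sds
        synth_y[m] <- y[i] + rnorm(1, 0, noise_scale * sd(y))
      }
    }
    colnames(synth_X) <- colnames(X)
    list(features = as_tibble(as.data.frame(rbind(X, synth_X))),
         target = c(y, synth_y),
         synthetic = c(rep(FALSE, n), rep(TRUE, length(rare))))
  })
}

# ---- learners --------------------------------------------------------------

fit_learner <- function(X, y, config) {
  Xm <- as.matrix(X)
  h <- config$hyper
  withr::with_seed(config$seed, switch(config$model,
    lasso = ,
    elastic_net = {
      alpha <- if (config$model == "lasso") 1 else h$alpha %||% 0.5
      cv <- glmnet::cv.glmnet(Xm, y, alpha = alpha,
                              nfolds = h$lambda_nfolds %||% 5)
      list(kind = config$model, fit = cv, lambda = cv$lambda.min)
    },
    random_forest = {
      d <- as.data.frame(Xm); d$.y <- y
      list(kind = "random_forest",
           fit = ranger::ranger(.y ~ ., data = d,
                                num.trees = h$num_trees %||% 300,
                                seed = config$seed))
    },
    gradient_boost = {
      list(kind = "gradient_boost",
           fit = xgboost::xgboost(Xm, y,
                                  nrounds = h$nrounds %||% 150,
                                  learning_rate = h$eta %||% 0.1,
                                  max_depth = h$max_depth %||% 3,
                                  subsample = h$subsample %||% 0.8,
                                  nthread = 1, verbosity = 0))
    },
    svm = {
      list(kind = "svm",
           fit = e1071::svm(Xm, y, kernel = "radial",
                            cost = h$cost %||% 1,
                            epsilon = h$epsilon %||% 0.1))
    }))
}

predict_learner <- function(learner, X) {
  Xm <- as.matrix(X)
  switch(learner$kind,
    lasso = ,
    elastic_net = as.numeric(predict(learner$fit, newx = Xm, s = "lambda.min")),
    random_forest = predict(learner$fit, data = as.data.frame(Xm))$predictions,
    gradient_boost = predict(learner$fit, Xm),
    svm = as.numeric(predict(learner$fit, Xm)))
}

# ---- cross-validated clock -------------------------------------------------

# deal rows of each age bin round-robin into folds, so every fold spans
# the whole age range (stratified k-fold for a continuous target)
stratified_folds <- function(ages, folds, bin_width, seed) {
  withr::with_seed(seed, {
    fold <- integer(length(ages))
    for (b in unique(age_bin(ages, bin_width))) {
      idx <- sample(which(age_bin(ages, bin_width) == b))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold
  })
}

#' Train a phenotypic-age clock
#'
#' Cross-validated regression of chronological age on behavioral and
#' morphological features. Ages are binned and dealt into stratified
#' folds; within each fold, imputation (age-group means) and optional
#' SMOGN oversampling are fitted on the training split only — never on
#' held-out rows — the learner is fitted, and held-out predictions are
#' collected. Reported metrics (R², adjusted R², RMSE) are computed on
#' the pooled held-out predictions; adjusted R² uses
#' `1 - (1 - R²)(n - 1)/(n - p - 1)` with `p` the number of feature
#' columns presented to the learner. The final model is refit on all
#' rows (imputer and oversampler included) for deployment.
#'
#' @param features feature tibble (numeric feature columns only;
#'   metadata columns `age_days`, `condition`, `cohort`, `track_id` are
#'   dropped automatically if present).
#' @param ages chronological ages, days (one per row).
#' @param config a [clock_config()].
#' @return a `clock_model`: config, fitted learner, imputer, feature
#'   names, `metrics` (one-row tibble), `cv_predictions` (tibble with
#'   `fold`, `age_days`, `predicted`), and per-fold imputer summaries.
#' @export
train_clock <- function(features, ages, config = clock_config()) {
  X <- as_tibble(features)
  X <- X[setdiff(names(X), c("age_days", "condition", "cohort", "track_id"))]
  stopifnot(nrow(X) == length(ages), all(vapply(X, is.numeric, logical(1))))
  if (nrow(X) < config$folds * 10) {
    abort(paste0("train_clock: need at least ", config$folds * 10,
                 " rows for ", config$folds, "-fold training"))
  }
  fold <- stratified_folds(ages, config$folds, config$bin_width_days,
                           config$seed)
  cv_pred <- vector("list", config$folds)
  fold_imputers <- vector("list", config$folds)
  for (f in seq_len(config$folds)) {
    tr_i <- which(fold != f); te_i <- which(fold == f)
    imp <- fit_imputer(X[tr_i, ], ages[tr_i], config$bin_width_days)
    fold_imputers[[f]] <- imp
    Xtr <- apply_imputer(imp, X[tr_i, ], ages[tr_i])
    ytr <- ages[tr_i]
    if (config$oversample == "smogn") {
      rs <- resample_smogn(Xtr, ytr, config$smogn_rel_threshold,
                           config$smogn_k, config$smogn_noise_scale,
                           seed = config$seed + f)
      Xtr <- rs$features; ytr <- rs$target
    }
    learner <- fit_learner(Xtr, ytr, config)
    Xte <- apply_imputer(imp, X[te_i, ], ages[te_i])
    cv_pred[[f]] <- tibble(fold = f, row = te_i, age_days = ages[te_i],
                           predicted = predict_learner(learner, Xte))
  }
  cv <- arrange(bind_rows(cv_pred), .data$row)
  p <- ncol(X)
  met <- regression_metrics(cv$age_days, cv$predicted, p)

  imp_all <- fit_imputer(X, ages, config$bin_width_days)
  Xall <- apply_imputer(imp_all, X, ages)
  yall <- ages
  if (config$oversample == "smogn") {
    rs <- resample_smogn(Xall, yall, config$smogn_rel_threshold,
                         config$smogn_k, config$smogn_noise_scale,
                         seed = config$seed)
    Xall <- rs$features; yall <- rs$target
  }
  final <- fit_learner(Xall, yall, config)
  train_met <- regression_metrics(yall, predict_learner(final, Xall), p)

  structure(list(config = config, learner = final, imputer = imp_all,
                 feature_names = names(X), n = nrow(X), p = p,
                 metrics = bind_rows(
                   mutate(met, split = "cv_heldout"),
                   mutate(train_met, split = "train")),
                 cv_predictions = cv,
                 fold_imputers = fold_imputers, folds = fold),
            class = "clock_model")
}

regression_metrics <- function(y, yhat, p) {
  n <- length(y)
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  tibble(n = n, p = p, r2 = r2, adj_r2 = adj, rmse = sqrt(ss_res / n))
}

#' @export
print.clock_model <- function(x, ...) {
  m <- x$metrics[x$metrics$split == "cv_heldout", ]
  cat("<clock_model> ", x$config$model, ", ", x$config$folds,
      "-fold CV on ", x$n, " rows x ", x$p, " features\n",
      "  held-out: adj R2 = ", round(m$adj_r2, 4), ", RMSE = ",
      round(m$rmse, 3), " days\n", sep = "")
  invisible(x)
}

#' @export
tidy.clock_model <- function(x, ...) x$metrics

#' @export
glance.clock_model <- function(x, ...) {
  m <- x$metrics[x$metrics$split == "cv_heldout", ]
  tibble(model = x$config$model, n = x$n, p = x$p, r2 = m$r2,
         adj_r2 = m$adj_r2, rmse = m$rmse)
}

#' @export
predict.clock_model <- function(object, newdata, ages = NULL, ...) {
  X <- as_tibble(newdata)
  unknown <- setdiff(object$feature_names, names(X))
  if (length(unknown) > 0) {
    abort(paste0("predict.clock_model: missing feature column(s): ",
                 paste(unknown, collapse = ", ")))
  }
  X <- X[object$feature_names]
  if (any(is.na(X))) {
    # impute with stored means; unknown ages fall back to global means
    imp_ages <- ages %||% rep(NA_real_, nrow(X))
    bins <- ifelse(is.na(imp_ages), NA_character_,
                   as.character(age_bin(imp_ages, object$imputer$bin_width)))
    for (f in object$feature_names) {
      x <- X[[f]]; miss <- is.na(x)
      if (!any(miss)) next
      fill <- ifelse(is.na(bins[miss]), NA_real_,
                     object$imputer$group_means[[f]][bins[miss]])
      fill[is.na(fill)] <- object$imputer$global_means[[f]]
      x[miss] <- fill
      X[[f]] <- x
    }
  }
  predict_learner(object$learner, X)
}

#' Feature importance of a fitted clock
#'
#' Two importance dialects, reported separately: `"permutation"` —
#' increase in prediction error (RMSE) on the supplied data when the
#' feature column is permuted, averaged over repeats, using the fitted
#' model; `"refit"` — increase in pooled cross-validated RMSE when the
#' model is retrained from scratch without the feature (incremental
#' error from excluding the feature).
#'
#' @param model a `clock_model`.
#' @param features feature tibble.
#' @param ages chronological ages.
#' @param method `"permutation"` or `"refit"`.
#' @param n_repeats permutation repeats.
#' @param seed integer seed.
#' @return tibble (`feature`, `importance`, `method`) sorted by
#'   decreasing importance.
#' @export
feature_importance <- function(model, features, ages,
                               method = c("permutation", "refit"),
                               n_repeats = 3, seed = 1L) {
  method <- match.arg(method)
  X <- as_tibble(features)[model$feature_names]
  X <- apply_imputer(model$imputer, X, ages)
  if (method == "permutation") {
    base_rmse <- sqrt(mean((ages - predict_learner(model$learner, X))^2))
    imp <- withr::with_seed(as.integer(seed), {
      vapply(model$feature_names, function(f) {
        mean(vapply(seq_len(n_repeats), function(r) {
          Xp <- X
          Xp[[f]] <- sample(Xp[[f]])
          sqrt(mean((ages - predict_learner(model$learner, Xp))^2)) - base_rmse
        }, numeric(1)))
      }, numeric(1))
    })
  } else {
    cfg <- model$config
    base <- train_clock(X, ages, cfg)
    base_rmse <- base$metrics$rmse[base$metrics$split == "cv_heldout"]
    imp <- vapply(model$feature_names, function(f) {
      sub <- train_clock(X[setdiff(model$feature_names, f)], ages, cfg)
      sub$metrics$rmse[sub$metrics$split == "cv_heldout"] - base_rmse
    }, numeric(1))
  }
  arrange(tibble(feature = model$feature_names, importance = unname(imp),
                 method = method), dplyr::desc(.data$importance))
}

#' Predict phenotypic age and intervention deltas
#'
#' Applies a fitted clock to a feature table and reports, per row, the
#' predicted (phenotypic) age, the chronological age and their
#' difference `delta = predicted - chronological`; healthier-than-
#' expected animals have negative deltas. When a `condition` label is
#' supplied, per-condition mean deltas with standard errors are
#' summarised.
#'
#' @param model a `clock_model`.
#' @param features feature tibble matching the training schema.
#' @param ages chronological ages, days.
#' @param condition optional per-row condition labels.
#' @return a `phenotypic_age` tibble (`predicted`, `chronological`,
#'   `delta`, `condition`) with a `summary` attribute (per-condition
#'   mean delta, SEM, n, origin-forced slope and its SE).
#' @export
predict_phenotypic_age <- function(model, features, ages, condition = NULL) {
  pred <- predict(model, features, ages = ages)
  cond <- condition %||% rep("all", length(ages))
  out <- tibble(predicted = pred, chronological = ages,
                delta = pred - ages, condition = cond)
  summ <- out |>
    group_by(.data$condition) |>
    summarise(n = n(), mean_delta = mean(.data$delta),
              sem_delta = sd(.data$delta) / sqrt(n()), .groups = "drop")
  slopes <- out |>
    group_by(.data$condition) |>
    summarise(aging_rate_slope(.data$predicted, .data$chronological),
              .groups = "drop")
  summ <- left_join(summ, slopes, by = "condition")
  structure(out, summary = summ, class = c("phenotypic_age", class(out)))
}

#' @export
glance.phenotypic_age <- function(x, ...) attr(x, "summary")

#' Origin-forced aging-rate slope
#'
#' Slope of the simple linear regression of predicted on chronological
#' age with both intercepts forced to zero: `slope = sum(x*y) /
#' sum(x^2)`. A control cohort should give a slope near 1; a slowed
#' aging rate gives a slope below 1. The standard error comes from the
#' no-intercept regression residuals.
#'
#' @param predicted predicted ages.
#' @param chronological chronological ages (not all zero).
#' @return one-row tibble: `slope`, `slope_se`, `n_slope`.
#' @export
aging_rate_slope <- function(predicted, chronological) {
  x <- as.numeric(chronological); y <- as.numeric(predicted)
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (all(x == 0)) abort("aging_rate_slope: chronological ages are all zero")
  slope <- sum(x * y) / sum(x^2)
  r <- y - slope * x
  se <- sqrt(sum(r^2) / (length(x) - 1) / sum(x^2))
  tibble(slope = slope, slope_se = se, n_slope = length(x))
}
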