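#' Automated census count over a short clip
#'
#' Animals in a crowded tank overlap and touch, so a single frame
#' under-counts. The census count is the median of the per-frame
#' detection counts over a short clip; when the per-frame counts vary
#' (a sign of fusion/occlusion) or the count exceeds `expected_max`, the
#' record is flagged for manual curation, implementing the
#' human-in-the-loop design.
#'
#' @param detections detection tibble with a `frame` column (the clip).
#' @param expected_max cohort size ceiling; counts cannot exceed it.
#' @param day census day/age label stored on the record.
#' @return a one-row `census` tibble: `day`, `auto_count`, `flag`.
#' @export
count_frame <- function(detections, expected_max = Inf, day = NA_real_) {
  det <- as_tibble(detections)
  if (nrow(det) == 0) {
    return(tibble(day = day, auto_count = 0L, flag = FALSE))
  }
  if (!("frame" %in% names(det))) det$frame <- 0L
  per_frame <- table(factor(det$frame, levels = unique(det$frame)))
  cnt <- as.integer(round(median(as.integer(per_frame))))
  flag <- length(unique(as.integer(per_frame))) > 1 || cnt > expected_max
  tibble(day = day, auto_count = min(cnt, expected_max), flag = flag)
}

#' Apply a curation ledger to automated census counts
#'
#' Overrides automated counts with manually curated values from a
#' ledger table, retaining the provenance of every override. The ledger
#' replaces the original point-and-click curation GUI with a plain
#' auditable file.
#'
#' @param census census tibble (`day`, `auto_count`, `flag`).
#' @param ledger tibble (`day`, `curated_count`, optional `note`); every
#'   `day` must exist in `census`.
#' @return census tibble with `count` (curated where present, else
#'   auto), `curated` (logical) and `note`.
#' @export
apply_curation <- function(census, ledger = NULL) {
  cen <- as_tibble(census)
  stopifnot(all(c("day", "auto_count") %in% names(cen)))
  if (is.null(ledger) || nrow(ledger) == 0) {
    return(mutate(cen, count = .data$auto_count, curated = FALSE,
                  note = NA_character_))
  }
  led <- as_tibble(ledger)
  stopifnot(all(c("day", "curated_count") %in% names(led)))
  unknown <- setdiff(led$day, cen$day)
  if (length(unknown) > 0) {
    abort(paste0("apply_curation: ledger references unknown day(s): ",
                 paste(unknown, collapse = ", ")))
  }
  if (!("note" %in% names(led))) led$note <- NA_character_
  out <- left_join(cen, select(led, "day", "curated_count", "note"), by = "day")
  mutate(out,
         curated = !is.na(.data$curated_count),
         count = ifelse(.data$curated, .data$curated_count, .data$auto_count),
         curated_count = NULL)
}

#' Convert a census series into per-animal survival records
#'
#' Each unit decrease in the (curated) live count between consecutive
#' census days emits one death at the later day (deaths between censuses
#' are assigned to the census at which they are first observed);
#' survivors at the last census are right-censored there.
#'
#' @param census curated census tibble with `day` and `count` (or
#'   `auto_count`).
#' @param cohort_size initial number of animals; defaults to the first
#'   count.
#' @return `survival_records` tibble: `id`, `time_days`, `event`
#'   (1 = death, 0 = censored). Deaths + censored = `cohort_size`.
#' @export
counts_to_records <- function(census, cohort_size = NULL) {
  cen <- arrange(as_tibble(census), .data$day)
  cnt_col <- if ("count" %in% names(cen)) "count" else "auto_count"
  counts <- cen[[cnt_col]]
  days <- cen$day
  bad <- which(diff(counts) > 0)
  if (length(bad) > 0) {
    abort(paste0("counts_to_records: live counts increase between day(s) ",
                 paste(sprintf("%s->%s", days[bad], days[bad + 1]),
                       collapse = ", "),
                 "; curate the census before conversion"))
  }
  cohort_size <- cohort_size %||% counts[1]
  if (counts[1] > cohort_size) {
    abort("counts_to_records: first count exceeds cohort size")
  }
  deaths <- c(cohort_size - counts[1], -diff(counts))
  times <- rep(days, deaths)
  survivors <- counts[length(counts)]
  tibble(
    id = seq_len(length(times) + survivors),
    time_days = c(times, rep(days[length(days)], survivors)),
    event = c(rep(1L, length(times)), rep(0L, survivors))
  )
}

as_surv <- function(records) {
  stopifnot(all(c("time_days", "event") %in% names(records)),
            all(records$time_days > 0))
  survival::Surv(records$time_days, records$event)
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator of the survival function with the median
#' lifespan defined as the smallest time at which the estimated survival
#' drops to 0.5 or below; `NA` (undefined) when the curve never reaches
#' 0.5 (e.g. heavy censoring).
#'
#' @param records survival tibble (`time_days`, `event`).
#' @return a `km_fit`: list with `curve` (tibble `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`), `median_days`, `n`, `n_events`.
#' @export
km_estimate <- function(records) {
  rec <- as_tibble(records)
  if (sum(rec$event) < 1) {
    warn("km_estimate: no events; curve is flat and the median undefined")
  }
  sf <- survival::survfit(as_surv(rec) ~ 1)
  curve <- tibble(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                  n_censor = sf$n.censor, surv = sf$surv)
  med <- if (any(curve$surv <= 0.5)) min(curve$time[curve$surv <= 0.5]) else NA_real_
  structure(list(curve = curve, median_days = med, n = nrow(rec),
                 n_events = sum(rec$event)),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat("<km_fit> n = ", x$n, ", events = ", x$n_events, ", median = ",
      ifelse(is.na(x$median_days), "undefined", paste0(x$median_days, " d")),
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.km_fit <- function(x, ...) x$curve

#' @export
glance.km_fit <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, median_days = x$median_days)
}

#' Two-group log-rank test
#'
#' Standard (unweighted) two-sample log-rank statistic with 1 degree of
#' freedom; invariant to swapping the group labels.
#'
#' @param records_a,records_b survival tibbles (`time_days`, `event`),
#'   each containing at least one event.
#' @return tibble: `chisq`, `df`, `p_value`, `n_a`, `n_b`.
#' @export
logrank <- function(records_a, records_b) {
  a <- as_tibble(records_a); b <- as_tibble(records_b)
  if (nrow(a) == 0 || nrow(b) == 0 || sum(a$event) == 0 || sum(b$event) == 0) {
    abort("logrank: both groups must contain events")
  }
  dat <- bind_rows(mutate(a, .grp = "A"), mutate(b, .grp = "B"))
  sd1 <- survival::survdiff(survival::Surv(time_days, event) ~ .grp, data = dat)
  chisq <- sd1$chisq
  tibble(chisq = chisq, df = 1L,
         p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
         n_a = nrow(a), n_b = nrow(b))
}

parametric_families <- c("exponential", "weibull", "gamma",
                         "generalized_gamma", "log_logistic", "log_normal",
                         "gompertz")

flexsurv_dist <- c(exponential = "exp", weibull = "weibull", gamma = "gamma",
                   generalized_gamma = "gengamma", log_logistic = "llogis",
                   log_normal = "lnorm", gompertz = "gompertz")

#' Fit a parametric lifespan model
#'
#' Maximum-likelihood fit of one of seven lifespan families with
#' right-censoring handled in the likelihood. Parameterizations follow
#' flexsurv: the generalized gamma is in the (mu, sigma, Q) form (Q = 0
#' is the log-normal and Q = 1 maps to the Weibull), and the Gompertz
#' hazard is `h(t) = rate * exp(shape * t)`, i.e. `rate` is the `a` and
#' `shape` the `b` of the generator's `h(t) = a * exp(b * t)`.
#'
#' @param records survival tibble (`time_days`, `event`).
#' @param family one of `"exponential"`, `"weibull"`, `"gamma"`,
#'   `"generalized_gamma"`, `"log_logistic"`, `"log_normal"`,
#'   `"gompertz"`.
#' @param fixed_shape optionally fix the Weibull shape (used for nesting
#'   identities such as Weibull(shape = 1) = exponential).
#' @return a `parametric_fit`: family, `estimates` tibble (term,
#'   estimate, se, transformed scale), `loglik`, `k` (free parameters),
#'   `aic`, `bic`, `n`, `n_events`, data fingerprint.
#' @export
fit_parametric <- function(records, family, fixed_shape = NULL) {
  family <- match.arg(family, parametric_families)
  rec <- as_tibble(records)
  k_par <- c(exponential = 1, weibull = 2, gamma = 2, generalized_gamma = 3,
             log_logistic = 2, log_normal = 2, gompertz = 2)[[family]]
  if (sum(rec$event) < k_par + 1) {
    abort(paste0("fit_parametric: ", family, " needs at least ", k_par + 1,
                 " events; got ", sum(rec$event)))
  }
  args <- list(formula = as_surv(rec) ~ 1, dist = flexsurv_dist[[family]])
  if (!is.null(fixed_shape)) {
    stopifnot(family == "weibull")
    args$fixedpars <- 1L # shape is the first parameter of dweibull
    args$inits <- c(fixed_shape, mean(rec$time_days))
  }
  fit <- tryCatch(
    suppressWarnings(do.call(flexsurv::flexsurvreg, args)),
    error = function(e) {
      abort(paste0("fit_parametric: ", family, " fit failed to converge: ",
                   conditionMessage(e)))
    })
  res <- fit$res
  est <- tibble(term = rownames(res), estimate = res[, "est"],
                se = res[, "se"])
  if (is.null(fixed_shape) && any(!is.finite(est$se))) {
    warn(paste0("fit_parametric: ", family,
                " produced non-finite standard errors"))
  }
  k <- fit$npars
  ll <- as.numeric(stats::logLik(fit))
  structure(list(family = family, estimates = est, loglik = ll, k = k,
                 aic = 2 * k - 2 * ll, bic = log(nrow(rec)) * k - 2 * ll,
                 n = nrow(rec), n_events = sum(rec$event),
                 fingerprint = data_fingerprint(rec), flexsurv = fit),
            class = "parametric_fit")
}

data_fingerprint <- function(rec) {
  c(n = nrow(rec), sum_t = sum(rec$time_days), sum_e = sum(rec$event))
}

#' @export
print.parametric_fit <- function(x, ...) {
  cat("<parametric_fit> ", x$family, ": loglik = ", round(x$loglik, 2),
      ", AIC = ", round(x$aic, 2), ", n = ", x$n, " (", x$n_events,
      " events)\n", sep = "")
  print(x$estimates)
  invisible(x)
}

#' @export
tidy.parametric_fit <- function(x, ...) x$estimates

#' @export
glance.parametric_fit <- function(x, ...) {
  tibble(family = x$family, loglik = x$loglik, k = x$k, aic = x$aic,
         bic = x$bic, n = x$n, n_events = x$n_events)
}

#' Fit all seven lifespan families
#'
#' @param records survival tibble.
#' @param families subset of the seven family names.
#' @return named list of `parametric_fit`s (families that fail to
#'   converge are dropped with a warning).
#' @export
fit_all_parametric <- function(records, families = parametric_families) {
  fits <- list()
  for (f in families) {
    fit <- tryCatch(fit_parametric(records, f), error = function(e) {
      warn(paste0("fit_all_parametric: dropping ", f, ": ",
                  conditionMessage(e)))
      NULL
    })
    if (!is.null(fit)) fits[[f]] <- fit
  }
  fits
}

#' Rank parametric fits by information criterion
#'
#' Orders fits of the same dataset by ascending AIC (BIC also reported),
#' with ties broken alphabetically by family name.
#'
#' @param fits list of `parametric_fit`s on identical data.
#' @return tibble ranked by AIC: `family`, `k`, `loglik`, `aic`,
#'   `delta_aic`, `bic`.
#' @export
select_model <- function(fits) {
  stopifnot(length(fits) >= 2)
  fps <- lapply(fits, `[[`, "fingerprint")
  if (!all(vapply(fps, function(f) isTRUE(all.equal(f, fps[[1]])), logical(1)))) {
    abort("select_model: fits come from different datasets")
  }
  tab <- bind_rows(lapply(fits, glance))
  tab <- arrange(tab, .data$aic, .data$family)
  mutate(tab, delta_aic = .data$aic - min(.data$aic),
         rank = row_number())[, c("rank", "family", "k", "loglik", "aic",
                                  "delta_aic", "bic")]
}

#' Read / write survival record tables as CSV
#' @param records survival tibble (`id`, `time_days`, `event`).
#' @param path file path.
#' @return `read_survival_csv` returns the tibble.
#' @export
write_survival_csv <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survival_csv
#' @export
read_survival_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("survival file not found: ", path))
  as_tibble(utils::read.csv(path))
}
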