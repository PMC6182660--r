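# Index-outcome association, survival models of remission duration, and
# Kaplan-Meier median-split analysis.

#' Per-arm, per-timepoint regression of outcome on baseline index
#'
#' Ordinary least squares of the chosen endpoint on the baseline
#' inflammatory index, fitted separately within each treatment arm (and for
#' `pct_change_at_t`, at each post-baseline timepoint). Slope p values use
#' the t distribution with n - 2 degrees of freedom.
#'
#' @param scores data.frame from [compute_index()] (baseline samples; the
#'   sample id is matched to the participant id of the endpoints).
#' @param endpoints data.frame from [endpoint_records()].
#' @param outcome `"pct_change_at_t"` or `"decline_slope"`.
#' @return data.frame with arm, timepoint_months (NA for decline slope),
#'   n, slope, intercept, r_squared, p_value, residual_sd.
#' @export
index_outcome_regression <- function(scores, endpoints,
                                     outcome = c("pct_change_at_t",
                                                 "decline_slope")) {
  outcome <- match.arg(outcome)
  idx <- scores$value[match(endpoints$participant_id, scores$sample_id)]
  if (anyNA(idx)) stop("endpoint participant without an index score")
  if (outcome == "decline_slope") {
    cols <- "decline_slope"
    tps <- NA_real_
  } else {
    cols <- grep("^pct_m", names(endpoints), value = TRUE)
    tps <- as.numeric(sub("^pct_m", "", cols))
  }
  rows <- list()
  for (arm in sort(unique(endpoints$arm))) {
    in_arm <- endpoints$arm == arm
    for (j in seq_along(cols)) {
      y <- endpoints[[cols[j]]][in_arm]
      x <- idx[in_arm]
      ok <- !is.na(y) & !is.na(x)
      if (sum(ok) < 3L) next
      if (stats::sd(x[ok]) == 0) stop("degenerate index variance in arm ", arm)
      fit <- stats::lm(y[ok] ~ x[ok])
      sm <- summary(fit)
      rows[[length(rows) + 1L]] <- data.frame(
        arm = arm, timepoint_months = tps[j], n = sum(ok),
        slope = unname(stats::coef(fit)[2L]),
        intercept = unname(stats::coef(fit)[1L]),
        r_squared = sm$r.squared,
        p_value = sm$coefficients[2L, 4L],
        residual_sd = sm$sigma,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Survival model of remission duration on the inflammatory index
#'
#' Weibull accelerated-failure-time fit (log duration linear in the index;
#' constant shape) or Cox proportional-hazards fit. For the Weibull model
#' the coefficient is on the log-time scale and the implied hazard ratio
#' per index unit is reported alongside, together with the median remission
#' duration as a function of the index.
#'
#' @param index data.frame from [compute_index()], matched to participants.
#' @param durations remission durations in months.
#' @param censored logical, TRUE = still in remission at last visit.
#' @param model `"weibull_aft"` or `"cox_ph"`.
#' @return list with model, coefficient, ci95, p_value, and for the Weibull
#'   fit shape, scale_intercept, hazard_ratio and `median_curve(x)`.
#' @export
fit_survival <- function(index, durations, censored,
                         model = c("weibull_aft", "cox_ph")) {
  model <- match.arg(model)
  x <- index$value
  if (length(x) != length(durations)) stop("length mismatch")
  if (all(censored)) stop("all observations censored")
  if (stats::sd(x) == 0) stop("constant index")
  event <- !censored
  # survreg/coxph treat zero survival times as invalid; remission observed
  # to fail at the first post-baseline visit gets a small positive time
  tt <- pmax(durations, 0.01)
  surv <- survival::Surv(tt, event)
  if (model == "weibull_aft") {
    fit <- survival::survreg(surv ~ x, dist = "weibull")
    sm <- summary(fit)
    co <- sm$table["x", ]
    shape <- 1 / fit$scale
    ci <- co["Value"] + c(-1, 1) * 1.96 * co["Std. Error"]
    b0 <- unname(stats::coef(fit)[1L])
    b1 <- unname(stats::coef(fit)[2L])
    list(model = model,
         coefficient = b1,
         ci95 = unname(ci),
         p_value = unname(co["p"]),
         shape = unname(shape),
         scale_intercept = b0,
         hazard_ratio = unname(exp(-shape * b1)),
         median_curve = function(xv) {
           exp(b0 + b1 * xv) * log(2)^(1 / shape)
         })
  } else {
    fit <- survival::coxph(surv ~ x)
    sm <- summary(fit)
    co <- sm$coefficients["x", ]
    ci <- unname(sm$conf.int["x", c("lower .95", "upper .95")])
    list(model = model,
         coefficient = unname(co["coef"]),
         ci95 = log(ci),
         p_value = unname(co["Pr(>|z|)"]),
         hazard_ratio = unname(co["exp(coef)"]))
  }
}

#' Kaplan-Meier comparison of remission above vs below the median index
#'
#' Splits participants at the median index (values exactly at the median go
#' to the "below" group), estimates the Kaplan-Meier survivor curve of
#' remission in each group and compares them with a two-sided logrank test.
#'
#' @param index data.frame from [compute_index()].
#' @param durations remission durations in months.
#' @param censored logical censoring flags.
#' @return list with `curves` (data.frame: group, time, surv), `logrank_p`,
#'   `chisq` and `groups` (the per-participant split).
#' @export
km_median_split <- function(index, durations, censored) {
  x <- index$value
  med <- stats::median(x)
  group <- factor(ifelse(x > med, "above", "below"),
                  levels = c("below", "above"))
  if (any(table(group) < 2L)) stop("need >= 2 participants per side")
  event <- !censored
  tt <- pmax(durations, 0.01)
  sf <- survival::survfit(survival::Surv(tt, event) ~ group)
  strata <- rep(names(sf$strata), sf$strata)
  curves <- data.frame(group = sub("group=", "", strata),
                       time = sf$time, surv = sf$surv,
                       stringsAsFactors = FALSE)
  if (sum(event) == 0L || length(unique(tt[event])) == 0L) {
    lr_p <- 1; chisq <- 0
  } else {
    lr <- survival::survdiff(survival::Surv(tt, event) ~ group)
    chisq <- unname(lr$chisq)
    lr_p <- stats::pchisq(chisq, df = 1L, lower.tail = FALSE)
  }
  list(curves = curves, logrank_p = lr_p, chisq = chisq, groups = group)
}
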