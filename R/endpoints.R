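# Beta cell function endpoints: percent change of stimulated C-peptide AUC,
# truncated decline slopes, IDAA1c, remission durations, Jenks split.

#' Percent change from baseline of stimulated C-peptide AUC
#'
#' @param course a [clinical_course()] with a C-peptide AUC series and
#'   baseline AUC > 0.
#' @return named numeric: percent change at each post-baseline visit
#'   (names are visit months).
#' @export
percent_change_auc <- function(course) {
  auc <- course$cpeptide_auc_nmol_l
  if (is.null(auc)) stop("no C-peptide series for ", course$participant_id)
  if (is.na(auc[1L]) || auc[1L] <= 0) {
    stop("baseline AUC must be positive for ", course$participant_id)
  }
  tv <- course$visit_times_months
  out <- 100 * (auc - auc[1L]) / auc[1L]
  stats::setNames(out[-1L], tv[-1L])
}

#' Rate of C-peptide decline by truncated linear regression
#'
#' Ordinary least squares of the AUC series (nmol/l, or percent change per
#' `outcome`) on time in years, fitted to the visits up to and including the
#' first visit at which the AUC reaches the detection floor; the run of
#' floor values after loss of secretion would otherwise attenuate the
#' fitted slope. `truncate = FALSE` fits all visits.
#'
#' @param course a [clinical_course()].
#' @param floor detection floor (nmol/l) triggering truncation, default 0.
#' @param truncate drop visits after the floor is first reached.
#' @param outcome fit absolute AUC (`"auc"`) or percent change from
#'   baseline (`"pct_change"`).
#' @return slope per year (more negative = faster decline).
#' @export
cpeptide_slope <- function(course, floor = 0, truncate = TRUE,
                           outcome = c("auc", "pct_change")) {
  outcome <- match.arg(outcome)
  auc <- course$cpeptide_auc_nmol_l
  if (is.null(auc)) stop("no C-peptide series for ", course$participant_id)
  tv <- course$visit_times_months
  ok <- !is.na(auc)
  auc <- auc[ok]; tv <- tv[ok]
  if (truncate) {
    hit <- which(auc <= floor)
    if (length(hit)) {
      keep <- seq_len(hit[1L])
      auc <- auc[keep]; tv <- tv[keep]
    }
  }
  if (length(auc) < 2L) stop("fewer than 2 usable visits for ",
                             course$participant_id)
  y <- if (outcome == "pct_change") 100 * (auc - auc[1L]) / auc[1L] else auc
  unname(stats::coef(stats::lm(y ~ I(tv / 12)))[2L])
}

#' Insulin-dose-adjusted HbA1c
#'
#' IDAA1c = HbA1c (%) + 4 x daily insulin dose (U per kg per day); values
#' at or below 9 indicate partial remission.
#'
#' @param hba1c_percent HbA1c in percent.
#' @param insulin_u_per_kg_day weight-normalised daily insulin dose.
#' @return IDAA1c value(s).
#' @export
idaa1c <- function(hba1c_percent, insulin_u_per_kg_day) {
  if (any(hba1c_percent < 0, na.rm = TRUE) ||
      any(insulin_u_per_kg_day < 0, na.rm = TRUE)) {
    stop("inputs must be non-negative")
  }
  hba1c_percent + 4 * insulin_u_per_kg_day
}

#' Partial-remission duration from a clinical course
#'
#' Remission persists while stimulated C-peptide AUC stays at or above the
#' floor (`mode = "cpeptide"`, 0.2 nmol/l) or while IDAA1c stays at or below
#' the cut (`mode = "idaa1c"`, 9). The duration is the last visit at which
#' the criterion held before its first violation (0 if violated at the
#' first post-baseline assessment); it is censored when the criterion still
#' holds at the final visit. Visits with a missing criterion value are
#' skipped.
#'
#' @param course a [clinical_course()].
#' @param mode `"cpeptide"` or `"idaa1c"`.
#' @param th thresholds list (floor 0.2 nmol/l; IDAA1c max 9).
#' @return list with `months` and `censored`.
#' @export
remission_duration <- function(course, mode = c("cpeptide", "idaa1c"),
                               th = default_thresholds()) {
  mode <- match.arg(mode)
  tv <- course$visit_times_months
  if (mode == "cpeptide") {
    series <- course$cpeptide_auc_nmol_l
    if (is.null(series)) stop("no C-peptide series for ",
                              course$participant_id)
    ok <- series >= th$cpeptide_floor_nmol_l
  } else {
    if (is.null(course$hba1c_percent) ||
        is.null(course$insulin_u_per_kg_day)) {
      stop("no IDAA1c series for ", course$participant_id)
    }
    ok <- idaa1c(course$hba1c_percent,
                 course$insulin_u_per_kg_day) <= th$idaa1c_max
  }
  keep <- !is.na(ok)
  tv <- tv[keep]; ok <- ok[keep]
  if (length(tv) == 0L) stop("no usable visits for ", course$participant_id)
  viol <- which(!ok)
  if (length(viol) == 0L) {
    return(list(months = tv[length(tv)], censored = TRUE))
  }
  first <- viol[1L]
  list(months = if (first == 1L) 0 else tv[first - 1L], censored = FALSE)
}

#' Jenks natural-breaks split into two classes
#'
#' Finds the contiguous two-class split of the sorted values minimising the
#' total within-class sum of squared deviations from the class means.
#'
#' @param values numeric vector with at least two distinct values.
#' @return list with `break_value` (midpoint between the two classes on the
#'   sorted scale) and `labels` (1 = lower class, 2 = upper class, in input
#'   order).
#' @export
jenks_two_class <- function(values) {
  v <- as.numeric(values)
  if (length(unique(v)) < 2L) stop("need at least two distinct values")
  ord <- order(v)
  s <- v[ord]
  n <- length(s)
  ssd <- function(x) sum((x - mean(x))^2)
  cost <- vapply(seq_len(n - 1L), function(i) {
    ssd(s[seq_len(i)]) + ssd(s[(i + 1L):n])
  }, numeric(1L))
  cut <- which.min(cost)
  labels <- integer(n)
  labels[ord] <- rep(1:2, c(cut, n - cut))
  list(break_value = (s[cut] + s[cut + 1L]) / 2, labels = labels)
}

#' Compute all endpoints for a set of clinical courses
#'
#' @param courses list of [clinical_course()] objects.
#' @param th thresholds list.
#' @param remission_mode forwarded to [remission_duration()].
#' @param slope_floor forwarded to [cpeptide_slope()] as `floor`.
#' @return data.frame with one row per participant: decline_slope,
#'   remission_months, remission_censored, arm, and one `pct_m<t>` column
#'   per post-baseline visit.
#' @export
endpoint_records <- function(courses, th = default_thresholds(),
                             remission_mode = c("cpeptide", "idaa1c"),
                             slope_floor = 0) {
  remission_mode <- match.arg(remission_mode)
  rows <- lapply(courses, function(cc) {
    pct <- percent_change_auc(cc)
    rem <- remission_duration(cc, remission_mode, th)
    out <- data.frame(participant_id = cc$participant_id,
                      arm = cc$arm,
                      decline_slope = cpeptide_slope(cc, floor = slope_floor),
                      remission_months = rem$months,
                      remission_censored = rem$censored,
                      stringsAsFactors = FALSE)
    for (nm in names(pct)) out[[paste0("pct_m", nm)]] <- pct[[nm]]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
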