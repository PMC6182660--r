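# Residual-based selection of treatment responders and matched placebo
# rapid progressors.

#' Fit placebo reference regression lines
#'
#' One ordinary-least-squares line of percent change from baseline
#' C-peptide AUC on baseline index per post-baseline timepoint, plus one
#' line for the decline slope. The residual SD about each line (SD of
#' placebo residuals) defines the SD unit of the responder criteria.
#' Timepoints with fewer than 3 placebo observations are omitted with a
#' warning.
#'
#' @param placebo_scores index scores of placebo participants.
#' @param placebo_endpoints [endpoint_records()] rows of the placebo arm.
#' @return data.frame with timepoint (months, or `"slope"`), intercept,
#'   slope, residual_sd, n.
#' @export
fit_reference_lines <- function(placebo_scores, placebo_endpoints) {
  idx <- placebo_scores$value[match(placebo_endpoints$participant_id,
                                    placebo_scores$sample_id)]
  cols <- c(grep("^pct_m", names(placebo_endpoints), value = TRUE),
            "decline_slope")
  labels <- c(sub("^pct_m", "", grep("^pct_m", names(placebo_endpoints),
                                     value = TRUE)), "slope")
  rows <- list()
  for (j in seq_along(cols)) {
    y <- placebo_endpoints[[cols[j]]]
    ok <- !is.na(y) & !is.na(idx)
    if (sum(ok) < 3L) {
      warning("reference line omitted (<3 placebo points): ", labels[j])
      next
    }
    fit <- stats::lm(y[ok] ~ idx[ok])
    res_sd <- stats::sd(stats::residuals(fit))
    rows[[length(rows) + 1L]] <- data.frame(
      timepoint = labels[j],
      intercept = unname(stats::coef(fit)[1L]),
      slope = unname(stats::coef(fit)[2L]),
      residual_sd = res_sd, n = sum(ok),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# residuals of one arm's endpoints about the placebo reference lines,
# in SD units; rows = participants, cols = reference-line timepoints
residuals_in_sd_units <- function(scores, endpoints, lines) {
  idx <- scores$value[match(endpoints$participant_id, scores$sample_id)]
  out <- vapply(seq_len(nrow(lines)), function(j) {
    ln <- lines[j, ]
    col <- if (ln$timepoint == "slope") "decline_slope"
           else paste0("pct_m", ln$timepoint)
    if (ln$residual_sd <= 0) stop("degenerate residual SD at reference line ",
                                  ln$timepoint)
    (endpoints[[col]] - (ln$intercept + ln$slope * idx)) / ln$residual_sd
  }, numeric(nrow(endpoints)))
  matrix(out, nrow = nrow(endpoints), ncol = nrow(lines))
}

#' Select treatment responders against the placebo reference lines
#'
#' A treated participant is a responder when their outcome lies more than
#' `th$responder_sd_timepoint` SD above the placebo per-timepoint line at
#' `th$responder_min_timepoints` or more timepoints AND more than
#' `th$responder_sd_slope` SD above the placebo decline-slope line. "Above"
#' means better-preserved C-peptide. Missing visits do not count either
#' way.
#'
#' @param treated_scores index scores of treated participants.
#' @param treated_endpoints [endpoint_records()] rows of the treated arm.
#' @param lines output of [fit_reference_lines()] (must contain at least 3
#'   timepoint lines and the slope line).
#' @param th thresholds list.
#' @return list with `responders` (participant ids) and `criteria`
#'   (per-participant residuals in SD units plus the two criterion flags).
#' @export
select_responders <- function(treated_scores, treated_endpoints, lines,
                              th = default_thresholds()) {
  tp_lines <- lines[lines$timepoint != "slope", , drop = FALSE]
  sl_line <- lines[lines$timepoint == "slope", , drop = FALSE]
  if (nrow(tp_lines) < 3L || nrow(sl_line) != 1L) {
    stop("need >= 3 timepoint lines and the slope line")
  }
  z_tp <- residuals_in_sd_units(treated_scores, treated_endpoints, tp_lines)
  z_sl <- residuals_in_sd_units(treated_scores, treated_endpoints, sl_line)
  n_above <- rowSums(z_tp > th$responder_sd_timepoint, na.rm = TRUE)
  crit1 <- n_above >= th$responder_min_timepoints
  crit2 <- as.vector(z_sl) > th$responder_sd_slope
  sel <- crit1 & crit2
  criteria <- data.frame(participant_id = treated_endpoints$participant_id,
                         z_tp, slope_z = as.vector(z_sl),
                         n_timepoints_above = n_above,
                         crit_timepoints = crit1, crit_slope = crit2,
                         stringsAsFactors = FALSE)
  colnames(criteria)[1L + seq_len(nrow(tp_lines))] <-
    paste0("z_m", tp_lines$timepoint)
  list(responders = treated_endpoints$participant_id[sel],
       criteria = criteria)
}

#' Match placebo rapid progressors to selected responders
#'
#' Eligible placebos lie at or below the placebo decline-slope reference
#' line (slope-line residual <= 0). Matching on baseline index is one-to-one
#' without replacement and minimises the total absolute index distance
#' (exact one-dimensional assignment, computed by dynamic programming over
#' the sorted index values); up to `n_matches` placebos are returned.
#'
#' @param selected participant ids of the selected treated responders.
#' @param placebo_scores index scores of the placebo pool.
#' @param placebo_endpoints [endpoint_records()] rows of the placebo arm.
#' @param treated_scores index scores providing the responders' indices.
#' @param lines reference lines (for the slope line).
#' @param n_matches maximum number of matched placebos.
#' @return character vector of matched placebo participant ids.
#' @export
match_placebos <- function(selected, placebo_scores, placebo_endpoints,
                           treated_scores, lines,
                           n_matches = length(selected)) {
  sl_line <- lines[lines$timepoint == "slope", , drop = FALSE]
  if (nrow(sl_line) != 1L) stop("slope reference line required")
  z_sl <- as.vector(residuals_in_sd_units(placebo_scores, placebo_endpoints,
                                          sl_line))
  eligible <- placebo_endpoints$participant_id[!is.na(z_sl) & z_sl <= 0]
  if (length(eligible) == 0L) stop("no eligible placebo participant")
  pool_idx <- placebo_scores$value[match(eligible, placebo_scores$sample_id)]
  sel_idx <- treated_scores$value[match(selected, treated_scores$sample_id)]
  m_target <- min(n_matches, length(eligible), length(selected))
  if (m_target == 0L) return(character(0))
  w <- sort(sel_idx)
  p_ord <- order(pool_idx)
  p <- pool_idx[p_ord]
  nw <- length(w); np <- length(p)
  # f[i, j, k]: min cost matching k pairs from wants i.. and pools j..
  # (sorted order makes the optimal matching order-preserving)
  inf <- Inf
  f <- array(inf, c(nw + 1L, np + 1L, m_target + 1L))
  f[, , 1L] <- 0
  for (i in nw:1L) for (j in np:1L) for (k in seq_len(m_target)) {
    best <- min(f[i + 1L, j, k + 1L], f[i, j + 1L, k + 1L],
                abs(w[i] - p[j]) + f[i + 1L, j + 1L, k])
    f[i, j, k + 1L] <- best
  }
  # backtrack to recover the matched pool members
  matched_j <- integer(0)
  i <- 1L; j <- 1L; k <- m_target
  while (k > 0L) {
    cur <- f[i, j, k + 1L]
    if (j <= np && i <= nw &&
        isTRUE(all.equal(cur, abs(w[i] - p[j]) + f[i + 1L, j + 1L, k]))) {
      matched_j <- c(matched_j, j)
      i <- i + 1L; j <- j + 1L; k <- k - 1L
    } else if (i <= nw && cur == f[i + 1L, j, k + 1L]) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  eligible[p_ord[matched_j]]
}
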