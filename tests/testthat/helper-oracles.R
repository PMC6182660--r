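# Independent oracle implementations and small utilities shared by the
# test files. Each oracle is written directly from the defining formula and
# stays independent of the package code paths it checks.

# adjusted Rand index between two labelings
rand_index_adj <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_rows <- sum(choose(rowSums(tab), 2))
  sum_cols <- sum(choose(colSums(tab), 2))
  sum_cells <- sum(choose(tab, 2))
  expected <- sum_rows * sum_cols / choose(n, 2)
  (sum_cells - expected) / ((sum_rows + sum_cols) / 2 - expected)
}

# Benjamini-Hochberg step-up by direct application of the definition:
# q_(i) = min_{j >= i} p_(j) * n / j, reported in input order
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[ord] * n / seq_len(n)))))
  out <- numeric(n)
  out[ord] <- q_sorted
  out
}

# AUC by exhaustive enumeration of positive/negative pairs
auc_oracle <- function(pos, neg) {
  wins <- 0
  for (x in pos) for (y in neg) {
    wins <- wins + if (x > y) 1 else if (x == y) 0.5 else 0
  }
  wins / (length(pos) * length(neg))
}

# two-class natural-breaks split by exhaustive minimisation
jenks_oracle <- function(v) {
  s <- sort(v)
  n <- length(s)
  ssd <- function(x) sum((x - mean(x))^2)
  costs <- sapply(seq_len(n - 1), function(i) {
    ssd(s[1:i]) + ssd(s[(i + 1):n])
  })
  cut <- which.min(costs)
  (s[cut] + s[cut + 1]) / 2
}

# Kaplan-Meier product-limit estimate computed by hand at event times
km_oracle <- function(time, event) {
  ut <- sort(unique(time[event]))
  s <- 1
  out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event)
    s <- s * (1 - d / at_risk)
    out[i] <- s
  }
  data.frame(time = ut, surv = out)
}

# topological overlap by direct summation
tom_oracle <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { out[i, j] <- 1; next }
    l <- sum(a[i, ] * a[, j])
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# straightforward re-implementation of the two responder criteria
responder_oracle <- function(idx, pct, slope, lines_tp, line_sl,
                             sd_mult_tp = 1.5, min_tp = 3, sd_mult_sl = 1) {
  n_above <- integer(length(idx))
  for (j in seq_len(nrow(lines_tp))) {
    pred <- lines_tp$intercept[j] + lines_tp$slope[j] * idx
    z <- (pct[, j] - pred) / lines_tp$residual_sd[j]
    n_above <- n_above + as.integer(!is.na(z) & z > sd_mult_tp)
  }
  pred_sl <- line_sl$intercept + line_sl$slope * idx
  z_sl <- (slope - pred_sl) / line_sl$residual_sd
  which(n_above >= min_tp & z_sl > sd_mult_sl)
}

# small helper: expression matrix with sequential probe/sample names
make_matrix <- function(values, probes = NULL, samples = NULL) {
  values <- as.matrix(values)
  if (is.null(probes)) probes <- sprintf("P%03d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("S%03d", seq_len(ncol(values)))
  expression_matrix(values, probes, samples)
}

# traits table used by the module pipeline on a generated trial
trial_traits <- function(trial, scores, endpoints) {
  ids <- colnames(trial$matrix)
  data.frame(
    baseline_auc = sapply(trial$clinical[ids],
                          function(cc) cc$cpeptide_auc_nmol_l[1]),
    decline_slope = endpoints$decline_slope[
      match(ids, endpoints$participant_id)],
    age = trial$samples$age_years[match(ids, trial$samples$sample_id)],
    index = scores$value[match(ids, scores$sample_id)]
  )
}
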