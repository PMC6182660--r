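# small builders for endpoint frames used by the stratification tests
ep_frame <- function(ids, arm, pct, slope) {
  out <- data.frame(participant_id = ids, arm = arm,
                    decline_slope = slope, remission_months = 12,
                    remission_censored = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(pct))) {
    out[[paste0("pct_m", c(3, 6, 12, 18, 24)[j])]] <- pct[, j]
  }
  out
}

test_that("placebo reference lines recover the generating slope", {
  set.seed(51)
  n <- 40
  idx <- rnorm(n)
  pct <- sapply(1:5, function(j) -10 * j - 0.85 * idx + rnorm(n, sd = 1))
  slope <- -0.2 - 0.1 * idx + rnorm(n, sd = 0.1)
  ep <- ep_frame(sprintf("pl%02d", 1:n), "placebo", pct, slope)
  sc <- data.frame(sample_id = ep$participant_id, value = idx)
  lines <- fit_reference_lines(sc, ep)
  expect_equal(nrow(lines), 6L)
  tp <- lines[lines$timepoint != "slope", ]
  expect_true(all(abs(tp$slope - (-0.85)) < 0.8))
  expect_true(all(tp$residual_sd > 0))
  # fewer than three points drops a line with a warning
  ep_na <- ep
  ep_na$pct_m3[-(1:2)] <- NA
  expect_warning(fit_reference_lines(sc, ep_na), "omitted")
})

test_that("responder criteria are applied jointly and literally", {
  lines <- data.frame(timepoint = c("3", "6", "12", "18", "24", "slope"),
                      intercept = c(-5, -10, -20, -30, -40, -0.2),
                      slope = -1, residual_sd = c(rep(2, 5), 0.1))
  mk <- function(z_tp, z_sl, idx = 0) {
    pct <- matrix(rep(lines$intercept[1:5] + lines$slope[1:5] * idx,
                      each = 1), 1) + z_tp * 2
    ep <- ep_frame("t1", "treated", pct,
                   lines$intercept[6] + lines$slope[6] * idx + z_sl * 0.1)
    sc <- data.frame(sample_id = "t1", value = idx)
    select_responders(sc, ep, lines)$responders
  }
  # exactly on every line: not selected
  expect_length(mk(rep(0, 5), 0), 0L)
  # +2 SD at three timepoints and +1.5 SD on the slope line: selected
  expect_equal(mk(c(2, 2, 2, 0, 0), 1.5), "t1")
  # only two timepoints above despite a strong slope: fails criterion one
  expect_length(mk(c(2, 2, 0, 0, 0), 2), 0L)
  # three timepoints above but on the slope line: fails criterion two
  expect_length(mk(c(2, 2, 2, 0, 0), 0.5), 0L)
  # degenerate residual SD is an error
  bad <- lines; bad$residual_sd[1] <- 0
  ep <- ep_frame("t1", "treated", matrix(0, 1, 5), 0)
  expect_error(select_responders(data.frame(sample_id = "t1", value = 0),
                                 ep, bad), "degenerate")
})

test_that("selection agrees with an independent re-implementation on random instances", {
  set.seed(52)
  th <- default_thresholds()
  for (i in 1:1000) {
    n <- sample(3:12, 1)
    idx <- rnorm(n)
    lines <- data.frame(timepoint = c("3", "6", "12", "18", "24", "slope"),
                        intercept = rnorm(6, -10),
                        slope = rnorm(6),
                        residual_sd = runif(6, 0.5, 3))
    pct <- matrix(rnorm(n * 5, -10, 6), n)
    if (i %% 3 == 0) pct[sample(length(pct), 3)] <- NA
    slope <- rnorm(n, -0.2, 0.5)
    ep <- ep_frame(sprintf("t%02d", 1:n), "treated", pct, slope)
    sc <- data.frame(sample_id = ep$participant_id, value = idx)
    got <- select_responders(sc, ep, lines, th)$responders
    want <- ep$participant_id[responder_oracle(
      idx, pct, slope, lines[1:5, ], lines[6, ],
      th$responder_sd_timepoint, th$responder_min_timepoints,
      th$responder_sd_slope)]
    expect_identical(got, want)
  }
})

test_that("selection is monotone in the timepoint threshold", {
  set.seed(53)
  lines <- data.frame(timepoint = c("3", "6", "12", "18", "24", "slope"),
                      intercept = -10, slope = -1,
                      residual_sd = c(rep(2, 5), 0.1))
  n <- 30
  idx <- rnorm(n)
  pct <- matrix(-10 - idx + rnorm(n * 5, sd = 4), n)
  ep <- ep_frame(sprintf("t%02d", 1:n), "treated", pct,
                 -10 - idx + rnorm(n, sd = 0.2))
  sc <- data.frame(sample_id = ep$participant_id, value = idx)
  strict <- select_responders(sc, ep, lines, default_thresholds())
  loose <- select_responders(sc, ep, lines,
                             default_thresholds(responder_sd_timepoint = 1.0))
  expect_true(all(strict$responders %in% loose$responders))
})

test_that("placebo matching respects eligibility and minimises total distance", {
  lines <- data.frame(timepoint = "slope", intercept = 0, slope = 0,
                      residual_sd = 1)
  ep <- ep_frame(c("p1", "p2", "p3"), "placebo",
                 matrix(0, 3, 5), c(0, 0.5, -1))
  sc_pl <- data.frame(sample_id = c("p1", "p2", "p3"),
                      value = c(0.1, 0.1, 2))
  sc_tr <- data.frame(sample_id = "t1", value = 0.1)
  # p2 sits above the slope line and is ineligible; p1 at 0 is boundary-
  # eligible and closest
  got <- match_placebos("t1", sc_pl, ep, sc_tr, lines, n_matches = 1L)
  expect_equal(got, "p1")
  # matching equals the exhaustive minimum-total-distance assignment
  set.seed(54)
  for (i in 1:200) {
    npool <- sample(2:8, 1); nsel <- sample(1:min(4, npool), 1)
    pool_idx <- round(rnorm(npool), 2)
    sel_idx <- round(rnorm(nsel), 2)
    ep <- ep_frame(sprintf("p%d", 1:npool), "placebo",
                   matrix(0, npool, 5), rep(-1, npool))
    sc_pl <- data.frame(sample_id = ep$participant_id, value = pool_idx)
    sc_tr <- data.frame(sample_id = sprintf("t%d", 1:nsel),
                        value = sel_idx)
    got <- match_placebos(sc_tr$sample_id, sc_pl, ep, sc_tr, lines)
    expect_length(got, nsel)
    # exhaustive assignment oracle over pool subsets and permutations
    idxperm <- function(v) {
      if (length(v) <= 1) return(list(v))
      out <- list()
      for (j in seq_along(v)) {
        for (rest in idxperm(v[-j])) out <- c(out, list(c(v[j], rest)))
      }
      out
    }
    best <- Inf
    for (cmb in utils::combn(npool, nsel, simplify = FALSE)) {
      for (pp in idxperm(cmb)) {
        best <- min(best, sum(abs(sel_idx - pool_idx[pp])))
      }
    }
    # within the returned set the optimal pairing is order-preserving
    pool_sub <- sc_pl$value[match(got, sc_pl$sample_id)]
    got_cost <- sum(abs(sort(sel_idx) - sort(pool_sub)))
    expect_equal(got_cost, best, tolerance = 1e-9)
  }
  # no eligible placebo is an error
  ep_bad <- ep_frame("p1", "placebo", matrix(0, 1, 5), 1)
  expect_error(match_placebos("t1", data.frame(sample_id = "p1", value = 0),
                              ep_bad, sc_tr, lines), "eligible")
})

test_that("planted responders are found with high sensitivity and specificity", {
  sens <- spec <- numeric(0)
  for (s in 101:112) {
    tr <- generate_trial(simulation_config(seed = s))
    sc <- compute_index(tr$matrix, tr$truth$partition)
    ep <- endpoint_records(tr$clinical, remission_mode = "idaa1c")
    pl <- ep$arm == "placebo"
    lines <- fit_reference_lines(sc[sc$sample_id %in%
                                      ep$participant_id[pl], ], ep[pl, ])
    sel <- select_responders(sc[sc$sample_id %in%
                                  ep$participant_id[!pl], ], ep[!pl, ],
                             lines)$responders
    truth <- names(tr$truth$responder)[tr$truth$responder]
    non <- setdiff(ep$participant_id[!pl], truth)
    sens <- c(sens, mean(truth %in% sel))
    spec <- c(spec, 1 - mean(non %in% sel))
  }
  expect_gte(mean(sens), 0.9)
  expect_gte(mean(spec), 0.9)
})
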