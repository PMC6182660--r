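# Synthetic cohort generator. Plants the statistical structure the analysis
# assumes: opposed inflammatory/regulatory programs across four
# cross-sectional cohorts, a two-arm trial with index-coupled placebo
# outcomes, Weibull remission times, latent subgroups carried by
# co-expression modules, and a preserved-decline responder subpopulation.

#' Simulation configuration
#'
#' Defaults encode the study conditions: cohort sizes 47/42/30/44
#' (recent-onset diabetes, low-HLA-risk siblings, high-HLA-risk siblings,
#' unrelated healthy controls), a 54:20 treated:placebo trial, a planted
#' 100 + 250 probe inflammatory/regulatory signature with a 0.6 log2 effect
#' against 0.5 log2 noise, a placebo-arm coupling of -0.85 percentage points
#' of C-peptide AUC change per index unit, a Weibull remission-time model
#' with shape 1.5 and -0.8 log-scale effect per index unit, and four latent
#' participant subgroups.
#'
#' @param n_probes total probes on the synthetic array.
#' @param n_signal_inflammatory,n_signal_regulatory planted signature sizes.
#' @param cohort_sizes named integer vector for ROT1D/LRS/HRS/uHC.
#' @param trial_n_treated,trial_n_placebo trial arm sizes.
#' @param effect_size_log2 cohort shift of signal probes (log2 units).
#' @param noise_sd_log2 per-value expression noise SD (log2 units).
#' @param placebo_coupling_slope percent-change points per index unit in the
#'   placebo arm (treated arm is decoupled, slope 0).
#' @param weibull_shape,weibull_log_scale_coef remission-time model: shape
#'   parameter and log-scale coefficient per index unit.
#' @param n_subgroups latent participant subgroups.
#' @param n_responders treated participants planted with preserved decline.
#' @param treatment_benefit scale of the subgroup-specific treated benefit
#'   (1 = default magnitudes, 0 = no benefit).
#' @param outcome_noise_sd visit-level outcome noise (percentage points).
#' @param module_size probes per planted co-expression module.
#' @param seed integer seed controlling all randomness.
#' @return named list of class `simulation_config`.
#' @export
simulation_config <- function(n_probes = 5000L,
                              n_signal_inflammatory = 100L,
                              n_signal_regulatory = 250L,
                              cohort_sizes = c(ROT1D = 47L, LRS = 42L,
                                               HRS = 30L, uHC = 44L),
                              trial_n_treated = 54L,
                              trial_n_placebo = 20L,
                              effect_size_log2 = 0.6,
                              noise_sd_log2 = 0.5,
                              placebo_coupling_slope = -0.85,
                              weibull_shape = 1.5,
                              weibull_log_scale_coef = -0.8,
                              n_subgroups = 4L,
                              n_responders = 8L,
                              treatment_benefit = 1,
                              outcome_noise_sd = 0.8,
                              module_size = 60L,
                              seed = 1L) {
  cfg <- list(n_probes = as.integer(n_probes),
              n_signal_inflammatory = as.integer(n_signal_inflammatory),
              n_signal_regulatory = as.integer(n_signal_regulatory),
              cohort_sizes = cohort_sizes,
              trial_n_treated = as.integer(trial_n_treated),
              trial_n_placebo = as.integer(trial_n_placebo),
              effect_size_log2 = effect_size_log2,
              noise_sd_log2 = noise_sd_log2,
              placebo_coupling_slope = placebo_coupling_slope,
              weibull_shape = weibull_shape,
              weibull_log_scale_coef = weibull_log_scale_coef,
              n_subgroups = as.integer(n_subgroups),
              n_responders = as.integer(n_responders),
              treatment_benefit = treatment_benefit,
              outcome_noise_sd = outcome_noise_sd,
              module_size = as.integer(module_size),
              seed = as.integer(seed))
  n_signal <- cfg$n_signal_inflammatory + cfg$n_signal_regulatory
  if (n_signal >= cfg$n_probes) stop("signal probes must be < n_probes")
  if (any(cfg$cohort_sizes <= 0) || cfg$trial_n_treated <= 0 ||
      cfg$trial_n_placebo <= 0) stop("all sizes must be positive")
  if (cfg$noise_sd_log2 <= 0) stop("noise SD must be positive")
  class(cfg) <- "simulation_config"
  cfg
}

probe_names <- function(n) sprintf("P%05d", seq_len(n))

# Per-probe baseline log2 means: a low-intensity tail (so the intensity
# filter has work to do) plus a broad expressed component. The first
# `n_keep_high` probes (signature and module carriers) always come from the
# expressed component.
draw_probe_means <- function(n, n_keep_high) {
  low <- stats::runif(n) < 0.15
  low[seq_len(n_keep_high)] <- FALSE
  mu <- ifelse(low, stats::runif(n, 1.0, 2.2), stats::runif(n, 4.5, 12))
  mu
}

# Per-probe noise scales: array probes have heterogeneous variances, so the
# noise SD varies uniformly within +/-40% of the configured level (the
# configured value is the mean scale).
draw_probe_sds <- function(n, base_sd) {
  stats::runif(n, 0.6 * base_sd, 1.4 * base_sd)
}

# Latent index -> expression link: inflammatory signal probes shift by
# +index/2 and regulatory ones by -index/2, so the centered set-mean
# contrast recovers the index up to noise.
index_shift_matrix <- function(index, infl_idx, reg_idx, n_probes) {
  shift <- matrix(0, n_probes, length(index))
  shift[infl_idx, ] <- rep(index / 2, each = length(infl_idx))
  shift[reg_idx, ] <- rep(-index / 2, each = length(reg_idx))
  shift
}

#' Generate the four cross-sectional cohorts
#'
#' Inflammatory signal probes are elevated in the diabetes (full effect) and
#' low-HLA-risk sibling (half effect) cohorts; regulatory signal probes in
#' the high-HLA-risk sibling (full) and unrelated control (half) cohorts.
#' The graded multipliers reproduce the observed cohort gradient of the
#' inflammatory index (diabetes > low-risk siblings > controls > high-risk
#' siblings). All remaining probes are exchangeable noise around their
#' baseline means.
#'
#' @param config a [simulation_config()].
#' @return list with `matrix` (expression matrix), `samples` (sample table)
#'   and `truth` (planted partition, per-cohort shift profiles).
#' @export
generate_cross_sectional <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_inf <- config$n_signal_inflammatory
  n_reg <- config$n_signal_regulatory
  infl_idx <- seq_len(n_inf)
  reg_idx <- n_inf + seq_len(n_reg)
  probes <- probe_names(config$n_probes)

  sizes <- config$cohort_sizes[c("ROT1D", "LRS", "HRS", "uHC")]
  cohort <- rep(names(sizes), sizes)
  n_samp <- length(cohort)
  sample_ids <- sprintf("XS%03d", seq_len(n_samp))

  # cohort multipliers of the planted effect, per gene set
  infl_mult <- c(ROT1D = 1, LRS = 0.5, HRS = 0, uHC = 0)
  reg_mult <- c(ROT1D = 0, LRS = 0, HRS = 1, uHC = 0.5)

  mu <- draw_probe_means(config$n_probes, n_reg + n_inf)
  sdp <- draw_probe_sds(config$n_probes, config$noise_sd_log2)
  vals <- matrix(stats::rnorm(config$n_probes * n_samp),
                 config$n_probes, n_samp) * sdp + mu
  es <- config$effect_size_log2
  vals[infl_idx, ] <- vals[infl_idx, ] +
    rep(es * infl_mult[cohort], each = n_inf)
  vals[reg_idx, ] <- vals[reg_idx, ] +
    rep(es * reg_mult[cohort], each = n_reg)

  ages <- c(ROT1D = 10.0, LRS = 8.4, HRS = 8.6, uHC = 15.0)
  age_sd <- c(ROT1D = 2.9, LRS = 2.0, HRS = 1.9, uHC = 4.1)
  age <- pmax(2, stats::rnorm(n_samp, ages[cohort], age_sd[cohort]))

  samples <- sample_table(sample_ids, sample_ids, cohort, "none", 0, age)
  truth <- list(
    partition = gene_set_partition(probes[infl_idx], probes[reg_idx]),
    infl_multipliers = infl_mult, reg_multipliers = reg_mult,
    effect_size_log2 = es
  )
  list(matrix = expression_matrix(vals, probes, sample_ids),
       samples = samples, truth = truth)
}

# Helmert-style orthogonal subgroup contrast patterns, unit SD per column.
subgroup_patterns <- function(k) {
  if (k < 2L) return(matrix(0, k, 1L))
  h <- stats::contr.helmert(k)
  apply(h, 2L, function(col) col / stats::sd(col))
}

#' Generate a two-arm longitudinal trial cohort
#'
#' Each participant carries a latent inflammatory index drawn around a
#' subgroup-specific mean; the baseline expression signature encodes the
#' index through the planted inflammatory/regulatory partition, and six
#' planted co-expression modules carry (a) subgroup mean patterns and (b)
#' couplings to baseline C-peptide AUC and to the participant's rate of
#' decline. Placebo percent-change outcomes at 3/6/12/18/24 months have
#' conditional mean `placebo_coupling_slope * index` plus a declining visit
#' trajectory; treated outcomes are decoupled from the index (slope 0) with
#' a small subgroup-specific benefit, largest in the high-inflammation
#' subgroups. Remission times follow a Weibull accelerated-failure model,
#' log-scale linear in the index, administratively censored at 24 months and
#' encoded in each participant's IDAA1c series. A planted subset of treated
#' participants ("responders") progresses at a fraction of their expected
#' rate.
#'
#' @param config a [simulation_config()].
#' @return list with `matrix` (baseline expression), `samples`, `clinical`
#'   (list of [clinical_course()]) and `truth` (planted parameters).
#' @export
generate_trial <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  n_inf <- config$n_signal_inflammatory
  n_reg <- config$n_signal_regulatory
  infl_idx <- seq_len(n_inf)
  reg_idx <- n_inf + seq_len(n_reg)
  probes <- probe_names(config$n_probes)
  k <- config$n_subgroups

  n_tr <- config$trial_n_treated
  n_pl <- config$trial_n_placebo
  n <- n_tr + n_pl
  pid <- sprintf("T%03d", seq_len(n))
  arm <- sample(rep(c("treated", "placebo"), c(n_tr, n_pl)))

  subgroup <- sample.int(k, n, replace = TRUE)
  idx_means <- seq(-0.5, 0.6, length.out = k)
  index <- stats::rnorm(n, idx_means[subgroup], 0.2)

  # clinical substrate: baseline AUC, decline-rate multiplier, age --
  # independent of subgroup and index, as observed in the trial cohort
  auc0 <- exp(stats::rnorm(n, log(0.6), 0.25))
  decline_mult <- pmax(0.55, stats::rnorm(n, 1, 0.3))
  age <- pmin(35, pmax(8, stats::rnorm(n, 14.7, 6.8)))

  # planted responders: treated participants progressing at 20% of their
  # expected rate, drawn uniformly from the treated arm
  responder <- rep(FALSE, n)
  treated_idx <- which(arm == "treated")
  n_resp <- min(config$n_responders, length(treated_idx))
  responder[sample(treated_idx, n_resp)] <- TRUE
  kappa <- 0.2
  eff_mult <- decline_mult * ifelse(responder, kappa, 1)

  # subgroup-specific treated benefit: fractional slowing of the decline,
  # largest in the high-inflammation subgroups
  benefit <- config$treatment_benefit *
    c(0.01, 0.015, 0.04, 0.05)[pmin(subgroup, 4L)]
  eff_mult[arm == "treated" & !responder] <-
    eff_mult[arm == "treated" & !responder] *
    (1 - benefit[arm == "treated" & !responder])

  visits <- c(0, 3, 6, 12, 18, 24)
  traj <- c(0, -15, -30, -45, -60, -75)  # mean % change trajectory
  pct <- matrix(0, n, length(visits),
                dimnames = list(pid, paste0("m", visits)))
  for (j in 2:length(visits)) {
    coupling <- ifelse(arm == "placebo",
                       config$placebo_coupling_slope * index, 0)
    # visit-level noise has a component proportional to the accumulated
    # decline, so visits fluctuate independently around each participant's
    # own trajectory
    sd_j <- sqrt(config$outcome_noise_sd^2 + (0.16 * abs(traj[j]))^2)
    pct[, j] <- traj[j] * eff_mult + coupling + stats::rnorm(n, sd = sd_j)
  }
  auc <- auc0 * pmax(1 + pct / 100, 0.005)

  # Weibull remission times: log-scale linear in index, tied to baseline
  # AUC and to the decline-rate multiplier so that dynamic-test and IDAA1c
  # remission readouts co-vary
  log_scale <- log(14) + config$weibull_log_scale_coef * index +
    1.2 * log(auc0 / 0.6) - 1.2 * log(decline_mult)
  remission <- stats::rweibull(n, shape = config$weibull_shape,
                               scale = exp(log_scale))
  rem_censored <- remission > 24
  rem_obs <- pmin(remission, 24)

  # IDAA1c series crossing 9 after the remission time
  insulin <- matrix(stats::runif(n * length(visits), 0.3, 0.6), n)
  idaa <- matrix(8.3, n, length(visits)) +
    matrix(stats::rnorm(n * length(visits), sd = 0.15), n)
  for (j in seq_along(visits)) {
    late <- visits[j] > remission
    idaa[late, j] <- idaa[late, j] + 1.4
  }
  hba1c <- idaa - 4 * insulin

  clinical <- lapply(seq_len(n), function(i) {
    clinical_course(pid[i], visits, auc[i, ], hba1c[i, ], insulin[i, ],
                    arm = arm[i])
  })
  names(clinical) <- pid

  # baseline expression: index-coupled signature + planted modules + noise.
  # Three clinical-trait modules (two tracking baseline C-peptide AUC with
  # opposite signs, one the participant's rate of decline) plus k
  # subgroup-pattern modules, each elevated in the subgroup that "owns" it
  # (a zero-sum simplex across the pattern modules, so the subgroup
  # geometry is preserved under profile-wise centering). All pattern
  # modules additionally share an index component, mirroring the
  # observation that the clinically informative modules also track the
  # inflammatory/regulatory balance; that shared component is what makes
  # them index-correlated.
  n_mod <- 3L + k
  mod_idx <- lapply(seq_len(n_mod), function(m) {
    n_inf + n_reg + (m - 1L) * config$module_size + seq_len(config$module_size)
  })
  zsc <- function(x) (x - mean(x)) / stats::sd(x)
  factors <- matrix(0, n, n_mod)
  factors[, 1] <- 1.4 * zsc(auc0) + stats::rnorm(n, sd = 0.5)
  factors[, 2] <- -1.0 * zsc(auc0) + stats::rnorm(n, sd = 1.1)
  factors[, 3] <- -1.5 * zsc(auc0 * decline_mult) + stats::rnorm(n, sd = 0.5)
  own_sd <- sqrt((1 / k) * (1 - 1 / k))
  zI <- zsc(index)
  for (m in seq_len(k)) {
    own <- ((subgroup == m) - 1 / k) / own_sd
    # index component signed like the owner subgroup's index side, so the
    # owner contrast and the index never cancel in the eigengene
    s_m <- if (idx_means[m] >= mean(idx_means)) 1 else -1
    factors[, 3L + m] <- 1.5 * own + 0.9 * s_m * zI + stats::rnorm(n, sd = 0.3)
  }

  mu <- draw_probe_means(config$n_probes,
                         n_inf + n_reg + n_mod * config$module_size)
  sdp <- draw_probe_sds(config$n_probes, config$noise_sd_log2)
  vals <- matrix(stats::rnorm(config$n_probes * n),
                 config$n_probes, n) * sdp + mu
  vals <- vals + index_shift_matrix(index, infl_idx, reg_idx, config$n_probes)
  for (m in seq_len(n_mod)) {
    loading <- stats::runif(config$module_size, 0.5, 1.0)
    vals[mod_idx[[m]], ] <- vals[mod_idx[[m]], ] + outer(loading, factors[, m])
  }

  samples <- sample_table(pid, pid, "TRIAL", arm, 0, age)
  truth <- list(
    partition = gene_set_partition(probes[infl_idx], probes[reg_idx]),
    subgroup = stats::setNames(subgroup, pid),
    index = stats::setNames(index, pid),
    coupling_slope = config$placebo_coupling_slope,
    auc0 = stats::setNames(auc0, pid),
    decline_mult = stats::setNames(decline_mult, pid),
    responder = stats::setNames(responder, pid),
    remission_months = stats::setNames(rem_obs, pid),
    remission_censored = stats::setNames(rem_censored, pid),
    module_probes = stats::setNames(
      lapply(mod_idx, function(ii) probes[ii]),
      paste0("mod", seq_len(n_mod))),
    module_factors = factors,
    pct_change = pct
  )
  list(matrix = expression_matrix(vals, probes, pid),
       samples = samples, clinical = clinical, truth = truth)
}

#' Generate a pair of signed log2-ratio vectors with fixed concordance
#'
#' Emulates the comparison of a treatment-arm response signature with a
#' spike-in signature: exactly `round(concordant_fraction * n_probes)`
#' positions share the sign of the reference vector.
#'
#' @param n_probes number of probes.
#' @param concordant_fraction fraction of sign-matching positions in [0,1].
#' @param seed integer seed.
#' @return list with numeric vectors `a` (reference) and `b`.
#' @export
generate_paired_signatures <- function(n_probes, concordant_fraction, seed) {
  if (n_probes < 1L) stop("n_probes must be >= 1")
  if (concordant_fraction < 0 || concordant_fraction > 1) {
    stop("concordant_fraction must be in [0, 1]")
  }
  set.seed(seed)
  a <- stats::rnorm(n_probes)
  a[a == 0] <- 0.1
  mag <- abs(stats::rnorm(n_probes))
  n_conc <- round(concordant_fraction * n_probes)
  conc <- sample.int(n_probes) <= n_conc
  b <- ifelse(conc, sign(a), -sign(a)) * mag
  list(a = a, b = b)
}
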