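#' Construct a validated expression matrix
#'
#' An expression matrix holds log2-scale signal intensities (relative
#' fluorescence units) with probe sets in rows and samples in columns. It is
#' represented as a plain numeric matrix whose dimnames carry the probe and
#' sample identifiers, so that all of base R's matrix machinery applies.
#'
#' @param values numeric matrix, probes x samples.
#' @param probe_ids character vector of unique probe identifiers
#'   (defaults to `rownames(values)`).
#' @param sample_ids character vector of unique sample identifiers
#'   (defaults to `colnames(values)`).
#' @return a numeric matrix with validated dimnames.
#' @export
expression_matrix <- function(values, probe_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(probe_ids) || is.null(sample_ids)) {
    stop("expression matrix requires probe and sample identifiers")
  }
  rownames(values) <- as.character(probe_ids)
  colnames(values) <- as.character(sample_ids)
  validate_expression_matrix(values)
  values
}

#' Validate an expression matrix
#'
#' Checks uniqueness of probe and sample identifiers, dimension agreement and
#' finiteness of all values; errors name the offending identifier.
#'
#' @param x numeric matrix with probe rownames and sample colnames.
#' @return `x`, invisibly.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expression matrix must be a numeric matrix")
  }
  pid <- rownames(x)
  sid <- colnames(x)
  if (is.null(pid) || length(pid) != nrow(x)) {
    stop("probe identifier count does not match row count")
  }
  if (is.null(sid) || length(sid) != ncol(x)) {
    stop("sample identifier count does not match column count")
  }
  if (anyDuplicated(pid)) {
    stop("duplicate probe identifier: ", pid[duplicated(pid)][1L])
  }
  if (anyDuplicated(sid)) {
    stop("duplicate sample identifier: ", sid[duplicated(sid)][1L])
  }
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop("non-finite value at probe ", pid[bad[1L]],
         ", sample ", sid[bad[2L]])
  }
  invisible(x)
}

#' Cohort levels used throughout the pipeline
#'
#' ROT1D: recent-onset type 1 diabetes; LRS / HRS: autoantibody-negative
#' siblings with low / high HLA-risk haplotypes; uHC: unrelated healthy
#' controls; TRIAL: participants of the two-arm longitudinal trial.
#' @export
cohort_levels <- function() c("ROT1D", "LRS", "HRS", "uHC", "TRIAL")

#' Treatment arm levels
#' @export
arm_levels <- function() c("placebo", "treated", "none")

#' Construct a validated sample table
#'
#' @param sample_id,participant_id character vectors.
#' @param cohort factor/character in [cohort_levels()].
#' @param arm factor/character in [arm_levels()]; must be `"none"` exactly
#'   for non-TRIAL samples.
#' @param timepoint_months non-negative numeric.
#' @param age_years positive numeric.
#' @return a `data.frame` with one row per sample.
#' @export
sample_table <- function(sample_id, participant_id, cohort, arm,
                         timepoint_months, age_years) {
  st <- data.frame(
    sample_id = as.character(sample_id),
    participant_id = as.character(participant_id),
    cohort = as.character(cohort),
    arm = as.character(arm),
    timepoint_months = as.numeric(timepoint_months),
    age_years = as.numeric(age_years),
    stringsAsFactors = FALSE
  )
  validate_sample_table(st)
  st
}

#' Validate a sample table
#' @param st data.frame as returned by [sample_table()].
#' @return `st`, invisibly.
#' @export
validate_sample_table <- function(st) {
  required <- c("sample_id", "participant_id", "cohort", "arm",
                "timepoint_months", "age_years")
  missing_cols <- setdiff(required, names(st))
  if (length(missing_cols)) {
    stop("sample table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(st$sample_id)) {
    stop("duplicate sample_id: ", st$sample_id[duplicated(st$sample_id)][1L])
  }
  if (!all(st$cohort %in% cohort_levels())) {
    stop("unknown cohort label: ",
         st$cohort[!st$cohort %in% cohort_levels()][1L])
  }
  if (!all(st$arm %in% arm_levels())) {
    stop("unknown arm label: ", st$arm[!st$arm %in% arm_levels()][1L])
  }
  trial <- st$cohort == "TRIAL"
  if (any(st$arm[!trial] != "none")) {
    stop("arm must be 'none' for non-trial samples")
  }
  if (any(trial & st$arm == "none")) {
    stop("trial samples must carry a treatment arm")
  }
  if (any(st$timepoint_months < 0)) stop("negative timepoint")
  if (any(st$age_years <= 0)) stop("non-positive age")
  invisible(st)
}

#' Construct one participant's clinical course
#'
#' Stores the longitudinal measurements used for every beta cell function
#' endpoint: visit times, 2 h stimulated C-peptide AUC (nmol/l), and
#' optionally HbA1c (%) and weight-normalised insulin dose (U/kg/day).
#' A baseline (time 0) visit is required; visits are sorted ascending.
#'
#' @param participant_id string.
#' @param visit_times_months non-negative numeric, distinct.
#' @param cpeptide_auc_nmol_l non-negative numeric, same length as visits
#'   (or NULL when MMTTs were not performed).
#' @param hba1c_percent,insulin_u_per_kg_day optional per-visit numerics;
#'   NA marks a missing measurement at a visit.
#' @param arm `"placebo"`, `"treated"` or `"none"`.
#' @return an object of class `clinical_course`.
#' @export
clinical_course <- function(participant_id, visit_times_months,
                            cpeptide_auc_nmol_l = NULL,
                            hba1c_percent = NULL,
                            insulin_u_per_kg_day = NULL,
                            arm = "none") {
  tv <- as.numeric(visit_times_months)
  if (length(tv) == 0L) stop("no visits for participant ", participant_id)
  if (any(tv < 0)) stop("negative visit time for ", participant_id)
  if (anyDuplicated(tv)) stop("duplicated visit time for ", participant_id)
  ord <- order(tv)
  check_len <- function(x, nm) {
    if (!is.null(x) && length(x) != length(tv)) {
      stop(nm, " length does not match visit count for ", participant_id)
    }
    if (is.null(x)) NULL else as.numeric(x)[ord]
  }
  course <- structure(list(
    participant_id = as.character(participant_id),
    visit_times_months = tv[ord],
    cpeptide_auc_nmol_l = check_len(cpeptide_auc_nmol_l, "cpeptide_auc"),
    hba1c_percent = check_len(hba1c_percent, "hba1c"),
    insulin_u_per_kg_day = check_len(insulin_u_per_kg_day, "insulin"),
    arm = match.arg(arm, arm_levels())
  ), class = "clinical_course")
  if (course$visit_times_months[1L] != 0) {
    stop("baseline visit missing for participant ", participant_id)
  }
  if (!is.null(course$cpeptide_auc_nmol_l) &&
      any(course$cpeptide_auc_nmol_l < 0, na.rm = TRUE)) {
    stop("negative C-peptide AUC for ", participant_id)
  }
  course
}

#' @export
print.clinical_course <- function(x, ...) {
  cat("clinical course:", x$participant_id, "(", x$arm, "arm ),",
      length(x$visit_times_months), "visits at",
      paste(x$visit_times_months, collapse = "/"), "months\n")
  invisible(x)
}

#' Construct a gene-set partition
#'
#' The disjoint inflammatory and regulatory probe-identifier sets that define
#' the numerator and denominator of the composite inflammatory index.
#'
#' @param inflammatory_probes,regulatory_probes character vectors.
#' @return object of class `gene_set_partition`.
#' @export
gene_set_partition <- function(inflammatory_probes, regulatory_probes) {
  infl <- unique(as.character(inflammatory_probes))
  reg <- unique(as.character(regulatory_probes))
  if (length(infl) == 0L || length(reg) == 0L) {
    stop("both gene sets must be non-empty")
  }
  overlap <- intersect(infl, reg)
  if (length(overlap)) {
    stop("gene sets are not disjoint; shared probe: ", overlap[1L])
  }
  structure(list(inflammatory_probes = infl, regulatory_probes = reg),
            class = "gene_set_partition")
}

#' @export
print.gene_set_partition <- function(x, ...) {
  cat("gene-set partition:", length(x$inflammatory_probes), "inflammatory /",
      length(x$regulatory_probes), "regulatory probes\n")
  invisible(x)
}

#' Default analysis thresholds
#'
#' Collects every tunable cut-off of the pipeline with its published default:
#' differential induction (1.2-fold, i.e. |log2 ratio| > 0.263, FDR < 20%,
#' ANOVA alpha 0.05; response-signature mode p < 0.02, FDR <= 30%), the
#' tree-ensemble Gini importance cut (3.49, data-derived on the original
#' arrays), remission criteria (C-peptide floor 0.2 nmol/l; IDAA1c <= 9),
#' responder-selection rules (> 1.5 SD above the per-timepoint placebo lines
#' at >= 3 timepoints and > 1 SD above the decline-slope line), and network
#' settings (soft power 12, scale-free fit R^2 > 0.8, 7000 top-MAD probes,
#' low-intensity cut at max log2 < 4 RFU, 4 participant subgroups).
#'
#' @param ... named overrides of individual thresholds.
#' @return named list of thresholds.
#' @export
default_thresholds <- function(...) {
  th <- list(
    log2_fc = 0.263,
    diff_fdr = 0.20,
    diff_alpha = 0.05,
    response_alpha = 0.02,
    response_fdr = 0.30,
    gini_min = 3.49,
    cpeptide_floor_nmol_l = 0.2,
    idaa1c_max = 9.0,
    responder_sd_timepoint = 1.5,
    responder_min_timepoints = 3L,
    responder_sd_slope = 1.0,
    soft_power = 12L,
    scale_free_r2_min = 0.8,
    mad_keep = 7000L,
    low_intensity_log2_max = 4.0,
    n_subgroups = 4L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(th))
  if (length(unknown)) stop("unknown threshold: ", unknown[1L])
  th[names(dots)] <- dots
  if (any(unlist(th) <= 0)) stop("all thresholds must be strictly positive")
  th
}
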