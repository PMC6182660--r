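# Composite inflammatory index scoring, cohort comparison, ROC evaluation.

#' Compute the composite inflammatory index
#'
#' For each sample, the index is the mean log2 intensity over the
#' inflammatory probe set minus the mean over the regulatory set -- the log
#' of a ratio of geometric mean intensities. With `center = TRUE` (default)
#' each probe is first centered across samples, which places the scores on a
#' cohort-relative scale spanning negative to positive values; `center =
#' FALSE` uses raw log2 values, and `mode = "ratio"` returns the literal
#' ratio of arithmetic set means of unlogged intensities.
#'
#' @param matrix expression matrix.
#' @param partition [gene_set_partition()]; probes absent from the matrix
#'   are dropped (an error if a whole set disappears).
#' @param center center each probe across samples first.
#' @param mode `"log_contrast"` (default) or `"ratio"`.
#' @return data.frame with columns sample_id, value.
#' @export
compute_index <- function(matrix, partition, center = TRUE,
                          mode = c("log_contrast", "ratio")) {
  mode <- match.arg(mode)
  validate_expression_matrix(matrix)
  infl <- intersect(partition$inflammatory_probes, rownames(matrix))
  reg <- intersect(partition$regulatory_probes, rownames(matrix))
  if (length(infl) == 0L || length(reg) == 0L) {
    stop("a gene set has no probes in the matrix")
  }
  x <- matrix
  if (center) x <- x - rowMeans(x)
  if (mode == "ratio") {
    val <- colMeans(2 ^ x[infl, , drop = FALSE]) /
      colMeans(2 ^ x[reg, , drop = FALSE])
  } else {
    val <- colMeans(x[infl, , drop = FALSE]) -
      colMeans(x[reg, , drop = FALSE])
  }
  data.frame(sample_id = colnames(matrix), value = unname(val),
             stringsAsFactors = FALSE)
}

#' Pairwise cohort comparison of index scores
#'
#' Two-tailed unpaired Welch t tests between every cohort pair, with the
#' per-cohort mean and standard error.
#'
#' @param scores data.frame from [compute_index()].
#' @param samples sample table.
#' @return list with `cohorts` (mean, se, n per cohort) and `pairs`
#'   (cohort_a, cohort_b, t, p_value).
#' @export
compare_cohort_indices <- function(scores, samples) {
  st <- samples[match(scores$sample_id, samples$sample_id), ]
  by_cohort <- split(scores$value, st$cohort)
  small <- names(by_cohort)[vapply(by_cohort, length, 1L) < 2L]
  if (length(small)) {
    warning("cohort excluded with < 2 samples: ",
            paste(small, collapse = ", "))
    by_cohort <- by_cohort[!names(by_cohort) %in% small]
  }
  if (length(by_cohort) < 2L) stop("need >= 2 cohorts with >= 2 samples")
  summ <- data.frame(
    cohort = names(by_cohort),
    n = vapply(by_cohort, length, 1L),
    mean = vapply(by_cohort, mean, 1),
    se = vapply(by_cohort, function(v) stats::sd(v) / sqrt(length(v)), 1),
    stringsAsFactors = FALSE, row.names = NULL
  )
  prs <- utils::combn(names(by_cohort), 2L, simplify = FALSE)
  pairs <- do.call(rbind, lapply(prs, function(pr) {
    a <- by_cohort[[pr[1L]]]; b <- by_cohort[[pr[2L]]]
    if (stats::sd(c(a, b)) == 0) {
      tt <- list(statistic = c(t = 0), p.value = 1)
    } else {
      tt <- stats::t.test(a, b)
    }
    data.frame(cohort_a = pr[1L], cohort_b = pr[2L],
               t = unname(tt$statistic), p_value = tt$p.value,
               stringsAsFactors = FALSE)
  }))
  list(cohorts = summ, pairs = pairs)
}

#' ROC curve and AUC by the rank (Mann-Whitney) formulation
#'
#' AUC is the fraction of positive/negative score pairs ranked correctly,
#' with ties counted one half. Curve points are reported at every distinct
#' threshold.
#'
#' @param scores data.frame from [compute_index()] (or any sample_id/value
#'   pairs).
#' @param positive character vector of sample ids forming the positive
#'   class.
#' @return list with `auc` and a `curve` data.frame (threshold, tpr, fpr).
#' @export
roc_auc <- function(scores, positive) {
  is_pos <- scores$sample_id %in% positive
  x <- scores$value[is_pos]
  y <- scores$value[!is_pos]
  if (length(x) == 0L || length(y) == 0L) {
    stop("both classes must be non-empty")
  }
  r <- rank(c(x, y), ties.method = "average")
  auc <- (sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2) /
    (length(x) * length(y))
  thr <- c(Inf, sort(unique(scores$value), decreasing = TRUE))
  curve <- data.frame(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(x >= t), 1),
    fpr = vapply(thr, function(t) mean(y >= t), 1)
  )
  list(auc = auc, curve = curve)
}
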