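# Differential induction, multiple-testing control, tree-ensemble
# importance, the dual-criteria signature, the inflammatory/regulatory
# partition, and signature concordance.

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false-discovery-rate adjustment; the returned values are monotone
#' non-decreasing in the sorted order and reported in input order.
#'
#' @param p_values numeric vector of p values in [0, 1].
#' @return adjusted values in [0, 1].
#' @export
bh_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Differential induction between sample groups
#'
#' For every probe and every contrast, reports the log2 ratio (difference of
#' group means on the log2 scale), a p value, and the within-contrast
#' Benjamini-Hochberg FDR. Pairwise mode ("welch") runs two-sided Welch t
#' tests for every ordered group pair (one direction per unordered pair);
#' "anova" mode runs a one-way ANOVA across all groups, with the log2 ratio
#' reported per pair against the shared ANOVA p value.
#'
#' A probe passes a contrast when `|log2_ratio| > th$log2_fc` and
#' `fdr < th$diff_fdr`, and additionally `p < alpha` when `alpha_mode` is
#' set (`th$diff_alpha` for cross-sectional work, `th$response_alpha` for
#' response signatures).
#'
#' @param matrix expression matrix.
#' @param groups named character vector mapping sample id to group.
#' @param th thresholds list, see [default_thresholds()].
#' @param test `"welch"` or `"anova"`.
#' @param alpha_mode require `p < alpha` in addition to the FDR criterion.
#' @param alpha the p cut-off used when `alpha_mode` is TRUE.
#' @return data.frame with columns probe_id, contrast, log2_ratio, p_value,
#'   fdr, direction, passes.
#' @export
differential_induction <- function(matrix, groups, th = default_thresholds(),
                                   test = c("welch", "anova"),
                                   alpha_mode = FALSE,
                                   alpha = th$diff_alpha) {
  test <- match.arg(test)
  validate_expression_matrix(matrix)
  groups <- groups[colnames(matrix)]
  if (anyNA(groups)) stop("every sample needs a group label")
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least two groups")
  if (any(tab < 2L)) {
    stop("group with fewer than 2 samples: ", names(tab)[tab < 2L][1L])
  }
  gl <- names(tab)
  pairs <- utils::combn(gl, 2L, simplify = FALSE)

  anova_p <- NULL
  if (test == "anova") {
    f <- factor(groups)
    anova_p <- apply(matrix, 1L, function(v) {
      stats::oneway.test(v ~ f, var.equal = TRUE)$p.value
    })
  }

  res <- lapply(pairs, function(pr) {
    a <- matrix[, groups == pr[1L], drop = FALSE]
    b <- matrix[, groups == pr[2L], drop = FALSE]
    lfc <- rowMeans(a) - rowMeans(b)
    if (test == "welch") {
      p <- vapply(seq_len(nrow(matrix)), function(i) {
        stats::t.test(a[i, ], b[i, ])$p.value
      }, numeric(1L))
    } else {
      p <- anova_p
    }
    data.frame(probe_id = rownames(matrix),
               contrast = paste(pr[1L], "vs", pr[2L]),
               log2_ratio = lfc,
               p_value = p,
               fdr = bh_fdr(p),
               direction = ifelse(lfc >= 0, "up", "down"),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, res)
  out$passes <- abs(out$log2_ratio) > th$log2_fc & out$fdr < th$diff_fdr
  if (alpha_mode) out$passes <- out$passes & out$p_value < alpha
  out
}

#' Tree-ensemble (Gini) importance, one group versus the rest
#'
#' Fits a seeded random forest classifying `one_vs_rest_group` against all
#' other samples and returns the per-probe mean decrease in Gini impurity.
#' Deterministic given the seed (single-threaded).
#'
#' @param matrix expression matrix.
#' @param labels named character vector mapping sample id to group.
#' @param one_vs_rest_group the group forming the positive class.
#' @param n_trees ensemble size.
#' @param seed integer seed.
#' @return data.frame with columns probe_id, gini.
#' @export
rf_importance <- function(matrix, labels, one_vs_rest_group,
                          n_trees = 1000L, seed = 1L) {
  validate_expression_matrix(matrix)
  labels <- labels[colnames(matrix)]
  if (anyNA(labels)) stop("every sample needs a label")
  y <- factor(ifelse(labels == one_vs_rest_group, "target", "rest"))
  if (nlevels(y) < 2L || any(table(y) < 2L)) {
    stop("need >= 2 samples in each class after binarisation")
  }
  df <- as.data.frame(t(matrix))
  colnames(df) <- rownames(matrix)
  fit <- ranger::ranger(x = df, y = y, num.trees = n_trees,
                        importance = "impurity", seed = seed,
                        num.threads = 1L)
  data.frame(probe_id = rownames(matrix),
             gini = unname(fit$variable.importance[rownames(matrix)]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Gini importance for every one-vs-rest contrast
#'
#' @param matrix expression matrix.
#' @param labels named character vector mapping sample id to group.
#' @param n_trees,seed forwarded to [rf_importance()]; the seed is offset
#'   per contrast.
#' @return data.frame with columns probe_id, contrast, gini.
#' @export
rf_importance_all <- function(matrix, labels, n_trees = 1000L, seed = 1L) {
  gl <- sort(unique(labels[colnames(matrix)]))
  out <- lapply(seq_along(gl), function(i) {
    imp <- rf_importance(matrix, labels, gl[i], n_trees, seed + i)
    imp$contrast <- paste(gl[i], "vs rest")
    imp
  })
  do.call(rbind, out)[, c("probe_id", "contrast", "gini")]
}

#' Dual-criteria signature selection
#'
#' Retains the probes that satisfy both the tree-ensemble importance
#' criterion (Gini above `th$gini_min` in any one-vs-rest contrast, or rank
#' within `gini_top_k` per contrast when given -- the absolute Gini scale is
#' data-dependent) and the regulation criterion (passing the differential
#' thresholds in at least one contrast). The result is sorted by probe id;
#' an empty intersection is returned as an empty vector with a message.
#'
#' @param diff output of [differential_induction()].
#' @param imp output of [rf_importance_all()] (or [rf_importance()] with a
#'   contrast column added).
#' @param th thresholds list.
#' @param gini_top_k optional per-contrast importance rank cut used instead
#'   of the absolute `th$gini_min`.
#' @return character vector of probe ids.
#' @export
select_signature <- function(diff, imp, th = default_thresholds(),
                             gini_top_k = NULL) {
  if (!setequal(unique(diff$probe_id), unique(imp$probe_id))) {
    stop("differential and importance results cover different probes")
  }
  diff_pass <- unique(diff$probe_id[diff$passes])
  if (is.null(gini_top_k)) {
    imp_pass <- unique(imp$probe_id[imp$gini > th$gini_min])
  } else {
    imp_pass <- unique(unlist(lapply(split(imp, imp$contrast), function(d) {
      d$probe_id[rank(-d$gini, ties.method = "first") <= gini_top_k]
    })))
  }
  sel <- sort(intersect(diff_pass, imp_pass))
  if (length(sel) == 0L) message("signature selection: empty intersection")
  sel
}

#' Partition a signature into inflammatory and regulatory gene sets
#'
#' Assigns each signature probe to the cohort where its mean expression is
#' maximal; probes peaking in the recent-onset diabetes or low-HLA-risk
#' sibling cohorts are labelled inflammatory, probes peaking in the
#' high-HLA-risk sibling or unrelated control cohorts regulatory. This
#' cohort-peak rule is an automated proxy for ontology-based curation.
#'
#' @param matrix expression matrix.
#' @param samples sample table with cohorts ROT1D, LRS, HRS, uHC.
#' @param signature character vector of probe ids.
#' @param inflammatory_cohorts,regulatory_cohorts cohort groupings.
#' @return [gene_set_partition()].
#' @export
partition_gene_sets <- function(matrix, samples, signature,
                                inflammatory_cohorts = c("ROT1D", "LRS"),
                                regulatory_cohorts = c("HRS", "uHC")) {
  if (length(signature) == 0L) stop("signature is empty")
  validate_expression_matrix(matrix)
  st <- samples[match(colnames(matrix), samples$sample_id), ]
  cohorts <- c(inflammatory_cohorts, regulatory_cohorts)
  sub <- matrix[signature, st$cohort %in% cohorts, drop = FALSE]
  coh <- st$cohort[st$cohort %in% cohorts]
  means <- vapply(cohorts, function(cc) {
    rowMeans(sub[, coh == cc, drop = FALSE])
  }, numeric(nrow(sub)))
  peak <- cohorts[max.col(means, ties.method = "first")]
  infl <- signature[peak %in% inflammatory_cohorts]
  reg <- signature[peak %in% regulatory_cohorts]
  if (length(infl) == 0L || length(reg) == 0L) {
    stop("one gene set is empty; revise selection thresholds")
  }
  gene_set_partition(infl, reg)
}

#' Directional concordance of two signed log2-ratio vectors
#'
#' Fraction of positions where the signs agree; when per-probe FDR values
#' are supplied, also the count restricted to `fdr < fdr_max`.
#'
#' @param a reference signed log2 ratios (no zeros).
#' @param b comparison signed log2 ratios.
#' @param fdr optional per-probe FDR values aligned with `a`.
#' @param fdr_max FDR cut for the restricted count.
#' @return list with `n`, `n_concordant`, `fraction`, and when FDR is given
#'   `n_concordant_fdr`, `fraction_fdr`.
#' @export
directional_concordance <- function(a, b, fdr = NULL, fdr_max = 0.30) {
  if (length(a) != length(b)) stop("length mismatch")
  if (any(a == 0)) stop("reference vector must not contain zeros")
  conc <- sign(a) == sign(b)
  out <- list(n = length(a), n_concordant = sum(conc),
              fraction = mean(conc))
  if (!is.null(fdr)) {
    if (length(fdr) != length(a)) stop("length mismatch")
    both <- conc & fdr < fdr_max
    out$n_concordant_fdr <- sum(both)
    out$fraction_fdr <- mean(both)
  }
  out
}
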