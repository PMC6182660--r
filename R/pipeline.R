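# High-level wrappers chaining the analysis stages end to end.

#' Cross-sectional signature pipeline
#'
#' Runs differential induction (one-way ANOVA across the four cohorts with
#' BH FDR, pairwise log2 ratios), pre-screens a working probe universe at a
#' loose fold cut (1.1-fold, same FDR) on which the one-vs-rest tree
#' ensembles are fitted, then applies dual-criteria signature selection and
#' the cohort-peak inflammatory/regulatory partition.
#'
#' Because the absolute Gini scale depends on the data set, the importance
#' criterion defaults to a per-contrast rank cut sized like the expected
#' signature (`gini_top_k`); pass `gini_top_k = NULL` to use the absolute
#' `th$gini_min` cut instead.
#'
#' @param matrix expression matrix.
#' @param samples sample table (cohort column defines the groups).
#' @param th thresholds list.
#' @param n_trees,seed forwarded to the tree ensemble.
#' @param gini_top_k per-contrast importance rank cut.
#' @param screen_log2_fc loose fold cut defining the tree-ensemble probe
#'   universe.
#' @return list with `diff`, `importance`, `signature`, `partition`.
#' @export
signature_pipeline <- function(matrix, samples, th = default_thresholds(),
                               n_trees = 1000L, seed = 1L,
                               gini_top_k = 400L,
                               screen_log2_fc = log2(1.1)) {
  groups <- stats::setNames(samples$cohort, samples$sample_id)
  diff <- differential_induction(matrix, groups, th, test = "anova")
  screen <- unique(diff$probe_id[abs(diff$log2_ratio) > screen_log2_fc &
                                   diff$fdr < th$diff_fdr])
  imp <- rf_importance_all(matrix[screen, , drop = FALSE], groups,
                           n_trees = n_trees, seed = seed)
  sig <- select_signature(diff[diff$probe_id %in% screen, ], imp, th,
                          gini_top_k = gini_top_k)
  part <- partition_gene_sets(matrix, samples, sig)
  list(diff = diff, importance = imp, signature = sig, partition = part)
}

#' Baseline co-expression module pipeline
#'
#' Filters low-intensity probes, keeps the `mad_keep` most variable probes,
#' confirms the soft-threshold power on the scale-free criterion, builds the
#' topological overlap matrix, detects modules, computes eigengenes and
#' their correlations with the supplied traits, and clusters participants
#' into `k` subgroups. The clustering uses the probes of the modules whose
#' eigengenes correlate with `cluster_trait` (the inflammatory index by
#' default, reflecting that the subgroup structure tracks the
#' inflammatory/regulatory balance); if no module qualifies, all
#' trait-associated modules are used, and failing that all modules.
#'
#' @param matrix baseline expression matrix (probes x participants).
#' @param traits data.frame of numeric traits aligned with the columns.
#' @param th thresholds list (low-intensity cut, subgroup count).
#' @param mad_keep number of high-MAD probes retained.
#' @param net [network_config()].
#' @param trait_alpha p cut defining trait-associated modules.
#' @param cluster_trait trait whose associated modules define the subgroup
#'   clustering probes.
#' @return list with `filtered`, `power_scan`, `modules`, `eigengenes`,
#'   `trait_cor`, `selected_modules`, `cluster_modules`, `subgroups`.
#' @export
module_pipeline <- function(matrix, traits, th = default_thresholds(),
                            mad_keep = min(th$mad_keep, nrow(matrix)),
                            net = network_config(), trait_alpha = 0.05,
                            cluster_trait = "index") {
  filt <- filter_low_intensity(matrix, max_log2 = th$low_intensity_log2_max)
  filt <- select_high_mad(filt, min(mad_keep, nrow(filt)))
  scan <- pick_soft_threshold(filt, net, r2_min = th$scale_free_r2_min)
  adj <- network_adjacency(filt, net$power, net$network_sign)
  tom <- topological_overlap(adj)
  det <- detect_modules(1 - tom, filt, net)
  eg <- det$eigengenes
  tc <- module_trait_correlation(eg, traits)
  sel <- unique(tc$module[tc$p_value < trait_alpha])
  if (length(sel) == 0L) sel <- colnames(eg)
  cl_sel <- if (cluster_trait %in% tc$trait) {
    tc$module[tc$trait == cluster_trait & tc$p_value < trait_alpha]
  } else character(0)
  if (length(cl_sel) == 0L) cl_sel <- sel
  probes <- names(det$modules)[det$modules %in% cl_sel]
  sg <- subgroup_clustering(filt[probes, , drop = FALSE], th$n_subgroups)
  list(filtered = filt, power_scan = scan, modules = det$modules,
       eigengenes = eg, trait_cor = tc, selected_modules = sel,
       cluster_modules = cl_sel, subgroups = sg$subgroup)
}
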