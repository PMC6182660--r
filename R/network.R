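# Weighted co-expression network construction, module detection, eigengene
# computation, module-trait correlation, and participant subgroup discovery.

#' Network configuration
#'
#' @param power_candidates soft-threshold powers scanned by
#'   [pick_soft_threshold()].
#' @param power the soft-threshold exponent, default 12.
#' @param network_sign `"unsigned"` (adjacency |cor|^power) or `"signed"`
#'   (((1+cor)/2)^power).
#' @param min_module_size smallest branch kept as a module.
#' @param merge_cut modules whose eigengenes correlate above `1 - merge_cut`
#'   are merged.
#' @param cut_height dissimilarity height at which the dendrogram is cut.
#'   Unassignable probes pair at dissimilarity near 1, so the cut sits just
#'   below that ceiling; module-internal merges occur well under it.
#' @param n_bins logarithmic connectivity bins for the scale-free fit.
#' @return named list.
#' @export
network_config <- function(power_candidates = 1:20, power = 12L,
                           network_sign = c("unsigned", "signed"),
                           min_module_size = 30L, merge_cut = 0.25,
                           cut_height = 0.985, n_bins = 10L) {
  network_sign <- match.arg(network_sign)
  if (power < 1L) stop("power must be >= 1")
  if (min_module_size < 2L) stop("min_module_size must be >= 2")
  list(power_candidates = as.integer(power_candidates),
       power = as.integer(power), network_sign = network_sign,
       min_module_size = as.integer(min_module_size),
       merge_cut = merge_cut, cut_height = cut_height,
       n_bins = as.integer(n_bins))
}

# correlation-based adjacency among probes (rows of the matrix)
network_adjacency <- function(matrix, power, network_sign = "unsigned") {
  cc <- stats::cor(t(matrix))
  a <- if (network_sign == "signed") ((1 + cc) / 2)^power else abs(cc)^power
  diag(a) <- 0
  a
}

#' Scan soft-threshold powers for scale-free topology
#'
#' For each candidate power, computes the adjacency, per-probe connectivity
#' k_i (row sums), and the scale-free fit R^2: the squared correlation of
#' log10 frequency against log10 mean connectivity over logarithmic
#' connectivity bins. Constant probes are excluded with a warning.
#'
#' @param matrix expression matrix (probes x samples).
#' @param config [network_config()].
#' @return list with `table` (power, scale_free_r2, mean_connectivity) and
#'   `power` (smallest candidate with R^2 above the threshold, NA if none).
#' @param r2_min scale-free fit threshold used to pick the power.
#' @export
pick_soft_threshold <- function(matrix, config = network_config(),
                                r2_min = 0.8) {
  validate_expression_matrix(matrix)
  if (ncol(matrix) < 3L || nrow(matrix) < 10L) {
    stop("need >= 3 samples and >= 10 probes")
  }
  sds <- apply(matrix, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("excluding ", sum(sds == 0), " constant probe(s)")
    matrix <- matrix[sds > 0, , drop = FALSE]
  }
  cc <- stats::cor(t(matrix))
  diag(cc) <- 0
  rows <- lapply(config$power_candidates, function(pw) {
    a <- if (config$network_sign == "signed") ((1 + cc) / 2)^pw
         else abs(cc)^pw
    diag(a) <- 0
    k <- rowSums(a)
    data.frame(power = pw, scale_free_r2 = scale_free_fit(k, config$n_bins),
               mean_connectivity = mean(k))
  })
  tab <- do.call(rbind, rows)
  hit <- tab$power[!is.na(tab$scale_free_r2) & tab$scale_free_r2 > r2_min]
  list(table = tab, power = if (length(hit)) hit[1L] else NA_integer_)
}

# R^2 of log10(bin frequency) on log10(bin mean connectivity), over
# equal-width connectivity bins (the usual scale-free fit index)
scale_free_fit <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(NA_real_)
  br <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, br, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  kmean <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0
  if (sum(ok) < 3L) return(NA_real_)
  summary(stats::lm(log10(freq[ok]) ~ log10(kmean[ok])))$r.squared
}

#' Topological overlap matrix
#'
#' TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' l_ij = sum_u a_iu a_uj and unit diagonal; `1 - TOM` is the network
#' dissimilarity used for module detection.
#'
#' @param adjacency symmetric matrix, zero diagonal, entries in [0, 1].
#' @return TOM matrix of the same dimension.
#' @export
topological_overlap <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (!isSymmetric(unname(a), tol = 1e-10)) stop("adjacency must be symmetric")
  if (any(diag(a) != 0)) stop("adjacency diagonal must be zero")
  if (any(a < 0 | a > 1)) stop("adjacency entries must lie in [0, 1]")
  k <- rowSums(a)
  l <- a %*% a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect co-expression modules from a TOM dissimilarity
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, cut at a fixed
#' dissimilarity height; branches of at least `min_module_size`
#' probes become modules and the rest are left unassigned ("grey"). Modules
#' whose eigengenes correlate above `1 - merge_cut` are merged. Module
#' labels are colour-style strings assigned by decreasing size.
#'
#' @param tom_dissim square dissimilarity matrix (1 - TOM).
#' @param matrix expression matrix (needed for eigengene-based merging);
#'   NULL skips the merge step.
#' @param config [network_config()].
#' @return list with `modules` (named character vector probe -> label),
#'   `sizes`, and `eigengenes` (samples x modules, NULL without `matrix`).
#' @export
detect_modules <- function(tom_dissim, matrix = NULL,
                           config = network_config()) {
  d <- as.matrix(tom_dissim)
  if (nrow(d) != ncol(d)) stop("dissimilarity must be square")
  probes <- rownames(d)
  if (is.null(probes)) probes <- paste0("probe", seq_len(nrow(d)))
  if (nrow(d) < config$min_module_size) {
    return(list(modules = stats::setNames(rep("grey", nrow(d)), probes),
                sizes = c(grey = nrow(d)), eigengenes = NULL))
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  cl <- stats::cutree(hc, h = config$cut_height)
  tab <- table(cl)
  keep <- names(tab)[tab >= config$min_module_size]
  lab <- ifelse(cl %in% as.integer(keep), as.character(cl), "grey")
  names(lab) <- probes

  if (!is.null(matrix) && length(keep) > 1L) {
    lab <- merge_similar_modules(lab, matrix, config$merge_cut)
  }
  lab <- relabel_by_size(lab)
  eg <- NULL
  if (!is.null(matrix) && any(lab != "grey")) {
    eg <- module_eigengenes(matrix, lab)
  }
  list(modules = lab, sizes = sort(table(lab), decreasing = TRUE),
       eigengenes = eg)
}

merge_similar_modules <- function(lab, matrix, merge_cut) {
  repeat {
    mods <- setdiff(unique(lab), "grey")
    if (length(mods) < 2L) return(lab)
    eg <- module_eigengenes(matrix, lab)
    cc <- stats::cor(eg)
    diag(cc) <- -Inf
    top <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
    if (cc[top[1L], top[2L]] <= 1 - merge_cut) return(lab)
    from <- colnames(cc)[top[2L]]; to <- colnames(cc)[top[1L]]
    lab[lab == from] <- to
  }
}

module_palette <- function() {
  c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
    "pink", "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue")
}

relabel_by_size <- function(lab) {
  mods <- setdiff(unique(lab), "grey")
  if (length(mods) == 0L) return(lab)
  sizes <- sort(table(lab[lab != "grey"]), decreasing = TRUE)
  pal <- module_palette()
  new <- c(pal, paste0("module", seq_len(max(0, length(sizes) - length(pal)))))
  map <- stats::setNames(new[seq_along(sizes)], names(sizes))
  out <- ifelse(lab == "grey", "grey", map[lab])
  stats::setNames(out, names(lab))
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' probe-standardised submatrix across samples: a unit-norm vector with one
#' entry per sample, sign-oriented to correlate positively with the module's
#' mean expression profile. Unassigned ("grey") probes get no eigengene.
#'
#' @param matrix expression matrix.
#' @param assignment named character vector probe -> module label.
#' @return numeric matrix, samples x modules.
#' @export
module_eigengenes <- function(matrix, assignment) {
  validate_expression_matrix(matrix)
  mods <- setdiff(unique(assignment), "grey")
  if (length(mods) == 0L) stop("no modules to summarise")
  eg <- vapply(mods, function(m) {
    probes <- intersect(names(assignment)[assignment == m], rownames(matrix))
    if (length(probes) < 2L) stop("module ", m, " has fewer than 2 probes")
    sub <- matrix[probes, , drop = FALSE]
    sds <- apply(sub, 1L, stats::sd)
    if (any(sds == 0)) stop("module ", m, " contains a constant probe")
    z <- (sub - rowMeans(sub)) / sds
    sv <- svd(z, nu = 0L, nv = 1L)
    v <- sv$v[, 1L]
    profile <- colMeans(z)
    if (stats::cor(v, profile) < 0) v <- -v
    v
  }, numeric(ncol(matrix)))
  rownames(eg) <- colnames(matrix)
  eg
}

#' Correlate module eigengenes with sample traits
#'
#' Pearson correlation and two-sided p value for every module x trait pair;
#' missing trait values are pairwise-deleted; constant traits are excluded
#' with a warning.
#'
#' @param eigengenes samples x modules matrix from [module_eigengenes()].
#' @param traits data.frame of numeric traits, rows aligned with the
#'   eigengene rows.
#' @return data.frame with module, trait, r, p_value, n.
#' @export
module_trait_correlation <- function(eigengenes, traits) {
  if (nrow(traits) != nrow(eigengenes)) stop("traits misaligned with samples")
  keep <- vapply(traits, function(v) stats::sd(v, na.rm = TRUE) > 0,
                 logical(1L))
  if (any(!keep)) {
    warning("excluding constant trait(s): ",
            paste(names(traits)[!keep], collapse = ", "))
    traits <- traits[, keep, drop = FALSE]
  }
  rows <- list()
  for (m in colnames(eigengenes)) for (tr in names(traits)) {
    ok <- !is.na(traits[[tr]])
    ct <- stats::cor.test(eigengenes[ok, m], traits[[tr]][ok])
    rows[[length(rows) + 1L]] <- data.frame(
      module = m, trait = tr, r = unname(ct$estimate),
      p_value = ct$p.value, n = sum(ok), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Cluster participants into subgroups on their baseline signatures
#'
#' Average-linkage hierarchical clustering of samples on correlation
#' distance (1 - Pearson r between baseline expression profiles over the
#' supplied probes), cut so that k major subgroups emerge. Probes are
#' standardised first, so the distance reflects each participant's
#' deviation profile rather than the shared probe baseline intensities.
#'
#' Average linkage isolates outlying samples on small terminal branches; a
#' plain k-branch cut would spend clusters on those. The tree is therefore
#' cut progressively deeper until k branches of at least `min_frac` of the
#' samples exist; participants on minor branches are then assigned to the
#' major subgroup at smallest average correlation distance. Deterministic.
#'
#' @param matrix expression matrix restricted to the probes of interest
#'   (e.g. members of trait-associated modules).
#' @param k number of major subgroups.
#' @param min_frac minimum fraction of samples for a branch to count as a
#'   major subgroup.
#' @return list with `subgroup` (named integer vector sample -> 1..k,
#'   numbered by decreasing size) and `hclust` (the linkage tree).
#' @export
subgroup_clustering <- function(matrix, k, min_frac = 0.05) {
  validate_expression_matrix(matrix)
  n <- ncol(matrix)
  if (k > n) stop("k exceeds the participant count")
  if (k == 1L) {
    return(list(subgroup = stats::setNames(rep(1L, n), colnames(matrix)),
                hclust = NULL))
  }
  sds <- apply(matrix, 1L, stats::sd)
  z <- (matrix - rowMeans(matrix)) / ifelse(sds > 0, sds, 1)
  dm <- 1 - stats::cor(z)
  hc <- stats::hclust(stats::as.dist(dm), method = "average")
  min_size <- max(2L, ceiling(min_frac * n))
  cl <- NULL
  for (ncut in k:n) {
    cand <- stats::cutree(hc, k = ncut)
    if (sum(table(cand) >= min_size) >= k) {
      cl <- cand
      break
    }
  }
  if (is.null(cl)) cl <- stats::cutree(hc, k = k)
  sizes <- sort(table(cl), decreasing = TRUE)
  major <- as.integer(names(sizes)[seq_len(min(k, length(sizes)))])
  # fold minor-branch samples into the closest major subgroup
  for (i in which(!cl %in% major)) {
    avg <- vapply(major, function(m) {
      mean(dm[i, cl == m & seq_len(n) != i])
    }, numeric(1L))
    cl[i] <- major[which.min(avg)]
  }
  sizes <- sort(table(cl), decreasing = TRUE)
  map <- stats::setNames(seq_along(sizes), names(sizes))
  list(subgroup = stats::setNames(unname(map[as.character(cl)]),
                                  colnames(matrix)),
       hclust = hc)
}

#' Clinical comparison of participant subgroups
#'
#' Per arm x subgroup descriptive means of each metric, pairwise two-tailed
#' unpaired t tests between subgroups within arm and between arms within
#' subgroup, and a two-sample Kolmogorov-Smirnov comparison of age
#' distributions between subgroup pairs. Subgroups with fewer than 2
#' members in an arm are reported descriptively but excluded from tests.
#'
#' @param subgroups named integer vector participant -> subgroup.
#' @param endpoints [endpoint_records()] data.frame.
#' @param samples sample table (supplies arm and age).
#' @return list with `means`, `t_tests`, `ks_age`.
#' @export
subgroup_clinical_comparison <- function(subgroups, endpoints, samples) {
  ep <- endpoints
  ep$subgroup <- subgroups[ep$participant_id]
  ep$age <- samples$age_years[match(ep$participant_id, samples$sample_id)]
  if (anyNA(ep$subgroup)) stop("participant without subgroup assignment")
  metrics <- c(grep("^pct_m", names(ep), value = TRUE),
               "decline_slope", "age")
  cells <- split(ep, list(ep$arm, ep$subgroup), drop = TRUE)
  means <- do.call(rbind, lapply(cells, function(d) {
    out <- data.frame(arm = d$arm[1L], subgroup = d$subgroup[1L],
                      n = nrow(d), stringsAsFactors = FALSE)
    for (m in metrics) out[[m]] <- mean(d[[m]], na.rm = TRUE)
    out
  }))
  rownames(means) <- NULL

  safe_t <- function(a, b) {
    if (length(a) < 2L || length(b) < 2L) return(NULL)
    if (stats::sd(c(a, b), na.rm = TRUE) == 0) return(list(p.value = 1))
    stats::t.test(a, b)
  }
  rows <- list()
  # between subgroups within arm
  for (arm in unique(ep$arm)) for (m in metrics) {
    sub <- ep[ep$arm == arm, ]
    gs <- sort(unique(sub$subgroup))
    if (length(gs) < 2L) next
    for (pr in utils::combn(gs, 2L, simplify = FALSE)) {
      tt <- safe_t(sub[[m]][sub$subgroup == pr[1L]],
                   sub[[m]][sub$subgroup == pr[2L]])
      if (is.null(tt)) next
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = "subgroup_within_arm", arm = arm, metric = m,
        group_a = pr[1L], group_b = pr[2L], p_value = tt$p.value,
        stringsAsFactors = FALSE)
    }
  }
  # between arms within subgroup
  for (g in sort(unique(ep$subgroup))) for (m in metrics) {
    sub <- ep[ep$subgroup == g, ]
    arms <- sort(unique(sub$arm))
    if (length(arms) < 2L) next
    tt <- safe_t(sub[[m]][sub$arm == arms[1L]],
                 sub[[m]][sub$arm == arms[2L]])
    if (is.null(tt)) next
    rows[[length(rows) + 1L]] <- data.frame(
      comparison = "arm_within_subgroup", arm = paste(arms, collapse = "_vs_"),
      metric = m, group_a = g, group_b = g, p_value = tt$p.value,
      stringsAsFactors = FALSE)
  }
  t_tests <- if (length(rows)) do.call(rbind, rows) else NULL

  ks_rows <- list()
  gs <- sort(unique(ep$subgroup))
  for (pr in utils::combn(gs, 2L, simplify = FALSE)) {
    a <- ep$age[ep$subgroup == pr[1L]]
    b <- ep$age[ep$subgroup == pr[2L]]
    if (length(a) < 2L || length(b) < 2L) next
    ks <- suppressWarnings(stats::ks.test(a, b))
    ks_rows[[length(ks_rows) + 1L]] <- data.frame(
      group_a = pr[1L], group_b = pr[2L], d = unname(ks$statistic),
      p_value = ks$p.value, stringsAsFactors = FALSE)
  }
  list(means = means, t_tests = t_tests,
       ks_age = if (length(ks_rows)) do.call(rbind, ks_rows) else NULL)
}
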