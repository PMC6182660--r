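test_that("topological overlap matches its defining formula", {
  # complete 3-node graph: TOM = (1 + 1)/(2 + 1 - 1) = 1 everywhere
  a3 <- matrix(1, 3, 3); diag(a3) <- 0
  t3 <- topological_overlap(a3)
  expect_true(all(abs(t3 - 1) < 1e-12))
  # empty graph: identity
  a0 <- matrix(0, 4, 4)
  t0 <- topological_overlap(a0)
  expect_equal(t0, diag(4))
  # random matrices against the direct-summation oracle
  set.seed(61)
  for (i in 1:20) {
    a <- matrix(runif(36), 6); a <- (a + t(a)) / 2; diag(a) <- 0
    expect_equal(topological_overlap(a), tom_oracle(a), tolerance = 1e-12)
  }
  # output is symmetric, within [0, 1], unit diagonal
  a <- matrix(runif(64), 8); a <- (a + t(a)) / 2; diag(a) <- 0
  tt <- topological_overlap(a)
  expect_true(isSymmetric(tt))
  expect_true(all(tt >= 0 & tt <= 1 + 1e-12))
  expect_equal(unname(diag(tt)), rep(1, 8))
  bad <- a; bad[1, 2] <- bad[1, 2] + 0.5
  expect_error(topological_overlap(bad), "symmetric")
  expect_error(topological_overlap(a + diag(8) * 0.5), "diagonal")
})

test_that("unsigned adjacency is invariant to sign flips and relabelling", {
  set.seed(62)
  m <- make_matrix(matrix(rnorm(10 * 8), 10))
  adj <- plasmind:::network_adjacency(m, 6)
  flipped <- m * rep(sample(c(-1, 1), 10, TRUE), 8)
  adj_f <- plasmind:::network_adjacency(
    expression_matrix(flipped, rownames(m), colnames(m)), 6)
  expect_equal(adj, adj_f, tolerance = 1e-12)
  perm <- sample(ncol(m))
  adj_p <- plasmind:::network_adjacency(m[, perm], 6)
  expect_equal(adj, adj_p, tolerance = 1e-12)
})

test_that("soft-threshold scan covers the candidates and flags scale-free fit", {
  set.seed(63)
  # hub-structured network: heavy-tailed loadings give a power-law-like
  # connectivity distribution
  n <- 150; s <- 50
  f <- rnorm(s)
  m <- make_matrix(outer(runif(n)^2, f) + matrix(rnorm(n * s, sd = 0.5), n))
  cfg <- network_config()
  scan <- pick_soft_threshold(m, cfg)
  expect_equal(nrow(scan$table), length(cfg$power_candidates))
  expect_true(12L %in% cfg$power_candidates)
  expect_true(any(scan$table$scale_free_r2 > 0.8, na.rm = TRUE))
  expect_false(is.na(scan$power))
  # constant probes are excluded with a warning
  m2 <- rbind(m, make_matrix(matrix(5, 1, s), probes = "CONST"))
  expect_warning(pick_soft_threshold(
    expression_matrix(m2, rownames(m2), colnames(m2)), cfg), "constant")
})

test_that("module detection recovers planted correlation blocks", {
  set.seed(64)
  n_per <- 50; ns <- 30
  f <- matrix(rnorm(3 * ns), 3)
  blocks <- do.call(rbind, lapply(1:3, function(b) {
    outer(rep(1, n_per), f[b, ]) * 1.0 + matrix(rnorm(n_per * ns, sd = 0.5),
                                                n_per)
  }))
  m <- make_matrix(blocks)
  truth <- rep(1:3, each = n_per)
  adj <- plasmind:::network_adjacency(m, 12)
  det <- detect_modules(1 - topological_overlap(adj), m)
  lab <- det$modules
  expect_gte(rand_index_adj(lab[lab != "grey"], truth[lab != "grey"]), 0.9)
  expect_lt(mean(lab == "grey"), 0.1)
  # pure noise: most probes stay unassigned
  noise <- make_matrix(matrix(rnorm(80 * ns), 80))
  adj_n <- plasmind:::network_adjacency(noise, 12)
  det_n <- detect_modules(1 - topological_overlap(adj_n), noise)
  expect_gt(mean(det_n$modules == "grey"), 0.5)
  # a block smaller than the minimum module size goes grey
  small <- do.call(rbind, list(
    outer(rep(1, 10), f[1, ]) + matrix(rnorm(10 * ns, sd = 0.3), 10),
    matrix(rnorm(60 * ns), 60)))
  ms <- make_matrix(small)
  det_s <- detect_modules(1 - topological_overlap(
    plasmind:::network_adjacency(ms, 12)), ms)
  expect_true(all(det_s$modules[1:10] == "grey"))
})

test_that("eigengenes equal the leading singular vector up to sign", {
  set.seed(65)
  f <- rnorm(20)
  m <- make_matrix(rbind(outer(runif(6, 0.5, 1), f) +
                           matrix(rnorm(120, sd = 0.3), 6),
                         matrix(rnorm(5 * 20), 5)))
  lab <- setNames(c(rep("blue", 6), rep("grey", 5)), rownames(m))
  eg <- module_eigengenes(m, lab)
  expect_equal(colnames(eg), "blue")
  expect_equal(sum(eg[, 1]^2), 1)
  z <- (m[1:6, ] - rowMeans(m[1:6, ])) / apply(m[1:6, ], 1, sd)
  sv <- svd(z)$v[, 1]
  expect_gt(abs(cor(eg[, 1], sv)), 1 - 1e-10)
  # sign orientation follows the module mean profile
  expect_gte(cor(eg[, 1], colMeans(z)), 0)
  # module of identical profiles: |cor| with the profile is one
  ident <- make_matrix(rbind(f, f + 5, matrix(rnorm(40), 2)))
  lab2 <- setNames(c("red", "red", "grey", "grey"), rownames(ident))
  eg2 <- module_eigengenes(ident, lab2)
  expect_equal(abs(cor(eg2[, 1], f)), 1)
  # first-PC optimality: no other unit vector explains more variance
  rand_dir <- replicate(50, {
    v <- rnorm(20); v <- v / sqrt(sum(v^2))
    sum((z %*% v)^2)
  })
  expect_gte(sum((z %*% eg[, 1])^2) + 1e-9, max(rand_dir))
  expect_error(module_eigengenes(make_matrix(matrix(5, 2, 4)),
                                 setNames(rep("m1", 2), c("P001", "P002"))),
               "constant")
})

test_that("module-trait correlations recover planted couplings", {
  set.seed(66)
  n <- 74
  trait <- rnorm(n)
  f <- 0.7 * scale(trait)[, 1] + rnorm(n, sd = sqrt(1 - 0.49))
  m <- make_matrix(rbind(outer(runif(30, 0.5, 1), f) +
                           matrix(rnorm(30 * n, sd = 0.4), 30)))
  lab <- setNames(rep("blue", 30), rownames(m))
  eg <- module_eigengenes(m, lab)
  tc <- module_trait_correlation(eg, data.frame(trait = trait,
                                                noise = rnorm(n)))
  r_hat <- tc$r[tc$trait == "trait"]
  expect_lt(abs(abs(r_hat) - 0.7), 0.15)
  expect_gt(tc$p_value[tc$trait == "noise"], 0.001)
  # trait equal to the eigengene itself: r = 1
  tc2 <- module_trait_correlation(eg, data.frame(self = eg[, 1]))
  expect_equal(tc2$r, 1)
  expect_lt(tc2$p_value, 1e-20)
  expect_warning(module_trait_correlation(eg, data.frame(flat = rep(1, n))),
                 "constant")
})

test_that("subgroup clustering is deterministic and honours k", {
  set.seed(67)
  m <- make_matrix(matrix(rnorm(40 * 12), 40))
  one <- subgroup_clustering(m, 1L)
  expect_true(all(one$subgroup == 1L))
  expect_error(subgroup_clustering(m, 13L), "exceeds")
  # duplicated participants sit in the same subgroup
  dup <- cbind(m, m[, 1, drop = FALSE])
  colnames(dup) <- c(colnames(m), "copy")
  sg <- subgroup_clustering(expression_matrix(dup, rownames(m),
                                              colnames(dup)), 3L)
  expect_equal(unname(sg$subgroup["copy"]),
               unname(sg$subgroup[colnames(m)[1]]))
})

test_that("subgroup clinical comparison detects planted contrasts", {
  set.seed(68)
  mk_ep <- function(ids, arm, shift) {
    data.frame(participant_id = ids, arm = arm,
               decline_slope = rnorm(length(ids), shift),
               remission_months = 12, remission_censored = FALSE,
               pct_m24 = rnorm(length(ids), shift * 10))
  }
  # planted 1.5-sd treated benefit in one subgroup, n = 15 per arm
  hits_t <- hits_ks <- 0L
  for (i in 1:30) {
    ids <- sprintf("p%02d", 1:60)
    ep <- rbind(mk_ep(ids[1:15], "treated", 1.5),
                mk_ep(ids[16:30], "placebo", 0),
                mk_ep(ids[31:45], "treated", 0),
                mk_ep(ids[46:60], "placebo", 0))
    sg <- setNames(rep(c(1L, 1L, 2L, 2L), each = 15), ids)
    ages <- c(rnorm(30, 10, 2), rnorm(30, 14, 2))  # 2 sd age shift
    st <- sample_table(ids, ids, "TRIAL", ep$arm, 0, ages)
    cmp <- subgroup_clinical_comparison(sg, ep, st)
    pt <- cmp$t_tests
    p_benefit <- pt$p_value[pt$comparison == "arm_within_subgroup" &
                              pt$group_a == 1 & pt$metric == "decline_slope"]
    hits_t <- hits_t + as.integer(p_benefit < 0.05)
    hits_ks <- hits_ks + as.integer(cmp$ks_age$p_value < 0.05)
  }
  expect_gte(hits_t / 30, 0.9)
  expect_gte(hits_ks / 30, 0.9)
  # identical subgroups stay null-calibrated
  set.seed(69)
  pvals <- replicate(60, {
    ids <- sprintf("q%02d", 1:24)
    ep <- mk_ep(ids, "placebo", 0)
    sg <- setNames(sample(rep(1:2, 12)), ids)
    st <- sample_table(ids, ids, "TRIAL", "placebo", 0, rnorm(24, 12, 2))
    cmp <- subgroup_clinical_comparison(sg, ep, st)
    cmp$t_tests$p_value[cmp$t_tests$metric == "decline_slope" &
                          cmp$t_tests$comparison == "subgroup_within_arm"]
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})
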