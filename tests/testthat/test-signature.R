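test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_fdr(0.7), 0.7)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(9)
  for (i in 1:200) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_fdr(p), bh_oracle(p))
  }
})

test_that("differential induction reports antisymmetric ratios and applies thresholds", {
  set.seed(2)
  m <- make_matrix(matrix(rnorm(40 * 12), 40) +
                     c(rep(1, 10), rep(0, 30)) %o%
                     rep(c(1, 0), each = 6))
  g <- setNames(rep(c("X", "Y"), each = 6), colnames(m))
  d_xy <- differential_induction(m, g)
  g_swapped <- setNames(rep(c("Y", "X"), each = 6), colnames(m))
  d_yx <- differential_induction(m, g_swapped)
  expect_equal(d_xy$log2_ratio, -d_yx$log2_ratio)
  expect_equal(d_xy$p_value, d_yx$p_value)

  # pass rule: |log2 ratio| above 0.263 and FDR under 0.20, jointly
  fake <- d_xy[1:2, ]
  fake$log2_ratio <- c(0.25, 0.30)
  fake$fdr <- c(0.01, 0.01)
  th <- default_thresholds()
  pass <- abs(fake$log2_ratio) > th$log2_fc & fake$fdr < th$diff_fdr
  expect_equal(pass, c(FALSE, TRUE))

  expect_error(differential_induction(m, setNames(rep("X", 12),
                                                  colnames(m))),
               "two groups")
  g_bad <- setNames(c("X", rep("Y", 11)), colnames(m))
  expect_error(differential_induction(m, g_bad), "fewer than 2")
})

test_that("a strong planted shift is detected with high power", {
  # 2-fold shift (1 log2 unit) against noise sd 0.3 at n = 20 per group
  set.seed(14)
  hits <- 0L
  for (i in 1:50) {
    m <- make_matrix(rbind(c(rnorm(20, 1, 0.3), rnorm(20, 0, 0.3)),
                           matrix(rnorm(40 * 49, 0, 0.3), 49)))
    g <- setNames(rep(c("A", "B"), each = 20), colnames(m))
    d <- differential_induction(m, g)
    hits <- hits + as.integer(d$passes[d$probe_id == "P001"])
  }
  expect_gte(hits / 50, 0.98)
})

test_that("forest importance ranks a perfect separator first and is seeded", {
  set.seed(8)
  n <- 30
  sep <- c(rep(0, n / 2), rep(3, n / 2))  # disjoint class supports
  m <- make_matrix(rbind(sep, matrix(rnorm(n * 30), 30)))
  g <- setNames(rep(c("A", "B"), each = n / 2), colnames(m))
  imp <- rf_importance(m, g, "A", n_trees = 300L, seed = 5L)
  expect_equal(imp$probe_id[which.max(imp$gini)], "P001")
  imp2 <- rf_importance(m, g, "A", n_trees = 300L, seed = 5L)
  expect_identical(imp, imp2)
  expect_error(rf_importance(m, setNames(rep("A", n), colnames(m)), "A"),
               ">= 2 samples")
})

test_that("noise-probe importance sits inside its permutation null", {
  set.seed(15)
  n <- 24
  m <- make_matrix(rbind(c(rep(0, n / 2), rep(2.5, n / 2)),
                         matrix(rnorm(n * 20), 20)))
  g <- setNames(rep(c("A", "B"), each = n / 2), colnames(m))
  obs <- rf_importance(m, g, "A", n_trees = 200L, seed = 1L)
  noise_gini <- obs$gini[obs$probe_id == "P005"]
  perm <- vapply(1:60, function(i) {
    gp <- setNames(sample(g), names(g))
    rf_importance(m, gp, "A", n_trees = 200L,
                  seed = 100L + i)$gini[obs$probe_id == "P005"]
  }, numeric(1))
  expect_lte(noise_gini, quantile(perm, 0.95) + 1e-9)
})

test_that("signature selection is an intersection and is threshold-monotone", {
  diff <- data.frame(probe_id = c("P1", "P2", "P3"), contrast = "A vs B",
                     log2_ratio = c(0.5, 0.5, 0.1),
                     p_value = c(0.001, 0.001, 0.5),
                     fdr = c(0.01, 0.01, 0.9),
                     direction = "up",
                     passes = c(TRUE, TRUE, FALSE))
  imp <- data.frame(probe_id = c("P1", "P2", "P3"),
                    contrast = "A vs rest",
                    gini = c(5, 1, 6))
  th <- default_thresholds()
  expect_equal(select_signature(diff, imp, th), "P1")  # P2 fails Gini,
  # P3 fails regulation, each alone is excluded
  relaxed <- default_thresholds(gini_min = 0.5)
  expect_true(all(select_signature(diff, imp, th) %in%
                    select_signature(diff, imp, relaxed)))
  expect_message(
    out <- select_signature(diff[3, ], imp[3, ],
                            default_thresholds(gini_min = 10)),
    "empty")
  expect_length(out, 0L)
})

test_that("cohort-peak partition assigns probes by their elevated cohort", {
  m <- make_matrix(rbind(c(5, 5, 1, 1, 1, 1, 1, 1),
                         c(1, 1, 1, 1, 1, 1, 6, 6)),
                   probes = c("PI", "PR"))
  st <- sample_table(colnames(m), colnames(m),
                     rep(c("ROT1D", "LRS", "HRS", "uHC"), each = 2),
                     "none", 0, 10)
  part <- partition_gene_sets(m, st, c("PI", "PR"))
  expect_equal(part$inflammatory_probes, "PI")
  expect_equal(part$regulatory_probes, "PR")
  expect_error(partition_gene_sets(m, st, character(0)), "empty")
  expect_error(partition_gene_sets(m[1, , drop = FALSE], st, "PI"),
               "empty|revise")
})

test_that("directional concordance counts sign matches and FDR-restricted matches", {
  a <- c(1, -2, 3, -4)
  expect_equal(directional_concordance(a, a)$fraction, 1)
  expect_equal(directional_concordance(a, -a)$fraction, 0)
  res <- directional_concordance(a, c(2, 5, 1, -1),
                                 fdr = c(0.1, 0.1, 0.5, 0.5),
                                 fdr_max = 0.3)
  expect_equal(res$n_concordant, 3L)
  expect_equal(res$n_concordant_fdr, 1L)
  expect_error(directional_concordance(a, 1:3), "length")
  expect_error(directional_concordance(c(0, 1), c(1, 1)), "zeros")
})

test_that("BH keeps the null discovery fraction controlled", {
  set.seed(33)
  frac <- replicate(200, {
    p <- runif(400)
    mean(bh_fdr(p) < 0.20)
  })
  expect_lt(mean(frac), 0.01)
})
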