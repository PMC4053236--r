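test_that("Fisher exact test reproduces the published table p-values", {
  expect_equal(round(fisher_exact_two_sided(29, 0, 29, 13), 4), 0.0005)
  expect_equal(round(fisher_exact_two_sided(47, 13, 11, 0), 2), 0.20)
  expect_equal(round(fisher_exact_two_sided(40, 4, 17, 9), 3), 0.012)
  expect_equal(round(fisher_exact_two_sided(51, 5, 6, 8), 4), 0.0003)
  expect_equal(fisher_exact_two_sided(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_two_sided(0, 0, 10, 12), 1)  # zero margin
  expect_equal(fisher_exact_two_sided(matrix(c(29, 29, 0, 13), 2)),
               fisher_exact_two_sided(29, 0, 29, 13))
  expect_error(fisher_exact_two_sided(1.5, 2, 3, 4), "integer")
  expect_error(fisher_exact_two_sided(-1, 2, 3, 4), "integer")
})

test_that("Fisher p is invariant under row swap, column swap and transpose", {
  set.seed(66)
  for (i in 1:30) {
    m <- matrix(rpois(4, 6), 2)
    p <- fisher_exact_two_sided(m)
    expect_equal(fisher_exact_two_sided(m[2:1, ]), p, tolerance = 1e-12)
    expect_equal(fisher_exact_two_sided(m[, 2:1]), p, tolerance = 1e-12)
    expect_equal(fisher_exact_two_sided(t(m)), p, tolerance = 1e-12)
    expect_true(p > 0 && p <= 1)
  }
})

test_that("Fisher p agrees with the reference implementation on random tables", {
  set.seed(77)
  for (i in 1:50) {
    m <- matrix(rpois(4, 8), 2)
    if (sum(m) == 0) next
    expect_equal(fisher_exact_two_sided(m),
                 stats::fisher.test(m)$p.value, tolerance = 1e-9)
  }
})

test_that("Clopper-Pearson intervals match the printed signature CIs", {
  ci <- clopper_pearson(51, 54)
  expect_equal(round(100 * ci[["lower"]]), 85)
  expect_equal(round(100 * ci[["upper"]]), 99)
  ci <- clopper_pearson(31, 53)
  expect_equal(ci[["lower"]], 0.4413398, tolerance = 1e-6)
  expect_equal(ci[["upper"]], 0.7186420, tolerance = 1e-6)
  expect_equal(clopper_pearson(13, 13)[["upper"]], 1)
  expect_equal(clopper_pearson(0, 13)[["lower"]], 0)
  expect_error(clopper_pearson(5, 4), "x <= n")
  expect_error(clopper_pearson(-1, 4), "x <= n")
})

test_that("Clopper-Pearson simulated coverage is at least nominal", {
  set.seed(88)
  n <- 20
  for (p in c(0.1, 0.5, 0.9)) {
    x <- rbinom(4000, n, p)
    covered <- vapply(x, function(xi) {
      ci <- clopper_pearson(xi, n)
      ci[["lower"]] <= p && p <= ci[["upper"]]
    }, logical(1))
    expect_gte(mean(covered), 0.95)
  }
})

test_that("diagnostic performance of the fixture rules matches the report", {
  ern <- er_negative_subset(generate_fixture_replica())
  truth <- ern$group == "MA"

  rule <- ihc_combined_rule(ern$her2_score, call_ihc_marker(ern, "gcdfp15"))
  perf <- diagnostic_performance(rule, truth)
  expect_equal(round(100 * perf$sensitivity), 94)
  expect_equal(perf$specificity, 1)
  expect_equal(round(perf$auc, 3), 0.972)
  expect_equal(round(100 * perf$sens_ci[["lower"]]), 85)

  ar <- call_ihc_marker(ern, "ar") == "positive"
  expect_message(perf <- diagnostic_performance(ar, truth), "excluded")
  expect_equal(perf$n_ma, 53)
  expect_equal(perf$n_excluded, 1)
  expect_equal(round(100 * perf$sensitivity), 58)
  expect_equal(round(perf$auc, 3), 0.792)
  expect_equal(round(100 * perf$sens_ci[["lower"]]), 44)

  perfect <- diagnostic_performance(truth, truth)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$auc, 1)

  expect_error(diagnostic_performance(rule, rep(TRUE, length(rule))),
               "each group")
})

test_that("binary-rule AUC stays in [0,1] and is 0.5 under independence", {
  set.seed(99)
  aucs <- vapply(1:30, function(i) {
    truth <- sample(c(TRUE, FALSE), 400, replace = TRUE)
    rule <- sample(c(TRUE, FALSE), 400, replace = TRUE)
    diagnostic_performance(rule, truth)$auc
  }, numeric(1))
  expect_true(all(aucs >= 0 & aucs <= 1))
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("marker-by-group comparisons reproduce the printed p-values", {
  coh <- generate_fixture_replica()
  expect_equal(round(compare_marker_by_group(coh, "egfr")$p, 3), 0.012)
  expect_equal(round(compare_marker_by_group(coh, "ck56")$p, 4), 0.0003)
  expect_equal(round(compare_marker_by_group(coh, "tp53")$p, 4), 0.0005)
  expect_equal(round(compare_marker_by_group(coh, "pik3ca")$p, 2), 0.20)
  expect_lt(compare_marker_by_group(coh, "her2_3plus")$p, 0.0001)
  expect_lt(compare_marker_by_group(coh, "AR")$p, 0.0001)  # mRNA

  # a marker distributed identically in both groups is non-significant
  flat <- as.data.frame(coh)
  flat$ihc_gcdfp15_pct <- 50
  expect_equal(compare_marker_by_group(ma_cohort(flat), "gcdfp15")$p, 1)
  flat$ihc_gcdfp15_pct <- NA
  expect_error(compare_marker_by_group(ma_cohort(flat), "gcdfp15"),
               "not assessable")
  expect_error(compare_marker_by_group(coh, "vimentin"), "vimentin")
})

test_that("MCA coordinates satisfy centering and match an eigen oracle", {
  set.seed(123)
  X <- matrix(rbinom(80, 1, 0.5), nrow = 20,
              dimnames = list(NULL, c("m1", "m2", "m3", "m4")))
  while (any(colSums(X) %in% c(0, nrow(X)))) {
    X <- matrix(rbinom(80, 1, 0.5), nrow = 20,
                dimnames = list(NULL, c("m1", "m2", "m3", "m4")))
  }
  res <- mca_coordinates(X, n_dims = 3)
  # mass-weighted row centroid is the origin, per dimension
  centroid <- colSums(res$row_coords * res$row_masses)
  expect_equal(unname(centroid), rep(0, 3), tolerance = 1e-10)
  expect_equal(sum(res$inertia_share), 1, tolerance = 1e-10)

  # independent oracle: eigen-decomposition of the residual cross-product
  Z <- do.call(cbind, lapply(1:4, function(j) cbind(X[, j], 1 - X[, j])))
  P <- Z / sum(Z)
  r <- rowSums(P); cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, cc)) %*% diag(1 / sqrt(cc))
  ev <- eigen(S %*% t(S), symmetric = TRUE)
  keep <- ev$values > 1e-12
  F_or <- diag(1 / sqrt(r)) %*% ev$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(ev$values[keep]))
  for (k in 1:3) {
    sgn <- sign(sum(res$row_coords[, k] * F_or[, k]))
    expect_equal(res$row_coords[, k], sgn * F_or[, k], tolerance = 1e-8,
                 ignore_attr = TRUE)
  }

  # two perfectly correlated markers: one dimension carries the association
  Y <- cbind(a = X[, 1], b = X[, 1])
  res2 <- mca_coordinates(Y)
  expect_gt(res2$inertia_share[1], 1 - 1e-8)

  expect_error(mca_coordinates(X[, 1, drop = FALSE]), "at least 2")
  Xc <- X; Xc[, 2] <- 1
  expect_error(mca_coordinates(Xc), "constant")
  Xna <- X; Xna[1, 1] <- NA
  expect_message(res3 <- mca_coordinates(Xna), "dropped")
  expect_equal(res3$n_used, 19)
})
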