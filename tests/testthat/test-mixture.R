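test_that("EM recovers the components of a simulated bimodal sample", {
  set.seed(101)
  x <- c(rnorm(250, 1.5, 0.3), rnorm(250, 3.2, 0.3))
  fit <- fit_two_gaussian_mixture(x)
  expect_true(fit$converged)
  expect_lt(abs(fit$mu[1] - 1.5), 0.1)
  expect_lt(abs(fit$mu[2] - 3.2), 0.1)
  expect_lt(abs(fit$w[1] - 0.5), 0.1)
  expect_equal(sum(fit$w), 1, tolerance = 1e-9)
  expect_true(all(fit$sd > 0))
  expect_lt(fit$mu[1], fit$mu[2])
})

test_that("the log-likelihood is non-decreasing on every EM fit", {
  set.seed(202)
  for (i in 1:10) {
    x <- c(rnorm(80, runif(1, 0, 2), runif(1, 0.2, 0.6)),
           rnorm(80, runif(1, 2.5, 5), runif(1, 0.2, 0.6)))
    fit <- fit_two_gaussian_mixture(x)
    expect_true(all(diff(fit$loglik_trace) >= -1e-6))
  }
})

test_that("degenerate and tiny inputs are refused or flagged", {
  expect_error(fit_two_gaussian_mixture(rnorm(5)), "at least 10")
  fit <- fit_two_gaussian_mixture(rep(2, 50))
  expect_false(fit$converged)
  expect_true(fit$degenerate)
})

test_that("two balanced point clusters give equal weights", {
  set.seed(7)
  x <- c(1 + rnorm(50, 0, 1e-3), 4 + rnorm(50, 0, 1e-3))
  fit <- fit_two_gaussian_mixture(x)
  expect_lt(abs(fit$w[1] - 0.5), 0.02)
  expect_lt(abs(fit$mu[1] - 1), 0.01)
  expect_lt(abs(fit$mu[2] - 4), 0.01)
})

test_that("the fit is invariant to the ordering of the input values", {
  set.seed(303)
  x <- c(rnorm(100, 1, 0.3), rnorm(100, 3, 0.3))
  f1 <- fit_two_gaussian_mixture(x)
  f2 <- fit_two_gaussian_mixture(rev(x))
  f3 <- fit_two_gaussian_mixture(sample(x))
  expect_equal(f1$mu, f2$mu, tolerance = 1e-6)
  expect_equal(f1$mu, f3$mu, tolerance = 1e-6)
  expect_equal(f1$w, f2$w, tolerance = 1e-6)
})

test_that("the closed-form density intersection matches a bisection oracle", {
  # symmetric case: the intersection is the midpoint of the means
  sym <- structure(list(w = c(0.5, 0.5), mu = c(1, 3), sd = c(0.4, 0.4),
                        degenerate = FALSE), class = "ma_mixture")
  expect_equal(mixture_intersection(sym), 2, tolerance = 1e-12)

  set.seed(404)
  for (i in 1:15) {
    w1 <- runif(1, 0.2, 0.8)
    mu1 <- runif(1, 0, 2)
    fit <- structure(list(w = c(w1, 1 - w1),
                          mu = c(mu1, mu1 + runif(1, 1.5, 3)),
                          sd = runif(2, 0.2, 0.5),
                          degenerate = FALSE), class = "ma_mixture")
    x0 <- mixture_intersection(fit)
    expect_equal(x0, bisect_intersection(fit), tolerance = 1e-8)
    # the density difference changes sign at the cutoff
    f <- function(x) fit$w[1] * dnorm(x, fit$mu[1], fit$sd[1]) -
      fit$w[2] * dnorm(x, fit$mu[2], fit$sd[2])
    expect_gt(f(x0 - 1e-4) * f(x0 + 1e-4), -Inf)
    expect_lt(sign(f(x0 - 1e-4)) * sign(f(x0 + 1e-4)), 0)
  }

  # extreme weight imbalance: no root between the means
  skew <- structure(list(w = c(1e-9, 1 - 1e-9), mu = c(0, 1),
                         sd = c(0.5, 0.5), degenerate = FALSE),
                    class = "ma_mixture")
  expect_error(mixture_intersection(skew), "midpoint")
})

test_that("cutoff recovery: median log-scale error below 0.1 at n = 500", {
  truth <- 2.25  # symmetric equal-weight components N(1.5, .25), N(3, .25)
  errs <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    x <- c(rnorm(250, 1.5, 0.25), rnorm(250, 3.0, 0.25))
    fit <- fit_two_gaussian_mixture(x)
    abs(mixture_intersection(fit) - truth)
  }, numeric(1))
  expect_lt(median(errs), 0.1)
})

test_that("cohort cutoffs: AR lands near the generator truth, fallbacks engage", {
  coh <- generate_cohort(cohort_config(n_ma = 408, n_bl = 92), seed = 31)
  cuts <- suppressWarnings(derive_cutoffs(coh))
  expect_true(all(is.finite(cuts) & cuts > 0))
  expect_named(cuts, PANEL_GENES)

  # generator-truth oracle: intersection of the population AR components
  cfg <- cohort_config()
  ar <- cfg$expression$AR
  w_neg <- (13 / 71) * (11 / 13)
  truth_log <- numeric_intersection(
    w_neg, ar$neg[["mean"]], ar$neg[["sd"]],
    1 - w_neg, ar$pos[["mean"]], ar$pos[["sd"]])
  truth <- 10^truth_log
  expect_lt(abs(cuts[["AR"]] - truth) / truth, 0.25)
  # consistent with the AR/FOXA1 overexpression convention of ratio 100
  expect_gt(cuts[["AR"]], 50)
  expect_lt(cuts[["AR"]], 200)

  # a unimodal gene falls back to its documented default with a warning
  const <- as.data.frame(coh)
  const$ratio_ESR1 <- 5
  expect_warning(cuts2 <- derive_cutoffs(ma_cohort(const), genes = "ESR1"),
                 "falling back")
  expect_equal(unname(cuts2[["ESR1"]]), 20)

  expect_error(derive_cutoffs(coh, genes = "MYC"), "MYC")
})
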