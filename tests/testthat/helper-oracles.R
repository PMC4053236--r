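# bisection root of the mixture component density difference, used as the
# independent numeric oracle for the closed-form intersection
bisect_intersection <- function(fit, tol = 1e-12) {
  f <- function(x) {
    fit$w[1] * dnorm(x, fit$mu[1], fit$sd[1]) -
      fit$w[2] * dnorm(x, fit$mu[2], fit$sd[2])
  }
  uniroot(f, lower = fit$mu[1], upper = fit$mu[2], tol = tol)$root
}

# numeric intersection of two weighted Gaussian densities given directly
numeric_intersection <- function(w1, m1, s1, w2, m2, s2) {
  f <- function(x) w1 * dnorm(x, m1, s1) - w2 * dnorm(x, m2, s2)
  uniroot(f, lower = m1, upper = m2, tol = 1e-12)$root
}

# small random binary-marker frame for tree tests
random_marker_frame <- function(n, p_markers = 4) {
  as.data.frame(lapply(seq_len(p_markers), function(j) {
    factor(sample(c("positive", "negative"), n, replace = TRUE))
  }), col.names = paste0("m", seq_len(p_markers)))
}

# a single-tumor expression panel
make_panel <- function(ESR1 = NA, AR = NA, FOXA1 = NA, ERBB2 = NA,
                       AGR2 = NA, ALCAM = NA, SPDEF = NA, TFF3 = NA,
                       UGT2B28A = NA) {
  c(ESR1 = ESR1, AR = AR, FOXA1 = FOXA1, ERBB2 = ERBB2, AGR2 = AGR2,
    ALCAM = ALCAM, SPDEF = SPDEF, TFF3 = TFF3, UGT2B28A = UGT2B28A)
}

# well-separated generator settings used for concordance checks
separated_config <- function(n_ma = 58, n_bl = 13) {
  cohort_config(
    n_ma = n_ma, n_bl = n_bl,
    expression = list(
      ESR1 = apocrineR:::gene_component(log10(3), 0.15, log10(500), 0.15, 0, 0),
      AR = apocrineR:::gene_component(log10(45), 0.15, log10(1500), 0.15, 1, 2 / 13),
      FOXA1 = apocrineR:::gene_component(log10(25), 0.15, log10(600), 0.15, 1, 0),
      ERBB2 = apocrineR:::gene_component(log10(2), 0.15, log10(40), 0.15, 38 / 56, 0),
      AGR2 = apocrineR:::gene_component(1, 0.15, 2.5, 0.15, 1, 0),
      ALCAM = apocrineR:::gene_component(1, 0.15, 2.5, 0.15, 1, 0),
      SPDEF = apocrineR:::gene_component(1, 0.15, 2.5, 0.15, 1, 0),
      TFF3 = apocrineR:::gene_component(1, 0.15, 2.5, 0.15, 1, 0),
      UGT2B28A = apocrineR:::gene_component(1, 0.15, 2.5, 0.15, 1, 0)),
    p_missing_erbb2_mrna = 0)
}
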