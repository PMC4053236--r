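as_2x2 <- function(a, b, c, d) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    m <- a
  } else {
    m <- matrix(c(a, c, b, d), nrow = 2)
  }
  if (any(m < 0) || any(m != round(m))) {
    stop("2x2 table cells must be non-negative integers", call. = FALSE)
  }
  if (sum(m) < 1) stop("2x2 table must contain at least one count",
                       call. = FALSE)
  m
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by full enumeration of the hypergeometric
#' support at fixed margins: the p-value is the sum of point probabilities
#' of all tables no more probable than the observed one (with a 1e-7
#' relative tolerance for floating-point ties — the de-facto standard
#' two-sided rule). A table with a zero margin has p = 1 by convention.
#'
#' @param a,b,c,d Cell counts, rows = marker status, columns = group;
#'   alternatively `a` may be a 2x2 matrix.
#' @return The p-value in (0, 1].
#' @export
#' @examples
#' fisher_exact_two_sided(29, 0, 29, 13)  # TP53 functional status by group
fisher_exact_two_sided <- function(a, b = NULL, c = NULL, d = NULL) {
  m <- as_2x2(a, b, c, d)
  r1 <- sum(m[1, ]); n1 <- sum(m[, 1]); n2 <- sum(m[, 2])
  if (r1 == 0 || sum(m[2, ]) == 0 || n1 == 0 || n2 == 0) return(1)
  support <- max(0, r1 - n2):min(r1, n1)
  probs <- stats::dhyper(support, n1, n2, r1)
  p_obs <- stats::dhyper(m[1, 1], n1, n2, r1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' The exact interval by beta-distribution inversion: lower bound
#' `qbeta(alpha/2, x, n - x + 1)` (0 when `x = 0`), upper bound
#' `qbeta(1 - alpha/2, x + 1, n - x)` (1 when `x = n`).
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' clopper_pearson(51, 54)  # sensitivity CI of the combined IHC rule
clopper_pearson <- function(x, n, level = 0.95) {
  if (length(x) != 1 || length(n) != 1 || is.na(x) || is.na(n) ||
      n < 1 || x < 0 || x > n || x != round(x) || n != round(n)) {
    stop("require integers 0 <= x <= n with n >= 1", call. = FALSE)
  }
  alpha <- 1 - level
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Diagnostic performance of a binary marker rule
#'
#' Sensitivity (rule-positive MA among assessable MA) and specificity
#' (rule-negative non-MA among assessable non-MA) with exact
#' Clopper-Pearson confidence intervals, and the area under the ROC curve.
#' For a binary rule the ROC has a single interior vertex, so
#' `AUC = (sensitivity + specificity) / 2`. Tumors with a missing rule
#' value are excluded, with the exclusion count reported (and messaged).
#'
#' @param rule_positive Logical vector: rule result per tumor (`NA` =
#'   not assessable).
#' @param truth_ma Logical vector: reference subtype (TRUE = molecular
#'   apocrine).
#' @param ci_level Confidence level for the exact intervals.
#' @return Object of class `ma_diagnostic`: list with `sensitivity`,
#'   `specificity`, `sens_ci`, `spec_ci`, `auc`, `n_ma`, `n_non_ma`,
#'   `n_excluded`, `ci_level`.
#' @export
#' @examples
#' coh <- er_negative_subset(generate_fixture_replica())
#' rule <- ihc_combined_rule(coh$her2_score, call_ihc_marker(coh, "gcdfp15"))
#' diagnostic_performance(rule, coh$group == "MA")
diagnostic_performance <- function(rule_positive, truth_ma,
                                   ci_level = 0.95) {
  stopifnot(length(rule_positive) == length(truth_ma))
  keep <- !is.na(rule_positive) & !is.na(truth_ma)
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    message(n_excluded,
            " tumor(s) with missing rule or reference value excluded")
  }
  rule <- rule_positive[keep]
  truth <- truth_ma[keep]
  n_ma <- sum(truth)
  n_non <- sum(!truth)
  if (n_ma == 0 || n_non == 0) {
    stop("need at least one assessable tumor in each group", call. = FALSE)
  }
  tp <- sum(rule & truth)
  tn <- sum(!rule & !truth)
  sens <- tp / n_ma
  spec <- tn / n_non
  structure(
    list(sensitivity = sens, specificity = spec,
         sens_ci = clopper_pearson(tp, n_ma, ci_level),
         spec_ci = clopper_pearson(tn, n_non, ci_level),
         auc = (sens + spec) / 2,
         n_ma = n_ma, n_non_ma = n_non, n_excluded = n_excluded,
         ci_level = ci_level),
    class = "ma_diagnostic")
}

#' @export
print.ma_diagnostic <- function(x, ...) {
  pct <- function(p) sprintf("%.0f%%", 100 * p)
  ci <- function(ci) sprintf("(%.0f to %.0f)", 100 * ci[1], 100 * ci[2])
  cat(sprintf("Sensitivity %s %s   Specificity %s %s   AUC %.3f\n",
              pct(x$sensitivity), ci(x$sens_ci),
              pct(x$specificity), ci(x$spec_ci), x$auc))
  cat(sprintf("  (%d MA, %d non-MA assessable; %d excluded)\n",
              x$n_ma, x$n_non_ma, x$n_excluded))
  invisible(x)
}

marker_call_by_name <- function(cohort, marker) {
  if (marker %in% c(NUCLEAR_MARKERS, CYTOPLASMIC_MARKERS)) {
    call_ihc_marker(cohort, marker)
  } else if (marker == "her2") {
    call_her2(cohort)
  } else if (marker == "her2_3plus") {
    s <- cohort$her2_score
    factor(ifelse(is.na(s), NA, ifelse(s == "3+", "positive", "negative")),
           levels = c("positive", "negative"))
  } else if (marker == "tp53") {
    factor(cohort$tp53, levels = c("nonfunctional", "functional"))
  } else if (marker == "pik3ca") {
    s <- cohort$pik3ca
    factor(ifelse(is.na(s), NA,
                  ifelse(s == "wild_type", "wild_type", "mutated")),
           levels = c("wild_type", "mutated"))
  } else if (marker %in% PANEL_GENES) {
    r <- cohort[[paste0("ratio_", marker)]]
    cut <- default_cutoffs()[[marker]]
    factor(ifelse(is.na(r), NA, ifelse(r > cut, "positive", "negative")),
           levels = c("positive", "negative"))
  } else {
    stop("unknown marker or status: '", marker, "'", call. = FALSE)
  }
}

#' Compare a marker or status between the MA and BL groups
#'
#' Builds the 2x2 contingency table of a marker call (or mutation /
#' functional status, or mRNA positivity at the default cutoff) against
#' the tumor group over non-missing calls, and tests association with the
#' two-sided Fisher exact test.
#'
#' @param cohort An [ma_cohort] with `group` labels.
#' @param marker An IHC marker name (see [call_ihc_marker()]), `"her2"`,
#'   `"her2_3plus"`, `"tp53"`, `"pik3ca"`, or a panel gene symbol for mRNA
#'   positivity.
#' @return List with the `table` (levels x group) and the Fisher `p`.
#' @export
#' @examples
#' compare_marker_by_group(generate_fixture_replica(), "egfr")
compare_marker_by_group <- function(cohort, marker) {
  calls <- marker_call_by_name(cohort, marker)
  grp <- factor(cohort$group, levels = c("MA", "BL"))
  keep <- !is.na(calls) & !is.na(grp)
  if (sum(keep & grp == "MA") == 0 || sum(keep & grp == "BL") == 0) {
    stop("marker '", marker, "' not assessable in both groups",
         call. = FALSE)
  }
  tab <- table(calls[keep], grp[keep])
  list(table = tab,
       p = fisher_exact_two_sided(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
}

#' Multiple correspondence analysis of a binary marker matrix
#'
#' Standard indicator-matrix MCA: each binary marker contributes a
#' positive and a negative indicator column; the standardized residual
#' matrix of the resulting correspondence table is decomposed by SVD and
#' coordinates are returned in principal normalization. Rows with any
#' missing marker are dropped listwise (messaged). Used to display how the
#' IHC markers co-vary across tumors.
#'
#' @param markers Data frame or matrix of logicals/0-1 per tumor (rows) and
#'   marker (columns).
#' @param n_dims Number of dimensions to return.
#' @return List with `row_coords`, `col_coords` (principal coordinates),
#'   `inertia_share` (shares of total inertia, summing to 1 over all
#'   non-trivial dimensions), `singular_values`, `n_used`.
#' @export
mca_coordinates <- function(markers, n_dims = 2) {
  X <- as.matrix(as.data.frame(lapply(as.data.frame(markers), function(x) {
    if (is.factor(x) || is.character(x)) {
      x <- as.character(x) == "positive"
    }
    as.numeric(x)
  })))
  if (ncol(X) < 2 || nrow(X) < 3) {
    stop("MCA requires at least 2 markers and 3 tumors", call. = FALSE)
  }
  keep <- stats::complete.cases(X)
  if (any(!keep)) {
    message(sum(!keep), " tumor(s) with missing marker values dropped")
  }
  X <- X[keep, , drop = FALSE]
  if (any(colSums(X) == 0 | colSums(X) == nrow(X))) {
    stop("constant marker column(s): rank-deficient indicator matrix",
         call. = FALSE)
  }
  # indicator expansion: one column per marker level
  Z <- do.call(cbind, lapply(seq_len(ncol(X)), function(j) {
    cbind(X[, j], 1 - X[, j])
  }))
  colnames(Z) <- as.vector(rbind(paste0(colnames(X), "+"),
                                 paste0(colnames(X), "-")))
  P <- Z / sum(Z)
  r <- rowSums(P)
  cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, cc)) %*% diag(1 / sqrt(cc))
  dec <- svd(S)
  nontrivial <- dec$d > 1e-12
  d <- dec$d[nontrivial]
  k <- min(n_dims, length(d))
  F_row <- diag(1 / sqrt(r)) %*% dec$u[, nontrivial, drop = FALSE] %*% diag(d, length(d))
  G_col <- diag(1 / sqrt(cc)) %*% dec$v[, nontrivial, drop = FALSE] %*% diag(d, length(d))
  rownames(F_row) <- rownames(X)
  rownames(G_col) <- colnames(Z)
  list(row_coords = F_row[, seq_len(k), drop = FALSE],
       col_coords = G_col[, seq_len(k), drop = FALSE],
       inertia_share = d^2 / sum(d^2),
       singular_values = d,
       row_masses = r,
       n_used = nrow(X))
}
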