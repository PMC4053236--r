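#' Fit a two-component Gaussian mixture by EM
#'
#' Used to dichotomize a bimodal expression-ratio distribution: the two
#' components model the negative and positive tumor populations on the
#' log10-ratio scale, and the positivity cutoff is taken at the
#' intersection of the two component densities (see
#' [density_intersection_cutoff()]).
#'
#' EM is initialized by splitting the sample at its median and taking the
#' moments of each half. Iteration stops when the log-likelihood improves
#' by less than `tol` or after `max_iter` iterations; the log-likelihood is
#' non-decreasing across iterations. If a component variance collapses
#' below `var_floor` the fit is re-initialized once (splitting at the
#' mean); a second collapse, or a degenerate (constant) sample, returns a
#' fit flagged `converged = FALSE`. Components are returned ordered by
#' mean.
#'
#' @param values Numeric vector, at least 10 finite values (typically
#'   log10-transformed ratios).
#' @param max_iter Maximum EM iterations.
#' @param tol Absolute log-likelihood convergence tolerance.
#' @param var_floor Lower bound on component variances.
#' @return An object of class `ma_mixture` with elements `w` (weights
#'   summing to 1), `mu` (ordered means), `sd`, `loglik`, `loglik_trace`,
#'   `n_iter`, `converged`, `degenerate`, `n`.
#' @export
#' @examples
#' set.seed(1)
#' x <- c(rnorm(250, 1.5, 0.3), rnorm(250, 3.2, 0.3))
#' fit <- fit_two_gaussian_mixture(x)
#' fit$mu
fit_two_gaussian_mixture <- function(values, max_iter = 500L, tol = 1e-8,
                                     var_floor = 1e-4) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 10) {
    stop("need at least 10 finite values to fit a two-component mixture",
         call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    # constant sample: no two-component structure to estimate
    return(structure(
      list(w = c(0.5, 0.5), mu = c(x[1], x[1]),
           sd = rep(sqrt(var_floor), 2), loglik = NA_real_,
           loglik_trace = numeric(0), n_iter = 0L,
           converged = FALSE, degenerate = TRUE, n = n),
      class = "ma_mixture"))
  }

  init_at <- function(cutpoint) {
    lo <- x[x <= cutpoint]
    hi <- x[x > cutpoint]
    if (length(lo) < 2 || length(hi) < 2) {
      lo <- x[x <= stats::median(x)]
      hi <- x[x > stats::median(x)]
    }
    list(w = c(length(lo), length(hi)) / n,
         mu = c(mean(lo), mean(hi)),
         sd = pmax(c(stats::sd(lo), stats::sd(hi)), sqrt(var_floor)))
  }

  run_em <- function(par) {
    trace <- numeric(0)
    ll_old <- -Inf
    iter <- 0L
    collapsed <- FALSE
    repeat {
      iter <- iter + 1L
      d1 <- par$w[1] * stats::dnorm(x, par$mu[1], par$sd[1])
      d2 <- par$w[2] * stats::dnorm(x, par$mu[2], par$sd[2])
      tot <- d1 + d2
      tot[tot == 0] <- .Machine$double.xmin
      ll <- sum(log(tot))
      trace <- c(trace, ll)
      if (abs(ll - ll_old) < tol || iter >= max_iter) {
        return(list(par = par, loglik = ll, trace = trace, n_iter = iter,
                    converged = abs(ll - ll_old) < tol,
                    collapsed = collapsed))
      }
      ll_old <- ll
      r2 <- d2 / tot
      r1 <- 1 - r2
      n1 <- sum(r1); n2 <- sum(r2)
      if (n1 < 1e-8 || n2 < 1e-8) {
        return(list(par = par, loglik = ll, trace = trace, n_iter = iter,
                    converged = FALSE, collapsed = TRUE))
      }
      mu <- c(sum(r1 * x) / n1, sum(r2 * x) / n2)
      v1 <- sum(r1 * (x - mu[1])^2) / n1
      v2 <- sum(r2 * (x - mu[2])^2) / n2
      if (v1 < var_floor || v2 < var_floor) collapsed <- TRUE
      par <- list(w = c(n1, n2) / n, mu = mu,
                  sd = sqrt(pmax(c(v1, v2), var_floor)))
    }
  }

  res <- run_em(init_at(stats::median(x)))
  degenerate <- FALSE
  if (res$collapsed) {
    # one re-initialization allowed before flagging the fit
    res2 <- run_em(init_at(mean(x)))
    if (res2$collapsed) {
      res <- if (res2$loglik > res$loglik) res2 else res
      res$converged <- FALSE
      degenerate <- TRUE
    } else {
      res <- res2
    }
  }

  ord <- order(res$par$mu)
  structure(
    list(w = res$par$w[ord], mu = res$par$mu[ord], sd = res$par$sd[ord],
         loglik = res$loglik, loglik_trace = res$trace,
         n_iter = res$n_iter, converged = res$converged && !degenerate,
         degenerate = degenerate, n = n),
    class = "ma_mixture")
}

#' @export
print.ma_mixture <- function(x, ...) {
  cat("Two-component Gaussian mixture (n =", x$n, ")\n")
  cat(sprintf("  component 1: w = %.3f, mean = %.4f, sd = %.4f\n",
              x$w[1], x$mu[1], x$sd[1]))
  cat(sprintf("  component 2: w = %.3f, mean = %.4f, sd = %.4f\n",
              x$w[2], x$mu[2], x$sd[2]))
  cat(sprintf("  loglik = %.4f after %d iterations (converged: %s)\n",
              x$loglik, x$n_iter, x$converged))
  invisible(x)
}

#' Intersection of the two mixture component densities
#'
#' Solves `w1 * dnorm(x, mu1, sd1) = w2 * dnorm(x, mu2, sd2)` in closed
#' form (a quadratic in `x`; linear when the variances are equal) and
#' returns the root strictly between the two component means. This is the
#' optimal dichotomization point of a two-class Gaussian model: below it
#' the first (lower) component is the more likely origin, above it the
#' second.
#'
#' @param fit An `ma_mixture` with distinct component means.
#' @return The intersection point on the scale of the fitted data.
#' @export
mixture_intersection <- function(fit) {
  stopifnot(inherits(fit, "ma_mixture"))
  if (fit$degenerate || !(fit$mu[1] < fit$mu[2])) {
    stop("density intersection requires a non-degenerate fit with ",
         "distinct ordered means", call. = FALSE)
  }
  w <- fit$w; mu <- fit$mu; s <- fit$sd
  if (abs(s[1] - s[2]) < 1e-12) {
    # equal variances: the quadratic degenerates to a linear equation
    x <- (mu[1] + mu[2]) / 2 + s[1]^2 * log(w[1] / w[2]) / (mu[2] - mu[1])
    roots <- x
  } else {
    a <- 1 / s[1]^2 - 1 / s[2]^2
    b <- -2 * (mu[1] / s[1]^2 - mu[2] / s[2]^2)
    cc <- mu[1]^2 / s[1]^2 - mu[2]^2 / s[2]^2 -
      2 * log((w[1] * s[2]) / (w[2] * s[1]))
    disc <- b^2 - 4 * a * cc
    if (disc < 0) {
      stop("component densities do not intersect between the means; ",
           "consider the midpoint (mu1+mu2)/2 as a fallback", call. = FALSE)
    }
    roots <- c((-b - sqrt(disc)) / (2 * a), (-b + sqrt(disc)) / (2 * a))
  }
  inside <- roots[roots > fit$mu[1] & roots < fit$mu[2]]
  if (length(inside) == 0) {
    stop("no density intersection strictly between the component means ",
         "(extreme weight imbalance); consider the midpoint (mu1+mu2)/2 ",
         "as a fallback", call. = FALSE)
  }
  inside[1]
}

#' Positivity cutoff on the expression-ratio scale
#'
#' Back-transforms the log10-scale density intersection of a mixture fitted
#' to `log10(ratio + pseudocount)` onto the ratio scale.
#'
#' @param fit An `ma_mixture` fitted on `log10(ratio + pseudocount)`.
#' @param pseudocount Pseudocount used in the log transform (default 1).
#' @return Positive ratio-scale cutoff.
#' @export
density_intersection_cutoff <- function(fit, pseudocount = 1) {
  10^mixture_intersection(fit) - pseudocount
}

#' Default positivity cutoffs of the signature
#'
#' ER-negativity is defined by an ESR1 ratio at or below 20; ERBB2 (HER2)
#' positivity by a ratio above 7; AR and FOXA1 overexpression by a ratio
#' above 100. The same 100 convention is used as the fallback for the five
#' AR-pathway genes when no cohort-specific mixture cutoff is available.
#'
#' @return Named numeric vector over [PANEL_GENES] with class `ma_cutoffs`.
#' @export
default_cutoffs <- function() {
  cuts <- stats::setNames(rep(100, length(PANEL_GENES)), PANEL_GENES)
  cuts["ESR1"] <- 20
  cuts["ERBB2"] <- 7
  structure(cuts, class = "ma_cutoffs")
}

#' Derive per-gene positivity cutoffs from a cohort
#'
#' For each gene, fits a two-component Gaussian mixture to
#' `log10(ratio + 1)` over the non-missing tumors and places the cutoff at
#' the intersection of the component densities, back-transformed to the
#' ratio scale. Genes whose fit fails (fewer than 10 values, degenerate
#' sample, or no usable intersection) fall back to the documented default
#' cutoff with a warning.
#'
#' A cutoff is only trusted when the sample actually shows a clear bimodal
#' distribution: fits that do not converge, or whose component separation
#' `(mu2 - mu1) / max(sd)` falls below `min_separation`, also fall back to
#' the default.
#'
#' @param cohort An [ma_cohort].
#' @param genes Genes to process (default all nine panel genes).
#' @param max_iter,tol,var_floor Passed to [fit_two_gaussian_mixture()].
#' @param pseudocount Pseudocount of the log transform.
#' @param min_separation Minimum component separation (in pooled sd units)
#'   for a fitted cutoff to be accepted.
#' @return Named numeric vector of ratio-scale cutoffs (class
#'   `ma_cutoffs`), with the per-gene fits in attribute `fits`.
#' @export
#' @examples
#' coh <- generate_cohort(seed = 1)
#' cuts <- derive_cutoffs(coh, genes = c("AR", "FOXA1"))
#' round(cuts, 1)
derive_cutoffs <- function(cohort, genes = PANEL_GENES, max_iter = 500L,
                           tol = 1e-8, var_floor = 1e-4, pseudocount = 1,
                           min_separation = 2) {
  defaults <- default_cutoffs()
  cuts <- numeric(0)
  fits <- list()
  for (g in genes) {
    col <- paste0("ratio_", g)
    if (!col %in% names(cohort)) {
      stop("gene ", g, " absent from the cohort expression panels",
           call. = FALSE)
    }
    v <- cohort[[col]]
    v <- v[!is.na(v)]
    cut_g <- tryCatch({
      fit <- fit_two_gaussian_mixture(log10(v + pseudocount),
                                      max_iter = max_iter, tol = tol,
                                      var_floor = var_floor)
      fits[[g]] <- fit
      if (fit$degenerate) stop("degenerate fit")
      if (!fit$converged) stop("EM did not converge")
      sep <- (fit$mu[2] - fit$mu[1]) / max(fit$sd)
      if (sep < min_separation) {
        stop(sprintf("no clear bimodal distribution (separation %.2f)", sep))
      }
      density_intersection_cutoff(fit, pseudocount = pseudocount)
    }, error = function(e) {
      warning(sprintf(
        "mixture cutoff for %s failed (%s); falling back to default %.9g",
        g, conditionMessage(e), defaults[[g]]), call. = FALSE)
      defaults[[g]]
    })
    if (!is.finite(cut_g) || cut_g <= 0) {
      warning(sprintf(
        "mixture cutoff for %s not positive; falling back to default %.9g",
        g, defaults[[g]]), call. = FALSE)
      cut_g <- defaults[[g]]
    }
    cuts[g] <- cut_g
  }
  structure(cuts, class = "ma_cutoffs", fits = fits)
}

#' Plot a fitted ratio mixture with its cutoff
#'
#' Histogram of the log10-transformed ratios overlaid with the two scaled
#' component densities and the density-intersection cutoff.
#'
#' @param x An `ma_mixture`.
#' @param values Optional data vector to histogram (log scale).
#' @param ... Passed to [graphics::hist()].
#' @export
plot.ma_mixture <- function(x, values = NULL, ...) {
  lim <- range(x$mu + 3 * c(-x$sd[1], x$sd[2]))
  if (!is.null(values)) {
    graphics::hist(values, freq = FALSE, main = "Two-Gaussian ratio mixture",
                   xlab = "log10(ratio + 1)", ...)
  } else {
    graphics::plot(NA, xlim = lim, ylim = c(0, 1.2 / (min(x$sd) * sqrt(2 * pi))),
                   xlab = "log10(ratio + 1)", ylab = "density",
                   main = "Two-Gaussian ratio mixture")
  }
  xs <- seq(lim[1], lim[2], length.out = 400)
  graphics::lines(xs, x$w[1] * stats::dnorm(xs, x$mu[1], x$sd[1]), col = 2)
  graphics::lines(xs, x$w[2] * stats::dnorm(xs, x$mu[2], x$sd[2]), col = 4)
  if (x$mu[1] < x$mu[2] && !x$degenerate) {
    graphics::abline(v = mixture_intersection(x), lty = 2)
  }
  invisible(x)
}
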