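# Maximum-likelihood logistic fit by iteratively reweighted least squares.
#
# Started at the null model (intercept = logit of the member fraction,
# slopes 0); converged when the relative deviance change drops below `tol`
# or after `max_iter` iterations (non-convergence is reported, not an
# error: separated sets yield extreme but still interpretable
# coefficients).  `ridge > 0` adds an L2 penalty on the slope terms only,
# an optional stabilizer for separated fits.
irls_logit <- function(X, y, ridge = 0, max_iter = 25L, tol = 1e-8) {
  n <- nrow(X); p <- ncol(X)
  if (qr(X)$rank < p)
    stop("collinear design: covariates are numerically rank-deficient")
  pbar <- mean(y)
  beta <- c(stats::qlogis(pbar), rep(0, p - 1L))
  null_dev <- -2 * (sum(y) * log(pbar) + sum(1 - y) * log(1 - pbar))
  dev <- null_dev
  converged <- FALSE
  it <- 0L
  pen <- diag(c(0, rep(ridge, p - 1L)), p)
  repeat {
    it <- it + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    A <- crossprod(X * sqrt(w)) + pen
    beta_new <- drop(solve(A, crossprod(X, w * z)))
    mu_new <- stats::plogis(drop(X %*% beta_new))
    mu_new <- pmin(pmax(mu_new, 1e-12), 1 - 1e-12)
    dev_new <- -2 * sum(y * log(mu_new) + (1 - y) * log(1 - mu_new))
    delta <- abs(dev_new - dev) / (abs(dev_new) + 0.1)
    beta <- beta_new; dev <- dev_new
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  eta <- drop(X %*% beta)
  mu_raw <- stats::plogis(eta)
  # fitted probabilities numerically 0 or 1 signal (quasi-)separation:
  # the MLE diverges and the flat-deviance stop is not real convergence
  separated <- ridge == 0 && any(mu_raw < 1e-10 | mu_raw > 1 - 1e-10)
  mu <- pmin(pmax(mu_raw, 1e-12), 1 - 1e-12)
  w <- mu * (1 - mu)
  cov <- solve(crossprod(X * sqrt(w)) + pen)
  se <- sqrt(diag(cov))
  list(coefficients = beta, se = se, deviance = dev,
       null_deviance = null_dev, converged = converged && !separated,
       separated = separated, n_iterations = it)
}

new_gsa_fit <- function(raw, names, model, n, n_members) {
  if (raw$separated)
    warning("fitted probabilities numerically 0 or 1: (quasi-)separated ",
            "set; coefficients are unstable (consider ridge > 0)")
  else if (!raw$converged)
    warning("IRLS did not converge in ", raw$n_iterations, " iteration(s)")
  coefficients <- setNames(raw$coefficients, names)
  se <- setNames(raw$se, names)
  p <- setNames(wald_pvalue(coefficients, se), names)
  structure(list(coefficients = coefficients, se = se, p = p,
                 converged = raw$converged, separated = raw$separated,
                 n_iterations = raw$n_iterations,
                 deviance = raw$deviance, null_deviance = raw$null_deviance,
                 model = model, n = n, n_members = n_members),
            class = "gsa_fit")
}

#' @export
print.gsa_fit <- function(x, ...) {
  cat(x$model, "logistic membership fit:", x$n_members, "members /",
      x$n, "genes\n")
  tab <- cbind(estimate = x$coefficients, se = x$se, p = x$p)
  print(signif(tab, 4L))
  cat("deviance", signif(x$deviance, 6L), "(null", signif(x$null_deviance, 6L),
      ") converged:", x$converged, "in", x$n_iterations, "iteration(s)\n")
  invisible(x)
}

check_member <- function(ind, n) {
  if (length(ind) != n) stop("membership length does not match the ranking")
  if (all(ind == 1L) || all(ind == 0L))
    stop("degenerate set: membership must contain both classes")
  ind
}

#' Fit the univariate logistic membership model
#'
#' Models the probability of a gene being annotated to a set as a logistic
#' function of a single ranking statistic X:
#' `logit P(member) = intercept + alpha * X`.  A significantly positive
#' `alpha` means the set is enriched among high X values (competitive
#' enrichment against the complement of the set).
#'
#' @param x numeric vector of ranking values, or a 1-dimensional
#'   [gene_ranking].
#' @param member a [membership_vector] or binary 0/1 vector aligned to `x`.
#' @param ridge optional non-negative L2 penalty on the slope (default 0).
#' @param max_iter,tol IRLS iteration cap and relative deviance tolerance.
#' @return A `gsa_fit` with coefficients `(Intercept)` and `alpha`,
#'   standard errors, two-sided Wald p-values, deviances and convergence
#'   information.
#' @export
fit_univariate <- function(x, member, ridge = 0, max_iter = 25L, tol = 1e-8) {
  if (inherits(x, "gene_ranking")) {
    if (ncol(x) != 1L) stop("fit_univariate expects a 1-dimensional ranking")
    x <- drop(unclass(x))
  }
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("x must be finite")
  if (stats::var(x) == 0) stop("degenerate covariate: x has zero variance")
  ind <- check_member(as_indicator(member), length(x))
  raw <- irls_logit(cbind(1, x), ind, ridge, max_iter, tol)
  new_gsa_fit(raw, c("(Intercept)", "alpha"), "univariate",
              length(x), sum(ind))
}

#' Fit the bivariate logistic membership model with interaction
#'
#' Models set membership as a logistic function of two ranking statistics
#' and their product:
#' `logit P(member) = intercept + alpha*X + beta*Y + gamma*X*Y`.
#' When `gamma != 0` the fitted log-odds surface is a hyperbolic
#' paraboloid (saddle surface); see [saddle_point()] and
#' [classify_pattern()].
#'
#' @param xy numeric matrix with two columns (X, Y), or a 2-dimensional
#'   [gene_ranking].
#' @param member a [membership_vector] or binary 0/1 vector aligned to the
#'   rows of `xy`.
#' @inheritParams fit_univariate
#' @return A `gsa_fit` with coefficients `(Intercept)`, `alpha`, `beta`
#'   and `gamma`.
#' @export
fit_bivariate <- function(xy, member, ridge = 0, max_iter = 25L, tol = 1e-8) {
  if (inherits(xy, "gene_ranking")) xy <- unclass(xy)
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L) stop("fit_bivariate expects exactly 2 ranking columns")
  if (any(!is.finite(xy))) stop("ranking values must be finite")
  if (any(apply(xy, 2L, stats::var) == 0))
    stop("degenerate covariate: zero-variance column")
  ind <- check_member(as_indicator(member), nrow(xy))
  X <- cbind(1, xy[, 1L], xy[, 2L], xy[, 1L] * xy[, 2L])
  raw <- irls_logit(X, ind, ridge, max_iter, tol)
  new_gsa_fit(raw, c("(Intercept)", "alpha", "beta", "gamma"), "bivariate",
              nrow(xy), sum(ind))
}

#' Two-sided Wald p-value for a fitted coefficient
#'
#' `p = 2 * (1 - Phi(|coef / se|))` with Phi the standard normal CDF, the
#' conventional reference distribution for maximum-likelihood logistic
#' coefficients.
#'
#' @param coef coefficient estimate(s) (log odds ratio scale).
#' @param se standard error(s), strictly positive.
#' @return p-value(s) in `[0, 1]`.
#' @examples
#' wald_pvalue(1.959964, 1)  # ~0.05
#' @export
wald_pvalue <- function(coef, se) {
  if (any(!is.finite(se)) || any(se <= 0))
    stop("invalid standard error: must be finite and > 0")
  2 * stats::pnorm(-abs(coef / se))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' FDR adjustment of one family of p-values.  In a gene-set analysis each
#' coefficient forms its own family: all sets' alpha p-values are adjusted
#' together, likewise all beta and all gamma.
#'
#' @param pvalues numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(pvalues) {
  pvalues <- as.numeric(pvalues)
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("invalid p-value: all inputs must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Saddle point of the fitted bivariate log-odds surface
#'
#' With a non-zero interaction the fitted surface
#' `intercept + alpha*X + beta*Y + gamma*X*Y` is a hyperbolic paraboloid
#' with stationary (saddle) point at `(-beta/gamma, -alpha/gamma)`; the
#' genes of the set concentrate in the quadrant opposite it.  When
#' `gamma = 0` the surface is a plane and the saddle point is undefined.
#'
#' @param fit a bivariate `gsa_fit`.
#' @return An object of class `saddle_point`: list with `x0`, `y0` and
#'   `defined`.
#' @export
saddle_point <- function(fit) {
  stopifnot(inherits(fit, "gsa_fit"))
  if (fit$model != "bivariate")
    stop("saddle_point requires a bivariate fit")
  g <- fit$coefficients[["gamma"]]
  if (g == 0) {
    sp <- list(x0 = NA_real_, y0 = NA_real_, defined = FALSE)
  } else {
    sp <- list(x0 = -fit$coefficients[["beta"]] / g,
               y0 = -fit$coefficients[["alpha"]] / g,
               defined = TRUE)
  }
  structure(sp, class = "saddle_point")
}

#' @export
print.saddle_point <- function(x, ...) {
  if (x$defined)
    cat("saddle point at (", x$x0, ",", x$y0, ")\n")
  else
    cat("no saddle point: interaction is zero (plane)\n")
  invisible(x)
}
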