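test_that("univariate fit matches the 2x2 contingency closed form", {
  # members: 3 at x=1, 1 at x=0; non-members: 5 at x=1, 15 at x=0
  x <- c(rep(1, 8), rep(0, 16))
  member <- c(rep(1, 3), rep(0, 5), rep(1, 1), rep(0, 15))
  fit <- fit_univariate(x, member)
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients["alpha"]), log(9), tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["(Intercept)"]), log(1 / 15),
               tolerance = 1e-6)
})

test_that("bivariate fit matches the saturated four-cell closed form and glm", {
  cells <- data.frame(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1),
                      members = c(10, 20, 30, 60),
                      nonmembers = c(90, 80, 70, 40))
  cfg <- binary_config(cells)
  fit <- fit_bivariate(cbind(cfg$x, cfg$y), cfg$member)
  oracle <- binary_bivariate_oracle(cells)
  expect_equal(unname(fit$coefficients), unname(oracle), tolerance = 1e-6)

  # independent route: R's own IRLS implementation
  g <- glm(cfg$member ~ cfg$x * cfg$y, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(g)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(summary(g)$coefficients[, 2]),
               tolerance = 1e-4)
  expect_equal(fit$deviance, deviance(g), tolerance = 1e-8)
})

test_that("coefficients and Wald p-values agree with glm on continuous data", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 400L
    x <- rnorm(n); y <- rnorm(n)
    member <- rbinom(n, 1L, plogis(-1.5 + 0.4 * x - 0.3 * y + 0.2 * x * y))
    if (sum(member) < 2L) next
    fit <- fit_bivariate(cbind(x, y), member)
    g <- glm(member ~ x * y, family = binomial())
    expect_equal(unname(fit$coefficients), unname(coef(g)), tolerance = 1e-6)
    expect_equal(unname(fit$coefficients / fit$se),
                 unname(summary(g)$coefficients[, 3]), tolerance = 1e-3)
  }
})

test_that("symmetric configurations force exactly null slopes", {
  # univariate: members at +-1, non-members at +-2, balanced
  x <- c(-1, 1, -2, 2)
  member <- c(1, 1, 0, 0)
  x <- rep(x, 10); member <- rep(member, 10)
  fit <- fit_univariate(x, member)
  expect_lt(abs(fit$coefficients["alpha"]), 1e-8)

  # bivariate: members on (+-1, +-1), non-members on (+-2, +-2)
  pts <- rbind(expand.grid(x = c(-1, 1), y = c(-1, 1)),
               expand.grid(x = c(-2, 2), y = c(-2, 2)))
  member2 <- rep(c(1, 0), each = 4)
  idx <- rep(seq_len(8), 5)
  fit2 <- fit_bivariate(as.matrix(pts[idx, ]), member2[idx])
  expect_lt(max(abs(fit2$coefficients[c("alpha", "beta", "gamma")])), 1e-8)
  expect_equal(unname(fit2$coefficients["(Intercept)"]), qlogis(0.5),
               tolerance = 1e-8)
})

test_that("simulated data from a known model is recovered within 3 SE", {
  set.seed(1203)
  n <- 20000L
  truth <- c(-2, 0.8)
  x <- rnorm(n)
  member <- rbinom(n, 1L, plogis(truth[1] + truth[2] * x))
  fit <- fit_univariate(x, member)
  expect_true(all(abs(fit$coefficients - truth) <= 3 * fit$se))

  truth2 <- c(-2, 0.5, 0.3, 0.4)
  x <- rnorm(n); y <- rnorm(n)
  member <- rbinom(n, 1L, plogis(truth2[1] + truth2[2] * x +
                                   truth2[3] * y + truth2[4] * x * y))
  fit2 <- fit_bivariate(cbind(x, y), member)
  expect_true(all(abs(fit2$coefficients - truth2) <= 3 * fit2$se))
})

test_that("affine equivariance: rescaling X rescales alpha, not its p-value", {
  set.seed(55)
  n <- 2000L
  x <- rnorm(n, sd = 2.5)
  member <- rbinom(n, 1L, plogis(-2 + 0.5 * x))
  f1 <- fit_univariate(x, member)
  s <- sd(x)
  f2 <- fit_univariate((x - mean(x)) / s, member)
  expect_equal(unname(f2$coefficients["alpha"]),
               unname(f1$coefficients["alpha"]) * s, tolerance = 1e-6)
  expect_equal(unname(f2$p["alpha"]), unname(f1$p["alpha"]),
               tolerance = 1e-8)
})

test_that("shifting member X values upward does not decrease alpha", {
  set.seed(77)
  n <- 1000L
  x <- rnorm(n)
  member <- rbinom(n, 1L, 0.1)
  if (sum(member) < 2L) member[1:5] <- 1L
  base <- fit_univariate(x, member)$coefficients["alpha"]
  for (delta in c(0.2, 0.5, 1)) {
    x2 <- x + delta * member
    shifted <- fit_univariate(x2, member)$coefficients["alpha"]
    expect_gte(shifted, base - 1e-10)
  }
})

test_that("degenerate inputs raise informative errors", {
  expect_error(fit_univariate(c(1, 2, 3), c(1, 1, 1)), "degenerate set")
  expect_error(fit_univariate(c(2, 2, 2), c(1, 0, 1)), "zero variance")
  x <- rnorm(40); m <- rep(c(1, 0), 20)
  expect_error(fit_bivariate(cbind(x, 2 * x), m), "collinear")
})

test_that("non-convergence under separation is flagged, not fatal", {
  set.seed(123)
  x <- c(rnorm(20, 5), rnorm(180, -5))
  member <- c(rep(1L, 20), rep(0L, 180))
  expect_warning(fit <- fit_univariate(x, member), "separated")
  expect_false(fit$converged)
  expect_true(fit$separated)
  expect_true(all(is.finite(fit$coefficients)))
  # the ridge stabilizer tames the estimate
  fit_r <- fit_univariate(x, member, ridge = 1)
  expect_true(fit_r$converged)
  expect_lt(abs(fit_r$coefficients["alpha"]),
            abs(fit$coefficients["alpha"]))
})

test_that("wald_pvalue follows the standard normal reference", {
  expect_equal(wald_pvalue(0, 1), 1)
  expect_equal(wald_pvalue(1.959964, 1), 0.05, tolerance = 1e-4)
  expect_equal(wald_pvalue(-1.959964, 1), wald_pvalue(1.959964, 1))
  expect_error(wald_pvalue(1, 0), "invalid standard error")
  expect_error(wald_pvalue(1, -2), "invalid standard error")
})

test_that("bh_adjust matches the direct step-up oracle and its bounds", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.5), 0.5)
  set.seed(99)
  for (case in 1:200) {
    m <- sample(1:60, 1)
    p <- runif(m)^sample(1:3, 1)
    adj <- bh_adjust(p)
    expect_equal(adj, bh_stepup_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= pmin(1, m * p) + 1e-15))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))  # order preserved
    perm <- sample(m)
    expect_equal(bh_adjust(p[perm]), adj[perm])
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "invalid p-value")
})

test_that("saddle_point reproduces (-beta/gamma, -alpha/gamma)", {
  sp <- saddle_point(fake_bivariate_fit(alpha = 1, beta = 2, gamma = 0.5))
  expect_true(sp$defined)
  expect_equal(c(sp$x0, sp$y0), c(-4, -2))

  origin <- saddle_point(fake_bivariate_fit(0, 0, 1))
  expect_equal(c(origin$x0, origin$y0), c(0, 0))

  flat <- saddle_point(fake_bivariate_fit(1, 1, 0))
  expect_false(flat$defined)

  uv <- fit_univariate(rnorm(50), rep(c(1, 0), 25))
  expect_error(saddle_point(uv), "bivariate")
})
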