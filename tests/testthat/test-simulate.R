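test_that("simulation_spec validates its fields", {
  expect_s3_class(simulation_spec(), "simulation_spec")
  expect_error(simulation_spec(n_genes = 100L, n_sets = 3L, set_size = 40L),
               "capacity")
  expect_error(simulation_spec(n_genes = 100L, n_sets = 2L, set_size = 50L),
               "capacity")
  expect_error(simulation_spec(rho = 1), "rho")
  expect_error(simulation_spec(pattern = "q9x"))
})

test_that("the same seed reproduces the dataset exactly; RNG state is local", {
  spec <- simulation_spec(n_genes = 500L, set_size = 20L, seed = 33L)
  set.seed(1); before <- runif(1)
  set.seed(1)
  d1 <- simulate_dataset(spec)
  after <- runif(1)
  d2 <- simulate_dataset(spec)
  expect_identical(unclass(d1$ranking), unclass(d2$ranking))
  expect_identical(d1$collection, d2$collection)
  expect_identical(d1$truth, d2$truth)
  expect_identical(before, after)  # global RNG stream untouched
})

test_that("a null plant is distributionally indistinguishable from background", {
  d <- simulate_dataset(simulation_spec(n_genes = 4000L, set_size = 400L,
                                        pattern = "null", effect = 0,
                                        seed = 44L))
  member <- d$collection$sets[[1]]
  inside <- rownames(d$ranking) %in% member
  for (j in 1:2) {
    ks <- suppressWarnings(ks.test(d$ranking[inside, j],
                                   d$ranking[!inside, j]))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("bimodal plants split into opposite corners with the right orientation", {
  for (pat in c("b13", "b24")) {
    spec <- simulation_spec(n_genes = 1000L, set_size = 100L, pattern = pat,
                            effect = 1, seed = 55L)
    d <- simulate_dataset(spec)
    genes <- d$collection$sets[[1]]
    xy <- d$ranking[genes, ]
    h1 <- seq_len(50L); h2 <- 51:100
    # halves sit at opposite corners
    expect_equal(sign(colMeans(xy[h1, ])), -sign(colMeans(xy[h2, ])),
                 ignore_attr = TRUE)
    # product orientation: positive along quadrants 1&3, negative along 2&4
    expected <- if (pat == "b13") 1 else -1
    expect_equal(sign(mean(xy[h1, 1] * xy[h1, 2])), expected)
    expect_equal(sign(mean(xy[h2, 1] * xy[h2, 2])), expected)
  }
})

test_that("the shared latent induces the requested equicorrelation structure", {
  rho <- 0.5; m <- 100L
  spec <- simulation_spec(n_genes = 5000L, n_sets = 30L, set_size = m,
                          pattern = "null", effect = 0, rho = rho,
                          seed = 66L)
  d <- simulate_dataset(spec)
  stats <- do.call(rbind, lapply(d$collection$sets, function(genes) {
    xy <- d$ranking[genes, ]
    cbind(msq = colMeans(xy)^2, v = apply(xy, 2L, var))
  }))
  # E[(set mean)^2] = rho + (1-rho)/m; E[within-set var] = 1 - rho
  expect_equal(mean(stats[, "msq"]), rho + (1 - rho) / m, tolerance = 0.4)
  expect_equal(mean(stats[, "v"]), 1 - rho, tolerance = 0.1)
})

test_that("calibration reports are reproducible and nominal under independence", {
  spec <- simulation_spec(n_genes = 600L, set_size = 30L, pattern = "null",
                          effect = 0, rho = 0, n_reps = 60L, seed = 77L)
  r1 <- calibrate_null(spec)
  r2 <- calibrate_null(spec)
  expect_identical(r1, r2)
  expect_equal(r1$coefficient, c("alpha", "beta", "gamma"))
  expect_true(all(r1$rate >= r1$ci_low & r1$rate <= r1$ci_high))
  # loose nominal check at this replicate count
  expect_true(all(r1$rate < 0.2))
  expect_error(calibrate_null(simulation_spec(effect = 0.5)), "effect = 0")
})

test_that("power increases with effect size and saturates for large shifts", {
  base <- function(effect, seed, ...) {
    estimate_power(simulation_spec(n_genes = 2000L, set_size = 50L,
                                   pattern = "q1i", effect = effect,
                                   n_reps = 50L, seed = seed), ...)
  }
  rate <- function(p) p$rate[p$measure == "rate_recovered"]
  expect_gte(rate(base(1.0, 88L)), rate(base(0.2, 88L)))
  # very large shifts separate the unpenalized fit (flagged, unstable
  # coefficients); the ridge stabilizer restores the power limit
  expect_gte(rate(base(3.0, 88L, ridge = 0.5)), 0.98)
  expect_error(estimate_power(simulation_spec(effect = 0)), "effect > 0")
})
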