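# Shared fixtures and independent oracles, all built in code.

write_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Direct Benjamini-Hochberg step-up formula: sort ascending,
# adj_(i) = min_{j >= i} p_(j) * m / j, capped at 1, original order.
# Independent of stats::p.adjust.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- ps * m / seq_len(m)
  for (i in seq_len(m)) adj[i] <- min(adj[i:m])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Binary-covariate configuration from per-cell member/non-member counts.
# cells: data.frame with columns x, y, members, nonmembers.
binary_config <- function(cells) {
  x <- rep(cells$x, cells$members + cells$nonmembers)
  y <- rep(cells$y, cells$members + cells$nonmembers)
  member <- unlist(lapply(seq_len(nrow(cells)), function(i)
    c(rep(1L, cells$members[i]), rep(0L, cells$nonmembers[i]))))
  list(x = x, y = y, member = member)
}

# Saturated-model closed form for all-binary designs: each coefficient is
# a log odds-ratio contrast of the four cell odds.
binary_bivariate_oracle <- function(cells) {
  odds <- function(xi, yi) {
    i <- which(cells$x == xi & cells$y == yi)
    cells$members[i] / cells$nonmembers[i]
  }
  c(intercept = log(odds(0, 0)),
    alpha = log(odds(1, 0) / odds(0, 0)),
    beta = log(odds(0, 1) / odds(0, 0)),
    gamma = log(odds(1, 1) * odds(0, 0) / (odds(1, 0) * odds(0, 1))))
}

# A fit-shaped object with prescribed coefficients, for geometry tests.
fake_bivariate_fit <- function(alpha, beta, gamma, intercept = 0) {
  co <- c(`(Intercept)` = intercept, alpha = alpha, beta = beta,
          gamma = gamma)
  structure(list(coefficients = co, se = rep(1, 4), p = rep(1, 4),
                 converged = TRUE, n_iterations = 1L, deviance = 0,
                 null_deviance = 0, model = "bivariate", n = 0L,
                 n_members = 0L),
            class = "gsa_fit")
}

# The 27 sign triples.
all_sign_triples <- function() {
  as.matrix(expand.grid(a = -1:1, b = -1:1, g = -1:1))
}
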