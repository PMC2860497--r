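result_columns <- c("set_id", "name", "size", "lor_0", "lor_X", "lor_Y",
                    "lor_I", "se_X", "se_Y", "se_I", "p_X", "p_Y", "p_I",
                    "padj_X", "padj_Y", "padj_I", "pattern", "converged")

empty_result <- function() {
  out <- data.frame(set_id = character(0), name = character(0),
                    size = integer(0), lor_0 = numeric(0),
                    lor_X = numeric(0), lor_Y = numeric(0),
                    lor_I = numeric(0), se_X = numeric(0),
                    se_Y = numeric(0), se_I = numeric(0),
                    p_X = numeric(0), p_Y = numeric(0), p_I = numeric(0),
                    padj_X = numeric(0), padj_Y = numeric(0),
                    padj_I = numeric(0), pattern = character(0),
                    converged = logical(0), stringsAsFactors = FALSE)
  class(out) <- c("gsa_result", "data.frame")
  out
}

prepare_sets <- function(ranking, coll, min_size, max_size, verbose) {
  stopifnot(inherits(ranking, "gene_ranking"),
            inherits(coll, "gene_set_collection"))
  if (length(coll) == 0L) stop("the gene-set collection is empty")
  universe <- ranking_universe(ranking)
  kept <- filter_by_size(coll, universe, min_size, max_size,
                         verbose = verbose)
  if (length(kept) == 0L)
    warning("no gene set within the size bounds [", min_size, ", ",
            max_size, "] after intersection with the universe")
  kept
}

run_gsa_engine <- function(ranking, coll, bivariate, min_size, max_size,
                           threshold, standardize, ridge, verbose) {
  if (standardize) ranking <- standardize_ranking(ranking)
  kept <- prepare_sets(ranking, coll, min_size, max_size, verbose)
  if (length(kept) == 0L) return(empty_result())
  universe <- ranking_universe(ranking)
  ids <- sort(names(kept))
  if (verbose)
    message("fitting ", length(ids), " set(s) on a universe of ",
            length(universe), " genes")
  rows <- lapply(ids, function(id) {
    member <- membership_vector(kept, id, universe)
    fit <- suppressWarnings(       # convergence status lands in the table
      if (bivariate) fit_bivariate(ranking, member, ridge = ridge)
      else fit_univariate(ranking, member, ridge = ridge))
    co <- fit$coefficients; se <- fit$se; p <- fit$p
    data.frame(
      set_id = id,
      name = if (is.na(kept$descriptions[[id]])) id else kept$descriptions[[id]],
      size = sum(member$indicator),
      lor_0 = co[["(Intercept)"]],
      lor_X = co[["alpha"]],
      lor_Y = if (bivariate) co[["beta"]] else NA_real_,
      lor_I = if (bivariate) co[["gamma"]] else NA_real_,
      se_X = se[["alpha"]],
      se_Y = if (bivariate) se[["beta"]] else NA_real_,
      se_I = if (bivariate) se[["gamma"]] else NA_real_,
      p_X = p[["alpha"]],
      p_Y = if (bivariate) p[["beta"]] else NA_real_,
      p_I = if (bivariate) p[["gamma"]] else NA_real_,
      converged = fit$converged,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # one BH family per coefficient, across exactly the fitted sets
  out$padj_X <- bh_adjust(out$p_X)
  if (bivariate) {
    out$padj_Y <- bh_adjust(out$p_Y)
    out$padj_I <- bh_adjust(out$p_I)
    out$pattern <- vapply(seq_len(nrow(out)), function(i) {
      s <- effective_signs(
        c(out$lor_X[i], out$lor_Y[i], out$lor_I[i]),
        c(out$padj_X[i], out$padj_Y[i], out$padj_I[i]), threshold)
      classify_pattern(s)
    }, character(1))
  } else {
    out$padj_Y <- NA_real_
    out$padj_I <- NA_real_
    out$pattern <- vapply(seq_len(nrow(out)), function(i) {
      s <- effective_signs(c(out$lor_X[i], 0, 0),
                           c(out$padj_X[i], 1, 1), threshold)
      classify_pattern(s)
    }, character(1))
  }
  out <- out[result_columns]
  rownames(out) <- NULL
  class(out) <- c("gsa_result", "data.frame")
  out
}

#' Run a multidimensional (bivariate) gene-set analysis
#'
#' For every gene set whose effective size lies within the bounds, fits
#' the bivariate logistic membership model with interaction on the two
#' ranking dimensions, adjusts p-values per coefficient family
#' (Benjamini-Hochberg across all fitted sets: all alpha together, all
#' beta, all gamma), and classifies each set into an enrichment pattern.
#'
#' @param ranking a 2-dimensional [gene_ranking]; its genes define the
#'   universe and the competitive complement of every set.
#' @param coll a [gene_set_collection].
#' @param min_size,max_size inclusive bounds on effective set size
#'   (defaults 10 and 500).
#' @param threshold significance level applied to adjusted p-values in
#'   the pattern classification (default 0.05).
#' @param standardize centre/scale the ranking columns before fitting
#'   (default `FALSE`: coefficients stay on the raw statistic scale).
#' @param ridge optional L2 stabilizer for separated fits (default 0).
#' @param verbose log filtering and fitting progress.
#' @return A `gsa_result` data.frame, one row per analysed set, ordered
#'   by `set_id`, with coefficients (`lor_*`, log odds ratio scale),
#'   standard errors, raw and adjusted p-values, the `pattern` label and
#'   a `converged` flag.
#' @export
run_md_gsa <- function(ranking, coll, min_size = 10L, max_size = 500L,
                       threshold = 0.05, standardize = FALSE, ridge = 0,
                       verbose = FALSE) {
  if (ncol(ranking) != 2L)
    stop("run_md_gsa needs a 2-dimensional ranking; see align_rankings()")
  run_gsa_engine(ranking, coll, TRUE, min_size, max_size, threshold,
                 standardize, ridge, verbose)
}

#' Run a univariate gene-set analysis
#'
#' The one-dimensional analogue of [run_md_gsa()]: fits
#' `logit P(member) = intercept + alpha * X` per set and adjusts the
#' alpha p-values as a single BH family.  Patterns reduce to `xh`
#' (enriched at high X), `xl` (low X) or `NS`.
#'
#' @param ranking a 1-dimensional [gene_ranking].
#' @inheritParams run_md_gsa
#' @return A `gsa_result` data.frame; Y and interaction columns are `NA`.
#' @export
run_uv_gsa <- function(ranking, coll, min_size = 10L, max_size = 500L,
                       threshold = 0.05, standardize = FALSE, ridge = 0,
                       verbose = FALSE) {
  if (ncol(ranking) != 1L)
    stop("run_uv_gsa needs a 1-dimensional ranking")
  run_gsa_engine(ranking, coll, FALSE, min_size, max_size, threshold,
                 standardize, ridge, verbose)
}

#' @export
print.gsa_result <- function(x, ...) {
  cat("gsa_result:", nrow(x), "gene set(s)\n")
  if (nrow(x) > 0L) {
    pat <- table(x$pattern)
    cat("  patterns:",
        paste(names(pat), pat, sep = ":", collapse = " "), "\n")
  }
  NextMethod()
}

#' Confidence-ellipse summary of a 2-D point cloud
#'
#' Summarises a set of points in the (X, Y) ranking plane by their sample
#' mean and covariance; the ellipse boundary is the locus of points at
#' squared Mahalanobis distance equal to the chi-square quantile with 2
#' degrees of freedom at the requested level.  Used to contrast the cloud
#' of all genes with the genes of one set.
#'
#' @param points numeric matrix or data.frame with 2 columns and at least
#'   3 rows.
#' @param level coverage level in (0, 1), default 0.95.
#' @return An object of class `ellipse_summary`: list with `mean`,
#'   `covariance`, `level`, `radius` (`sqrt(qchisq(level, 2))`) and
#'   `degenerate` (singular covariance).
#' @export
ellipse_summary <- function(points, level = 0.95) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("'points' must have exactly 2 columns")
  if (nrow(points) < 3L)
    stop("insufficient data: at least 3 points are required")
  if (level <= 0 || level >= 1) stop("'level' must lie in (0, 1)")
  m <- colMeans(points)
  S <- stats::cov(points)
  structure(list(mean = m, covariance = S, level = level,
                 radius = sqrt(stats::qchisq(level, df = 2L)),
                 degenerate = det(S) <= .Machine$double.eps),
            class = "ellipse_summary")
}

#' Boundary points of a confidence ellipse
#'
#' @param es an [ellipse_summary].
#' @param n number of boundary points.
#' @return An `n x 2` matrix tracing the ellipse.
#' @export
ellipse_points <- function(es, n = 180L) {
  stopifnot(inherits(es, "ellipse_summary"))
  theta <- seq(0, 2 * pi, length.out = n)
  circle <- cbind(cos(theta), sin(theta))
  ev <- eigen(es$covariance, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  pts <- circle %*% diag(sqrt(lam) * es$radius) %*% t(ev$vectors)
  sweep(pts, 2L, es$mean, "+")
}

#' Diagnostic plot of one gene set in the ranking plane
#'
#' Scatter of all genes (grey) with the set's genes highlighted (red),
#' crosshairs at the two means and confidence ellipses for the full cloud
#' (blue) and for the set (red); the red ellipse marks the trend of the
#' relationship between the two variables within the set.
#'
#' @param ranking a 2-dimensional [gene_ranking].
#' @param coll a [gene_set_collection].
#' @param set_id the set to highlight.
#' @param level ellipse coverage level.
#' @param ... passed to [plot()].
#' @return The two [ellipse_summary] objects, invisibly.
#' @export
plot_set <- function(ranking, coll, set_id, level = 0.95, ...) {
  stopifnot(inherits(ranking, "gene_ranking"), ncol(ranking) == 2L)
  member <- membership_vector(coll, set_id, ranking_universe(ranking))
  xy <- unclass(ranking)
  es_all <- ellipse_summary(xy, level)
  es_set <- ellipse_summary(xy[member$indicator == 1L, , drop = FALSE], level)
  plot(xy, col = adjustcolor("grey40", 0.4), pch = 16, cex = 0.5,
       xlab = colnames(xy)[1L], ylab = colnames(xy)[2L],
       main = set_id, ...)
  points(xy[member$indicator == 1L, , drop = FALSE], col = "red",
         pch = 16, cex = 0.7)
  abline(v = es_all$mean[1L], h = es_all$mean[2L], col = "blue", lty = 3)
  abline(v = es_set$mean[1L], h = es_set$mean[2L], col = "red", lty = 3)
  lines(ellipse_points(es_all), col = "blue", lwd = 2)
  lines(ellipse_points(es_set), col = "red", lwd = 2)
  invisible(list(all = es_all, set = es_set))
}

#' Write a gene-set analysis result table
#'
#' Tab-separated, one header line, numeric columns rounded to 6
#' significant digits, rows in their (already deterministic) order.
#'
#' @param results a `gsa_result` from [run_md_gsa()] or [run_uv_gsa()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  stopifnot(is.data.frame(results))
  out <- results
  num <- vapply(out, is.numeric, logical(1)) & names(out) != "size"
  out[num] <- lapply(out[num], function(v) as.character(signif(v, 6L)))
  con <- file(path, open = "wb")  # LF endings on every platform
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA", eol = "\n")
  invisible(path)
}

#' Read back a result table written by [write_results()]
#'
#' @param path path to the TSV.
#' @return A `gsa_result` data.frame.
#' @export
read_results <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           colClasses = c(set_id = "character",
                                          name = "character",
                                          pattern = "character"))
  class(out) <- c("gsa_result", "data.frame")
  out
}
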