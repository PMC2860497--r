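#' Construct a gene ranking
#'
#' A `gene_ranking` holds one or two finite per-gene ranking statistics
#' (moderated t, log odds ratio, hazard ratio, splicing index, copy-number
#' score, ...) over a shared gene universe.  It is stored as a numeric
#' matrix with gene identifiers as row names and one column per dimension.
#'
#' @param values numeric vector (one dimension) or matrix with 1 or 2
#'   columns; genes as names/rownames.
#' @param genes optional character vector of gene identifiers overriding
#'   the names of `values`.
#' @param dimension_names optional column labels (e.g. `c("TR", "RS")`).
#' @return An object of class `gene_ranking` (a numeric matrix).
#' @examples
#' gene_ranking(c(g1 = 1.2, g2 = -0.4, g3 = 0.1))
#' @export
gene_ranking <- function(values, genes = NULL, dimension_names = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values)) values <- matrix(values, ncol = 1L,
                                           dimnames = list(names(values), NULL))
  storage.mode(values) <- "double"
  if (!is.null(genes)) rownames(values) <- as.character(genes)
  if (is.null(rownames(values))) stop("gene identifiers are required")
  if (!ncol(values) %in% 1:2)
    stop("a gene ranking has 1 or 2 dimensions, got ", ncol(values))
  if (anyDuplicated(rownames(values)))
    stop("duplicated gene identifiers; aggregate before constructing")
  if (any(!is.finite(values)))
    stop("ranking values must be finite; clean with read_ranking()")
  if (nrow(values) < 2L) stop("a ranking needs at least 2 genes")
  v <- apply(values, 2L, stats::var)
  if (any(v == 0))
    stop("degenerate covariate: ranking column with zero variance")
  if (!is.null(dimension_names)) colnames(values) <- dimension_names
  if (is.null(colnames(values)))
    colnames(values) <- c("X", "Y")[seq_len(ncol(values))]
  structure(values, class = c("gene_ranking", "matrix", "array"))
}

#' @export
print.gene_ranking <- function(x, ...) {
  cat("gene_ranking:", nrow(x), "genes x", ncol(x), "dimension(s) [",
      paste(colnames(x), collapse = ", "), "]\n")
  print(head(unclass(x), 4L))
  if (nrow(x) > 4L) cat("  ...\n")
  invisible(x)
}

ranking_universe <- function(r) rownames(r)

#' Read a gene ranking from a TSV file
#'
#' Rows with non-finite values are dropped and duplicated gene identifiers
#' are aggregated by their arithmetic mean; both events are reported with
#' a warning.
#'
#' @param path path to a tab-separated file.
#' @param id_col column (index) holding the gene identifier.
#' @param value_cols columns holding the statistic(s); default: all
#'   numeric-convertible columns after `id_col` (at most 2).
#' @param header logical; the file has a header line.
#' @return A [gene_ranking].
#' @export
read_ranking <- function(path, id_col = 1L, value_cols = NULL,
                         header = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = header,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  if (ncol(tab) < 2L) stop("format error: need a gene column and >= 1 numeric column")
  if (is.null(value_cols)) {
    cand <- setdiff(seq_len(ncol(tab)), id_col)
    cand <- cand[vapply(tab[cand], is.numeric, logical(1))]
    if (length(cand) == 0L) stop("format error: no numeric ranking column found")
    value_cols <- head(cand, 2L)
  }
  genes <- as.character(tab[[id_col]])
  vals <- as.matrix(tab[value_cols])
  storage.mode(vals) <- "double"
  ok <- apply(is.finite(vals), 1L, all)
  if (any(!ok)) {
    warning(sum(!ok), " row(s) with non-finite values dropped")
    genes <- genes[ok]; vals <- vals[ok, , drop = FALSE]
  }
  if (nrow(vals) == 0L) stop("empty input: no usable rows after cleaning")
  if (anyDuplicated(genes)) {
    warning(sum(duplicated(genes)),
            " duplicated gene id row(s) aggregated by mean")
    vals <- apply(vals, 2L, function(col) tapply(col, genes, mean))
    if (is.null(dim(vals))) vals <- matrix(vals, ncol = length(value_cols),
                                           dimnames = list(sort(unique(genes)), NULL))
    genes <- rownames(vals)
  }
  nm <- if (header) colnames(tab)[value_cols] else NULL
  gene_ranking(vals, genes = genes, dimension_names = nm)
}

#' Align two one-dimensional rankings into one bivariate ranking
#'
#' The bivariate membership model needs both statistics on a common
#' universe: the intersection of the two input universes, ordered
#' lexicographically for reproducible output.
#'
#' @param rx,ry one-dimensional [gene_ranking] objects (the X and Y
#'   measurements).
#' @param verbose log the intersection size.
#' @return A 2-dimensional [gene_ranking].
#' @export
align_rankings <- function(rx, ry, verbose = FALSE) {
  stopifnot(inherits(rx, "gene_ranking"), inherits(ry, "gene_ranking"))
  if (ncol(rx) != 1L || ncol(ry) != 1L)
    stop("align_rankings expects two 1-dimensional rankings")
  common <- sort(intersect(rownames(rx), rownames(ry)))
  if (length(common) == 0L) stop("empty input: the two universes do not intersect")
  if (verbose) message("align_rankings: ", length(common), " shared genes")
  nx <- colnames(rx); ny <- colnames(ry)
  if (identical(nx, ny)) { nx <- paste0(nx, ".x"); ny <- paste0(ny, ".y") }
  gene_ranking(cbind(rx[common, 1L], ry[common, 1L]), genes = common,
               dimension_names = c(nx, ny))
}

#' Aggregate subunit-level values to one value per gene
#'
#' Summarises subunit measurements (typically exon-level splicing indices)
#' into a gene-level statistic by the median; an even number of subunits
#' uses the midpoint of the two central values.
#'
#' @param table data.frame (or 2-column matrix) with gene identifiers in
#'   the first column and numeric subunit values in the second, many rows
#'   per gene.
#' @return A [gene_ranking] with one dimension.
#' @export
aggregate_subunits <- function(table) {
  if (is.matrix(table)) table <- as.data.frame(table, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(table), ncol(table) >= 2L)
  gene <- as.character(table[[1L]])
  val <- as.numeric(table[[2L]])
  ok <- is.finite(val)
  if (any(!ok)) {
    warning(sum(!ok), " non-finite subunit value(s) dropped")
    gene <- gene[ok]; val <- val[ok]
  }
  if (length(val) == 0L) stop("empty input: no usable subunit values")
  med <- tapply(val, gene, stats::median)
  gene_ranking(as.numeric(med), genes = names(med))
}

#' Standardize ranking columns
#'
#' Centres each dimension to mean 0 and scales it to sample standard
#' deviation 1.  Off by default throughout the package: the membership
#' model is fitted on the raw ranking statistics, so coefficients stay on
#' their native scale.
#'
#' @param r a [gene_ranking].
#' @return The standardized [gene_ranking].
#' @export
standardize_ranking <- function(r) {
  stopifnot(inherits(r, "gene_ranking"))
  s <- apply(r, 2L, stats::sd)
  if (any(s == 0)) stop("degenerate covariate: zero-variance column")
  z <- scale(unclass(r), center = TRUE, scale = s)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  gene_ranking(z, dimension_names = colnames(r))
}
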