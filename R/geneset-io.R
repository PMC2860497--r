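#' Construct a gene-set collection
#'
#' A `gene_set_collection` maps set identifiers (GO terms, KEGG pathways,
#' arbitrary module names) to character vectors of unique gene identifiers,
#' with an optional free-text description per set.
#'
#' @param sets named list of character vectors of gene identifiers.
#' @param descriptions optional named character vector of descriptions;
#'   names must be a subset of `names(sets)`.
#' @return An object of class `gene_set_collection`.
#' @examples
#' gene_set_collection(list(S1 = c("g1", "g2"), S2 = "g3"))
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!is.list(sets)) stop("'sets' must be a list of character vectors")
  ids <- names(sets)
  if (length(sets) > 0L && (is.null(ids) || any(!nzchar(ids))))
    stop("every set must have a non-empty identifier")
  if (anyDuplicated(ids))
    stop("duplicate set identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(descriptions)) {
    descriptions <- setNames(rep(NA_character_, length(ids)), ids)
  } else {
    descriptions <- setNames(as.character(descriptions)[match(ids, names(descriptions))], ids)
  }
  structure(list(sets = sets, descriptions = descriptions),
            class = "gene_set_collection")
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' @export
names.gene_set_collection <- function(x) names(x$sets)

#' @export
print.gene_set_collection <- function(x, ...) {
  n <- length(x)
  cat("gene_set_collection with", n, "set(s)\n")
  if (n > 0L) {
    sz <- lengths(x$sets)
    cat("  sizes: min", min(sz), "/ median", stats::median(sz),
        "/ max", max(sz), "\n")
    show <- head(names(x), 5L)
    cat("  ", paste(show, collapse = ", "),
        if (n > 5L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Sizes of the sets in a collection
#'
#' @param coll a [gene_set_collection].
#' @param universe optional character vector; when given, sizes are
#'   effective sizes, i.e. computed after intersecting each set with it.
#' @return Named integer vector of set sizes.
#' @export
set_sizes <- function(coll, universe = NULL) {
  stopifnot(inherits(coll, "gene_set_collection"))
  if (is.null(universe)) return(lengths(coll$sets))
  vapply(coll$sets, function(g) sum(g %in% universe), integer(1))
}

#' Read gene sets from a GMT file
#'
#' GMT is the de facto gene-set exchange format: one set per line,
#' tab-separated fields `id`, `description`, then one gene per field.
#' Duplicate genes within a line are collapsed (with a warning).
#'
#' @param path path to a GMT file.
#' @return A [gene_set_collection].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("malformed GMT line(s) with fewer than 3 fields: line ",
         paste(bad, collapse = ", "))
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate set identifier(s) in GMT file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  desc <- setNames(vapply(fields, `[[`, character(1), 2L), ids)
  genes <- lapply(fields, function(f) f[-(1:2)])
  ndup <- sum(vapply(genes, anyDuplicated, integer(1)) > 0L)
  if (ndup > 0L)
    warning(ndup, " set(s) contained duplicated gene identifiers; collapsed")
  gene_set_collection(setNames(lapply(genes, unique), ids), desc)
}

#' Write gene sets to a GMT file
#'
#' Missing descriptions are written as `"NA"`.
#'
#' @param coll a [gene_set_collection].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(coll, path) {
  stopifnot(inherits(coll, "gene_set_collection"))
  desc <- coll$descriptions
  desc[is.na(desc)] <- "NA"
  lines <- vapply(names(coll), function(id) {
    paste(c(id, desc[[id]], coll$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a two-column gene/term annotation file
#'
#' The common flat export of GO or KEGG annotation: tab-separated lines
#' `gene<TAB>term`.  The mapping is inverted to term -> genes and
#' deduplicated.
#'
#' @param path path to the annotation file.
#' @param header logical; skip a header line.
#' @return A [gene_set_collection] (descriptions all `NA`).
#' @export
read_annotation_pairs <- function(path, header = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (header && length(lines) > 0L) lines <- lines[-1L]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(gene_set_collection(list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad))
    stop("annotation line(s) without exactly 2 fields: line ",
         paste(bad + header, collapse = ", "))
  gene <- vapply(fields, `[[`, character(1), 1L)
  term <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(split(gene, term), unique)
  gene_set_collection(sets[order(names(sets))])
}

#' Filter gene sets by effective size
#'
#' Functional modules annotated to very many genes are too general to be
#' informative and very small modules cannot be fitted reliably, so only
#' sets of intermediate size are analysed (default 10 to 500 genes).
#' Sizes are computed after intersecting each set with the gene universe
#' (when given), because the fitted model only ever sees universe genes.
#'
#' @param coll a [gene_set_collection].
#' @param universe optional character vector of measured gene identifiers.
#' @param min_size,max_size inclusive size bounds.
#' @param verbose log counts of removed sets with `message()`.
#' @return The filtered [gene_set_collection].
#' @export
filter_by_size <- function(coll, universe = NULL, min_size = 10L,
                           max_size = 500L, verbose = FALSE) {
  stopifnot(inherits(coll, "gene_set_collection"),
            min_size >= 1L, max_size >= min_size)
  sz <- set_sizes(coll, universe)
  keep <- sz >= min_size & sz <= max_size
  if (verbose)
    message("filter_by_size: removed ", sum(sz < min_size), " set(s) below ",
            min_size, " and ", sum(sz > max_size), " above ", max_size,
            "; ", sum(keep), " retained")
  gene_set_collection(coll$sets[keep], coll$descriptions[keep])
}

#' Membership indicator of one set over a gene universe
#'
#' The binary response of the logistic membership model: 1 for universe
#' genes annotated to the set, 0 otherwise.  Genes annotated to the set
#' but absent from the universe are ignored (their count is reported when
#' `verbose = TRUE`).
#'
#' @param coll a [gene_set_collection].
#' @param set_id identifier of the set.
#' @param universe character vector of gene identifiers (no duplicates).
#' @param verbose log the count of annotated genes missing from the
#'   universe.
#' @return An object of class `membership_vector`: a list with elements
#'   `universe` and `indicator` (integer 0/1, one per universe gene).
#' @export
membership_vector <- function(coll, set_id, universe, verbose = FALSE) {
  stopifnot(inherits(coll, "gene_set_collection"))
  if (!set_id %in% names(coll)) stop("unknown set identifier: ", set_id)
  if (anyDuplicated(universe)) stop("universe contains duplicated genes")
  genes <- coll$sets[[set_id]]
  ind <- as.integer(universe %in% genes)
  dropped <- sum(!genes %in% universe)
  if (verbose && dropped > 0L)
    message("membership_vector: ", dropped, " annotated gene(s) of ",
            set_id, " absent from the universe")
  if (all(ind == 1L) || all(ind == 0L))
    stop("degenerate set '", set_id,
         "': membership indicator needs both classes")
  structure(list(universe = universe, indicator = ind),
            class = "membership_vector")
}

# Coerce a membership_vector or plain 0/1 vector to an integer indicator.
as_indicator <- function(member) {
  if (inherits(member, "membership_vector")) return(member$indicator)
  ind <- as.integer(member)
  if (!all(ind %in% c(0L, 1L))) stop("membership must be binary (0/1)")
  ind
}
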