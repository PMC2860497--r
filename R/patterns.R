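# Enrichment-pattern taxonomy.
#
# Each gene set is summarised by the effective signs of (alpha, beta,
# gamma): a coefficient counts as 0 unless its adjusted p-value falls
# strictly below the significance threshold, otherwise it keeps the sign
# of its estimate.  The 27 possible sign triples map onto 15 labels:
#
#   q1i..q4i  quadrant patterns with interaction (saddle surface; the set
#             sits in the quadrant opposite the saddle point)
#   b13, b24  bimodal: only the interaction is significant, the set
#             splits between quadrants 1&3 (gamma > 0) or 2&4 (gamma < 0)
#   q1f..q4f  flat quadrant patterns (plane, both main effects)
#   xh,xl,yh,yl  single-axis enrichment
#   NS        nothing significant
#
# Triples with a significant interaction and opposite-sign main effects
# are classified by the quadrant opposite the saddle point
# (-beta/gamma, -alpha/gamma), i.e. the quadrant with sign pattern
# (sign(beta*gamma), sign(alpha*gamma)).

.sign_chr <- c(`-1` = "-", `0` = "0", `1` = "+")

.pattern_map <- c(
  # gamma > 0
  "+++" = "q1i", "+0+" = "q1i", "0++" = "q1i",
  "--+" = "q3i", "-0+" = "q3i", "0-+" = "q3i",
  "+-+" = "q2i", "-++" = "q4i",
  "00+" = "b13",
  # gamma < 0
  "-+-" = "q2i", "-0-" = "q2i", "0+-" = "q2i",
  "+--" = "q4i", "+0-" = "q4i", "0--" = "q4i",
  "++-" = "q3i", "---" = "q1i",
  "00-" = "b24",
  # gamma = 0 (plane)
  "++0" = "q1f", "--0" = "q3f", "-+0" = "q2f", "+-0" = "q4f",
  "+00" = "xh", "-00" = "xl", "0+0" = "yh", "0-0" = "yl",
  "000" = "NS")

#' All enrichment-pattern labels
#'
#' @return Character vector of the 15 pattern labels.
#' @export
pattern_labels <- function() {
  c("q1i", "q2i", "q3i", "q4i", "b13", "b24",
    "q1f", "q2f", "q3f", "q4f", "xh", "xl", "yh", "yl", "NS")
}

#' Effective coefficient signs after significance thresholding
#'
#' Maps each coefficient to 0 when its adjusted p-value is greater than or
#' equal to the threshold, and to the sign of its estimate otherwise.
#' Ties at the threshold are non-significant.
#'
#' @param estimate numeric vector of coefficient estimates.
#' @param padj adjusted p-values, same length, in `[0, 1]`.
#' @param threshold significance level on the adjusted p-values
#'   (default 0.05).
#' @return Integer vector in `{-1, 0, 1}`, same names as `estimate`.
#' @examples
#' effective_signs(c(alpha = 0.3, beta = -0.2, gamma = 0.1),
#'                 c(0.01, 0.5, 0.03))
#' @export
effective_signs <- function(estimate, padj, threshold = 0.05) {
  stopifnot(length(estimate) == length(padj))
  if (any(!is.finite(padj)) || any(padj < 0) || any(padj > 1))
    stop("invalid p-value: adjusted p-values must lie in [0, 1]")
  s <- as.integer(sign(estimate)) * as.integer(padj < threshold)
  setNames(s, names(estimate))
}

#' Classify a sign triple into an enrichment pattern
#'
#' Pure lookup from the effective sign triple `(alpha, beta, gamma)` to
#' one of the 15 pattern labels; every one of the 27 triples maps to
#' exactly one label.
#'
#' @param signs integer (or numeric) vector of length 3 with values in
#'   `{-1, 0, 1}`: effective signs of alpha, beta, gamma, typically from
#'   [effective_signs()].
#' @return A single pattern label (see [pattern_labels()]).
#' @examples
#' classify_pattern(c(1, 1, 1))   # "q1i"
#' classify_pattern(c(0, 0, -1))  # "b24"
#' classify_pattern(c(1, 0, 0))   # "xh"
#' @export
classify_pattern <- function(signs) {
  signs <- as.integer(signs)
  if (length(signs) != 3L || !all(signs %in% c(-1L, 0L, 1L)))
    stop("'signs' must be three values in {-1, 0, 1}")
  key <- paste(.sign_chr[as.character(signs)], collapse = "")
  unname(.pattern_map[[key]])
}
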