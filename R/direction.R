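#' Sorted deduplication of an observation vector
#'
#' Sorts a numeric vector ascending and collapses duplicate values,
#' recording their multiplicities. The spacing-based direction scores are
#' computed on these deduplicated series so that no spacing is zero.
#'
#' @param x Numeric vector, length at least 2.
#' @return A list with `values` (strictly increasing distinct values),
#'   `counts` (multiplicities, summing to `length(x)`), `m_distinct`
#'   and `m` (original length).
#' @export
#' @examples
#' dedup_sorted(c(1, 1, 2, 3))
dedup_sorted <- function(x) {
  if (!is.numeric(x) || length(x) < 2L)
    stop_data("need a numeric vector of length >= 2")
  if (any(!is.finite(x))) stop_data("non-finite values in input")
  s <- sort(x)
  r <- rle(s)
  if (length(r$values) < 2L)
    stop_data("degenerate variable: all %d observations identical", length(x))
  list(values = r$values, counts = r$lengths,
       m_distinct = length(r$values), m = length(x))
}

#' Pairwise causal-direction scores
#'
#' Computes the two IGCI spacing scores for an (xi, xj) pair. Each variable
#' is sorted ascending and deduplicated independently; the score for
#' xi -> xj is the multiplicity-weighted mean of
#' \eqn{\log[\Delta \tilde x_j(k) / \Delta \tilde x_i(k)]} over
#' \eqn{k = 1..K} with \eqn{K = \min(\tilde m_i, \tilde m_j) - 1}, and
#' symmetrically (with xj's multiplicities) for xj -> xi. With duplicate-free
#' data of equal length this is the classic spacing estimator of the entropy
#' difference \eqn{H(x_j) - H(x_i)}; the smaller score marks the cause.
#'
#' Both variables should be on a common reference scale (min-max normalized
#' to \[0, 1\]) for the scores to be comparable; [causal_direction_matrix()]
#' does this by default.
#'
#' @param xi,xj Numeric vectors of equal length (at least 3).
#' @return A list with scores `c_ij` (for xi -> xj) and `c_ji`.
#' @export
pairwise_direction_scores <- function(xi, xj) {
  if (length(xi) != length(xj))
    stop_data("xi and xj must have equal length")
  if (length(xi) < 3L) stop_data("need at least 3 observations")
  di <- dedup_sorted(xi)
  dj <- dedup_sorted(xj)
  K <- min(di$m_distinct, dj$m_distinct) - 1L
  if (K < 1L) stop_data("not enough distinct values to score")
  lr <- log(diff(dj$values)[seq_len(K)]) - log(diff(di$values)[seq_len(K)])
  wi <- di$counts[seq_len(K)]
  wj <- dj$counts[seq_len(K)]
  list(c_ij = sum(wi * lr) / sum(wi),
       c_ji = -sum(wj * lr) / sum(wj))
}

#' Pairwise causal direction matrix
#'
#' Scores every unordered variable pair and assembles the binary direction
#' matrix G: `G[i, j] = 1` when the score for xi -> xj is smaller than the
#' score for xj -> xi (xi is inferred to cause xj, directly or indirectly),
#' and `G[j, i] = 1 - G[i, j]`. Exact ties are oriented from the lower to
#' the higher column index, so G always equals the transpose of its
#' complement.
#'
#' @param x Numeric sample matrix (n x d, d >= 2) with column names.
#' @param minmax If `TRUE` (default) each column is min-max normalized to
#'   \[0, 1\] before scoring, giving the scores a common uniform reference
#'   measure; set `FALSE` to score on the raw scale.
#' @return A d x d binary matrix with zero diagonal and exactly one
#'   direction per pair.
#' @export
causal_direction_matrix <- function(x, minmax = TRUE) {
  check_sample_matrix(x)
  d <- ncol(x)
  if (d < 2L) stop_data("need at least 2 variables")
  for (v in seq_len(d))
    if (length(unique(x[, v])) < 2L)
      stop_data("degenerate variable '%s': constant column", colnames(x)[v])
  if (minmax) x <- minmax_normalize(x)
  g <- matrix(0, d, d, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(d - 1L)) {
    for (j in seq.int(i + 1L, d)) {
      sc <- pairwise_direction_scores(x[, i], x[, j])
      gij <- if (sc$c_ij < sc$c_ji) 1 else if (sc$c_ji < sc$c_ij) 0 else 1
      g[i, j] <- gij
      g[j, i] <- 1 - gij
    }
  }
  g
}

#' Complement of a direction matrix
#'
#' Entrywise `1 - G`, including the diagonal (which therefore becomes 1, so
#' a penalty masked by the complement also suppresses self-loops). For a
#' valid direction matrix the complement equals `t(G)` off the diagonal.
#'
#' @param g Binary direction matrix.
#' @return Binary matrix of the same shape.
#' @export
complement_matrix <- function(g) {
  if (!is.matrix(g) || !all(g %in% c(0, 1)))
    stop_data("g must be a binary matrix")
  1 - g
}
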