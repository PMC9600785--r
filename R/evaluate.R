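#' Structural Hamming distance with its breakdown
#'
#' Counts the edit operations turning the predicted graph into the truth:
#' `extra` (NE, predicted edges absent from the truth), `missing` (NM,
#' truth edges absent from the prediction) and `reversed` (NR, pairs where
#' exactly the opposite single direction is present), with
#' `shd = NE + NM + NR`. A reversed pair counts one operation and
#' contributes to neither NE nor NM. Pairs carrying both directions in one
#' graph (impossible for this package's own output, but accepted) are
#' scored edgewise: the matching direction pairs off and the surplus
#' direction counts as extra or missing.
#'
#' @param pred,truth Binary adjacency matrices with identical dimensions
#'   and variable names.
#' @return A list of class `"shd_breakdown"` with `extra`, `missing`,
#'   `reversed` and `shd`.
#' @export
#' @examples
#' a <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
#' b <- a; a["a", "b"] <- 1; b["b", "a"] <- 1
#' shd_breakdown(a, b)
shd_breakdown <- function(pred, truth) {
  check_adjacency(pred, binary = TRUE, arg = "pred")
  check_adjacency(truth, binary = TRUE, arg = "truth")
  if (!all(dim(pred) == dim(truth)))
    stop_data("pred (%d nodes) and truth (%d nodes) differ in size",
              ncol(pred), ncol(truth))
  if (!is.null(colnames(pred)) && !is.null(colnames(truth)) &&
      !identical(colnames(pred), colnames(truth)))
    stop_data("pred and truth have different variable names")
  d <- ncol(pred)
  ne <- 0L; nm <- 0L; nr <- 0L
  for (i in seq_len(d - 1L)) {
    for (j in seq.int(i + 1L, d)) {
      p <- c(pred[i, j], pred[j, i])
      t_ <- c(truth[i, j], truth[j, i])
      if (sum(p) == 1L && sum(t_) == 1L && !all(p == t_)) {
        nr <- nr + 1L
      } else {
        ne <- ne + sum(p == 1L & t_ == 0L)
        nm <- nm + sum(p == 0L & t_ == 1L)
      }
    }
  }
  structure(list(extra = ne, missing = nm, reversed = nr,
                 shd = ne + nm + nr),
            class = "shd_breakdown")
}

#' Entrywise binary-classification metrics for a predicted graph
#'
#' Treats every ordered off-diagonal adjacency entry (d(d-1) instances) as
#' a binary-classification instance with "edge present" as the positive
#' class, and reports accuracy, precision, recall and F1. Precision,
#' recall and F1 are defined as 0 when their denominators are 0.
#'
#' @inheritParams shd_breakdown
#' @return A list of class `"classification_metrics"` with `accuracy`,
#'   `precision`, `recall`, `f1` and the confusion counts `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
classification_metrics <- function(pred, truth) {
  check_adjacency(pred, binary = TRUE, arg = "pred")
  check_adjacency(truth, binary = TRUE, arg = "truth")
  if (!all(dim(pred) == dim(truth)))
    stop_data("pred (%d nodes) and truth (%d nodes) differ in size",
              ncol(pred), ncol(truth))
  off <- !diag(ncol(pred))
  p <- pred[off]
  t_ <- truth[off]
  tp <- sum(p == 1 & t_ == 1)
  fp <- sum(p == 1 & t_ == 0)
  fn <- sum(p == 0 & t_ == 1)
  tn <- sum(p == 0 & t_ == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(accuracy = (tp + tn) / (tp + fp + fn + tn),
                 precision = precision, recall = recall, f1 = f1,
                 tp = tp, fp = fp, fn = fn, tn = tn),
            class = "classification_metrics")
}

#' @export
print.shd_breakdown <- function(x, ...) {
  cat(sprintf("SHD %d (extra %d, missing %d, reversed %d)\n",
              x$shd, x$extra, x$missing, x$reversed))
  invisible(x)
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}
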