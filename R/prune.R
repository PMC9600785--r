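#' Second-order polynomial expansion of parent columns
#'
#' Builds the design matrix for the per-child pruning regression: the
#' parent columns themselves, then all pairwise cross products
#' \eqn{x_k x_h} (k < h, lexicographic), then the squares. Column names
#' record the term identity (`"p"`, `"p1:p2"`, `"p^2"`).
#'
#' @param x Numeric sample matrix.
#' @param parents Column indices (or names) of the parent variables,
#'   nonempty.
#' @return n x (2l + l(l-1)/2) design matrix with a `"terms"` attribute
#'   (data frame with `type` in linear/cross/square and parent positions
#'   `k`, `h`).
#' @export
expand_second_order <- function(x, parents) {
  check_sample_matrix(x)
  if (is.character(parents)) parents <- match(parents, colnames(x))
  if (length(parents) < 1L || anyNA(parents) ||
      any(parents < 1L | parents > ncol(x)))
    stop_data("parents must be a nonempty set of valid column indices")
  l <- length(parents)
  vn <- colnames(x)[parents]
  cols <- list()
  terms <- list()
  for (k in seq_len(l)) {
    cols[[length(cols) + 1L]] <- x[, parents[k]]
    terms[[length(terms) + 1L]] <- data.frame(type = "linear", k = k, h = NA)
  }
  if (l >= 2L) {
    for (k in seq_len(l - 1L)) {
      for (h in seq.int(k + 1L, l)) {
        cols[[length(cols) + 1L]] <- x[, parents[k]] * x[, parents[h]]
        terms[[length(terms) + 1L]] <- data.frame(type = "cross", k = k, h = h)
      }
    }
  }
  for (k in seq_len(l)) {
    cols[[length(cols) + 1L]] <- x[, parents[k]]^2
    terms[[length(terms) + 1L]] <- data.frame(type = "square", k = k, h = NA)
  }
  terms <- do.call(rbind, terms)
  nm <- character(nrow(terms))
  nm[terms$type == "linear"] <- vn[terms$k[terms$type == "linear"]]
  nm[terms$type == "cross"] <- paste0(vn[terms$k[terms$type == "cross"]], ":",
                                      vn[terms$h[terms$type == "cross"]])
  nm[terms$type == "square"] <- paste0(vn[terms$k[terms$type == "square"]],
                                       "^2")
  out <- do.call(cbind, cols)
  colnames(out) <- nm
  attr(out, "terms") <- terms
  out
}

#' Fit the quadratic parent model for one child
#'
#' Ordinary least squares of the child column on the second-order
#' expansion of its parent columns plus an intercept:
#' \deqn{x_i = \sum_k a_k x_{pa(k)} + \sum_{k<h} b_{kh} x_{pa(k)} x_{pa(h)}
#'       + \sum_k c_k x_{pa(k)}^2 + const.}
#' A rank-deficient design (e.g. duplicated parent data) is fitted by the
#' minimum-norm pseudo-inverse solution, with a warning.
#'
#' @param x Numeric sample matrix.
#' @param child Column index (or name) of the child variable.
#' @param parents Column indices (or names) of its parents, nonempty.
#' @return A list of class `"sem_coefficients"` with `child`, `parents`,
#'   `intercept`, `linear` (a_k, named by parent), `quadratic` (c_k) and
#'   `cross` (l x l symmetric matrix of b_kh, zero diagonal; `NULL` when
#'   l = 1).
#' @export
fit_parent_coefficients <- function(x, child, parents) {
  check_sample_matrix(x)
  if (is.character(child)) child <- match(child, colnames(x))
  design <- expand_second_order(x, parents)
  if (is.character(parents)) parents <- match(parents, colnames(x))
  if (child %in% parents) stop_data("child cannot be its own parent")
  if (nrow(x) <= ncol(design) + 1L)
    stop_data("too few samples (%d) to fit %d coefficients",
              nrow(x), ncol(design) + 1L)
  d_full <- cbind(`(intercept)` = 1, design)
  y <- x[, child]
  qr_d <- qr(d_full)
  if (qr_d$rank < ncol(d_full)) {
    warning("rank-deficient design; using the minimum-norm solution",
            call. = FALSE)
    sv <- svd(d_full)
    pos <- sv$d > max(sv$d) * 1e-10
    coef <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
    coef <- drop(coef)
  } else {
    coef <- qr.coef(qr_d, y)
  }
  names(coef) <- colnames(d_full)
  terms <- attr(design, "terms")
  l <- length(parents)
  vn <- colnames(x)[parents]
  a <- coef[1L + which(terms$type == "linear")]
  names(a) <- vn
  cc <- coef[1L + which(terms$type == "square")]
  names(cc) <- vn
  b <- NULL
  if (l >= 2L) {
    b <- matrix(0, l, l, dimnames = list(vn, vn))
    ci <- which(terms$type == "cross")
    for (idx in ci) {
      b[terms$k[idx], terms$h[idx]] <- coef[1L + idx]
      b[terms$h[idx], terms$k[idx]] <- coef[1L + idx]
    }
  }
  structure(list(child = child, parents = parents,
                 intercept = unname(coef[1L]),
                 linear = a, quadratic = cc, cross = b),
            class = "sem_coefficients")
}

#' Prune weak edges by polynomial-regression coefficients
#'
#' For every child node with at least one parent in `g`, fits the
#' second-order polynomial regression of [fit_parent_coefficients()] and
#' removes the edge from parent k when the linear, quadratic and every
#' cross coefficient involving k are all below `epsilon2` in absolute
#' value. Decisions use the parent sets of the input graph in a single
#' pass (no re-fitting after removals); edges are only ever removed, so
#' an acyclic input stays acyclic.
#'
#' @param x Numeric sample matrix. The threshold compares fitted
#'   coefficients against `epsilon2` directly, so the scale of `x`
#'   matters; [learn_structure()] prunes on the raw-scale data.
#' @param g Binary adjacency matrix (rows = parents, columns = children).
#' @param epsilon2 Positive pruning threshold (default 0.6, the published
#'   setting).
#' @return The pruned binary adjacency matrix.
#' @export
prune_graph <- function(x, g, epsilon2 = 0.6) {
  check_sample_matrix(x)
  check_adjacency(g, binary = TRUE)
  if (epsilon2 <= 0) stop_data("epsilon2 must be positive")
  if (ncol(g) != ncol(x))
    stop_data("graph size (%d) does not match data (%d variables)",
              ncol(g), ncol(x))
  out <- g
  for (child in seq_len(ncol(g))) {
    parents <- which(g[, child] == 1)
    if (length(parents) == 0L) next
    fit <- fit_parent_coefficients(x, child, parents)
    for (k in seq_along(parents)) {
      weak <- abs(fit$linear[k]) < epsilon2 && abs(fit$quadratic[k]) < epsilon2
      if (weak && !is.null(fit$cross))
        weak <- all(abs(fit$cross[k, -k]) < epsilon2)
      if (weak) out[parents[k], child] <- 0
    }
  }
  out
}
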