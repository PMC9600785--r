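#' Optimizer configuration
#'
#' Collects the hyper-parameters of the constrained continuous structure
#' optimization. Defaults follow the published experimental settings: unit
#' step sizes, inner tolerance `delta = 1e-8`, weight threshold
#' `epsilon = 0.2`. The l2 weight `lambda` is not pinned down by the published
#' settings; the default 0.01 keeps the ridge bias on unit-variance data
#' well below the 0.2 edge threshold.
#'
#' @param lambda l2 regularization weight (>= 0) on the adjacency weights.
#' @param gamma0 Initial gradient-descent step size for the inner loop.
#' @param gamma1,gamma2 Multiplier update step sizes for the acyclicity and
#'   direction constraints.
#' @param delta Inner-loop convergence tolerance on the objective change.
#' @param epsilon Threshold on |weight| used by [threshold_weights()].
#' @param max_inner,max_outer Iteration caps for the inner descent loop and
#'   the multiplier updates.
#' @param tol_h,tol_g Feasibility tolerances for the acyclicity value h(W)
#'   and the direction penalty g(W).
#' @param hard_direction If `TRUE`, entries forbidden by the direction
#'   matrix are projected to zero after every step instead of (in addition
#'   to) being penalized; default `FALSE` keeps the soft formulation.
#' @return A list of class `"optimizer_config"`.
#' @export
optimizer_config <- function(lambda = 0.01,
                             gamma0 = 1, gamma1 = 1, gamma2 = 1,
                             delta = 1e-8, epsilon = 0.2,
                             max_inner = 1000L, max_outer = 100L,
                             tol_h = 1e-8, tol_g = 1e-8,
                             hard_direction = FALSE) {
  stopifnot(lambda >= 0, gamma0 > 0, gamma1 > 0, gamma2 > 0,
            delta > 0, epsilon > 0, max_inner >= 1, max_outer >= 1,
            tol_h > 0, tol_g > 0)
  structure(list(lambda = lambda, gamma0 = gamma0, gamma1 = gamma1,
                 gamma2 = gamma2, delta = delta, epsilon = epsilon,
                 max_inner = as.integer(max_inner),
                 max_outer = as.integer(max_outer),
                 tol_h = tol_h, tol_g = tol_g,
                 hard_direction = isTRUE(hard_direction)),
            class = "optimizer_config")
}

expm_dense <- function(m) {
  as.matrix(Matrix::expm(Matrix::Matrix(m, sparse = FALSE)))
}

#' Trace-exponential acyclicity term
#'
#' \eqn{h(W) = tr(e^{W \circ W}) - d}, which is nonnegative and zero exactly
#' when the support of W is acyclic, with gradient
#' \eqn{(e^{W \circ W})^T \circ 2W}.
#'
#' @param w Square numeric weight matrix.
#' @return List with `value` and the d x d `gradient`.
#' @export
acyclicity_term <- function(w) {
  if (!is.matrix(w) || nrow(w) != ncol(w) || any(!is.finite(w)))
    stop_data("w must be a finite square matrix")
  e <- expm_dense(w * w)
  list(value = sum(diag(e)) - ncol(w), gradient = t(e) * (2 * w))
}

#' Structural-equation least-squares loss
#'
#' \eqn{S(W) = \frac{1}{2n}\|X - XW\|_F^2 + \lambda\|W\|_F^2} with gradient
#' \eqn{\frac{1}{n}X^T(XW - X) + 2\lambda W}; the gradient diagonal is
#' forced to zero because self-loops are excluded.
#'
#' @param x n x d sample matrix (normalized).
#' @param w d x d weight matrix.
#' @param lambda l2 regularization weight.
#' @return List with `value` and `gradient`.
#' @export
sem_loss <- function(x, w, lambda = 0) {
  if (ncol(x) != nrow(w) || nrow(w) != ncol(w))
    stop_data("dimension mismatch between x (%d cols) and w", ncol(x))
  n <- nrow(x)
  r <- x %*% w - x
  grad <- crossprod(x, r) / n + 2 * lambda * w
  diag(grad) <- 0
  list(value = sum(r * r) / (2 * n) + lambda * sum(w * w), gradient = grad)
}

#' Direction-matrix penalty
#'
#' \eqn{g(W) = \|W \circ \bar G\|_F^2} with gradient \eqn{2 W \circ \bar G}
#' (the complement is binary). Zero exactly when every nonzero weight sits
#' where the direction matrix permits an edge.
#'
#' @param w d x d weight matrix.
#' @param g_bar Complement of the direction matrix ([complement_matrix()]).
#' @return List with `value` and `gradient`.
#' @export
direction_penalty <- function(w, g_bar) {
  if (!all(dim(w) == dim(g_bar)))
    stop_data("w and g_bar must have identical dimensions")
  m <- w * g_bar
  list(value = sum(m * m), gradient = 2 * m * g_bar)
}

#' Learn the weighted adjacency matrix by constrained optimization
#'
#' Minimizes the structural-equation least-squares loss over weighted
#' adjacency matrices subject to the acyclicity constraint
#' \eqn{h(W) = tr(e^{W \circ W}) - d = 0} and the direction-matrix
#' constraint \eqn{g(W) = \|W \circ \bar G\|_F^2 = 0}, via the Lagrangian
#' \eqn{L(W, \alpha, \beta) = S(W) + \alpha h(W) + \beta g(W)}. The inner
#' loop runs gradient descent on W (with backtracking halving of the step
#' when the objective would increase) until the objective change drops
#' below `delta`; the outer loop performs dual ascent on the multipliers,
#' \eqn{\alpha \leftarrow \alpha + \gamma_1 h(W)},
#' \eqn{\beta \leftarrow \beta + \gamma_2 g(W)}, stopping when both
#' constraint values fall below their tolerances. W starts at zero, as do
#' both multipliers; the diagonal of W is pinned to zero throughout.
#'
#' @param x n x d sample matrix, z-score normalized.
#' @param g d x d binary causal direction matrix
#'   (see [causal_direction_matrix()]).
#' @param cfg An [optimizer_config()].
#' @return The d x d weight matrix, with attributes `converged` (logical),
#'   `trace` (per-outer-iteration data frame of h, g and objective values),
#'   `alpha`, `beta` and `objective`. A warning is raised when the
#'   feasibility tolerances were not met within the iteration caps.
#' @export
optimize_structure <- function(x, g, cfg = optimizer_config()) {
  check_sample_matrix(x)
  d <- ncol(x)
  if (d == 1L) {
    w <- matrix(0, 1, 1, dimnames = list(colnames(x), colnames(x)))
    return(structure(w, converged = TRUE, alpha = 0, beta = 0,
                     objective = sem_loss(x, w, cfg$lambda)$value,
                     trace = data.frame(outer = integer(), h = numeric(),
                                        g = numeric(), objective = numeric())))
  }
  check_adjacency(g, binary = TRUE, arg = "g")
  if (!all(g + t(g) == 1 - diag(d)))
    stop_data("g is not a valid direction matrix (one direction per pair)")
  g_bar <- complement_matrix(g)
  n <- nrow(x)
  gram <- crossprod(x) / n           # X'X / n; removes n from the loop
  eye <- diag(d)

  # One expensive expm per state; shared by the objective and the gradient.
  eval_state <- function(w, alpha, beta) {
    e <- expm_dense(w * w)
    h_val <- sum(diag(e)) - d
    g_val <- sum((w * g_bar)^2)
    m <- eye - w
    list(e = e, h = h_val, g = g_val,
         l = 0.5 * sum(m * (gram %*% m)) + cfg$lambda * sum(w * w) +
           alpha * h_val + beta * g_val)
  }
  gradient <- function(w, st, alpha, beta) {
    gr <- gram %*% (w - eye) + 2 * cfg$lambda * w +
      alpha * (t(st$e) * (2 * w)) +
      beta * (2 * w * g_bar)
    diag(gr) <- 0
    gr
  }
  project <- function(w) {
    diag(w) <- 0
    if (cfg$hard_direction) w[g_bar == 1] <- 0
    w
  }

  w <- matrix(0, d, d, dimnames = list(colnames(x), colnames(x)))
  alpha <- 0
  beta <- 0
  trace <- vector("list", cfg$max_outer)
  converged <- FALSE
  st <- eval_state(w, alpha, beta)

  for (outer in seq_len(cfg$max_outer)) {
    step <- cfg$gamma0
    for (inner in seq_len(cfg$max_inner)) {
      gr <- gradient(w, st, alpha, beta)
      step <- min(cfg$gamma0, 2 * step)   # warm-started backtracking
      repeat {
        w_new <- project(w - step * gr)
        st_new <- eval_state(w_new, alpha, beta)
        if (is.finite(st_new$l) && st_new$l <= st$l) break
        step <- step / 2
        if (step < 1e-14) break
      }
      if (step < 1e-14) break             # no descent direction left
      done <- abs(st$l - st_new$l) < cfg$delta
      w <- w_new
      st <- st_new
      if (done) break
    }
    trace[[outer]] <- data.frame(outer = outer, h = st$h, g = st$g,
                                 objective = st$l)
    if (st$h <= cfg$tol_h && st$g <= cfg$tol_g) {
      converged <- TRUE
      break
    }
    alpha <- alpha + cfg$gamma1 * st$h
    beta <- beta + cfg$gamma2 * st$g
    st <- eval_state(w, alpha, beta)
  }
  if (!converged)
    warning(sprintf(paste0("structure optimization hit the iteration cap ",
                           "before feasibility (h = %.3g, g = %.3g); ",
                           "returning the best iterate"),
                    trace[[length(Filter(Negate(is.null), trace))]]$h,
                    trace[[length(Filter(Negate(is.null), trace))]]$g),
            call. = FALSE)
  structure(w, converged = converged, alpha = alpha, beta = beta,
            objective = st$l,
            trace = do.call(rbind, Filter(Negate(is.null), trace)))
}

#' Threshold a weight matrix into a binary graph
#'
#' Keeps an edge i -> j exactly when `|W[i, j]| > epsilon` (strict).
#'
#' @param w Weight matrix.
#' @param epsilon Positive threshold (default 0.2, the published setting).
#' @return Binary adjacency matrix with zero diagonal.
#' @export
threshold_weights <- function(w, epsilon = 0.2) {
  if (epsilon <= 0) stop_data("epsilon must be positive")
  g <- (abs(w) > epsilon) * 1
  diag(g) <- 0
  dimnames(g) <- dimnames(w)
  g
}
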