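#' Synthetic-data generator configuration
#'
#' Study conditions for the quadratic structural-equation-model generator:
#' a random strictly upper-triangular Bernoulli(0.5) DAG over `d` nodes,
#' quadratic responses with coefficients drawn uniformly from
#' \eqn{\pm[0.5, 1.5]} and independently zeroed with probability 0.5,
#' standard Gaussian noise, 5000 raw samples filtered to the 3000 with the
#' smallest absolute row sums.
#'
#' @param d Number of nodes (default 11, the size of the T-cell signaling
#'   benchmark).
#' @param edge_prob Bernoulli edge probability above the diagonal.
#' @param n_raw Number of raw samples drawn.
#' @param n_keep Number of samples retained after the outlier filter.
#' @param coef_low,coef_high Magnitude bounds of nonzero coefficients.
#' @param zero_prob Probability that a coefficient is set to zero.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(d = 11L, edge_prob = 0.5,
                             n_raw = 5000L, n_keep = 3000L,
                             coef_low = 0.5, coef_high = 1.5,
                             zero_prob = 0.5, noise_sd = 1,
                             seed = NULL) {
  stopifnot(d >= 1, edge_prob >= 0, edge_prob <= 1,
            n_raw >= 2, n_keep >= 2, n_keep <= n_raw,
            coef_low >= 0, coef_high >= coef_low,
            zero_prob >= 0, zero_prob <= 1, noise_sd >= 0)
  structure(list(d = as.integer(d), edge_prob = edge_prob,
                 n_raw = as.integer(n_raw), n_keep = as.integer(n_keep),
                 coef_low = coef_low, coef_high = coef_high,
                 zero_prob = zero_prob, noise_sd = noise_sd, seed = seed),
            class = "generator_config")
}

#' Random upper-triangular DAG adjacency
#'
#' Each entry strictly above the diagonal is an independent Bernoulli(p)
#' draw; the node order 1..d is therefore a topological order and the
#' graph is acyclic by construction.
#'
#' @param d Number of nodes.
#' @param p Edge probability.
#' @param seed Optional integer seed.
#' @param var_names Optional node names (default `x1..xd`).
#' @return d x d binary adjacency matrix.
#' @export
random_dag_adjacency <- function(d, p = 0.5, seed = NULL, var_names = NULL) {
  stopifnot(d >= 1, p >= 0, p <= 1)
  if (!is.null(seed)) set.seed(seed)
  vn <- var_names %||% default_var_names(d)
  adj <- matrix(0, d, d, dimnames = list(vn, vn))
  if (d > 1L) {
    upper <- which(upper.tri(adj))
    adj[upper] <- stats::rbinom(length(upper), 1L, p)
  }
  adj
}

# One coefficient: zero w.p. zero_prob, else uniform on +/-[low, high].
draw_coefs <- function(n, cfg) {
  nonzero <- stats::runif(n) >= cfg$zero_prob
  mag <- stats::runif(n, cfg$coef_low, cfg$coef_high)
  sign <- ifelse(stats::runif(n) < 0.5, -1, 1)
  ifelse(nonzero, sign * mag, 0)
}

#' Draw quadratic-SEM coefficients for a DAG
#'
#' For every child, draws the linear (a_k), quadratic (c_k) and pairwise
#' cross (b_kh) coefficients over its parents, each independently zero
#' with probability `zero_prob` and otherwise uniform on
#' \eqn{\pm[coef\_low, coef\_high]}. A parent whose linear, quadratic and
#' every cross coefficient were all drawn zero contributes nothing to the
#' child, so that edge is deleted from the returned effective adjacency —
#' the ground truth used for evaluation.
#'
#' @param adj Strictly upper-triangular binary adjacency matrix.
#' @param cfg A [generator_config()].
#' @param seed Optional integer seed.
#' @return List with `coefs` (per-child list of `"sem_coefficients"`-style
#'   lists, `NULL` for roots) and `effective_adj`.
#' @export
sample_sem_coefficients <- function(adj, cfg = generator_config(d = ncol(adj)),
                                    seed = NULL) {
  check_adjacency(adj, binary = TRUE, arg = "adj")
  if (any(adj[lower.tri(adj, diag = TRUE)] != 0))
    stop_data("adj must be strictly upper triangular")
  if (!is.null(seed)) set.seed(seed)
  d <- ncol(adj)
  vn <- colnames(adj) %||% default_var_names(d)
  effective <- adj
  coefs <- vector("list", d)
  for (child in seq_len(d)) {
    parents <- which(adj[, child] == 1)
    l <- length(parents)
    if (l == 0L) next
    a <- draw_coefs(l, cfg)
    cc <- draw_coefs(l, cfg)
    b <- NULL
    if (l >= 2L) {
      b <- matrix(0, l, l)
      for (k in seq_len(l - 1L)) {
        for (h in seq.int(k + 1L, l)) {
          val <- draw_coefs(1L, cfg)
          b[k, h] <- val
          b[h, k] <- val
        }
      }
    }
    for (k in seq_len(l)) {
      contributes <- a[k] != 0 || cc[k] != 0 ||
        (!is.null(b) && any(b[k, -k] != 0))
      if (!contributes) effective[parents[k], child] <- 0
    }
    names(a) <- vn[parents]
    names(cc) <- vn[parents]
    if (!is.null(b)) dimnames(b) <- list(vn[parents], vn[parents])
    coefs[[child]] <- list(child = child, parents = parents,
                           intercept = 0, linear = a, quadratic = cc,
                           cross = b)
  }
  list(coefs = coefs, effective_adj = effective)
}

#' Generate raw samples from quadratic-SEM coefficients
#'
#' Evaluates the nodes in index order (a topological order of the
#' upper-triangular DAG): roots are pure noise, non-roots are the quadratic
#' polynomial of their already-generated parent columns plus independent
#' Gaussian noise of sd `noise_sd`.
#'
#' @param coefs Per-child coefficient list from [sample_sem_coefficients()].
#' @param cfg A [generator_config()].
#' @param seed Optional integer seed.
#' @param var_names Optional node names.
#' @return An `n_raw` x d sample matrix.
#' @export
generate_samples <- function(coefs, cfg, seed = NULL, var_names = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- length(coefs)
  n <- cfg$n_raw
  vn <- var_names %||% default_var_names(d)
  x <- matrix(0, n, d, dimnames = list(NULL, vn))
  for (node in seq_len(d)) {
    mu <- 0
    co <- coefs[[node]]
    if (!is.null(co)) {
      p <- x[, co$parents, drop = FALSE]
      mu <- drop(p %*% co$linear) + drop(p^2 %*% co$quadratic)
      if (!is.null(co$cross)) {
        l <- length(co$parents)
        for (k in seq_len(l - 1L))
          for (h in seq.int(k + 1L, l))
            mu <- mu + co$cross[k, h] * p[, k] * p[, h]
      }
    }
    x[, node] <- mu + stats::rnorm(n, 0, cfg$noise_sd)
  }
  x
}

#' Generate a complete synthetic dataset
#'
#' Composes the full recipe: random upper-triangular Bernoulli DAG,
#' quadratic-SEM coefficient draw (with zero-contribution edges removed
#' from the ground truth), raw sampling, then retention of the `n_keep`
#' samples with the smallest absolute row sums. Fully reproducible from
#' `cfg$seed`.
#'
#' @param cfg A [generator_config()].
#' @return List with `x` (filtered sample matrix, `n_keep` rows), `truth`
#'   (effective adjacency), `raw_adjacency` (the Bernoulli draw before
#'   zero-coefficient deletion) and `coefficients`.
#' @export
#' @examples
#' ds <- make_dataset(generator_config(d = 5, n_raw = 500, n_keep = 300,
#'                                     seed = 1))
#' dim(ds$x)
#' sum(ds$truth)
make_dataset <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  adj <- random_dag_adjacency(cfg$d, cfg$edge_prob)
  sem <- sample_sem_coefficients(adj, cfg)
  x <- generate_samples(sem$coefs, cfg, var_names = colnames(adj))
  x <- filter_outliers_by_abs_sum(x, cfg$n_keep)
  list(x = x, truth = sem$effective_adj, raw_adjacency = adj,
       coefficients = sem$coefs)
}
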