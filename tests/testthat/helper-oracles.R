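# Shared fixtures and independent oracles for the test suite.

# Random sample matrix with named columns.
rand_sample_matrix <- function(n, d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(n * d), n, d,
         dimnames = list(NULL, paste0("v", seq_len(d))))
}

# Named square matrix from an edge list (rows = parents).
mk_adj <- function(d, edges = NULL, var_names = paste0("x", seq_len(d))) {
  m <- matrix(0, d, d, dimnames = list(var_names, var_names))
  if (!is.null(edges)) for (e in edges) m[e[1], e[2]] <- 1
  m
}

# Depth-first-search cycle detection, independent of the trace-exponential
# acyclicity term.
has_cycle_dfs <- function(adj) {
  d <- ncol(adj)
  state <- integer(d)  # 0 = unvisited, 1 = on stack, 2 = done
  visit <- function(v) {
    state[v] <<- 1L
    for (w in which(adj[v, ] != 0)) {
      if (state[w] == 1L) return(TRUE)
      if (state[w] == 0L && visit(w)) return(TRUE)
    }
    state[v] <<- 2L
    FALSE
  }
  for (v in seq_len(d)) if (state[v] == 0L && visit(v)) return(TRUE)
  FALSE
}

# Brute-force SHD oracle: classify each unordered pair by its (pred, truth)
# pattern against a hand-frozen operation table.
shd_oracle <- function(pred, truth) {
  pat <- function(fwd, rev) {
    if (fwd == 1 && rev == 1) "both"
    else if (fwd == 1) "fwd"
    else if (rev == 1) "rev"
    else "none"
  }
  ops <- list(  # pattern pair -> c(extra, missing, reversed)
    "none|none" = c(0, 0, 0), "none|fwd" = c(0, 1, 0),
    "none|rev" = c(0, 1, 0), "none|both" = c(0, 2, 0),
    "fwd|none" = c(1, 0, 0), "fwd|fwd" = c(0, 0, 0),
    "fwd|rev" = c(0, 0, 1), "fwd|both" = c(0, 1, 0),
    "rev|none" = c(1, 0, 0), "rev|fwd" = c(0, 0, 1),
    "rev|rev" = c(0, 0, 0), "rev|both" = c(0, 1, 0),
    "both|none" = c(2, 0, 0), "both|fwd" = c(1, 0, 0),
    "both|rev" = c(1, 0, 0), "both|both" = c(0, 0, 0))
  d <- ncol(pred)
  tot <- c(0, 0, 0)
  for (i in seq_len(d - 1)) {
    for (j in seq.int(i + 1, d)) {
      key <- paste(pat(pred[i, j], pred[j, i]),
                   pat(truth[i, j], truth[j, i]), sep = "|")
      tot <- tot + ops[[key]]
    }
  }
  list(extra = tot[1], missing = tot[2], reversed = tot[3], shd = sum(tot))
}

# Random binary digraph with zero diagonal (may contain 2-cycles).
rand_digraph <- function(d, p = 0.3) {
  m <- matrix(rbinom(d * d, 1, p), d, d,
              dimnames = list(paste0("x", 1:d), paste0("x", 1:d)))
  diag(m) <- 0
  m
}

# Central finite-difference gradient of a scalar function of a matrix.
fd_gradient <- function(f, w, eps = 1e-6) {
  g <- w * 0
  for (i in seq_len(nrow(w))) {
    for (j in seq_len(ncol(w))) {
      wp <- w; wp[i, j] <- w[i, j] + eps
      wm <- w; wm[i, j] <- w[i, j] - eps
      g[i, j] <- (f(wp) - f(wm)) / (2 * eps)
    }
  }
  g
}
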