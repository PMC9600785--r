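# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_data <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("cdgraph_data_error", "cdgraph_error")))
}

stop_usage <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("cdgraph_usage_error", "cdgraph_error")))
}

# Validate an n x d numeric sample matrix with unique column names.
check_sample_matrix <- function(x, arg = "x") {
  if (!is.matrix(x) || !is.numeric(x))
    stop_data("%s must be a numeric matrix", arg)
  if (nrow(x) < 2L) stop_data("%s needs at least 2 rows (has %d)", arg, nrow(x))
  if (ncol(x) < 1L) stop_data("%s needs at least 1 column", arg)
  if (any(!is.finite(x)))
    stop_data("%s contains missing or non-finite values", arg)
  vn <- colnames(x)
  if (is.null(vn)) stop_data("%s must have column (variable) names", arg)
  if (anyDuplicated(vn)) stop_data("%s has duplicated variable names", arg)
  invisible(x)
}

# Validate a d x d matrix with zero diagonal; binary = entries in {0, 1}.
check_adjacency <- function(m, binary = FALSE, arg = "graph") {
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) != ncol(m))
    stop_data("%s must be a square numeric matrix", arg)
  if (any(!is.finite(m))) stop_data("%s contains non-finite entries", arg)
  if (any(diag(m) != 0)) stop_data("%s must have a zero diagonal", arg)
  if (binary && !all(m %in% c(0, 1)))
    stop_data("%s must be binary (0/1)", arg)
  invisible(m)
}

default_var_names <- function(d) paste0("x", seq_len(d))

# Full-precision numeric formatting so text round-trips are lossless.
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  # integers print cleanly (e.g. "1" not "1.0000000000000000")
  ints <- is.finite(x) & x == round(x) & abs(x) < 2^53
  out[ints] <- sprintf("%.0f", x[ints])
  out
}
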