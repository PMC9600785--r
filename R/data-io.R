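#' Read a sample matrix from delimited text
#'
#' Reads an n x d observation matrix (samples in rows, variables in columns)
#' from a delimited text file with a header line of variable names. Every
#' cell below the header must parse as a finite real number.
#'
#' @param path Path to the file.
#' @param delimiter Field delimiter, `","` (default) or `"\t"`.
#' @return A numeric matrix with column names; rows keep file order.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("a,b", "1,2", "3,4"), f)
#' load_sample_matrix(f)
load_sample_matrix <- function(path, delimiter = ",") {
  if (!file.exists(path)) stop_data("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop_data("%s: need a header line and data rows", path)
  header <- strsplit(lines[[1L]], delimiter, fixed = TRUE)[[1L]]
  header <- trimws(header)
  if (anyDuplicated(header))
    stop_data("%s: duplicated variable names in header (%s)", path,
              paste(unique(header[duplicated(header)]), collapse = ", "))
  d <- length(header)
  cells <- strsplit(lines[-1L], delimiter, fixed = TRUE)
  widths <- lengths(cells)
  if (any(widths != d))
    stop_data("%s: row %d has %d fields, expected %d", path,
              which(widths != d)[1L], widths[widths != d][1L], d)
  vals <- suppressWarnings(as.numeric(trimws(unlist(cells))))
  if (anyNA(vals) || any(!is.finite(vals))) {
    bad <- which(is.na(vals) | !is.finite(vals))[1L]
    stop_data("%s: non-numeric or non-finite value at data row %d, column '%s'",
              path, (bad - 1L) %/% d + 1L, header[(bad - 1L) %% d + 1L])
  }
  x <- matrix(vals, ncol = d, byrow = TRUE, dimnames = list(NULL, header))
  check_sample_matrix(x, arg = path)
  x
}

#' Write a sample matrix to delimited text
#'
#' Numbers are written with 17 significant digits so that
#' [load_sample_matrix()] reproduces the values exactly.
#'
#' @param x Numeric sample matrix with column names.
#' @param path Output path.
#' @param delimiter Field delimiter.
#' @return Invisibly, `path`.
#' @export
write_sample_matrix <- function(x, path, delimiter = ",") {
  check_sample_matrix(x)
  body <- apply(matrix(fmt_num(x), nrow = nrow(x)), 1L,
                paste, collapse = delimiter)
  writeLines(c(paste(colnames(x), collapse = delimiter), body), path)
  invisible(path)
}

#' Column-wise z-score normalization
#'
#' Centres each variable and divides by its population standard deviation
#' (denominator n). This is the scale used by the structure optimizer and
#' the pruning regressions.
#'
#' @param x Numeric sample matrix.
#' @return Matrix of the same shape; each column has mean 0 and population
#'   sd 1.
#' @export
zscore_normalize <- function(x) {
  check_sample_matrix(x)
  mu <- colMeans(x)
  sdev <- sqrt(colMeans(sweep(x, 2L, mu)^2))
  if (any(sdev == 0))
    stop_data("constant column(s): %s",
              paste(colnames(x)[sdev == 0], collapse = ", "))
  sweep(sweep(x, 2L, mu), 2L, sdev, `/`)
}

#' Column-wise min-max normalization to [0, 1]
#'
#' Maps each variable affinely onto \[0, 1\]. Used as the common reference
#' measure for the pairwise causal-direction scores.
#'
#' @inheritParams zscore_normalize
#' @return Matrix of the same shape with every column spanning \[0, 1\].
#' @export
minmax_normalize <- function(x) {
  check_sample_matrix(x)
  lo <- apply(x, 2L, min)
  hi <- apply(x, 2L, max)
  if (any(hi == lo))
    stop_data("constant column(s): %s",
              paste(colnames(x)[hi == lo], collapse = ", "))
  sweep(sweep(x, 2L, lo), 2L, hi - lo, `/`)
}

#' Keep the samples with the smallest absolute row sums
#'
#' Outlier filter used on generated data: rows are ranked by
#' \eqn{\sum_j |x_{ij}|} and the `keep` smallest are retained, in their
#' original relative order. Ties are broken by original row index.
#'
#' @param x Numeric sample matrix.
#' @param keep Number of rows to retain (positive, at most `nrow(x)`).
#' @return The filtered matrix with `keep` rows.
#' @export
filter_outliers_by_abs_sum <- function(x, keep) {
  check_sample_matrix(x)
  if (length(keep) != 1L || !is.finite(keep) || keep <= 0 || keep != round(keep))
    stop_data("keep must be a positive integer")
  if (keep > nrow(x))
    stop_data("keep (%d) exceeds the number of rows (%d)", keep, nrow(x))
  s <- rowSums(abs(x))
  idx <- order(s, seq_along(s))[seq_len(keep)]
  x[sort(idx), , drop = FALSE]
}

#' Write an adjacency matrix
#'
#' Supports two plain-text formats: `"matrix-csv"` writes the full d x d
#' matrix with a header row and an index column of variable names;
#' `"edge-list"` writes one `source<TAB>target<TAB>weight` line per nonzero
#' entry, sorted by (source index, target index).
#'
#' @param g Square numeric matrix (binary graph or weight matrix) with a
#'   zero diagonal; dimnames optional (defaults `x1..xd`).
#' @param path Output path.
#' @param format `"matrix-csv"` or `"edge-list"`.
#' @return Invisibly, `path`.
#' @export
write_adjacency <- function(g, path, format = c("matrix-csv", "edge-list")) {
  format <- match.arg(format)
  check_adjacency(g)
  vn <- colnames(g) %||% default_var_names(ncol(g))
  if (format == "matrix-csv") {
    body <- vapply(seq_len(nrow(g)), function(i)
      paste(c(vn[i], fmt_num(g[i, ])), collapse = ","), character(1L))
    writeLines(c(paste(c("", vn), collapse = ","), body), path)
  } else {
    nz <- which(t(g) != 0)  # transpose so ordering is by (row, col)
    j <- (nz - 1L) %/% ncol(g) + 1L  # source (row of g)
    i <- (nz - 1L) %% ncol(g) + 1L   # target (col of g)
    writeLines(sprintf("%s\t%s\t%s", vn[j], vn[i], fmt_num(g[cbind(j, i)])),
               path)
  }
  invisible(path)
}

#' Read an adjacency matrix written by [write_adjacency()]
#'
#' @param path Path to a matrix-csv file (header row + index column).
#' @return Square numeric matrix with dimnames.
#' @export
read_adjacency <- function(path) {
  if (!file.exists(path)) stop_data("file not found: %s", path)
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m))
    stop_data("%s: adjacency matrix must be square (got %d x %d)",
              path, nrow(m), ncol(m))
  if (!is.numeric(m)) stop_data("%s: non-numeric entries", path)
  storage.mode(m) <- "double"
  m
}
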