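#' @useDynLib neurofem, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import Matrix
#' @importFrom methods as is
#' @importFrom stats median rgamma rnorm runif sd cor cov setNames
NULL

# row-wise cross product of n x 3 matrices
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

rownorms <- function(m) sqrt(rowSums(m * m))

vnorm <- function(v) sqrt(sum(v * v))

# matrix coercion guard for 3-column point sets
as_points3 <- function(x, what = "points") {
  x <- as.matrix(x)
  if (ncol(x) != 3L)
    stop(sprintf("%s must have 3 columns, got %d", what, ncol(x)))
  storage.mode(x) <- "double"
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# split a numeric text line into tokens, tolerating CRLF and extra whitespace
split_tokens <- function(line) {
  line <- gsub("\r", "", line, fixed = TRUE)
  strsplit(trimws(line), "[[:space:],;]+")[[1]]
}

read_text_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readLines(path, warn = FALSE)
}

stop_parse <- function(path, lineno, msg) {
  stop(sprintf("parse error in '%s' line %d: %s", path, lineno, msg),
       call. = FALSE)
}
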