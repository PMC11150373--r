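#' @keywords internal
#' @importFrom stats rnorm runif setNames
#' @importFrom utils read.csv write.csv write.table
"_PACKAGE"

# Shared input checks -------------------------------------------------------

check_finite_matrix <- function(M, name = deparse(substitute(M))) {
  if (!is.matrix(M) || !is.numeric(M)) {
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  }
  if (!all(is.finite(M))) {
    stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  }
  invisible(M)
}

check_square <- function(M, name = deparse(substitute(M))) {
  if (nrow(M) != ncol(M)) {
    stop(sprintf("`%s` must be square (got %d x %d)", name, nrow(M), ncol(M)),
         call. = FALSE)
  }
  invisible(M)
}

# Row-wise softmax with per-row max subtraction (overflow-safe, value-identical).
softmax_rows <- function(M) {
  E <- exp(M - apply(M, 1L, max))
  E / rowSums(E)
}

# Stable column softmax: normalize each column over its row index.
softmax_cols <- function(M) {
  E <- exp(sweep(M, 2L, apply(M, 2L, max), "-"))
  sweep(E, 2L, colSums(E), "/")
}
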