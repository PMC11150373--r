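# Attention variants: scaled dot-product self-attention, its parameter-free
# simplification, and the SVD-based low-rank dimension attention with double
# normalization. All functions use the samples-as-rows convention:
# X is n x d with n samples and d feature dimensions.

#' Scaled dot-product self-attention
#'
#' Recodes the input into query, key and value matrices through three linear
#' maps and returns the attention-weighted values
#' \eqn{A V} with \eqn{A = \mathrm{softmax}(Q K^\top / \sqrt{d_k})},
#' \eqn{Q = X W_q^\top}, \eqn{K = X W_k^\top}, \eqn{V = X W_v^\top}.
#' Weight matrices are stored output-by-input, so they act on the feature axis.
#'
#' @param X numeric matrix, n samples x d feature dimensions.
#' @param Wq,Wk numeric matrices, d' x d (query/key maps).
#' @param Wv numeric matrix, d x d (value map).
#' @param dk positive integer, the query/key dimension used in the
#'   \eqn{1/\sqrt{d_k}} scaling; defaults to `nrow(Wq)`.
#' @return n x d numeric matrix of attention-weighted values. The n x n
#'   attention matrix (rows sum to 1) is attached as attribute `"A"`.
#' @examples
#' X <- matrix(c(1, 0, 1, 0, 1, 1), nrow = 3)
#' self_attention(X, diag(2), diag(2), diag(2))
#' @export
self_attention <- function(X, Wq, Wk, Wv, dk = nrow(Wq)) {
  check_finite_matrix(X)
  check_finite_matrix(Wq); check_finite_matrix(Wk); check_finite_matrix(Wv)
  d <- ncol(X)
  if (ncol(Wq) != d || ncol(Wk) != d || ncol(Wv) != d) {
    stop("weight maps must have as many columns as X has feature dimensions",
         call. = FALSE)
  }
  if (nrow(Wq) != nrow(Wk)) {
    stop("Wq and Wk must have the same output dimension", call. = FALSE)
  }
  if (!is.numeric(dk) || length(dk) != 1L || dk < 1) {
    stop("`dk` must be a positive integer", call. = FALSE)
  }
  Q <- X %*% t(Wq)
  K <- X %*% t(Wk)
  V <- X %*% t(Wv)
  A <- softmax_rows(Q %*% t(K) / sqrt(dk))
  out <- A %*% V
  attr(out, "A") <- A
  out
}

#' Simplified self-attention
#'
#' Parameter-free self-attention computed directly from the input:
#' \eqn{A = \mathrm{softmax}(X X^\top)} row-wise, output \eqn{A X}.
#' Attention here measures similarity between samples, not between feature
#' dimensions; it is the reference point the low-rank dimension attention
#' ([lra_weights()]) improves on.
#'
#' @inheritParams self_attention
#' @return n x d numeric matrix; the n x n attention matrix is attached as
#'   attribute `"A"`.
#' @export
simplified_self_attention <- function(X) {
  check_finite_matrix(X)
  A <- softmax_rows(tcrossprod(X))
  out <- A %*% X
  attr(out, "A") <- A
  out
}

#' Double normalization
#'
#' Normalizes a square matrix into a nonnegative attention matrix with unit
#' row sums: first a column-wise softmax
#' \eqn{\tilde a_{ij} = \exp(m_{ij}) / \sum_i \exp(m_{ij})}, then a row-wise
#' sum normalization \eqn{a_{ij} = \tilde a_{ij} / \sum_j \tilde a_{ij}}.
#' The column softmax subtracts the per-column maximum before exponentiating;
#' this is value-identical and avoids overflow for large Gram entries.
#'
#' @param M finite square numeric matrix.
#' @param keep_intermediates if `TRUE`, attach the pre-normalization matrix
#'   (`"abar"`) and the column-softmaxed matrix (`"atilde"`) as attributes.
#' @return square matrix with strictly positive entries whose rows sum to 1.
#' @examples
#' double_norm(diag(2))  # [[e/(e+1), 1/(e+1)], [1/(e+1), e/(e+1)]]
#' @export
double_norm <- function(M, keep_intermediates = FALSE) {
  check_finite_matrix(M)
  check_square(M)
  atilde <- softmax_cols(M)
  A <- atilde / rowSums(atilde)
  if (keep_intermediates) {
    attr(A, "abar") <- M
    attr(A, "atilde") <- atilde
  }
  A
}

# Deterministic sign convention for singular vector pairs: for each column k,
# if the largest-magnitude entry of U[, k] is negative (ties broken by lowest
# row index), both U[, k] and V[, k] are negated. Leaves U diag(S) V^T
# unchanged while making the product U V reproducible across SVD backends
# whenever the spectrum is non-degenerate.
fix_svd_signs <- function(U, V) {
  for (k in seq_len(ncol(U))) {
    i <- which.max(abs(U[, k]))
    if (U[i, k] < 0) {
      U[, k] <- -U[, k]
      V[, k] <- -V[, k]
    }
  }
  list(U = U, V = V)
}

#' Low-rank dimension attention weights
#'
#' The low-rank attention (LRA) block: computes the Gram matrix
#' \eqn{G = X^\top X}, takes its singular value decomposition
#' \eqn{G = U \, \mathrm{diag}(S) \, V^\top}, forms the matrix product
#' \eqn{U V} of the left and right singular vector matrices (after a
#' deterministic sign convention), and double-normalizes it into a d x d
#' attention matrix over feature dimensions.
#'
#' The result is a constant weighting, not a trainable parameter: consumers
#' must treat it as data, and no gradient flows through the SVD
#' (see [apply_lra_weighting()]). Because singular vectors are invariant to
#' positive rescaling of `X`, so is the returned attention matrix.
#'
#' For degenerate (repeated) singular values the factorization itself is not
#' unique; the contract is determinism for a fixed SVD backend, not a unique
#' mathematical value.
#'
#' @param X numeric matrix, n samples x d feature dimensions.
#' @param product `"UV"` (default) multiplies the left singular vector matrix
#'   by the right singular vector matrix; `"UVt"` uses \eqn{U V^\top} instead.
#'   For the symmetric positive semi-definite Gram matrix, \eqn{U V^\top}
#'   collapses to the identity, making the attention input-independent; it is
#'   exposed for comparison only.
#' @param keep_intermediates passed to [double_norm()].
#' @return d x d attention matrix with unit row sums.
#' @examples
#' lra_weights(diag(c(2, 1)))
#' @export
lra_weights <- function(X, product = c("UV", "UVt"), keep_intermediates = FALSE) {
  product <- match.arg(product)
  check_finite_matrix(X)
  if (ncol(X) < 1L) stop("X must have at least one feature dimension", call. = FALSE)
  G <- crossprod(X)
  sv <- tryCatch(svd(G), error = function(e) {
    stop(sprintf("SVD failed to converge on the %d x %d Gram matrix: %s",
                 nrow(G), ncol(G), conditionMessage(e)), call. = FALSE)
  })
  fixed <- fix_svd_signs(sv$u, sv$v)
  P <- if (product == "UV") fixed$U %*% fixed$V else tcrossprod(fixed$U, fixed$V)
  double_norm(P, keep_intermediates = keep_intermediates)
}

#' Apply low-rank attention weighting to a feature matrix
#'
#' Returns `X %*% lra_weights(X)`: each sample's feature vector reweighted by
#' the dimension-attention matrix of the whole batch. The attention matrix
#' participates in the forward value only; gradient-based consumers in this
#' package differentiate this map as if the attention matrix were a constant
#' (the gradient-isolation contract).
#'
#' @inheritParams lra_weights
#' @param A optional precomputed attention matrix; when supplied it is used
#'   as-is (this is how training code freezes the weights per forward pass).
#' @return n x d matrix; the attention matrix used is attached as `"A"`.
#' @export
apply_lra_weighting <- function(X, A = NULL) {
  check_finite_matrix(X)
  if (is.null(A)) A <- lra_weights(X)
  out <- X %*% A
  attr(out, "A") <- A
  out
}
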