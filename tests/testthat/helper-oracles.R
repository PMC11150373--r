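# Independent oracles, deliberately naive: element-by-element loops and
# textbook formulas, sharing no code with the implementation.

# Eq.-style scaled dot-product attention, double loop over samples.
oracle_self_attention <- function(X, Wq, Wk, Wv, dk) {
  n <- nrow(X)
  Q <- X %*% t(Wq); K <- X %*% t(Wk); V <- X %*% t(Wv)
  out <- matrix(0, n, ncol(V))
  for (i in seq_len(n)) {
    logits <- numeric(n)
    for (j in seq_len(n)) logits[j] <- sum(Q[i, ] * K[j, ]) / sqrt(dk)
    w <- exp(logits) / sum(exp(logits))
    for (j in seq_len(n)) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  out
}

oracle_simplified_attention <- function(X) {
  n <- nrow(X)
  out <- matrix(0, n, ncol(X))
  for (i in seq_len(n)) {
    logits <- numeric(n)
    for (j in seq_len(n)) logits[j] <- sum(X[i, ] * X[j, ])
    w <- exp(logits - max(logits))
    w <- w / sum(w)
    for (j in seq_len(n)) out[i, ] <- out[i, ] + w[j] * X[j, ]
  }
  out
}

# Two-pass double normalization, no max subtraction.
oracle_double_norm <- function(M) {
  d <- ncol(M)
  atilde <- matrix(0, d, d)
  for (j in seq_len(d)) atilde[, j] <- exp(M[, j]) / sum(exp(M[, j]))
  A <- matrix(0, d, d)
  for (i in seq_len(d)) A[i, ] <- atilde[i, ] / sum(atilde[i, ])
  A
}

# LRA weights from an eigendecomposition of the symmetric PSD Gram matrix:
# eigenpairs give the singular triplets (descending eigenvalues), then the
# same sign convention, product, and two-pass normalization.
oracle_lra_weights <- function(X) {
  G <- t(X) %*% X
  eg <- eigen(G, symmetric = TRUE)
  U <- eg$vectors
  V <- U  # for PSD G, right singular vectors equal the left ones
  for (k in seq_len(ncol(U))) {
    i <- which.max(abs(U[, k]))
    if (U[i, k] < 0) {
      U[, k] <- -U[, k]
      V[, k] <- -V[, k]
    }
  }
  oracle_double_norm(U %*% V)
}

# Naive sliding-window 1D convolution for one sample: x is L x C_in,
# kernels W[[co]] is a list over output channels of K x C_in matrices.
oracle_conv1d <- function(x, W, b, stride, pad) {
  L <- nrow(x); C_in <- ncol(x); K <- nrow(W[[1L]])
  xp <- rbind(matrix(0, pad, C_in), x, matrix(0, pad, C_in))
  L_out <- (nrow(xp) - K) %/% stride + 1L
  out <- matrix(0, L_out, length(W))
  for (co in seq_along(W)) {
    for (p in seq_len(L_out)) {
      s <- (p - 1L) * stride
      acc <- 0
      for (k in seq_len(K)) for (ci in seq_len(C_in)) {
        acc <- acc + xp[s + k, ci] * W[[co]][k, ci]
      }
      out[p, co] <- acc + b[co]
    }
  }
  out
}

# Nested-list access for finite-difference checks over parameter trees.
get_leaf <- function(tree, path) Reduce(function(t, k) t[[k]], path, tree)

set_leaf <- function(tree, path, val) {
  if (length(path) == 1L) {
    tree[[path[[1L]]]] <- val
    return(tree)
  }
  tree[[path[[1L]]]] <- set_leaf(tree[[path[[1L]]]], path[-1L], val)
  tree
}

fd_grad <- function(f, w, idx, eps = 1e-6) {
  vapply(idx, function(i) {
    wp <- w; wp[i] <- wp[i] + eps
    wm <- w; wm[i] <- wm[i] - eps
    (f(wp) - f(wm)) / (2 * eps)
  }, numeric(1L))
}

# Full width at half maximum around the global peak, by direct scan.
oracle_fwhm <- function(y, fs) {
  p <- which.max(y)
  half <- y[p] / 2
  lo <- p
  while (lo > 1L && y[lo] > half) lo <- lo - 1L
  hi <- p
  while (hi < length(y) && y[hi] > half) hi <- hi + 1L
  (hi - lo) / fs
}

`%||%` <- function(a, b) if (is.null(a)) b else a
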