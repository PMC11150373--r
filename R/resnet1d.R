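# 1D-adapted ResNet-18 classifier. Feature maps are stored as 3D arrays
# (n samples, L positions, C channels). Convolutions are computed by im2col
# + matrix multiplication; the backward pass is hand-derived layer by layer.
#
# Topology: stem Conv1 (1->3, k3 s3 p0), Conv2 (3->64, k3 s3 p0), BatchNorm,
# ReLU; four stages of two basic blocks with channels 64/128/256/512; block
# convolutions are kernel 3, stride 1, padding 1, with stride-2 downsampling
# and a 1x1 projection shortcut at the entry of stages 2-4; global average
# pooling; fully connected 4-class output.

#' Rectified linear unit
#'
#' Elementwise `max(x, 0)`; zero maps to zero.
#' @param x numeric array.
#' @return array of the same shape.
#' @examples
#' relu(c(2, -3, 0))  # 2 0 0
#' @export
relu <- function(x) {
  if (!all(is.finite(x))) stop("`x` contains non-finite values", call. = FALSE)
  pmax(x, 0)
}

conv_out_len <- function(L, K, stride, pad) (L + 2L * pad - K) %/% stride + 1L

conv_spec <- function(C_in, C_out, K, stride, pad) {
  list(C_in = C_in, C_out = C_out, K = K, stride = stride, pad = pad)
}

# --- convolution ------------------------------------------------------------

im2col <- function(x, K, stride, pad) {
  dn <- dim(x); n <- dn[1L]; L <- dn[2L]; C <- dn[3L]
  Lp <- L + 2L * pad
  if (pad > 0L) {
    Xp <- array(0, c(n, Lp, C))
    Xp[, pad + seq_len(L), ] <- x
  } else Xp <- x
  L_out <- (Lp - K) %/% stride + 1L
  M <- array(0, c(n, L_out, C * K))
  for (k in seq_len(K)) {
    pos <- k + (seq_len(L_out) - 1L) * stride
    M[, , k + K * (seq_len(C) - 1L)] <- Xp[, pos, , drop = FALSE]
  }
  dim(M) <- c(n * L_out, C * K)
  list(M = M, n = n, L = L, L_out = L_out, C = C)
}

conv1d_forward <- function(x, p) {
  ic <- im2col(x, p$spec$K, p$spec$stride, p$spec$pad)
  Y <- sweep(ic$M %*% t(p$W), 2L, p$b, "+")
  dim(Y) <- c(ic$n, ic$L_out, p$spec$C_out)
  list(y = Y, cache = ic)
}

conv1d_backward <- function(dy, p, cache) {
  n <- cache$n; L_out <- cache$L_out; C <- cache$C
  K <- p$spec$K; stride <- p$spec$stride; pad <- p$spec$pad
  dim(dy) <- c(n * L_out, p$spec$C_out)
  dW <- crossprod(dy, cache$M)
  db <- colSums(dy)
  dM <- dy %*% p$W
  dim(dM) <- c(n, L_out, C * K)
  Lp <- cache$L + 2L * pad
  dXp <- array(0, c(n, Lp, C))
  for (k in seq_len(K)) {
    pos <- k + (seq_len(L_out) - 1L) * stride
    dXp[, pos, ] <- dXp[, pos, , drop = FALSE] +
      dM[, , k + K * (seq_len(C) - 1L), drop = FALSE]
  }
  dx <- if (pad > 0L) dXp[, pad + seq_len(cache$L), , drop = FALSE] else dXp
  list(dx = dx, grads = list(W = dW, b = db))
}

# --- batch normalization ----------------------------------------------------

bn_forward <- function(x, p, mode) {
  dn <- dim(x); m <- dn[1L] * dn[2L]; C <- dn[3L]
  xm <- x; dim(xm) <- c(m, C)
  if (mode == "train") {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2L, mu, "-")
    v <- colMeans(xc^2)
    p$run_mean <- (1 - p$momentum) * p$run_mean + p$momentum * mu
    p$run_var <- (1 - p$momentum) * p$run_var + p$momentum * v
  } else {
    mu <- p$run_mean
    v <- p$run_var
    xc <- sweep(xm, 2L, mu, "-")
  }
  ivstd <- 1 / sqrt(v + p$eps)
  xhat <- sweep(xc, 2L, ivstd, "*")
  y <- sweep(sweep(xhat, 2L, p$gamma, "*"), 2L, p$beta, "+")
  dim(y) <- dn
  list(y = y, params = p, cache = list(xhat = xhat, ivstd = ivstd, dims = dn))
}

bn_backward <- function(dy, p, cache) {
  dn <- cache$dims; m <- dn[1L] * dn[2L]; C <- dn[3L]
  dym <- dy; dim(dym) <- c(m, C)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2L, p$gamma, "*")
  dx <- sweep(dxhat, 2L, colMeans(dxhat), "-") -
    sweep(cache$xhat, 2L, colMeans(dxhat * cache$xhat), "*")
  dx <- sweep(dx, 2L, cache$ivstd, "*")
  dim(dx) <- dn
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

# --- parameter construction -------------------------------------------------

init_conv <- function(spec) {
  fan_in <- spec$C_in * spec$K
  list(W = matrix(stats::rnorm(spec$C_out * fan_in, 0, sqrt(2 / fan_in)),
                  spec$C_out, fan_in),
       b = numeric(spec$C_out), spec = spec)
}

init_bn <- function(C, momentum, eps) {
  list(gamma = rep(1, C), beta = numeric(C),
       run_mean = numeric(C), run_var = rep(1, C),
       momentum = momentum, eps = eps)
}

init_block <- function(C_in, C_out, entry_stride, momentum, eps) {
  bp <- list(
    conv_a = init_conv(conv_spec(C_in, C_out, 3L, entry_stride, 1L)),
    bn_a = init_bn(C_out, momentum, eps),
    conv_b = init_conv(conv_spec(C_out, C_out, 3L, 1L, 1L)),
    bn_b = init_bn(C_out, momentum, eps)
  )
  if (C_in != C_out || entry_stride != 1L) {
    bp$proj_conv <- init_conv(conv_spec(C_in, C_out, 1L, entry_stride, 0L))
    bp$proj_bn <- init_bn(C_out, momentum, eps)
  }
  bp
}

#' Classifier configuration
#'
#' @param in_length latent length fed to the stem (default 64); must survive
#'   the two stride-3 stem convolutions (`floor((L - 3)/3) + 1` applied twice
#'   must be >= 1, i.e. `in_length >= 9`).
#' @param channels per-stage channel counts (default `c(64, 128, 256, 512)`).
#' @param n_classes number of output classes.
#' @param no_downsample keep every stage at stride 1 (the literal reading of
#'   per-block stride-1 convolutions); default `FALSE` places stride-2
#'   downsampling with 1x1 projection shortcuts at the entry of stages 2-4.
#' @param bn_momentum,bn_eps batch-normalization running-statistics momentum
#'   and variance floor.
#' @param seed integer seed for weight initialization.
#' @return an object of class `classifier_config`.
#' @export
classifier_config <- function(in_length = 64L, channels = c(64L, 128L, 256L, 512L),
                              n_classes = 4L, no_downsample = FALSE,
                              bn_momentum = 0.1, bn_eps = 1e-5, seed = 1L) {
  L1 <- conv_out_len(in_length, 3L, 3L, 0L)
  L2 <- if (L1 >= 3L) conv_out_len(L1, 3L, 3L, 0L) else 0L
  if (L1 < 3L || L2 < 1L) {
    stop(sprintf("in_length = %d is too small for the two stride-3 stem convolutions",
                 in_length), call. = FALSE)
  }
  stopifnot(length(channels) == 4L, n_classes >= 2L)
  structure(list(in_length = as.integer(in_length),
                 channels = as.integer(channels),
                 n_classes = as.integer(n_classes),
                 no_downsample = isTRUE(no_downsample),
                 bn_momentum = bn_momentum, bn_eps = bn_eps,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' Initialize classifier parameters
#'
#' He-normal convolution weights, unit batch-norm scales, Glorot fully
#' connected layer; all drawn from the config's seed.
#'
#' @param config a [classifier_config()].
#' @return nested parameter list of class `resnet1d_params`.
#' @export
init_classifier <- function(config) {
  ch <- config$channels
  with_seed(config$seed, {
    params <- list(
      conv1 = init_conv(conv_spec(1L, 3L, 3L, 3L, 0L)),
      conv2 = init_conv(conv_spec(3L, ch[1L], 3L, 3L, 0L)),
      bn_stem = init_bn(ch[1L], config$bn_momentum, config$bn_eps),
      stages = lapply(1:4, function(s) {
        C_in <- if (s == 1L) ch[1L] else ch[s - 1L]
        stride <- if (s == 1L || config$no_downsample) 1L else 2L
        list(init_block(C_in, ch[s], stride, config$bn_momentum, config$bn_eps),
             init_block(ch[s], ch[s], 1L, config$bn_momentum, config$bn_eps))
      }),
      fc = list(W = glorot(config$n_classes, ch[4L]),
                b = numeric(config$n_classes))
    )
    structure(params, class = "resnet1d_params")
  })
}

#' Number of parameters in a parameter tree
#' @param params a nested parameter list.
#' @return integer count of weight, bias and batch-norm scale/shift entries.
#' @export
n_parameters <- function(params) {
  if (!is.list(params)) return(0L)
  nms <- names(params)
  if (is.null(nms)) nms <- rep("", length(params))
  total <- 0L
  for (i in seq_along(params)) {
    el <- params[[i]]
    if (nms[i] %in% c("W", "b", "gamma", "beta")) total <- total + length(el)
    else if (is.list(el)) total <- total + n_parameters(el)
  }
  total
}

# --- residual block ---------------------------------------------------------

#' Forward pass through one basic residual block
#'
#' Inner path `F`: conv -> batch-norm -> ReLU -> conv -> batch-norm -> ReLU;
#' the block output is `F(x) + shortcut(x)`, with an identity shortcut when
#' shapes agree and a 1x1 projection convolution (plus batch-norm) otherwise.
#'
#' @param x input feature map: a 3D array (n, length, channels) or an
#'   n x length matrix treated as single-channel.
#' @param params block parameters as built by [init_classifier()] (elements
#'   `conv_a`, `bn_a`, `conv_b`, `bn_b`, optionally `proj_conv`, `proj_bn`).
#' @param mode `"train"` (batch statistics) or `"eval"` (running statistics).
#' @return the output feature map; the updated parameters (running
#'   batch-norm statistics) are attached as attribute `"params"`.
#' @export
res_block_forward <- function(x, params, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (is.matrix(x)) x <- array(x, c(nrow(x), ncol(x), 1L))
  fw <- block_forward(x, params, mode)
  out <- fw$y
  attr(out, "params") <- fw$params
  out
}

block_forward <- function(x, bp, mode) {
  ca <- conv1d_forward(x, bp$conv_a)
  ba <- bn_forward(ca$y, bp$bn_a, mode); bp$bn_a <- ba$params
  ra <- pmax(ba$y, 0)
  cb <- conv1d_forward(ra, bp$conv_b)
  bb <- bn_forward(cb$y, bp$bn_b, mode); bp$bn_b <- bb$params
  rb <- pmax(bb$y, 0)
  if (!is.null(bp$proj_conv)) {
    pc <- conv1d_forward(x, bp$proj_conv)
    pb <- bn_forward(pc$y, bp$proj_bn, mode); bp$proj_bn <- pb$params
    sc <- pb$y
    proj_cache <- list(conv = pc$cache, bn = pb$cache)
  } else {
    if (!identical(dim(rb), dim(x))) {
      stop("residual shapes differ and the block has no projection shortcut",
           call. = FALSE)
    }
    sc <- x
    proj_cache <- NULL
  }
  list(y = rb + sc, params = bp,
       cache = list(conv_a = ca$cache, bn_a = ba$cache, ra = ra,
                    conv_b = cb$cache, bn_b = bb$cache, rb = rb,
                    proj = proj_cache))
}

block_backward <- function(dy, bp, cache) {
  g <- list()
  # inner path
  drb <- dy * (cache$rb > 0)
  bb <- bn_backward(drb, bp$bn_b, cache$bn_b); g$bn_b <- bb$grads
  cb <- conv1d_backward(bb$dx, bp$conv_b, cache$conv_b); g$conv_b <- cb$grads
  dra <- cb$dx * (cache$ra > 0)
  ba <- bn_backward(dra, bp$bn_a, cache$bn_a); g$bn_a <- ba$grads
  ca <- conv1d_backward(ba$dx, bp$conv_a, cache$conv_a); g$conv_a <- ca$grads
  dx <- ca$dx
  # shortcut
  if (!is.null(bp$proj_conv)) {
    pb <- bn_backward(dy, bp$proj_bn, cache$proj$bn); g$proj_bn <- pb$grads
    pc <- conv1d_backward(pb$dx, bp$proj_conv, cache$proj$conv); g$proj_conv <- pc$grads
    dx <- dx + pc$dx
  } else {
    dx <- dx + dy
  }
  list(dx = dx, grads = g)
}

# --- full network -----------------------------------------------------------

#' Classifier forward pass
#'
#' Reshapes each latent row into a single-channel sequence and runs the full
#' network. `f1` is the stem feature map (after Conv1, Conv2, BatchNorm,
#' ReLU), `f2` the feature map after stages 1-2, and `f3` the length-4 class
#' scores after stages 3-4, global average pooling and the fully connected
#' layer; softmax probabilities are reported alongside.
#'
#' @param latents numeric matrix, n x `in_length`.
#' @param params a `resnet1d_params` tree from [init_classifier()].
#' @param config the matching [classifier_config()].
#' @param mode `"eval"` (running batch-norm statistics; deterministic) or
#'   `"train"` (batch statistics; running statistics are updated in the
#'   returned `params`).
#' @return list with `scores` (n x n_classes), `probs` (softmax rows, sum 1),
#'   `f1`, `f2`, `params` (updated), and `caches` for the backward pass.
#' @export
classifier_forward <- function(latents, params, config, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  check_finite_matrix(latents)
  if (ncol(latents) != config$in_length) {
    stop(sprintf("latents have %d columns but config$in_length is %d",
                 ncol(latents), config$in_length), call. = FALSE)
  }
  n <- nrow(latents)
  x <- array(latents, c(n, config$in_length, 1L))
  caches <- list()
  c1 <- conv1d_forward(x, params$conv1); caches$conv1 <- c1$cache
  c2 <- conv1d_forward(c1$y, params$conv2); caches$conv2 <- c2$cache
  bs <- bn_forward(c2$y, params$bn_stem, mode); params$bn_stem <- bs$params
  caches$bn_stem <- bs$cache
  x <- pmax(bs$y, 0)
  caches$stem_out <- x
  f1 <- x
  caches$stages <- vector("list", 4L)
  for (s in 1:4) {
    caches$stages[[s]] <- vector("list", 2L)
    for (b in 1:2) {
      fw <- block_forward(x, params$stages[[s]][[b]], mode)
      params$stages[[s]][[b]] <- fw$params
      caches$stages[[s]][[b]] <- fw$cache
      x <- fw$y
    }
    if (s == 2L) f2 <- x
  }
  L_final <- dim(x)[2L]
  feat <- apply(x, c(1L, 3L), mean)          # global average pool -> n x C
  if (n == 1L) feat <- matrix(feat, 1L)
  scores <- sweep(feat %*% t(params$fc$W), 2L, params$fc$b, "+")
  probs <- softmax_rows(scores)
  caches$feat <- feat
  caches$L_final <- L_final
  caches$final_dim <- dim(x)
  list(scores = scores, probs = probs, f1 = f1, f2 = f2,
       params = params, caches = caches)
}

classifier_backward <- function(dscores, params, caches) {
  g <- list()
  g$fc <- list(W = crossprod(dscores, caches$feat), b = colSums(dscores))
  dfeat <- dscores %*% params$fc$W
  fd <- caches$final_dim
  dx <- array(0, fd)
  for (l in seq_len(fd[2L])) dx[, l, ] <- dfeat / fd[2L]
  g$stages <- vector("list", 4L)
  for (s in 4:1) {
    g$stages[[s]] <- vector("list", 2L)
    for (b in 2:1) {
      bk <- block_backward(dx, params$stages[[s]][[b]], caches$stages[[s]][[b]])
      g$stages[[s]][[b]] <- bk$grads
      dx <- bk$dx
    }
  }
  dx <- dx * (caches$stem_out > 0)
  bs <- bn_backward(dx, params$bn_stem, caches$bn_stem); g$bn_stem <- bs$grads
  c2 <- conv1d_backward(bs$dx, params$conv2, caches$conv2); g$conv2 <- c2$grads
  c1 <- conv1d_backward(c2$dx, params$conv1, caches$conv1); g$conv1 <- c1$grads
  dl <- c1$dx
  list(grads = g, dlatents = matrix(dl, dim(dl)[1L], dim(dl)[2L]))
}

# --- Adam over nested parameter trees --------------------------------------

tree_zero_like <- function(g) {
  if (is.list(g)) lapply(g, tree_zero_like) else g * 0
}

adam_tree_step <- function(params, grads, m, v, t, lr,
                           beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.list(grads)) {
    idx <- if (is.null(names(grads))) seq_along(grads) else names(grads)
    for (k in idx) {
      if (is.null(grads[[k]])) next
      r <- adam_tree_step(params[[k]], grads[[k]], m[[k]], v[[k]], t, lr,
                          beta1, beta2, eps)
      params[[k]] <- r$params; m[[k]] <- r$m; v[[k]] <- r$v
    }
    return(list(params = params, m = m, v = v))
  }
  m <- beta1 * m + (1 - beta1) * grads
  v <- beta2 * v + (1 - beta2) * grads^2
  params <- params - lr * (m / (1 - beta1^t)) / (sqrt(v / (1 - beta2^t)) + eps)
  list(params = params, m = m, v = v)
}

softmax_ce_grad <- function(probs, onehot) {
  loss <- -mean(log(rowSums(probs * onehot) + 1e-12))
  list(loss = loss, dscores = (probs - onehot) / nrow(probs))
}

mse_onehot_grad <- function(probs, onehot) {
  n <- nrow(probs); k <- ncol(probs)
  loss <- mean((probs - onehot)^2)
  dprobs <- 2 * (probs - onehot) / (n * k)
  dscores <- probs * (dprobs - rowSums(dprobs * probs))
  list(loss = loss, dscores = dscores)
}

#' Train the 1D ResNet-18 classifier
#'
#' Minibatch Adam on the latent features. The default loss is cross-entropy
#' on the logits; `"mse_one_hot"` instead minimizes the mean squared error
#' between the softmax probabilities and one-hot labels.
#'
#' @param latents numeric matrix, n x `in_length`.
#' @param labels integer class labels in `0:(n_classes - 1)`.
#' @param config a [classifier_config()].
#' @param epochs training epochs.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size (clamped to n).
#' @param loss `"cross_entropy"` or `"mse_one_hot"`.
#' @param seed seed for batch shuffling (initialization uses `config$seed`).
#' @return list of class `resnet1d` with `params`, `trace` (mean per-epoch
#'   training loss), and `config`.
#' @export
train_classifier <- function(latents, labels, config = classifier_config(),
                             epochs = 30L, learning_rate = 1e-3,
                             batch_size = 128L,
                             loss = c("cross_entropy", "mse_one_hot"),
                             seed = 1L) {
  loss <- match.arg(loss)
  labels <- as.integer(labels)
  stopifnot(nrow(latents) == length(labels),
            all(labels >= 0L), all(labels < config$n_classes))
  params <- init_classifier(config)
  grad_fn <- if (loss == "cross_entropy") softmax_ce_grad else mse_onehot_grad
  n <- nrow(latents)
  bs <- min(batch_size, n)
  m <- NULL; v <- NULL; t <- 0L
  trace <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        Xb <- latents[idx, , drop = FALSE]
        Yb <- diag(config$n_classes)[labels[idx] + 1L, , drop = FALSE]
        fw <- classifier_forward(Xb, params, config, mode = "train")
        params <- fw$params
        lg <- grad_fn(fw$probs, Yb)
        if (!is.finite(lg$loss)) {
          stop(sprintf("non-finite classifier loss at epoch %d", ep), call. = FALSE)
        }
        grads <- classifier_backward(lg$dscores, params, fw$caches)$grads
        if (is.null(m)) { m <- tree_zero_like(grads); v <- tree_zero_like(grads) }
        t <- t + 1L
        upd <- adam_tree_step(params, grads, m, v, t, learning_rate)
        # adam_tree_step only touches keys present in `grads`; running
        # batch-norm statistics pass through untouched
        params <- upd$params; m <- upd$m; v <- upd$v
        ep_loss <- ep_loss + lg$loss * length(idx)
      }
      trace[ep] <- ep_loss / n
    }
  })
  structure(list(params = params, trace = trace, config = config,
                 loss = loss),
            class = "resnet1d")
}

#' @export
print.resnet1d <- function(x, ...) {
  cat(sprintf("<resnet1d>  in_length %d, channels %s, %d classes, %d parameters\n",
              x$config$in_length, paste(x$config$channels, collapse = "/"),
              x$config$n_classes, n_parameters(x$params)))
  if (length(x$trace)) {
    cat(sprintf("  %s loss: %.4f (first epoch) -> %.4f (final)\n",
                x$loss, x$trace[1L], x$trace[length(x$trace)]))
  }
  invisible(x)
}

#' Predict class labels with a trained classifier
#'
#' Eval-mode forward pass; ties in the argmax go to the lowest class index.
#'
#' @param object a `resnet1d` model from [train_classifier()].
#' @param latents numeric matrix, n x `in_length`.
#' @param ... unused.
#' @return list with `labels` (integer 0-based predictions) and `probs`.
#' @export
predict.resnet1d <- function(object, latents, ...) {
  fw <- classifier_forward(latents, object$params, object$config, mode = "eval")
  labels <- apply(fw$probs, 1L, which.max) - 1L  # which.max: first (lowest) index
  list(labels = as.integer(labels), probs = fw$probs)
}
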