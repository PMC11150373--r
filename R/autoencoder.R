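# LRA-weighted autoencoder: three tanh encoder layers, each applied to its
# input reweighted by a fresh low-rank attention matrix, and a two-layer
# decoder. Gradients are hand-derived; the attention matrices enter the
# forward value only (gradient isolation) - the backward pass treats every
# attention matrix as a constant, so no derivative ever flows through the SVD.

#' Autoencoder configuration
#'
#' @param input_dim segment length d fed to the encoder.
#' @param encoder_dims output sizes of the three encoder layers.
#' @param decoder_dims output size of the inner decoder layer; the final
#'   decoder layer always maps back to `input_dim`.
#' @param learning_rate Adam learning rate.
#' @param epochs number of training epochs.
#' @param batch_size minibatch size; `NULL` (default) trains full-batch.
#' @param seed seed for weight initialization and batch shuffling.
#' @param final_activation `"tanh"` (reconstructions bounded in (-1,1); the
#'   training data are affinely mapped into [-0.95, 0.95] first) or
#'   `"linear"`.
#' @return an object of class `ae_config`.
#' @export
ae_config <- function(input_dim = 250L, encoder_dims = c(128L, 96L, 64L),
                      decoder_dims = 128L, learning_rate = 1e-3,
                      epochs = 200L, batch_size = NULL, seed = 1L,
                      final_activation = c("tanh", "linear")) {
  final_activation <- match.arg(final_activation)
  stopifnot(input_dim >= 1L, length(encoder_dims) == 3L, all(encoder_dims >= 1L),
            length(decoder_dims) == 1L, decoder_dims >= 1L,
            learning_rate > 0, epochs >= 0L)
  structure(list(input_dim = as.integer(input_dim),
                 encoder_dims = as.integer(encoder_dims),
                 decoder_dims = as.integer(decoder_dims),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = if (is.null(batch_size)) NULL else as.integer(batch_size),
                 seed = as.integer(seed), final_activation = final_activation),
            class = "ae_config")
}

glorot <- function(n_out, n_in) {
  r <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_out * n_in, -r, r), n_out, n_in)
}

#' Initialize autoencoder weights
#'
#' Glorot-uniform weights, zero biases, drawn from the config's seed.
#' Weight matrices are stored output-by-input and applied as `X %*% t(W)`.
#'
#' @param config an [ae_config()].
#' @return named list `W1,b1,...,W5,b5` of class `ae_state`.
#' @export
init_autoencoder <- function(config) {
  dims <- c(config$input_dim, config$encoder_dims, config$decoder_dims,
            config$input_dim)
  with_seed(config$seed, {
    state <- list()
    for (i in 1:5) {
      state[[paste0("W", i)]] <- glorot(dims[i + 1L], dims[i])
      state[[paste0("b", i)]] <- numeric(dims[i + 1L])
    }
    structure(state, class = "ae_state")
  })
}

linear_tanh <- function(X, W, b) tanh(sweep(X %*% t(W), 2L, b, "+"))

# Forward pass. `attn` may carry precomputed attention matrices (A1, A2, A3)
# to freeze the weighting (used by gradient checks); otherwise each layer
# recomputes lra_weights on its own input.
ae_forward <- function(X, state, config, attn = NULL) {
  A1 <- if (is.null(attn)) lra_weights(X) else attn$A1
  O1 <- linear_tanh(X %*% A1, state$W1, state$b1)
  A2 <- if (is.null(attn)) lra_weights(O1) else attn$A2
  O2 <- linear_tanh(O1 %*% A2, state$W2, state$b2)
  A3 <- if (is.null(attn)) lra_weights(O2) else attn$A3
  O3 <- linear_tanh(O2 %*% A3, state$W3, state$b3)
  O4 <- linear_tanh(O3, state$W4, state$b4)
  Z5 <- sweep(O4 %*% t(state$W5), 2L, state$b5, "+")
  O5 <- if (config$final_activation == "tanh") tanh(Z5) else Z5
  list(O1 = O1, O2 = O2, O3 = O3, O4 = O4, O5 = O5,
       attn = list(A1 = A1, A2 = A2, A3 = A3))
}

#' Encode a feature matrix through the LRA-weighted encoder
#'
#' Each encoder layer computes `tanh((O %*% F(O)) %*% t(W) + b)` where `F(O)`
#' is the low-rank attention matrix of that layer's own input, recomputed on
#' every call and treated as a constant by all gradient consumers.
#'
#' @param X numeric matrix, n x `input_dim`.
#' @param state an `ae_state`.
#' @param config the matching [ae_config()].
#' @return list with encoder activations `O1`, `O2`, `O3` and the attention
#'   matrices used (`attn`).
#' @export
ae_encode <- function(X, state, config) {
  check_finite_matrix(X)
  if (ncol(X) != config$input_dim) {
    stop(sprintf("X has %d columns but the encoder expects %d",
                 ncol(X), config$input_dim), call. = FALSE)
  }
  A1 <- lra_weights(X)
  O1 <- linear_tanh(X %*% A1, state$W1, state$b1)
  A2 <- lra_weights(O1)
  O2 <- linear_tanh(O1 %*% A2, state$W2, state$b2)
  A3 <- lra_weights(O2)
  O3 <- linear_tanh(O2 %*% A3, state$W3, state$b3)
  list(O1 = O1, O2 = O2, O3 = O3, attn = list(A1 = A1, A2 = A2, A3 = A3))
}

#' Decode a latent matrix back to signal space
#'
#' `O4 = tanh(O3 %*% t(W4) + b4)`; the reconstruction is
#' `tanh(O4 %*% t(W5) + b5)` (or linear per config).
#'
#' @param O3 latent matrix, n x `encoder_dims[3]`.
#' @inheritParams ae_encode
#' @return reconstruction matrix, n x `input_dim`.
#' @export
ae_decode <- function(O3, state, config) {
  check_finite_matrix(O3)
  if (ncol(O3) != config$encoder_dims[3L]) {
    stop(sprintf("O3 has %d columns but the decoder expects %d",
                 ncol(O3), config$encoder_dims[3L]), call. = FALSE)
  }
  O4 <- linear_tanh(O3, state$W4, state$b4)
  Z5 <- sweep(O4 %*% t(state$W5), 2L, state$b5, "+")
  if (config$final_activation == "tanh") tanh(Z5) else Z5
}

# Loss + gradients for one batch. Mean squared reconstruction error over all
# entries; backward treats the attention matrices as constants: the gradient
# reaching a weighted layer input (O %*% A) is mapped back through t(A) only.
# `dO3_extra` injects an additional gradient at the latent O3 (joint training
# with a downstream classifier).
ae_grads <- function(X, state, config, attn = NULL, dO3_extra = NULL) {
  fw <- ae_forward(X, state, config, attn = attn)
  n <- nrow(X); d <- ncol(X)
  err <- fw$O5 - X
  loss <- mean(err^2)
  g <- list()
  dO5 <- 2 * err / (n * d)
  dZ5 <- if (config$final_activation == "tanh") dO5 * (1 - fw$O5^2) else dO5
  g$W5 <- crossprod(dZ5, fw$O4); g$b5 <- colSums(dZ5)
  dO4 <- dZ5 %*% state$W5
  dZ4 <- dO4 * (1 - fw$O4^2)
  g$W4 <- crossprod(dZ4, fw$O3); g$b4 <- colSums(dZ4)
  dO <- dZ4 %*% state$W4
  if (!is.null(dO3_extra)) dO <- dO + dO3_extra
  A <- fw$attn
  inputs <- list(X, fw$O1, fw$O2)
  for (i in 3:1) {
    Oi <- list(fw$O1, fw$O2, fw$O3)[[i]]
    dZ <- dO * (1 - Oi^2)
    Xi_w <- inputs[[i]] %*% A[[paste0("A", i)]]
    g[[paste0("W", i)]] <- crossprod(dZ, Xi_w)
    g[[paste0("b", i)]] <- colSums(dZ)
    if (i > 1L) {
      dO <- tcrossprod(dZ %*% state[[paste0("W", i)]], A[[paste0("A", i)]])
    }
  }
  list(loss = loss, grads = g, forward = fw)
}

# Adam optimizer over a flat named list of arrays.
adam_init <- function(state) {
  list(m = lapply(state, function(p) p * 0),
       v = lapply(state, function(p) p * 0), t = 0L)
}

adam_step <- function(state, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (k in names(grads)) {
    opt$m[[k]] <- beta1 * opt$m[[k]] + (1 - beta1) * grads[[k]]
    opt$v[[k]] <- beta2 * opt$v[[k]] + (1 - beta2) * grads[[k]]^2
    state[[k]] <- state[[k]] -
      lr * (opt$m[[k]] / bc1) / (sqrt(opt$v[[k]] / bc2) + eps)
  }
  list(state = state, opt = opt)
}

# Affine map of Z-scored data into [-lim, lim] so the tanh-bounded decoder
# can reach every target. The inverse map constants are stored with the map.
tanh_range_map <- function(X, lim = 0.95) {
  lo <- min(X); hi <- max(X)
  if (hi == lo) hi <- lo + 1
  scale <- 2 * lim / (hi - lo)
  offset <- -lim - scale * lo
  list(scale = scale, offset = offset, lo = lo, hi = hi)
}

apply_range_map <- function(X, map) X * map$scale + map$offset

invert_range_map <- function(X, map) (X - map$offset) / map$scale

#' Pretrain the LRA autoencoder on signal reconstruction
#'
#' Minimizes the mean squared error between the (range-mapped) input segments
#' and their reconstruction with Adam. Attention matrices are recomputed at
#' every forward pass on the current layer inputs and excluded from the
#' gradient graph. With the default tanh output, the Z-scored segments are
#' affinely mapped into [-0.95, 0.95] before training (the map is returned
#' and stored for inversion); with `final_activation = "linear"` no mapping
#' is applied.
#'
#' @param data a [beat_dataset()] (or plain matrix) of training segments.
#' @param config an [ae_config()].
#' @return list of class `lra_autoencoder` with elements `state`
#'   (the trained `ae_state`), `trace` (per-epoch reconstruction MSE,
#'   length `epochs`), `config`, and `range_map`.
#' @export
pretrain_autoencoder <- function(data, config = ae_config()) {
  X <- if (inherits(data, "beat_dataset")) data$segments else as.matrix(data)
  if (nrow(X) == 0L) stop("empty training data", call. = FALSE)
  if (ncol(X) != config$input_dim) {
    stop(sprintf("segments have %d samples but config$input_dim is %d",
                 ncol(X), config$input_dim), call. = FALSE)
  }
  range_map <- NULL
  if (config$final_activation == "tanh") {
    range_map <- tanh_range_map(X)
    X <- apply_range_map(X, range_map)
  }
  state <- init_autoencoder(config)
  opt <- adam_init(state)
  trace <- numeric(config$epochs)
  n <- nrow(X)
  bs <- if (is.null(config$batch_size)) n else min(config$batch_size, n)
  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord <- if (bs < n) sample.int(n) else seq_len(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        gr <- ae_grads(X[idx, , drop = FALSE], state, config)
        if (!is.finite(gr$loss)) {
          stop(sprintf("non-finite reconstruction loss at epoch %d", ep),
               call. = FALSE)
        }
        upd <- adam_step(state, gr$grads, opt, config$learning_rate)
        state <- upd$state; opt <- upd$opt
        ep_loss <- ep_loss + gr$loss * length(idx)
      }
      trace[ep] <- ep_loss / n
    }
  })
  structure(list(state = state, trace = trace, config = config,
                 range_map = range_map),
            class = "lra_autoencoder")
}

#' @export
print.lra_autoencoder <- function(x, ...) {
  dims <- c(x$config$input_dim, x$config$encoder_dims, x$config$decoder_dims,
            x$config$input_dim)
  cat(sprintf("<lra_autoencoder>  %s, %d epochs trained\n",
              paste(dims, collapse = " -> "), length(x$trace)))
  if (length(x$trace)) {
    cat(sprintf("  reconstruction MSE: %.5f (first) -> %.5f (final)\n",
                x$trace[1L], x$trace[length(x$trace)]))
  }
  invisible(x)
}

#' Encode data with a pretrained autoencoder
#'
#' Applies the stored range map (if any) and returns the latent encoder
#' output O3.
#'
#' @param model an object returned by [pretrain_autoencoder()].
#' @param X segment matrix, n x `input_dim`.
#' @return latent matrix, n x `encoder_dims[3]`.
#' @export
latent_features <- function(model, X) {
  stopifnot(inherits(model, "lra_autoencoder"))
  if (!is.null(model$range_map)) X <- apply_range_map(X, model$range_map)
  ae_encode(X, model$state, model$config)$O3
}

#' Save a model checkpoint
#'
#' Checkpoints are a flat named key-to-array mapping (weights, biases,
#' batch-norm running statistics, config fields, range-map constants, seed)
#' written with R's native serialization (version 3). Round-trips are
#' bit-exact: `identical(load_checkpoint(save_checkpoint(x, f)), x)` holds.
#'
#' @param object any model object from this package.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
save_checkpoint <- function(object, path) {
  saveRDS(object, path, version = 3L)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop(sprintf("no checkpoint at '%s'", path), call. = FALSE)
  readRDS(path)
}
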