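small_cfg <- function(seed = 3L) {
  classifier_config(in_length = 12L, channels = c(4L, 5L, 6L, 7L), seed = seed)
}

test_that("relu follows the piecewise definition with zero at the boundary", {
  expect_equal(relu(2), 2)
  expect_equal(relu(-3), 0)
  expect_equal(relu(0), 0)
  x <- c(-1.5, 0, 2.5, -0.1)
  expect_equal(relu(x), c(0, 0, 2.5, 0))
  expect_error(relu(c(1, NA)), "non-finite")
})

test_that("a residual block with zeroed inner path is the identity", {
  bp <- lraecg:::init_block(2L, 2L, 1L, 0.1, 1e-5)
  for (layer in c("conv_a", "conv_b")) {
    bp[[layer]]$W <- bp[[layer]]$W * 0
  }
  x <- array(rnorm(2 * 6 * 2), c(2L, 6L, 2L))
  out <- res_block_forward(x, bp, mode = "eval")
  expect_equal(unclass(out), x, ignore_attr = TRUE)
})

test_that("block convolution matches the sliding-window oracle on a hand case", {
  # single channel, length 5, kernel [1, 0, -1], stride 1, pad 1
  x <- c(0, 1, 2, 1, 0)
  p <- list(W = matrix(c(1, 0, -1), 1L, 3L), b = 0,
            spec = lraecg:::conv_spec(1L, 1L, 3L, 1L, 1L))
  fw <- lraecg:::conv1d_forward(array(x, c(1L, 5L, 1L)), p)
  oracle <- oracle_conv1d(matrix(x, 5L, 1L),
                          list(matrix(c(1, 0, -1), 3L, 1L)), 0, 1L, 1L)
  expect_equal(as.numeric(fw$y), as.numeric(oracle), tolerance = 1e-10)
  # assemble the full block by hand: conv -> identity bn -> relu twice + x
  bp <- lraecg:::init_block(1L, 1L, 1L, 0.1, 1e-5)
  bp$conv_a <- p
  bp$conv_b$W <- matrix(c(0, 1, 0), 1L, 3L)  # identity kernel
  bp$conv_b$b <- 0
  big_var <- function(bn) { bn$eps <- 0; bn$run_mean <- 0; bn$run_var <- 1; bn }
  bp$bn_a <- big_var(bp$bn_a); bp$bn_b <- big_var(bp$bn_b)
  out <- res_block_forward(array(x, c(1L, 5L, 1L)), bp, mode = "eval")
  expect_equal(as.numeric(out), pmax(pmax(as.numeric(oracle), 0), 0) + x,
               tolerance = 1e-10)
})

test_that("convolutions agree with the naive oracle on seeded fixtures", {
  set.seed(42)
  for (r in 1:6) {
    C_in <- sample(1:3, 1L); C_out <- sample(1:3, 1L)
    K <- sample(1:3, 1L); stride <- sample(1:2, 1L); pad <- sample(0:1, 1L)
    L <- sample((K + 2):9, 1L)
    p <- list(W = matrix(rnorm(C_out * C_in * K), C_out, C_in * K),
              b = rnorm(C_out),
              spec = lraecg:::conv_spec(C_in, C_out, K, stride, pad))
    x <- matrix(rnorm(L * C_in), L, C_in)
    Wl <- lapply(seq_len(C_out), function(co) {
      matrix(p$W[co, ], K, C_in)  # column-major: k fastest, matching (c-1)*K+k
    })
    fw <- lraecg:::conv1d_forward(array(x, c(1L, L, C_in)), p)
    oracle <- oracle_conv1d(x, Wl, p$b, stride, pad)
    got <- matrix(fw$y[1L, , ], dim(fw$y)[2L], C_out)
    expect_equal(got, oracle, tolerance = 1e-8)
  }
})

test_that("stride-1 padding-1 blocks preserve length", {
  bp <- lraecg:::init_block(3L, 3L, 1L, 0.1, 1e-5)
  for (L in c(4L, 7L, 11L)) {
    x <- array(rnorm(2 * L * 3), c(2L, L, 3L))
    expect_identical(dim(res_block_forward(x, bp, "eval"))[2L], L)
  }
})

test_that("the stem shrinks a 64-length latent to 21 then 7 positions", {
  expect_identical(lraecg:::conv_out_len(64L, 3L, 3L, 0L), 21L)
  expect_identical(lraecg:::conv_out_len(21L, 3L, 3L, 0L), 7L)
  cfg <- classifier_config(in_length = 64L, seed = 1L)
  params <- init_classifier(cfg)
  X <- matrix(rnorm(3 * 64), 3L, 64L)
  fw <- classifier_forward(X, params, cfg, mode = "eval")
  expect_identical(dim(fw$f1)[2L], 7L)
  expect_error(classifier_config(in_length = 8L), "too small")
})

test_that("probabilities are a proper distribution; zero FC gives uniform classes", {
  cfg <- small_cfg()
  params <- init_classifier(cfg)
  set.seed(2)
  X <- matrix(rnorm(6 * 12), 6L, 12L)
  fw <- classifier_forward(X, params, cfg, mode = "eval")
  expect_equal(rowSums(fw$probs), rep(1, 6L), tolerance = 1e-9)
  params$fc$W <- params$fc$W * 0
  params$fc$b <- params$fc$b * 0
  fw0 <- classifier_forward(X, params, cfg, mode = "eval")
  expect_equal(unclass(fw0$probs), matrix(0.25, 6L, 4L), ignore_attr = TRUE)
})

test_that("eval-mode forward is bitwise deterministic", {
  cfg <- small_cfg()
  params <- init_classifier(cfg)
  set.seed(8)
  X <- matrix(rnorm(4 * 12), 4L, 12L)
  f1 <- classifier_forward(X, params, cfg, mode = "eval")
  f2 <- classifier_forward(X, params, cfg, mode = "eval")
  expect_identical(f1$scores, f2$scores)
  expect_identical(f1$probs, f2$probs)
})

test_that("zeroing all inner paths reduces identity-shaped stages to the identity", {
  cfg <- classifier_config(in_length = 12L, channels = c(3L, 3L, 3L, 3L),
                           no_downsample = TRUE, seed = 5L)
  params <- init_classifier(cfg)
  for (s in 1:4) for (b in 1:2) {
    params$stages[[s]][[b]]$conv_a$W <- params$stages[[s]][[b]]$conv_a$W * 0
    params$stages[[s]][[b]]$conv_b$W <- params$stages[[s]][[b]]$conv_b$W * 0
    params$stages[[s]][[b]]$bn_a$gamma <- params$stages[[s]][[b]]$bn_a$gamma * 0
    params$stages[[s]][[b]]$bn_b$gamma <- params$stages[[s]][[b]]$bn_b$gamma * 0
    params$stages[[s]][[b]]$bn_a$beta <- params$stages[[s]][[b]]$bn_a$beta * 0
    params$stages[[s]][[b]]$bn_b$beta <- params$stages[[s]][[b]]$bn_b$beta * 0
  }
  x <- array(rnorm(2 * 5 * 3), c(2L, 5L, 3L))
  out <- x
  for (s in 1:4) for (b in 1:2) {
    out <- unclass(res_block_forward(out, params$stages[[s]][[b]], "eval"))
    attributes(out)[c("params")] <- NULL
  }
  expect_equal(out, x, ignore_attr = TRUE)
})

test_that("default configuration parameter count is stable", {
  params <- init_classifier(classifier_config())
  expect_identical(n_parameters(params), 3850896L)
})

test_that("classifier gradients match finite differences at sampled leaves", {
  cfg <- small_cfg()
  set.seed(1)
  X <- matrix(rnorm(5 * 12), 5L, 12L)
  y <- c(0L, 1L, 2L, 3L, 0L)
  params <- init_classifier(cfg)
  Y <- diag(4L)[y + 1L, ]
  loss_of <- function(p) {
    fw <- classifier_forward(X, p, cfg, mode = "train")
    -mean(log(rowSums(fw$probs * Y) + 1e-12))
  }
  fw <- classifier_forward(X, params, cfg, mode = "train")
  lg <- lraecg:::softmax_ce_grad(fw$probs, Y)
  bk <- lraecg:::classifier_backward(lg$dscores, fw$params, fw$caches)
  paths <- list(list("conv1", "W"), list("conv2", "W"), list("bn_stem", "gamma"),
                list("stages", 2L, 1L, "proj_conv", "W"),
                list("stages", 3L, 2L, "conv_b", "W"),
                list("stages", 4L, 2L, "bn_b", "beta"), list("fc", "W"))
  for (path in paths) {
    w <- get_leaf(params, path)
    idx <- sample(seq_along(w), min(3L, length(w)))
    fd <- fd_grad(function(wv) {
      loss_of(set_leaf(params, path, array(wv, dim(w) %||% length(w))))
    }, as.numeric(w), idx, eps = 1e-5)
    an <- as.numeric(get_leaf(bk$grads, path))[idx]
    expect_equal(an, fd, tolerance = 1e-4)
  }
})

test_that("training reduces the loss and ties resolve to the lowest class", {
  set.seed(77)
  lat <- rbind(matrix(rnorm(20 * 12, mean = 1), 20L, 12L),
               matrix(rnorm(20 * 12, mean = -1), 20L, 12L))
  y <- rep(c(0L, 1L), each = 20L)
  clf <- train_classifier(lat, y, small_cfg(), epochs = 8L, batch_size = 20L,
                          seed = 5L)
  expect_lt(clf$trace[8L], clf$trace[1L])
  # exact score ties must go to the lowest class index
  clf0 <- clf
  clf0$params$fc$W <- clf0$params$fc$W * 0
  clf0$params$fc$b <- clf0$params$fc$b * 0
  pred <- predict(clf0, lat)
  expect_true(all(pred$labels == 0L))
})

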