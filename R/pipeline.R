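# End-to-end orchestration: dataset construction, seeded stratified
# splitting, staged (or joint) training of the LRA autoencoder and the
# ResNet-18 classifier, and held-out evaluation.

#' End-to-end run configuration
#'
#' @param source `"synthetic"`, `"fixture"` or `"wfdb"`. For file sources,
#'   `paths` holds one or more record stems passed to [load_record()].
#' @param paths record stems for file sources.
#' @param n_train_per_class,n_test_per_class synthetic beats per class in the
#'   train and held-out split.
#' @param d segment length in samples.
#' @param window beat-segmentation window, `c(pre = , post = )`;
#'   `pre + post` must equal `d`.
#' @param seed master seed; data generation, the split, the autoencoder and
#'   classifier initializations and the batch order all derive from it.
#' @param test_fraction held-out fraction for file sources (synthetic sources
#'   use the explicit per-class counts).
#' @param ae_epochs,ae_learning_rate,ae_batch_size autoencoder training
#'   hyperparameters ([ae_config()]).
#' @param encoder_dims,decoder_dims autoencoder layer widths.
#' @param clf_epochs,clf_learning_rate,clf_batch_size classifier training
#'   hyperparameters.
#' @param classifier_loss `"cross_entropy"` (default) or `"mse_one_hot"`.
#' @param joint_training train autoencoder and classifier jointly on the sum
#'   of reconstruction and classification loss instead of in stages.
#' @return an object of class `run_config`.
#' @export
run_config <- function(source = c("synthetic", "fixture", "wfdb"),
                       paths = NULL,
                       n_train_per_class = 200L, n_test_per_class = 80L,
                       d = 250L, window = c(pre = 100L, post = 150L),
                       seed = 42L, test_fraction = 0.2,
                       ae_epochs = 200L, ae_learning_rate = 1e-3,
                       ae_batch_size = NULL,
                       encoder_dims = c(128L, 96L, 64L), decoder_dims = 128L,
                       clf_epochs = 30L, clf_learning_rate = 1e-3,
                       clf_batch_size = 128L,
                       classifier_loss = c("cross_entropy", "mse_one_hot"),
                       joint_training = FALSE) {
  source <- match.arg(source)
  classifier_loss <- match.arg(classifier_loss)
  if (source != "synthetic" && is.null(paths)) {
    stop(sprintf("source '%s' needs `paths`", source), call. = FALSE)
  }
  if (sum(window) != d) stop("window pre + post must equal d", call. = FALSE)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("`test_fraction` must lie in (0, 1)", call. = FALSE)
  }
  structure(as.list(environment()), class = "run_config")
}

# Deterministic stratified split: exactly `n_test` held-out rows per class
# when given, otherwise a fraction.
stratified_split <- function(labels, seed, n_test = NULL, fraction = 0.2) {
  with_seed(seed, {
    test_idx <- integer(0)
    for (cls in sort(unique(labels))) {
      rows <- which(labels == cls)
      k <- if (!is.null(n_test)) min(n_test, length(rows) - 1L)
           else max(1L, round(fraction * length(rows)))
      test_idx <- c(test_idx, sample(rows, k))
    }
    sort(test_idx)
  })
}

build_dataset <- function(config) {
  if (config$source == "synthetic") {
    n <- config$n_train_per_class + config$n_test_per_class
    return(synth_beat_dataset(n, d = config$d, seed = config$seed))
  }
  dialect <- if (config$source == "fixture") "csv_fixture" else "wfdb"
  parts <- lapply(config$paths, function(p) {
    loaded <- load_record(p, dialect = dialect)
    segment_beats(loaded$record, loaded$annotations, window = config$window)
  })
  segs <- do.call(rbind, lapply(parts, function(x) x$segments))
  labels <- unlist(lapply(parts, function(x) x$labels))
  prov <- do.call(rbind, lapply(parts, function(x) x$provenance))
  if (length(labels) == 0L) {
    stop("dataset is empty after annotation filtering", call. = FALSE)
  }
  beat_dataset(segs, labels, parts[[1L]]$label_map, provenance = prov)
}

joint_train <- function(X_train, labels, ae_cfg, clf_cfg, config) {
  range_map <- tanh_range_map(X_train)
  Xs <- apply_range_map(X_train, range_map)
  state <- init_autoencoder(ae_cfg)
  clf_params <- init_classifier(clf_cfg)
  ae_opt <- adam_init(state)
  cm <- NULL; cv <- NULL; ct <- 0L
  n <- nrow(Xs)
  bs <- min(config$clf_batch_size, n)
  epochs <- config$clf_epochs
  trace <- numeric(epochs)
  onehot_full <- diag(clf_cfg$n_classes)
  with_seed(config$seed + 2L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        Xb <- Xs[idx, , drop = FALSE]
        Yb <- onehot_full[labels[idx] + 1L, , drop = FALSE]
        enc <- ae_encode(Xb, state, ae_cfg)
        fw <- classifier_forward(enc$O3, clf_params, clf_cfg, mode = "train")
        clf_params <- fw$params
        lg <- if (config$classifier_loss == "cross_entropy") {
          softmax_ce_grad(fw$probs, Yb)
        } else mse_onehot_grad(fw$probs, Yb)
        bk <- classifier_backward(lg$dscores, clf_params, fw$caches)
        gr <- ae_grads(Xb, state, ae_cfg, attn = enc$attn,
                       dO3_extra = bk$dlatents)
        total <- lg$loss + gr$loss
        if (!is.finite(total)) {
          stop(sprintf("non-finite joint loss at epoch %d", ep), call. = FALSE)
        }
        upd <- adam_step(state, gr$grads, ae_opt, ae_cfg$learning_rate)
        state <- upd$state; ae_opt <- upd$opt
        if (is.null(cm)) { cm <- tree_zero_like(bk$grads); cv <- tree_zero_like(bk$grads) }
        ct <- ct + 1L
        cu <- adam_tree_step(clf_params, bk$grads, cm, cv, ct,
                             config$clf_learning_rate)
        clf_params <- cu$params; cm <- cu$m; cv <- cu$v
        ep_loss <- ep_loss + total * length(idx)
      }
      trace[ep] <- ep_loss / n
    }
  })
  list(autoencoder = structure(list(state = state, trace = trace, config = ae_cfg,
                                    range_map = range_map),
                               class = "lra_autoencoder"),
       classifier = structure(list(params = clf_params, trace = trace,
                                   config = clf_cfg,
                                   loss = config$classifier_loss),
                              class = "resnet1d"))
}

#' Train the full LRA-autoencoder + ResNet-18 pipeline
#'
#' Builds the dataset, splits it into train and held-out parts with the
#' seeded stratified split, pretrains the LRA autoencoder on reconstruction
#' (or trains jointly per `config$joint_training`), trains the classifier on
#' the latent O3 features, and evaluates on the held-out split. The whole run
#' is reproducible from the config alone.
#'
#' @param config a [run_config()].
#' @return list of class `pipeline_result` with `autoencoder`, `classifier`,
#'   `report` (an `evaluation_report` on the held-out split), `split`
#'   (test indices), and `config`.
#' @export
train_pipeline <- function(config = run_config()) {
  data <- build_dataset(config)
  n_test <- if (config$source == "synthetic") config$n_test_per_class else NULL
  test_idx <- stratified_split(data$labels, config$seed + 1L,
                               n_test = n_test, fraction = config$test_fraction)
  train_idx <- setdiff(seq_along(data$labels), test_idx)
  X_train <- data$segments[train_idx, , drop = FALSE]
  X_test <- data$segments[test_idx, , drop = FALSE]
  y_train <- data$labels[train_idx]
  y_test <- data$labels[test_idx]

  ae_cfg <- ae_config(input_dim = config$d,
                      encoder_dims = config$encoder_dims,
                      decoder_dims = config$decoder_dims,
                      learning_rate = config$ae_learning_rate,
                      epochs = config$ae_epochs,
                      batch_size = config$ae_batch_size,
                      seed = config$seed)
  clf_cfg <- classifier_config(in_length = config$encoder_dims[3L],
                               seed = config$seed)

  if (config$joint_training) {
    models <- joint_train(X_train, y_train, ae_cfg, clf_cfg, config)
    ae <- models$autoencoder
    clf <- models$classifier
  } else {
    ae <- pretrain_autoencoder(beat_dataset(X_train, y_train, data$label_map),
                               ae_cfg)
    latents_train <- latent_features(ae, X_train)
    clf <- train_classifier(latents_train, y_train, clf_cfg,
                            epochs = config$clf_epochs,
                            learning_rate = config$clf_learning_rate,
                            batch_size = config$clf_batch_size,
                            loss = config$classifier_loss,
                            seed = config$seed + 2L)
  }

  report <- evaluate_model(list(autoencoder = ae, classifier = clf),
                           beat_dataset(X_test, y_test, data$label_map),
                           config = config)
  structure(list(autoencoder = ae, classifier = clf, report = report,
                 split = test_idx, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$classifier)
  cat(sprintf("  held-out accuracy: %.3f (%d test beats)\n",
              x$report$metrics$accuracy, sum(x$report$confusion)))
  invisible(x)
}

#' Evaluate trained models on a beat dataset
#'
#' Eval-mode forward pass over all segments, argmax prediction (ties to the
#' lowest class index), confusion matrix and one-vs-rest metrics.
#'
#' @param artifacts list with elements `autoencoder` (a pretrained
#'   `lra_autoencoder`) and `classifier` (a `resnet1d`).
#' @param dataset a [beat_dataset()] whose segment length matches the
#'   autoencoder's `input_dim`.
#' @param config optional [run_config()] recorded in the report metadata.
#' @return object of class `evaluation_report`: confusion matrix
#'   (rows = true, columns = predicted), `metrics` (a [class_metrics()]),
#'   `label_map`, predictions, and run metadata.
#' @export
evaluate_model <- function(artifacts, dataset, config = NULL) {
  ae <- artifacts$autoencoder
  clf <- artifacts$classifier
  if (ncol(dataset$segments) != ae$config$input_dim) {
    stop(sprintf("dataset segments have %d samples but the model expects %d",
                 ncol(dataset$segments), ae$config$input_dim), call. = FALSE)
  }
  latents <- latent_features(ae, dataset$segments)
  pred <- predict(clf, latents)
  k <- clf$config$n_classes
  lv <- seq_len(k) - 1L
  confusion <- table(factor(dataset$labels, levels = lv),
                     factor(pred$labels, levels = lv))
  confusion <- matrix(as.integer(confusion), k, k,
                      dimnames = list(true = dataset$label_map[as.character(lv)],
                                      predicted = dataset$label_map[as.character(lv)]))
  metrics <- class_metrics(confusion)
  structure(list(confusion = confusion, metrics = metrics,
                 label_map = dataset$label_map,
                 predictions = pred$labels,
                 metadata = list(
                   n_test = nrow(dataset$segments),
                   seed = if (!is.null(config)) config$seed else NA_integer_,
                   ae_trace = ae$trace,
                   clf_trace = clf$trace)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Confusion matrix (rows = true, columns = predicted):\n")
  print(x$confusion)
  cat("\n")
  print(x$metrics)
  invisible(x)
}

#' Hash of an evaluation report
#'
#' Deterministic hash of the report's confusion matrix, metrics and label
#' map; identical (config, seed) runs produce identical hashes.
#'
#' @param report an `evaluation_report`.
#' @return character hash.
#' @export
report_hash <- function(report) {
  stopifnot(inherits(report, "evaluation_report"))
  rlang::hash(list(confusion = report$confusion,
                   per_class = report$metrics$per_class,
                   accuracy = report$metrics$accuracy,
                   label_map = report$label_map))
}

#' Serialize an evaluation report to JSON
#'
#' @param report an `evaluation_report`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_report <- function(report, path) {
  out <- list(
    label_map = as.list(report$label_map),
    confusion = unname(apply(report$confusion, 1L, as.integer, simplify = FALSE)),
    per_class = report$metrics$per_class,
    accuracy = report$metrics$accuracy,
    metadata = report$metadata,
    hash = report_hash(report)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Dump the attention matrix of an input as dense CSV
#'
#' Computes [lra_weights()] of the given segment matrix and writes the d x d
#' attention matrix as plain CSV (no header).
#'
#' @param X segment matrix.
#' @param path output CSV file.
#' @return invisibly, `path`.
#' @export
attention_dump <- function(X, path) {
  A <- lra_weights(as.matrix(X))
  utils::write.table(A, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
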