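# Record containers, Z-score standardization, beat segmentation and
# fixed-length preparation. Conventions used throughout the package:
# all sample indices are 0-based and windows are half-open [start, end).

#' Construct an ECG record
#'
#' @param signal numeric vector or matrix (samples x leads), units mV.
#' @param fs sampling rate in Hz (360 for MIT-BIH-style records, 300 for
#'   PhysioNet-2017-style records).
#' @param lead_names character vector of lead names.
#' @param record_id record identifier string.
#' @return an object of class `ecg_record`.
#' @export
ecg_record <- function(signal, fs, lead_names = NULL, record_id = "record") {
  if (is.vector(signal)) signal <- matrix(signal, ncol = 1L)
  if (!is.numeric(signal) || !all(is.finite(signal))) {
    stop("`signal` must be finite numeric", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a positive sampling rate in Hz", call. = FALSE)
  }
  fs <- as.numeric(fs)
  if (is.null(lead_names)) lead_names <- paste0("lead", seq_len(ncol(signal)))
  structure(
    list(signal = signal, fs = fs, lead_names = lead_names,
         record_id = as.character(record_id)),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record '%s'>  %d samples, %d lead(s), fs = %g Hz (%.1f s)\n",
              x$record_id, nrow(x$signal), ncol(x$signal), x$fs,
              nrow(x$signal) / x$fs))
  invisible(x)
}

#' Construct a beat-annotation table
#'
#' @param sample_index integer vector of 0-based R-peak sample positions.
#' @param symbol character vector of annotation symbols; `N`, `L`, `R`, `V`
#'   are the classification targets, any other symbol is carried through and
#'   filtered at segmentation time.
#' @return data.frame with columns `sample_index`, `symbol`.
#' @export
beat_annotations <- function(sample_index, symbol) {
  if (length(sample_index) != length(symbol)) {
    stop("`sample_index` and `symbol` must have equal length", call. = FALSE)
  }
  if (length(sample_index) && any(sample_index < 0)) {
    stop("annotation sample indices must be nonnegative (0-based)", call. = FALSE)
  }
  data.frame(sample_index = as.integer(sample_index),
             symbol = as.character(symbol),
             stringsAsFactors = FALSE)
}

#' Beat-class label maps
#'
#' Integer-to-class maps: `"mitbih"` gives `0:N, 1:L, 2:R, 3:V`;
#' `"physionet2017"` gives `0:Noisy, 1:N, 2:AF, 3:Other`.
#' @param dialect which map to return.
#' @return named character vector; names are the integer codes.
#' @export
label_map <- function(dialect = c("mitbih", "physionet2017")) {
  dialect <- match.arg(dialect)
  switch(dialect,
    mitbih = c(`0` = "N", `1` = "L", `2` = "R", `3` = "V"),
    physionet2017 = c(`0` = "Noisy", `1` = "N", `2` = "AF", `3` = "Other"))
}

#' Construct a beat dataset
#'
#' Fixed-length (usually Z-scored) segments with integer class labels in
#' 0..3 and per-segment provenance.
#'
#' @param segments numeric matrix, n segments x d samples.
#' @param labels integer vector of class labels in `0:3`.
#' @param label_map named character vector mapping label codes to class names
#'   (see [label_map()]).
#' @param provenance data.frame with one row per segment (record id and
#'   annotation index, or synthetic seed); `NULL` for none.
#' @return an object of class `beat_dataset`.
#' @export
beat_dataset <- function(segments, labels, label_map = lraecg::label_map("mitbih"),
                         provenance = NULL) {
  if (!is.matrix(segments)) segments <- matrix(segments, nrow = length(labels))
  if (nrow(segments) != length(labels)) {
    stop("`segments` rows and `labels` length differ", call. = FALSE)
  }
  labels <- as.integer(labels)
  if (length(labels) && (any(labels < 0) || any(labels > length(label_map) - 1L))) {
    stop("labels out of range for the label map", call. = FALSE)
  }
  structure(
    list(segments = segments, labels = labels, label_map = label_map,
         provenance = provenance),
    class = "beat_dataset"
  )
}

#' @export
print.beat_dataset <- function(x, ...) {
  cat(sprintf("<beat_dataset>  %d segments x %d samples\n",
              nrow(x$segments), ncol(x$segments)))
  if (nrow(x$segments)) {
    tab <- table(factor(x$labels, levels = as.integer(names(x$label_map)),
                        labels = x$label_map))
    cat("  classes: ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Z-score standardization
#'
#' Standardizes a signal to zero mean and unit variance,
#' \eqn{z = (x - \mu)/\sigma}, with \eqn{\mu} the mean and \eqn{\sigma} the
#' population standard deviation of the record (divisor `n`, not `n - 1`;
#' set `sample_sd = TRUE` for the `n - 1` divisor).
#' A constant record has \eqn{\sigma = 0}; it is returned as all zeros with a
#' warning rather than dividing by zero.
#'
#' @param x finite numeric vector, length >= 1.
#' @param sample_sd use the sample (n-1) standard deviation instead of the
#'   population one.
#' @return numeric vector of the same length.
#' @examples
#' zscore(c(1, 2, 3))  # -1.2247, 0, 1.2247
#' @export
zscore <- function(x, sample_sd = FALSE) {
  if (!is.numeric(x) || length(x) < 1L) {
    stop("`x` must be a numeric vector of length >= 1", call. = FALSE)
  }
  if (!all(is.finite(x))) stop("`x` contains non-finite values", call. = FALSE)
  mu <- mean(x)
  v <- mean((x - mu)^2)
  if (sample_sd && length(x) > 1L) v <- v * length(x) / (length(x) - 1L)
  if (v == 0) {
    warning("constant signal: standard deviation is zero, returning zeros")
    return(rep(0, length(x)))
  }
  (x - mu) / sqrt(v)
}

#' Segment an annotated record into fixed-length beats
#'
#' Z-scores the selected lead once per record, then extracts a
#' `window["pre"] + window["post"]`-sample slice around every annotation whose
#' symbol belongs to the target classes and whose window
#' `[index - pre, index + post)` lies fully inside the record. Out-of-window
#' beats are dropped and counted; non-target symbols are excluded.
#'
#' @param record an [ecg_record()].
#' @param annotations a [beat_annotations()] data.frame, sorted by index.
#' @param window named integer vector `c(pre = , post = )`; the segment length
#'   is `pre + post` (default 100 + 150 = 250 samples, about 0.69 s at 360 Hz).
#' @param lead which lead to use (default first).
#' @param target_symbols symbols kept for classification, in label order.
#' @return a [beat_dataset()]; the number of boundary-dropped beats is
#'   attached as attribute `"dropped"`.
#' @export
segment_beats <- function(record, annotations,
                          window = c(pre = 100L, post = 150L),
                          lead = 1L,
                          target_symbols = c("N", "L", "R", "V")) {
  stopifnot(inherits(record, "ecg_record"))
  pre <- as.integer(window[["pre"]]); post <- as.integer(window[["post"]])
  if (pre < 0L || post < 1L) stop("invalid window", call. = FALSE)
  d <- pre + post
  x <- zscore(record$signal[, lead])
  n_samp <- length(x)
  lmap <- stats::setNames(target_symbols, as.character(seq_along(target_symbols) - 1L))

  keep_symbol <- annotations$symbol %in% target_symbols
  ann <- annotations[keep_symbol, , drop = FALSE]
  in_bounds <- ann$sample_index - pre >= 0L & ann$sample_index + post <= n_samp
  dropped <- sum(!in_bounds)
  ann <- ann[in_bounds, , drop = FALSE]

  if (nrow(ann) == 0L) {
    message(sprintf(
      "record '%s': no usable beats (%d non-target symbols, %d boundary drops)",
      record$record_id, sum(!keep_symbol), dropped))
    out <- beat_dataset(matrix(numeric(0), 0L, d), integer(0), lmap,
                        provenance = data.frame(record_id = character(0),
                                                sample_index = integer(0)))
    attr(out, "dropped") <- dropped
    return(out)
  }

  segs <- t(vapply(ann$sample_index,
                   function(i) x[(i - pre + 1L):(i + post)],  # 0-based -> R 1-based
                   numeric(d)))
  labels <- match(ann$symbol, target_symbols) - 1L
  out <- beat_dataset(segs, labels, lmap,
                      provenance = data.frame(record_id = record$record_id,
                                              sample_index = ann$sample_index))
  attr(out, "dropped") <- dropped
  out
}

#' Prepare a variable-length record as one fixed-length vector
#'
#' For single-label rhythm records (PhysioNet-2017-style): Z-scores the lead,
#' then truncates from the start if longer than `target_len`, or zero-pads at
#' the end if shorter. Z-score statistics are computed on the original signal,
#' before any padding.
#'
#' @param record an [ecg_record()].
#' @param target_len target length in samples (default 9000 = 30 s at 300 Hz).
#' @param lead which lead to use.
#' @return numeric vector of length `target_len`.
#' @export
prepare_fixed_length <- function(record, target_len = 9000L, lead = 1L) {
  stopifnot(inherits(record, "ecg_record"))
  if (target_len < 1L) stop("`target_len` must be >= 1", call. = FALSE)
  x <- record$signal[, lead]
  if (length(x) == 0L) stop("empty signal", call. = FALSE)
  z <- zscore(x)
  if (length(z) >= target_len) z[seq_len(target_len)]
  else c(z, rep(0, target_len - length(z)))
}
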