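# The csv_fixture dialect: a plain-text record format shared by the synthetic
# generator and the loader so every pipeline stage is testable offline.
#
#   <id>.csv       "# lraecg csv_fixture v1" header comment, "# fs=<Hz>" and
#                  "# record_id=<id>" comments, then CSV with columns
#                  sample_index, <lead name>...
#   <id>.ann.csv   same header comment, then CSV with columns
#                  sample_index, symbol (0-based indices).

FIXTURE_MAGIC <- "# lraecg csv_fixture v1"

#' Load an ECG record with annotations
#'
#' Reads a record plus its beat annotations from disk. `path` is the record
#' stem: for the `csv_fixture` dialect the files `<path>.csv` and
#' `<path>.ann.csv` are read; for the `wfdb` dialect the standard
#' `<path>.hea` / `<path>.dat` / `<path>.atr` triple is parsed
#' (signal formats 212 and 16; see [read_wfdb_record()]).
#' All returned indices are 0-based.
#'
#' @param path record stem (file path without extension).
#' @param dialect `"csv_fixture"` or `"wfdb"`.
#' @return list with elements `record` (an [ecg_record()]) and `annotations`
#'   (a [beat_annotations()] data.frame).
#' @export
load_record <- function(path, dialect = c("csv_fixture", "wfdb")) {
  dialect <- match.arg(dialect)
  switch(dialect,
         csv_fixture = load_csv_fixture(path),
         wfdb = read_wfdb_record(path))
}

load_csv_fixture <- function(path) {
  sig_file <- paste0(path, ".csv")
  ann_file <- paste0(path, ".ann.csv")
  for (f in c(sig_file, ann_file)) {
    if (!file.exists(f)) {
      stop(sprintf("missing fixture member: '%s'", f), call. = FALSE)
    }
  }
  header <- readLines(sig_file, n = 10L)
  if (!identical(header[1L], FIXTURE_MAGIC)) {
    stop(sprintf("'%s' is not a csv_fixture file (bad header comment)", sig_file),
         call. = FALSE)
  }
  meta <- grep("^# [a-z_]+=", header, value = TRUE)
  kv <- sub("^# ", "", meta)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[a-z_]+=", "", kv)
  fs <- as.numeric(vals[match("fs", keys)])
  record_id <- vals[match("record_id", keys)]
  if (is.na(fs)) stop(sprintf("'%s': missing fs= header", sig_file), call. = FALSE)
  if (is.na(record_id)) record_id <- basename(path)

  sig <- utils::read.csv(sig_file, comment.char = "#")
  if (names(sig)[1L] != "sample_index") {
    stop(sprintf("'%s': first column must be sample_index", sig_file), call. = FALSE)
  }
  leads <- as.matrix(sig[, -1L, drop = FALSE])
  rec <- ecg_record(leads, fs = fs, lead_names = colnames(leads),
                    record_id = record_id)

  ann_lines <- readLines(ann_file)
  if (!identical(ann_lines[1L], FIXTURE_MAGIC)) {
    stop(sprintf("'%s' is not a csv_fixture annotation file", ann_file),
         call. = FALSE)
  }
  ann <- utils::read.csv(ann_file, comment.char = "#",
                         colClasses = c("integer", "character"))
  if (nrow(ann)) {
    bad <- which(is.na(ann$symbol) | !grepl("^[^[:space:]]+$", ann$symbol))
    if (length(bad)) {
      # +1 comment line, +1 header line before the first data row
      line_no <- bad[1L] + sum(startsWith(ann_lines, "#")) + 1L
      stop(sprintf("'%s' line %d: malformed annotation symbol", ann_file, line_no),
           call. = FALSE)
    }
  }
  list(record = rec, annotations = beat_annotations(ann$sample_index, ann$symbol))
}

#' Write a record or beat dataset as plain-text fixtures
#'
#' For an [ecg_record()], writes the `csv_fixture` dialect files
#' `<path>.csv` and `<path>.ann.csv` that [load_record()] reads back; the
#' annotations default to the R-peak indices the synthetic generator stored on
#' the record. For a [beat_dataset()], writes `<path>.segments.csv` (one row
#' per beat) and `<path>.labels.csv` (label + provenance).
#'
#' @param x an `ecg_record` or `beat_dataset`.
#' @param path output stem (extensions are appended).
#' @param annotations optional [beat_annotations()] overriding the record's own.
#' @return invisibly, the character vector of files written.
#' @export
write_fixture <- function(x, path, annotations = NULL) {
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop(sprintf("output directory '%s' does not exist", dir), call. = FALSE)
  }
  if (inherits(x, "ecg_record")) {
    if (is.null(annotations)) {
      annotations <- attr(x, "annotations")
      if (is.null(annotations)) annotations <- beat_annotations(integer(0), character(0))
    }
    sig_file <- paste0(path, ".csv")
    ann_file <- paste0(path, ".ann.csv")
    n <- nrow(x$signal)
    sig <- data.frame(sample_index = seq_len(n) - 1L, x$signal)
    names(sig) <- c("sample_index", x$lead_names)
    writeLines(c(FIXTURE_MAGIC,
                 sprintf("# fs=%.10g", x$fs),
                 sprintf("# record_id=%s", x$record_id)), sig_file)
    suppressWarnings(utils::write.table(sig, sig_file, sep = ",", row.names = FALSE,
                                        col.names = TRUE, quote = FALSE, append = TRUE))
    writeLines(FIXTURE_MAGIC, ann_file)
    suppressWarnings(utils::write.table(annotations, ann_file, sep = ",",
                                        row.names = FALSE, col.names = TRUE,
                                        quote = FALSE, append = TRUE))
    return(invisible(c(sig_file, ann_file)))
  }
  if (inherits(x, "beat_dataset")) {
    seg_file <- paste0(path, ".segments.csv")
    lab_file <- paste0(path, ".labels.csv")
    utils::write.table(x$segments, seg_file, sep = ",",
                       row.names = FALSE, col.names = FALSE)
    lab <- data.frame(label = x$labels)
    if (!is.null(x$provenance)) lab <- cbind(lab, x$provenance)
    utils::write.csv(lab, lab_file, row.names = FALSE)
    return(invisible(c(seg_file, lab_file)))
  }
  stop("`x` must be an ecg_record or a beat_dataset", call. = FALSE)
}
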