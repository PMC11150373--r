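# Minimal read-only WFDB support: plain-text .hea headers, format 212 and
# format 16 .dat signals, MIT-format .atr annotations. Covers the record
# layout of MIT-BIH-style archives (multi-signal frames, ADC gain/baseline
# scaling to mV); written against the published format description since no
# WFDB reader package is available in R.

# MIT annotation type codes -> display symbols (common subset).
WFDB_ANN_SYMBOLS <- c(
  "N", "L", "R", "a", "V", "F", "J", "A", "S", "E", "j", "/", "Q", "~",
  "", "|", "", "s", "T", "*", "D", "\"", "=", "p", "B", "^", "t", "+",
  "u", "?", "!", "[", "]", "e", "n", "@", "x", "f", "(", ")", "r"
)

wfdb_symbol <- function(code) {
  ifelse(code >= 1L & code <= length(WFDB_ANN_SYMBOLS),
         WFDB_ANN_SYMBOLS[code], "?")
}

parse_hea <- function(hea_file) {
  lines <- readLines(hea_file)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  rec_fields <- strsplit(trimws(lines[1L]), "[[:space:]]+")[[1L]]
  if (length(rec_fields) < 2L) {
    stop(sprintf("'%s': malformed record line", hea_file), call. = FALSE)
  }
  record_id <- sub("/.*$", "", rec_fields[1L])
  nsig <- as.integer(rec_fields[2L])
  fs <- if (length(rec_fields) >= 3L) as.numeric(sub("/.*$", "", rec_fields[3L])) else 250
  nsamp <- if (length(rec_fields) >= 4L) as.integer(rec_fields[4L]) else NA_integer_
  sig <- lapply(seq_len(nsig), function(i) {
    f <- strsplit(trimws(lines[1L + i]), "[[:space:]]+")[[1L]]
    fmt <- as.integer(sub("[x:+].*$", "", f[2L]))
    gain_field <- if (length(f) >= 3L) f[3L] else "200"
    gain <- as.numeric(sub("[(/].*$", "", gain_field))
    if (is.na(gain) || gain == 0) gain <- 200
    baseline <- if (grepl("\\(", gain_field)) {
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_field))
    } else NA_real_
    adczero <- if (length(f) >= 5L) as.numeric(f[5L]) else 0
    desc <- if (length(f) >= 9L) paste(f[9:length(f)], collapse = " ") else
      sprintf("sig%d", i - 1L)
    list(file = f[1L], fmt = fmt, gain = gain,
         baseline = if (is.na(baseline)) adczero else baseline, desc = desc)
  })
  list(record_id = record_id, nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

read_dat_212 <- function(raw, n_values) {
  n_pairs <- ceiling(n_values / 2)
  raw <- as.integer(raw[seq_len(3L * n_pairs)])
  b1 <- raw[seq(1L, by = 3L, length.out = n_pairs)]
  b2 <- raw[seq(2L, by = 3L, length.out = n_pairs)]
  b3 <- raw[seq(3L, by = 3L, length.out = n_pairs)]
  s1 <- b1 + bitwShiftL(bitwAnd(b2, 0x0FL), 8L)
  s2 <- b3 + bitwShiftL(bitwShiftR(b2, 4L), 8L)
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)  # 12-bit two's complement
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  out <- numeric(2L * n_pairs)
  out[c(TRUE, FALSE)] <- s1
  out[c(FALSE, TRUE)] <- s2
  out[seq_len(n_values)]
}

#' Read a WFDB record (header, signal, annotations)
#'
#' Parses `<path>.hea`, `<path>.dat` (signal formats 212 and 16) and, when
#' present, `<path>.atr` (MIT annotation format). ADC units are converted to
#' mV via each signal's gain and baseline. Annotation sample indices are
#' returned 0-based.
#'
#' @param path record stem (path without extension).
#' @return list with `record` (an [ecg_record()]) and `annotations`
#'   (a [beat_annotations()] data.frame, empty if no `.atr` member exists).
#' @export
read_wfdb_record <- function(path) {
  hea_file <- paste0(path, ".hea")
  if (!file.exists(hea_file)) {
    stop(sprintf("missing WFDB member: '%s'", hea_file), call. = FALSE)
  }
  hdr <- parse_hea(hea_file)
  dat_file <- file.path(dirname(path), hdr$signals[[1L]]$file)
  if (!file.exists(dat_file)) {
    stop(sprintf("missing WFDB member: '%s'", dat_file), call. = FALSE)
  }
  fmt <- hdr$signals[[1L]]$fmt
  raw <- readBin(dat_file, "raw", n = file.size(dat_file))
  nsig <- hdr$nsig
  adc <- switch(as.character(fmt),
    "212" = {
      n_values <- if (is.na(hdr$nsamp)) (length(raw) * 2L) %/% 3L else
        hdr$nsamp * nsig
      read_dat_212(raw, n_values)
    },
    "16" = {
      n_values <- if (is.na(hdr$nsamp)) length(raw) %/% 2L else hdr$nsamp * nsig
      readBin(raw, "integer", n = n_values, size = 2L, signed = TRUE,
              endian = "little")
    },
    stop(sprintf("unsupported WFDB signal format %d (formats 212 and 16 are supported)",
                 fmt), call. = FALSE))
  nsamp <- length(adc) %/% nsig
  sig <- matrix(adc[seq_len(nsamp * nsig)], ncol = nsig, byrow = TRUE)
  for (j in seq_len(nsig)) {
    sig[, j] <- (sig[, j] - hdr$signals[[j]]$baseline) / hdr$signals[[j]]$gain
  }
  rec <- ecg_record(sig, fs = hdr$fs,
                    lead_names = vapply(hdr$signals, `[[`, "", "desc"),
                    record_id = hdr$record_id)

  atr_file <- paste0(path, ".atr")
  ann <- if (file.exists(atr_file)) read_atr(atr_file) else
    beat_annotations(integer(0), character(0))
  list(record = rec, annotations = ann)
}

# MIT annotation format: stream of 16-bit little-endian words; the high 6
# bits are the type code, the low 10 bits a time increment. Code 59 (SKIP)
# is followed by a 4-byte interval (high word first); codes 60-62
# (NUM/SUB/CHN) and 63 (AUX, with padded payload) carry no time.
read_atr <- function(atr_file) {
  raw <- readBin(atr_file, "raw", n = file.size(atr_file))
  words <- readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L,
                   signed = FALSE, endian = "little")
  time <- 0
  idx <- integer(0); code <- integer(0)
  i <- 1L
  while (i <= length(words)) {
    w <- words[i]
    a <- bitwShiftR(w, 10L)
    interval <- bitwAnd(w, 0x3FFL)
    if (a == 0L && interval == 0L) break
    if (a == 59L) {            # SKIP: long interval in the next two words
      if (i + 2L > length(words)) break
      time <- time + bitwShiftL(words[i + 1L], 16L) + words[i + 2L]
      i <- i + 3L
    } else if (a == 63L) {     # AUX: skip payload, padded to even length
      i <- i + 1L + (interval + interval %% 2L) %/% 2L
    } else if (a >= 60L) {     # NUM/SUB/CHN: field modifiers, no time
      i <- i + 1L
    } else {
      time <- time + interval
      idx <- c(idx, time)
      code <- c(code, a)
      i <- i + 1L
    }
  }
  beat_annotations(idx, wfdb_symbol(code))
}
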