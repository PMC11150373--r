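# Minimal WFDB writer used only to round-trip-test the package's reader.
# Follows the published header, format 212/16 signal and MIT annotation
# layouts for the feature subset the reader supports.

write_wfdb_fixture <- function(dir, id, adc, fs, gain, baseline, fmt = 212L,
                               ann_index = integer(0), ann_code = integer(0)) {
  nsig <- ncol(adc); nsamp <- nrow(adc)
  hea <- c(sprintf("%s %d %g %d", id, nsig, fs, nsamp),
           vapply(seq_len(nsig), function(j) {
             sprintf("%s.dat %d %g(%d)/mV 12 0 0 0 0 lead%d",
                     id, fmt, gain[j], baseline[j], j)
           }, ""))
  writeLines(hea, file.path(dir, paste0(id, ".hea")))

  vals <- as.integer(t(adc))  # frame-interleaved
  if (fmt == 212L) {
    if (length(vals) %% 2L) vals <- c(vals, 0L)
    v <- ifelse(vals < 0L, vals + 4096L, vals)
    s1 <- v[c(TRUE, FALSE)]; s2 <- v[c(FALSE, TRUE)]
    bytes <- as.raw(rbind(bitwAnd(s1, 0xFFL),
                          bitwOr(bitwShiftL(bitwShiftR(s2, 8L), 4L),
                                 bitwShiftR(s1, 8L)),
                          bitwAnd(s2, 0xFFL)))
    writeBin(bytes, file.path(dir, paste0(id, ".dat")))
  } else if (fmt == 16L) {
    writeBin(vals, file.path(dir, paste0(id, ".dat")), size = 2L,
             endian = "little")
  } else stop("unsupported fixture format")

  if (length(ann_index)) {
    words <- integer(0)
    prev <- 0L
    for (i in seq_along(ann_index)) {
      delta <- ann_index[i] - prev
      if (delta >= 1024L) {  # SKIP: code 59, then 4-byte interval, then 0-delta
        words <- c(words, bitwShiftL(59L, 10L),
                   bitwShiftR(delta, 16L), bitwAnd(delta, 0xFFFFL),
                   bitwShiftL(ann_code[i], 10L))
      } else {
        words <- c(words, bitwOr(bitwShiftL(ann_code[i], 10L), delta))
      }
      prev <- ann_index[i]
    }
    words <- c(words, 0L)
    words <- ifelse(words > 32767L, words - 65536L, words)
    writeBin(as.integer(words), file.path(dir, paste0(id, ".atr")),
             size = 2L, endian = "little")
  }
  file.path(dir, id)
}
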