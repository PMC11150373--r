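test_that("zscore standardizes with the population standard deviation", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(round(zscore(c(1, 2, 3)), 4L), c(-1.2247, 0, 1.2247))
  # sample-sd variant is switchable
  expect_equal(zscore(c(1, 2, 3), sample_sd = TRUE), c(-1, 0, 1), tolerance = 1e-12)
})

test_that("zscore of a constant record warns and returns zeros", {
  expect_warning(z <- zscore(c(5, 5, 5)), "constant")
  expect_equal(z, c(0, 0, 0))
})

test_that("zscore matches a two-pass oracle and is idempotent", {
  set.seed(19)
  x <- rnorm(1000L, mean = 3, sd = 7)
  z <- zscore(x)
  mu <- sum(x) / length(x)
  sd_pop <- sqrt(sum((x - mu)^2) / length(x))
  expect_equal(z, (x - mu) / sd_pop, tolerance = 1e-12)
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sqrt(mean(z^2)) - 1), 1e-9)
  expect_equal(zscore(z), z, tolerance = 1e-9)
})

make_record <- function(n = 1000L, fs = 360) {
  set.seed(23)
  ecg_record(sin(seq_len(n) / 10) + rnorm(n, sd = 0.1), fs = fs,
             record_id = "fixture")
}

test_that("segment_beats drops boundary windows and counts them", {
  rec <- make_record()
  ann <- beat_annotations(c(10L, 300L, 700L), c("N", "N", "V"))
  ds <- segment_beats(rec, ann, window = c(pre = 100L, post = 150L))
  expect_identical(nrow(ds$segments), 2L)
  expect_identical(ncol(ds$segments), 250L)
  expect_identical(attr(ds, "dropped"), 1L)
  expect_identical(ds$labels, c(0L, 3L))
})

test_that("segment_beats excludes non-target symbols", {
  rec <- make_record()
  ann <- beat_annotations(c(200L, 300L, 400L, 500L, 600L),
                          c("N", "A", "L", "R", "V"))
  ds <- segment_beats(rec, ann, window = c(pre = 100L, post = 150L))
  expect_identical(nrow(ds$segments), 4L)
  expect_identical(sort(ds$labels), 0:3)
  expect_identical(attr(ds, "dropped"), 0L)
})

test_that("segment count equals target annotations minus boundary drops", {
  rec <- make_record(2000L)
  set.seed(3)
  idx <- sort(sample(0:1999, 25L))
  sym <- sample(c("N", "L", "R", "V", "Q"), 25L, replace = TRUE)
  ann <- beat_annotations(idx, sym)
  ds <- segment_beats(rec, ann, window = c(pre = 100L, post = 150L))
  target <- sym %in% c("N", "L", "R", "V")
  in_bounds <- idx - 100L >= 0L & idx + 150L <= 2000L
  expect_identical(nrow(ds$segments), sum(target & in_bounds))
  expect_identical(attr(ds, "dropped"), sum(target & !in_bounds))
})

test_that("segments are cut from the record-level Z-scored lead", {
  rec <- make_record()
  ann <- beat_annotations(500L, "N")
  ds <- segment_beats(rec, ann, window = c(pre = 100L, post = 150L))
  z <- zscore(rec$signal[, 1L])
  expect_equal(ds$segments[1L, ], z[401:650], ignore_attr = TRUE)
})

test_that("an empty usable annotation set yields an empty dataset, not an error", {
  rec <- make_record()
  ann <- beat_annotations(c(500L), c("Q"))
  expect_message(ds <- segment_beats(rec, ann, window = c(pre = 100L, post = 150L)),
                 "no usable beats")
  expect_identical(nrow(ds$segments), 0L)
  expect_identical(ncol(ds$segments), 250L)
})

test_that("prepare_fixed_length truncates, pads, and Z-scores before padding", {
  r9000 <- ecg_record(rnorm(9000L), fs = 300)
  expect_length(prepare_fixed_length(r9000, 9000L), 9000L)
  expect_equal(prepare_fixed_length(r9000, 9000L), zscore(r9000$signal[, 1L]),
               ignore_attr = TRUE)
  r12000 <- ecg_record(rnorm(12000L), fs = 300)
  out <- prepare_fixed_length(r12000, 9000L)
  expect_equal(out, zscore(r12000$signal[, 1L])[1:9000], ignore_attr = TRUE)
  set.seed(6)
  r6000 <- ecg_record(rnorm(6000L, mean = 2), fs = 300)
  out <- prepare_fixed_length(r6000, 9000L)
  expect_length(out, 9000L)
  expect_true(all(out[6001:9000] == 0))
  # statistics from the unpadded signal: the first 6000 samples are exactly
  # the Z-scored record, so their mean is 0 (padding did not shift it)
  expect_lt(abs(mean(out[1:6000])), 1e-9)
  expect_equal(out[1:6000], zscore(r6000$signal[, 1L]), ignore_attr = TRUE)
})

test_that("csv fixtures round-trip through write_fixture and load_record", {
  dir <- withr::local_tempdir()
  rec <- synth_rhythm_record(default_rhythm_specs()$N, seed = 4L)
  stem <- file.path(dir, "rt")
  write_fixture(rec, stem)
  back <- load_record(stem, dialect = "csv_fixture")
  expect_equal(back$record$signal, rec$signal, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(back$record$fs, rec$fs)
  expect_identical(back$annotations, attr(rec, "annotations"))
})

test_that("loader surfaces missing members and malformed symbols", {
  dir <- withr::local_tempdir()
  expect_error(load_record(file.path(dir, "nope"), "csv_fixture"), "missing")
  rec <- ecg_record(rnorm(100L), fs = 360)
  stem <- file.path(dir, "bad")
  write_fixture(rec, stem, annotations = beat_annotations(50L, "N"))
  ann_lines <- readLines(paste0(stem, ".ann.csv"))
  ann_lines[3L] <- "60, "
  writeLines(ann_lines, paste0(stem, ".ann.csv"))
  expect_error(load_record(stem, "csv_fixture"), "line 3")
})

test_that("a last-sample annotation is loadable but dropped at segmentation", {
  dir <- withr::local_tempdir()
  rec <- ecg_record(rnorm(500L), fs = 360)
  stem <- file.path(dir, "edge")
  write_fixture(rec, stem, annotations = beat_annotations(c(250L, 499L), c("N", "N")))
  back <- load_record(stem, "csv_fixture")
  expect_identical(back$annotations$sample_index, c(250L, 499L))
  ds <- segment_beats(back$record, back$annotations,
                      window = c(pre = 100L, post = 150L))
  expect_identical(nrow(ds$segments), 1L)
  expect_identical(attr(ds, "dropped"), 1L)
})

test_that("beat dataset export writes segments and labels side by side", {
  dir <- withr::local_tempdir()
  ds <- synth_beat_dataset(3L, d = 50L, seed = 2L, pre = 20L)
  files <- write_fixture(ds, file.path(dir, "ds"))
  segs <- as.matrix(utils::read.csv(files[1L], header = FALSE))
  labs <- utils::read.csv(files[2L])
  expect_equal(unname(segs), unname(ds$segments), tolerance = 1e-10)
  expect_identical(labs$label, ds$labels)
})
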