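test_that("EDF round-trip preserves labels, rates, durations and values", {
  rec <- make_test_recording()
  path <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec, path)
  back <- read_recording(path, list(flow = "Flow", thoracic = "Thorax",
                                    spo2 = "SpO2"))
  for (ch in c("flow", "thoracic", "spo2")) {
    expect_identical(back[[ch]]$label, rec[[ch]]$label)
    expect_equal(back[[ch]]$rate, rec[[ch]]$rate)
    expect_identical(length(back[[ch]]$values), length(rec[[ch]]$values))
    # one 16-bit quantization step of the channel's physical range
    rng <- diff(range(rec[[ch]]$values))
    expect_lt(max(abs(back[[ch]]$values - rec[[ch]]$values)),
              max(rng, 2) / 65535 + 1e-12)
  }
  expect_equal(back$total_duration, rec$total_duration)
})

test_that("EDF header fields agree with a raw byte-level dump of the file", {
  rec <- make_test_recording()
  path <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec, path)
  # independent dump: read the fixed-offset ASCII fields directly
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  expect_identical(trimws(substr(hdr, 1, 8)), "0")
  n_records <- as.integer(trimws(substr(hdr, 237, 244)))
  rec_dur <- as.numeric(trimws(substr(hdr, 245, 252)))
  n_sig <- as.integer(trimws(substr(hdr, 253, 256)))
  expect_identical(n_sig, 3L)
  expect_equal(n_records * rec_dur, 60)
  labels <- vapply(0:2, function(i) {
    trimws(readChar(con, 16, useBytes = TRUE))
  }, "")
  expect_identical(labels, c("Flow", "Thorax", "SpO2"))
  # samples-per-record block sits after 7 more 3-signal field blocks
  seek(con, 256 + 3 * (16 + 80 + 8 + 8 + 8 + 8 + 8 + 80))
  spr <- vapply(0:2, function(i) {
    as.integer(trimws(readChar(con, 8, useBytes = TRUE)))
  }, 0L)
  expect_identical(spr / rec_dur, c(200, 10, 1))  # native rates preserved
})

test_that("reading a recording with a missing mapped channel names it", {
  rec <- make_test_recording()
  path <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec, path)
  expect_error(
    read_recording(path, list(flow = "Flow", thoracic = "Abdomen",
                              spo2 = "SpO2")),
    "Abdomen")
  expect_error(read_recording(file.path(tempdir(), "nope.edf")),
               "not found")
})

test_that("writing rejects out-of-range SpO2 at construction", {
  expect_error(
    sleep_recording(series(sin(1:600), 10, "Flow"),
                    series(sin(1:600), 10, "Thorax"),
                    series(c(rep(95, 59), 101), 1, "SpO2")),
    "\\[0, 100\\]")
})

test_that("extract_window slices by exact index arithmetic", {
  s <- series(seq_len(7200), rate = 1, label = "x")  # 2 h at 1 Hz
  w <- extract_window(s, start = 3600, duration = 1200)
  expect_identical(length(w$values), 1200L)
  expect_identical(w$values[1], 3601)                # 0-based index 3600
  expect_identical(extract_window(s, 0, 7200)$values, s$values)
  # 20-min request on an 18-min series reports the available duration
  short <- series(seq_len(1080), rate = 1)
  expect_error(extract_window(short, 0, 1200), "1080")
})

test_that("nested window extraction composes", {
  s <- series(stats::rnorm(5000), rate = 4, label = "x")
  inner <- extract_window(extract_window(s, 100, 900), 250, 300)
  direct <- extract_window(s, 350, 300)
  expect_identical(inner$values, direct$values)
  expect_equal(inner$rate, direct$rate)
})

test_that("decimation keeps every k-th value and divides the rate", {
  s <- series(c(1, 2, 3, 4, 5, 6, 7, 8), rate = 8)
  d <- decimate_keep_kth(s, 4)
  expect_identical(d$values, c(1, 5))
  expect_equal(d$rate, 2)
  expect_identical(decimate_keep_kth(s, 1)$values, s$values)
  expect_error(decimate_keep_kth(s, 0), "positive integer")
})

test_that("decimation composes and reproduces the f2 sample-count arithmetic", {
  s <- series(stats::rnorm(2400), rate = 8)
  d12 <- decimate_keep_kth(decimate_keep_kth(s, 2), 3)
  d6 <- decimate_keep_kth(s, 6)
  expect_identical(d12$values, d6$values)
  # full-night flow decimated by 4 then windowed 80 min has the same count
  # as a 20-min undecimated window (240000 samples at 200 Hz)
  full <- series(numeric(200 * 6 * 3600), rate = 200)
  a <- extract_window(decimate_keep_kth(full, 4), 3600, 80 * 60)
  b <- extract_window(full, 3600, 20 * 60)
  expect_identical(length(a$values), 240000L)
  expect_identical(length(a$values), length(b$values))
})

test_that("block-mean resampling averages within blocks", {
  s <- series(c(1, 3, 2, 4, 10, 20), rate = 2)
  r <- resample_mean(s, 1)
  expect_identical(r$values, c(2, 3, 15))
  expect_equal(r$rate, 1)
  expect_error(resample_mean(s, 0.3), "whole number")
})
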