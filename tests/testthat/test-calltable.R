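# calltable_io: containers, dialects, round-trips, motion series.

test_that("native round-trip is lossless and writes are byte-identical", {
  set.seed(1)
  n <- 100
  x <- call_table(onset = sort(runif(n, 0, 3000)),
                  duration = runif(n, 0.02, 1.5),
                  peak_frequency = runif(n, 19000, 80000),
                  mean_power = rnorm(n, -50, 5),
                  call_type = sample(c("long22", "fifty", "fortyfour"), n, TRUE))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_call_table(x, f1)
  write_call_table(x, f2)
  expect_identical(readLines(f1), readLines(f2))
  y <- read_call_table(f1)
  for (col in c("onset", "duration", "peak_frequency", "mean_power")) {
    expect_equal(y[[col]], x[[col]], tolerance = 1e-9)
  }
  expect_identical(y$call_type, x$call_type)
  expect_identical(y$call_id, x$call_id)
})

test_that("empty and single-record tables write and read back", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_call_table(call_table(), f)
  expect_length(readLines(f), 1)  # header only
  expect_equal(nrow(read_call_table(f)), 0)
  one <- call_table(onset = 1, duration = 0.5, peak_frequency = 42400)
  write_call_table(one, f)
  back <- read_call_table(f)
  expect_equal(back$peak_frequency, 42400)
  expect_equal(back$duration, 0.5)
})

test_that("avisoft_like dialect converts ms/kHz to s/Hz", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("label\tstart_time_s\tduration_ms\tpeak_freq_khz\tmean_power_db",
               "v1\t12.5\t250\t42.4\t-51"), f)
  x <- read_call_table(f, dialect = "avisoft_like")
  expect_equal(x$duration, 0.250)
  expect_equal(x$peak_frequency, 42400)
  expect_equal(x$onset, 12.5)
})

test_that("deepsqueak_like dialect converts kHz and keeps extras", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,begin_time_s,call_length_s,principal_frequency_khz,score",
               "7,3.2,0.4,24.4,0.91"), f)
  x <- read_call_table(f, dialect = "deepsqueak_like")
  expect_equal(x$peak_frequency, 24400)
  expect_equal(x$score, 0.91)  # unknown column preserved as annotation
})

test_that("unsorted rows come back onset-sorted, stable for ties", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("call_id,rat_id,session_id,onset_s,duration_s,peak_freq_hz,mean_power_db,call_type,subtype",
               "a,r,s,5.0,0.1,25000,,unknown,",
               "b,r,s,1.0,0.1,25000,,unknown,",
               "c,r,s,5.0,0.2,25000,,unknown,",
               "d,r,s,0.5,0.1,25000,,unknown,",
               "e,r,s,3.0,0.1,25000,,unknown,"), f)
  x <- read_call_table(f)
  # hand-sorted: d(0.5) b(1.0) e(3.0) a(5.0) c(5.0) - a before c (file order)
  expect_identical(x$call_id, c("d", "b", "e", "a", "c"))
})

test_that("format and validation errors name the offender", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("call_id,onset_s,peak_freq_hz", "a,1,25000"), f)
  expect_error(read_call_table(f), "duration_s", class = "usv44_format_error")
  writeLines(c("call_id,rat_id,session_id,onset_s,duration_s,peak_freq_hz,mean_power_db,call_type,subtype",
               "a,r,s,1.0,-0.3,25000,,unknown,"), f)
  expect_error(read_call_table(f), "row 1", class = "usv44_validation_error")
  expect_error(read_call_table(withr::local_tempfile()), class = "usv44_io_error")
})

test_that("round-trip property holds for arbitrary valid records", {
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(1:40, 1)
    x <- call_table(onset = sort(runif(n, 0, 100)),
                    duration = runif(n, 0.011, 2),
                    peak_frequency = runif(n, 15000, 90000))
    f <- withr::local_tempfile(fileext = ".csv")
    write_call_table(x, f)
    y <- read_call_table(f)
    expect_equal(y$onset, x$onset, tolerance = 1e-9)
    expect_equal(y$peak_frequency, x$peak_frequency, tolerance = 1e-9)
  }
})

test_that("invariants are enforced by constructors", {
  expect_error(call_table(onset = 1, duration = 0.1, peak_frequency = 130000),
               class = "usv44_validation_error")
  expect_error(call_contour(c(0, 0.1), c(25000)), class = "usv44_validation_error")
  expect_error(call_contour(c(0, 0.1, 0.1), rep(25000, 3)),
               class = "usv44_validation_error")
  expect_error(session_meta(shock_times = c(100, 50)),
               class = "usv44_validation_error")
  expect_error(motion_series(c(1, -2)), class = "usv44_validation_error")
  # subtype only on fortyfour
  expect_error(call_table(onset = 1, duration = 0.4, peak_frequency = 25000,
                          call_type = "long22", subtype = "flat"),
               class = "usv44_validation_error")
})

test_that("motion series round-trips; blank lines are errors with position", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(as.character(rep(0, 300)), f)
  m <- read_motion_series(f, 30)
  expect_length(m$values, 300)
  expect_true(all(m$values == 0))
  writeLines(as.character(rep(c(0, 100), 50)), f)
  expect_equal(read_motion_series(f)$values, rep(c(0, 100), 50))
  writeLines(c("1", "", "3"), f)
  expect_error(read_motion_series(f), "line 2", class = "usv44_format_error")
})

test_that("contours and session meta survive their sidecar formats", {
  ct <- list(a = flat_contour(42000, 0.3), b = step_contour(c(27000, 40000)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_contours(ct, f)
  back <- read_contours(f)
  expect_named(back, c("a", "b"))
  expect_equal(back$a$frequencies, ct$a$frequencies, tolerance = 1e-6)
  meta <- session_meta(shock_times = c(600, 852), session_length = 3120)
  g <- withr::local_tempfile(fileext = ".cfg")
  write_session_meta(meta, g)
  m2 <- read_session_meta(g)
  expect_equal(m2$shock_times, meta$shock_times)
  expect_equal(m2$attenuation_profile, meta$attenuation_profile,
               ignore_attr = TRUE)
})
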