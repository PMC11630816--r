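# behavior: freezing runs, bin linkage, call-nested freezing.

test_that("run-length scoring matches hand computation", {
  p <- freeze_params()  # threshold 18, min 30 frames
  all_still <- motion_series(rep(0, 300))
  expect_equal(sum(score_freezing(all_still, p)), 300)
  # 29 sub-threshold frames flanked by movement: nothing freezes
  m29 <- motion_series(c(rep(50, 10), rep(0, 29), rep(50, 10)))
  expect_equal(sum(score_freezing(m29, p)), 0)
  # runs of 40 and 20: exactly the 40 freeze
  m4020 <- motion_series(c(rep(0, 40), rep(50, 5), rep(0, 20), rep(50, 5)))
  mask <- score_freezing(m4020, p)
  expect_equal(sum(mask), 40)
  expect_true(all(mask[1:40]))
})

test_that("freeze mask is monotone in threshold and min_frames (property)", {
  set.seed(19)
  m <- motion_series(runif(600, 0, 40))
  lo <- score_freezing(m, freeze_params(motion_threshold = 10, min_frames = 10))
  hi <- score_freezing(m, freeze_params(motion_threshold = 25, min_frames = 10))
  expect_true(all(hi[lo]))  # raising threshold never unfreezes
  few <- score_freezing(m, freeze_params(motion_threshold = 18, min_frames = 5))
  many <- score_freezing(m, freeze_params(motion_threshold = 18, min_frames = 20))
  expect_gte(sum(few), sum(many))  # lowering min_frames never loses frames
})

test_that("freezing percentage is window-consistent", {
  mask <- c(rep(TRUE, 60), rep(FALSE, 60))
  expect_equal(freezing_percent(mask, 0, 2, 30), 100)
  expect_equal(freezing_percent(mask, 0, 4, 30), 50)
  # concatenation: union of disjoint windows = frame-weighted mean
  a <- freezing_percent(mask, 0, 1, 30)
  b <- freezing_percent(mask, 1, 4, 30)
  expect_equal(freezing_percent(mask, 0, 4, 30), (a * 30 + b * 90) / 120)
  expect_true(is.nan(freezing_percent(mask, 10, 11, 30)))
})

test_that("bin linkage categorizes 10-s bins per the exclusivity rule", {
  meta <- session_meta(shock_times = c(600), session_length = 700)
  mask <- rep(TRUE, 700 * 30)
  calls <- make_calls(onsets = c(610, 622, 625, 641),
                      durations = c(0.9, 0.9, 0.05, 0.6),
                      freqs = c(25000, 25000, 60000, 42000),
                      types = c("long22", "long22", "fifty", "fortyfour"))
  rep_ <- bin_linkage(calls, mask, meta)
  expect_equal(nrow(rep_), 70)
  expect_equal(rep_$category[rep_$start == 610], "only_long22")
  expect_equal(rep_$category[rep_$start == 620], "mixed")   # long22 + fifty
  expect_equal(rep_$category[rep_$start == 640], "only_fortyfour")
  expect_equal(rep_$category[rep_$start == 650], "no_calls")
  expect_equal(rep_$category[rep_$start == 0], "baseline")
  expect_equal(rep_$category[rep_$start == 290], "baseline")
  # call-free bin between baseline end and first shock: no category
  expect_true(is.na(rep_$category[rep_$start == 300]))
  expect_true(all(rep_$freezing == 100))
  expect_error(bin_linkage(calls, mask[1:100], meta),
               class = "usv44_validation_error")
})

test_that("call-nested windows center within the longer call", {
  motion <- motion_series(rep(0, 300), 30)  # fully frozen
  a <- list(onset = 2.0, duration = 0.3)
  b <- list(onset = 5.0, duration = 0.9)
  res <- call_nested_freezing(a, b, motion, freeze_params(min_frames = 3))
  expect_equal(res$window_length, 0.3)
  expect_equal(res$freezing_a, 100)
  expect_equal(res$freezing_b, 100)
  # equal durations use both full spans
  res2 <- call_nested_freezing(list(onset = 1, duration = 0.5),
                               list(onset = 3, duration = 0.5), motion,
                               freeze_params(min_frames = 5))
  expect_equal(res2$window_length, 0.5)
  expect_error(call_nested_freezing(list(onset = 1, duration = 0.05), b,
                                    motion, freeze_params(min_frames = 3)),
               class = "usv44_validation_error")
})

test_that("reduced min_frames picks up freezing inside short windows", {
  # 12 frozen frames centered under a 0.4 s call: invisible at 30 frames,
  # counted at 3 frames
  vals <- rep(50, 300); vals[121:132] <- 0
  motion <- motion_series(vals, 30)
  call <- list(onset = 4.0, duration = 0.4)
  other <- list(onset = 8.0, duration = 0.4)
  res3 <- call_nested_freezing(call, other, motion, freeze_params(min_frames = 3))
  expect_gt(res3$freezing_a, 0)
  res30 <- score_freezing(motion, freeze_params(min_frames = 30))
  expect_equal(sum(res30), 0)
})

test_that("synthetic cohort freezing reproduces the planted ordering", {
  cfg <- small_cohort_config(n_rats = 3, seed = 41)
  coh <- generate_cohort(cfg)
  reports <- lapply(coh$sessions, function(s) {
    typed <- classify_table(s$calls)$records
    mask <- score_freezing(s$motion, freeze_params())
    bin_linkage(typed, mask, s$meta)
  })
  summ <- bin_summary(do.call(rbind, reports))
  get <- function(cat) summ$mean_freezing[summ$category == cat]
  expect_gt(get("only_fortyfour"), get("no_calls"))
  expect_gt(get("no_calls"), get("baseline"))
})
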