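# subtypes: element segmentation, affix trimming, categorization, ratios.

test_that("segmentation places boundaries at instantaneous jumps only", {
  expect_equal(nrow(segment_elements(flat_contour(42400, jitter = 500))), 1)
  two <- segment_elements(step_contour(c(29000, 44000), duration = 0.6))
  expect_equal(nrow(two), 2)
  expect_equal(two$median_frequency, c(29000, 44000), tolerance = 1e-6)
  expect_equal(two$start[2], two$end[1])  # elements tile the contour
  # jitter below threshold never splits
  expect_equal(nrow(segment_elements(flat_contour(40000, jitter = 1500))), 1)
  # slow drift across > threshold total is not an instantaneous jump
  tt <- seq(0, 0.5, 0.005)
  drift <- call_contour(tt, 24500 + 8000 * tt)
  expect_equal(nrow(segment_elements(drift)), 1)
  # a jump across a long silent gap (> max_jump_gap) does not split
  sparse <- call_contour(c(0, 0.005, 0.05, 0.055), c(29000, 29000, 44000, 44000))
  expect_equal(nrow(segment_elements(sparse)), 1)
})

test_that("affix rule drops only sub-1/5th end fragments, once per end", {
  el <- function(durs, freqs = seq(30000, by = 5000, length.out = length(durs))) {
    starts <- cumsum(c(0, durs[-length(durs)]))
    data.frame(start = starts, end = starts + durs, median_frequency = freqs)
  }
  expect_equal(nrow(trim_affixes(el(c(0.05, 0.50)))), 1)   # prefix dropped
  expect_equal(nrow(trim_affixes(el(c(0.20, 0.50)))), 2)   # kept (0.20 >= 0.10)
  expect_equal(nrow(trim_affixes(el(c(0.50)))), 1)         # single unchanged
  tr <- trim_affixes(el(c(0.05, 0.50, 0.05)))              # both ends dropped
  expect_equal(nrow(tr), 1)
  expect_equal(nrow(attr(tr, "affixes")), 2)
  # applied once per end: middle short elements are never trimmed
  expect_equal(nrow(trim_affixes(el(c(0.3, 0.02, 0.3)))), 3)
})

test_that("categorization implements the five-subtype taxonomy", {
  el <- function(freqs) data.frame(start = seq_along(freqs) - 1,
                                   end = seq_along(freqs),
                                   median_frequency = freqs)
  expect_equal(categorize_subtype(el(42400)), "flat")
  expect_equal(categorize_subtype(el(c(27000, 39500))), "step_up")
  expect_equal(categorize_subtype(el(c(52200, 33000))), "step_down")
  expect_equal(categorize_subtype(el(c(44000, 30000, 44500))), "insert")
  expect_equal(categorize_subtype(el(c(40000, 30000, 41000, 29000, 40000))),
               "complex")
  expect_error(categorize_subtype(el(c(44000, 44000, 30000))),
               class = "usv44_internal_error")
})

test_that("subtype pipeline is deterministic and shift-invariant", {
  ct <- step_contour(c(28000, 42000), fracs = c(0.4, 0.6), duration = 0.62)
  a <- assign_subtype(ct)
  shifted <- call_contour(ct$times, ct$frequencies)  # times are call-relative
  expect_equal(assign_subtype(shifted)$subtype, a$subtype)
  expect_equal(a$subtype, "step_up")
  expect_equal(a$n_elements, 2)
})

test_that("element and cohort frequency ratios behave", {
  el2 <- data.frame(start = c(0, 0.3), end = c(0.3, 0.6),
                    median_frequency = c(29400, 44100))
  expect_equal(element_ratio(el2), 1.5)
  el2r <- el2; el2r$median_frequency <- rev(el2r$median_frequency)
  expect_equal(element_ratio(el2r), 1.5)  # order-invariant
  expect_error(element_ratio(el2[1, ]), class = "usv44_validation_error")
  expect_equal(pair_ratio_22_44(rep(24000, 10), rep(36000, 10)), 1.5)
  expect_equal(pair_ratio_22_44(rep(25000, 5), rep(25000, 5)), 1)
  expect_error(pair_ratio_22_44(numeric(), 1), class = "usv44_validation_error")
})

test_that("generated step contours recover planted ratio and subtype", {
  cfg <- synthetic_config()
  set.seed(31)
  ratios <- replicate(60, {
    ct <- generate_contour("fortyfour", "step_up", 0.6, 40000, cfg)
    el <- trim_affixes(segment_elements(ct))
    expect_equal(nrow(el), 2)
    expect_gt(el$median_frequency[2], el$median_frequency[1])
    element_ratio(el)
  })
  se <- cfg$step_ratio_sd / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - cfg$step_ratio_mean), 3 * se + 0.01)
  # every planted subtype is recovered by the segmentation chain
  for (st in c("flat", "step_down", "insert", "complex")) {
    ct <- generate_contour("fortyfour", st, 0.8, 41000, cfg)
    expect_equal(assign_subtype(ct)$subtype, st)
  }
  # flat contours are flat by construction
  ctf <- generate_contour("fortyfour", "flat", 0.5, 42400, cfg)
  expect_lt(diff(range(ctf$frequencies)), 2000)
})

test_that("subtype_table fills only contoured fortyfour calls", {
  x <- make_calls(c(0, 2), c(0.6, 0.5), c(40000, 25000),
                  types = c("fortyfour", "long22"))
  cts <- list(c001 = step_contour(c(28000, 42000), duration = 0.6))
  out <- subtype_table(x, cts)
  expect_equal(out$subtype, c("step_up", NA))
  shares <- attr(out, "subtype_shares")
  expect_equal(unname(shares["step_up"]), 1, ignore_attr = TRUE)
})
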