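# Element segmentation of call contours and the five-subtype taxonomy of
# long high-pitched (44-kHz) calls: flat, step up, step down, insert,
# complex. An *element* is a near-constant-frequency stretch of the contour
# delimited by instantaneous frequency jumps; short leading/trailing
# fragments (prefix/suffix affixes) are discounted before categorization.

#' Subtype segmentation parameters
#'
#' @param jump_threshold minimum |delta frequency| between consecutive
#'   contour points to count as an instantaneous jump, Hz. Default 4000:
#'   clearly below the >=10 kHz jumps of step calls, clearly above
#'   within-element drift.
#' @param max_jump_gap maximum time between consecutive points for a jump to
#'   count as instantaneous, seconds. Default 0.010.
#' @param affix_ratio a leading (prefix) or trailing (suffix) element shorter
#'   than this fraction of its neighbor is discounted. Default 0.2 (the
#'   "less than 1/5th" rule).
#' @param flatness_tolerance within-element frequency spread regarded as
#'   flat, Hz. Default 2000.
#' @return a list of class `subtype_params`.
#' @export
subtype_params <- function(jump_threshold = 4000, max_jump_gap = 0.010,
                           affix_ratio = 0.2, flatness_tolerance = 2000) {
  stopifnot(jump_threshold > 0, max_jump_gap > 0,
            affix_ratio > 0, affix_ratio < 1, flatness_tolerance > 0)
  structure(list(jump_threshold = jump_threshold, max_jump_gap = max_jump_gap,
                 affix_ratio = affix_ratio,
                 flatness_tolerance = flatness_tolerance),
            class = "subtype_params")
}

#' Segment a contour into constant-frequency elements
#'
#' An element boundary is placed between consecutive contour points whenever
#' the frequency changes by more than `jump_threshold` within at most
#' `max_jump_gap` seconds. Elements tile the contour: element k spans from
#' the time of its first point to the time of the first point of element
#' k+1 (the last element ends at the last contour time). Each element's
#' frequency is summarized by the median of its points (robust to onset
#' transients).
#'
#' @param contour a [call_contour()].
#' @param params a [subtype_params()].
#' @return data.frame with columns `start`, `end` (call-relative seconds) and
#'   `median_frequency` (Hz), one row per element in temporal order.
#' @export
segment_elements <- function(contour, params = subtype_params()) {
  if (!inherits(contour, "call_contour")) {
    contour <- call_contour(contour$times, contour$frequencies, contour$amplitudes)
  }
  t <- contour$times
  f <- contour$frequencies
  df <- abs(diff(f))
  dt <- diff(t)
  jump_after <- which(df > params$jump_threshold & dt <= params$max_jump_gap)
  starts_idx <- c(1L, jump_after + 1L)
  ends_idx <- c(jump_after, length(t))
  n <- length(starts_idx)
  start <- t[starts_idx]
  end <- c(t[starts_idx[-1]], t[length(t)])
  if (n > 1 && end[n] <= start[n]) end[n] <- start[n] + mean(dt)
  data.frame(
    start = start,
    end = end,
    median_frequency = vapply(seq_len(n), function(k)
      stats::median(f[starts_idx[k]:ends_idx[k]]), numeric(1))
  )
}

#' Discount short prefix/suffix affixes
#'
#' The first element is dropped iff its duration is less than
#' `affix_ratio` times the duration of the *following* element; the last
#' element symmetrically against the *previous* one. Applied exactly once per
#' end (both conditions evaluated on the untrimmed sequence); at least one
#' element is always retained.
#'
#' @param elements element data.frame from [segment_elements()].
#' @param params a [subtype_params()].
#' @return the trimmed element data.frame, with the dropped affixes in
#'   attribute `"affixes"`.
#' @export
trim_affixes <- function(elements, params = subtype_params()) {
  n <- nrow(elements)
  if (n < 1) stop_usv("need >= 1 element", class = "usv44_validation_error")
  if (n == 1) return(elements)
  dur <- elements$end - elements$start
  drop_first <- dur[1] < params$affix_ratio * dur[2]
  drop_last <- dur[n] < params$affix_ratio * dur[n - 1]
  keep <- setdiff(seq_len(n), c(if (drop_first) 1L, if (drop_last) n))
  if (!length(keep)) keep <- which.max(dur)  # unreachable for valid ratios < 1
  out <- elements[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "affixes") <- elements[setdiff(seq_len(n), keep), , drop = FALSE]
  out
}

#' Categorize a 44-kHz call by its (trimmed) elements
#'
#' One element: `flat`. Two elements: `step_up` if the first is lower in
#' frequency, else `step_down`. Three elements whose middle differs from both
#' neighbors: `insert`. More than three: `complex`.
#'
#' @param elements affix-trimmed element data.frame.
#' @return a subtype string.
#' @export
categorize_subtype <- function(elements) {
  n <- nrow(elements)
  if (n < 1) stop_usv("need >= 1 element", class = "usv44_validation_error")
  f <- elements$median_frequency
  if (n == 1) return("flat")
  if (n == 2) return(if (f[2] > f[1]) "step_up" else "step_down")
  if (n == 3) {
    if (f[2] != f[1] && f[2] != f[3]) return("insert")
    stop_usv("3-element call whose middle matches a neighbor: segmentation inconsistency",
             class = "usv44_internal_error")
  }
  "complex"
}

#' Full subtype assignment for one contour
#'
#' Convenience composition `categorize_subtype(trim_affixes(segment_elements(...)))`.
#'
#' @inheritParams segment_elements
#' @return list with `subtype`, `elements` (trimmed), `n_elements`.
#' @export
assign_subtype <- function(contour, params = subtype_params()) {
  el <- trim_affixes(segment_elements(contour, params), params)
  list(subtype = categorize_subtype(el), elements = el, n_elements = nrow(el))
}

#' Subtype every 44-kHz call in a table
#'
#' @param records a typed `call_table`.
#' @param contours named list of contours keyed by `call_id`.
#' @param params a [subtype_params()].
#' @return the table with `subtype` filled for `fortyfour` calls that have a
#'   contour, plus attribute `"subtype_shares"` (proportions over assigned
#'   calls).
#' @export
subtype_table <- function(records, contours, params = subtype_params()) {
  records <- as_call_table(records)
  idx <- which(records$call_type == "fortyfour")
  for (i in idx) {
    ct <- contours[[records$call_id[i]]]
    if (!is.null(ct)) records$subtype[i] <- assign_subtype(ct, params)$subtype
  }
  assigned <- records$subtype[idx]
  shares <- if (any(!is.na(assigned))) {
    prop.table(table(factor(assigned[!is.na(assigned)], levels = SUBTYPES)))
  } else {
    table(factor(character(), levels = SUBTYPES))
  }
  attr(records, "subtype_shares") <- shares
  records
}

#' Frequency ratio of a two-element (step) call
#'
#' @param elements element data.frame with exactly 2 rows.
#' @return `max(median_frequency) / min(median_frequency)`, always >= 1.
#' @export
element_ratio <- function(elements) {
  if (nrow(elements) != 2) {
    stop_usv("element_ratio needs exactly 2 elements (got %d)", nrow(elements),
             class = "usv44_validation_error")
  }
  f <- elements$median_frequency
  max(f) / min(f)
}

#' 22-kHz vs 44-kHz peak-frequency ratio within a rat
#'
#' For rats transitioning from long 22-kHz to 44-kHz calling, the ratio of
#' the mean 44-kHz peak frequency to the mean long-22-kHz peak frequency
#' (conventionally computed over the last ten 22-kHz calls and the first ten
#' 44-kHz calls around the transition).
#'
#' @param long22_frequencies Hz, non-empty.
#' @param fortyfour_frequencies Hz, non-empty.
#' @return `mean(fortyfour) / mean(long22)`.
#' @export
pair_ratio_22_44 <- function(long22_frequencies, fortyfour_frequencies) {
  if (!length(long22_frequencies) || !length(fortyfour_frequencies)) {
    stop_usv("both frequency sequences must be non-empty",
             class = "usv44_validation_error")
  }
  mean(fortyfour_frequencies) / mean(long22_frequencies)
}
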