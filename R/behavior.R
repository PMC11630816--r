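# Freezing scoring and call-locked freezing linkage.
#
# Freezing is the absence of movement: a video frame counts as frozen iff it
# belongs to a maximal run of at least `min_frames` consecutive frames whose
# motion index is below `motion_threshold`. Frames are half-open intervals
# [k/fps, (k+1)/fps); a frame belongs to a time window iff its start lies in
# the window.

#' Freezing parameters
#'
#' @param motion_threshold motion-index units; frames strictly below it are
#'   candidate freezing frames. Default 18 (conditioning-software default).
#' @param min_frames minimum run length, frames. Default 30 (1 s at 30 fps);
#'   reduced values (3/5/10/15) are used for call-locked scoring.
#' @param frame_rate frames per second. Default 30.
#' @return a list of class `freeze_params`.
#' @export
freeze_params <- function(motion_threshold = 18, min_frames = 30,
                          frame_rate = 30) {
  stopifnot(motion_threshold >= 0, min_frames >= 1, frame_rate > 0)
  structure(list(motion_threshold = motion_threshold,
                 min_frames = as.integer(min_frames),
                 frame_rate = frame_rate),
            class = "freeze_params")
}

#' Score per-frame freezing from a motion series
#'
#' @param motion a [motion_series()].
#' @param params a [freeze_params()].
#' @return logical vector, one element per frame; `TRUE` = frozen.
#' @export
score_freezing <- function(motion, params = freeze_params()) {
  below <- motion$values < params$motion_threshold
  r <- rle(below)
  r$values <- r$values & r$lengths >= params$min_frames
  inverse.rle(r)
}

#' Freezing percentage over a time window
#'
#' @param mask per-frame freeze mask from [score_freezing()].
#' @param from,to window bounds in seconds (half-open `[from, to)`).
#' @param frame_rate frames per second.
#' @return freezing percentage in [0, 100]; `NaN` for an empty window.
#' @export
freezing_percent <- function(mask, from, to, frame_rate = 30) {
  frames <- which_frames(from, to, frame_rate, length(mask))
  if (!length(frames)) return(NaN)
  100 * mean(mask[frames])
}

# frames whose start k/fps lies in [from, to), clipped to the mask length
which_frames <- function(from, to, frame_rate, n_frames) {
  lo <- ceiling(from * frame_rate - 1e-9)
  hi <- ceiling(to * frame_rate - 1e-9) - 1
  lo <- max(lo, 0)
  hi <- min(hi, n_frames - 1)
  if (hi < lo) integer() else (lo:hi) + 1L
}

#' Call-locked 10-s bin freezing report
#'
#' Tiles the session into `bin_length`-second bins and categorizes each bin:
#' `baseline` for bins in the pre-shock baseline window (the first 5 minutes,
#' truncated at the first shock if earlier); otherwise, from the set of call
#' types whose onsets fall in the bin: `only_long22`, `only_fortyfour`,
#' `mixed` (any other non-empty composition), or, for call-free bins after
#' the first shock, `no_calls`. Call-free bins between the baseline window
#' and the first shock belong to no analysis category (`NA`).
#'
#' @param records typed `call_table` of one session.
#' @param mask per-frame freeze mask covering the session.
#' @param meta a [session_meta()].
#' @param bin_length bin length, seconds (default 10).
#' @param baseline_length baseline window length, seconds (default 300).
#' @return data.frame with `start`, `category`, `freezing` (percent), one row
#'   per bin.
#' @export
bin_linkage <- function(records, mask, meta, bin_length = 10,
                        baseline_length = 300) {
  n_frames_needed <- floor(meta$session_length * meta$frame_rate)
  if (length(mask) < n_frames_needed) {
    stop_usv("freeze mask (%d frames) shorter than session (%d frames)",
             length(mask), n_frames_needed, class = "usv44_validation_error")
  }
  records <- as.data.frame(records)
  starts <- (seq_len(ceiling(meta$session_length / bin_length)) - 1) * bin_length
  first_shock <- if (length(meta$shock_times)) meta$shock_times[1] else Inf
  base_end <- min(baseline_length, first_shock)
  category <- character(length(starts))
  freezing <- numeric(length(starts))
  for (b in seq_along(starts)) {
    s <- starts[b]
    e <- min(s + bin_length, meta$session_length)
    in_bin <- records$onset >= s & records$onset < e
    types <- unique(records$call_type[in_bin])
    category[b] <- if (s < base_end) "baseline"
      else if (!length(types)) (if (s >= first_shock) "no_calls" else NA_character_)
      else if (identical(types, "long22")) "only_long22"
      else if (identical(types, "fortyfour")) "only_fortyfour"
      else "mixed"
    freezing[b] <- freezing_percent(mask, s, e, meta$frame_rate)
  }
  data.frame(start = starts, category = category, freezing = freezing)
}

#' Summarize a bin report by category
#'
#' @param report a [bin_linkage()] data.frame (or several rbind-ed).
#' @return data.frame of per-category bin counts and mean freezing.
#' @export
bin_summary <- function(report) {
  report <- report[!is.na(report$category), , drop = FALSE]
  cats <- c("baseline", "no_calls", "only_long22", "only_fortyfour", "mixed")
  data.frame(
    category = cats,
    n_bins = vapply(cats, function(k) sum(report$category == k), integer(1)),
    mean_freezing = vapply(cats, function(k) {
      v <- report$freezing[report$category == k]
      if (length(v)) mean(v) else NaN
    }, numeric(1)),
    row.names = NULL
  )
}

#' Freezing during matched pairs of calls
#'
#' For a (long 22-kHz, 44-kHz) call pair, freezing is evaluated over the
#' entire span of the shorter call and over an equal-length window centered
#' in the longer call, using a freeze mask recomputed globally at a reduced
#' `min_frames` (3/5/10/15 frames, matching the shortened time scale).
#'
#' @param call_a,call_b lists with `onset` and `duration` (seconds); `call_a`
#'   conventionally the long 22-kHz call and `call_b` the 44-kHz call.
#' @param motion a [motion_series()] for the session.
#' @param params a [freeze_params()] with the reduced `min_frames`.
#' @return list with `freezing_a`, `freezing_b` (percent) and
#'   `window_length` (seconds).
#' @export
call_nested_freezing <- function(call_a, call_b, motion,
                                 params = freeze_params(min_frames = 3)) {
  for (call in list(call_a, call_b)) {
    if (call$duration < params$min_frames / params$frame_rate) {
      stop_usv("call of %.3f s is shorter than min_frames/frame_rate = %.3f s",
               call$duration, params$min_frames / params$frame_rate,
               class = "usv44_validation_error")
    }
  }
  mask <- score_freezing(motion, params)
  w <- min(call_a$duration, call_b$duration)
  win <- function(call) {
    mid <- call$onset + call$duration / 2
    c(mid - w / 2, mid + w / 2)
  }
  wa <- win(call_a)
  wb <- win(call_b)
  list(freezing_a = freezing_percent(mask, wa[1], wa[2], params$frame_rate),
       freezing_b = freezing_percent(mask, wb[1], wb[2], params$frame_rate),
       window_length = w)
}
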