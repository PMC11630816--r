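# Domain containers: call tables, contours, session metadata, motion series.
#
# A call table is a plain data.frame of class "call_table" with one row per
# detected vocalization. In memory, units are ALWAYS seconds and Hz; dialects
# that store ms/kHz are converted on read and on write. Time is seconds from
# session start, 0-based; a call occupies the half-open interval
# [onset, onset + duration).

CALLTABLE_COLUMNS <- c("call_id", "rat_id", "session_id", "onset", "duration",
                       "peak_frequency", "mean_power", "call_type", "subtype")

#' Construct a validated call table
#'
#' @param call_id,rat_id,session_id opaque identifiers (coerced to character).
#' @param onset onset in seconds from session start (>= 0).
#' @param duration call duration in seconds (> 0).
#' @param peak_frequency peak frequency in Hz, in (0, 125000).
#' @param mean_power mean power in dB (may be `NA`).
#' @param call_type one of `long22`, `short22`, `fifty`, `fortyfour`,
#'   `unknown`.
#' @param subtype optional subtype, only meaningful for `fortyfour` calls:
#'   one of `flat`, `step_up`, `step_down`, `insert`, `complex`, or `NA`.
#' @return a `data.frame` of class `call_table`, sorted by onset (stable for
#'   ties).
#' @export
call_table <- function(call_id = character(), rat_id = "r1", session_id = "s1",
                       onset = numeric(), duration = numeric(),
                       peak_frequency = numeric(), mean_power = NA_real_,
                       call_type = "unknown", subtype = NA_character_) {
  n <- length(onset)
  if (length(call_id) == 0 && n > 0) call_id <- sprintf("c%04d", seq_len(n))
  df <- data.frame(
    call_id = as.character(call_id),
    rat_id = rep_len(as.character(rat_id), n),
    session_id = rep_len(as.character(session_id), n),
    onset = as.numeric(onset),
    duration = as.numeric(duration),
    peak_frequency = as.numeric(peak_frequency),
    mean_power = rep_len(as.numeric(mean_power), n),
    call_type = rep_len(as.character(call_type), n),
    subtype = rep_len(as.character(subtype), n),
    stringsAsFactors = FALSE
  )
  as_call_table(df)
}

#' Validate a data.frame as a call table
#'
#' Checks the container invariants (positive durations, peak frequencies
#' inside (0, Nyquist), known type labels, subtype only on `fortyfour`) and
#' returns the table sorted by onset with a stable sort, so that file order
#' breaks ties reproducibly.
#'
#' @param df a data.frame with at least the mandatory columns `call_id`,
#'   `onset`, `duration`, `peak_frequency`. Unknown extra columns are kept
#'   untouched as opaque annotations.
#' @return the validated, onset-sorted `call_table`.
#' @export
as_call_table <- function(df) {
  stopifnot(is.data.frame(df))
  for (col in c("call_id", "onset", "duration", "peak_frequency")) {
    if (!col %in% names(df)) {
      stop_usv("missing mandatory column '%s'", col, class = "usv44_format_error")
    }
  }
  if (!"rat_id" %in% names(df)) df$rat_id <- "r1"
  if (!"session_id" %in% names(df)) df$session_id <- "s1"
  if (!"mean_power" %in% names(df)) df$mean_power <- NA_real_
  if (!"call_type" %in% names(df)) df$call_type <- "unknown"
  if (!"subtype" %in% names(df)) df$subtype <- NA_character_
  df$call_type <- as.character(df$call_type)
  df$subtype <- as.character(df$subtype)

  bad <- which(!is.finite(df$duration) | df$duration <= 0)
  if (length(bad)) {
    stop_usv("row %d: duration must be a positive number (got %s)",
             bad[1], as.character(df$duration[bad[1]]),
             class = "usv44_validation_error")
  }
  bad <- which(!is.finite(df$onset) | df$onset < 0)
  if (length(bad)) {
    stop_usv("row %d: onset must be >= 0", bad[1],
             class = "usv44_validation_error")
  }
  bad <- which(!is.finite(df$peak_frequency) | df$peak_frequency <= 0 |
                 df$peak_frequency >= NYQUIST_HZ)
  if (length(bad)) {
    stop_usv("row %d: peak_frequency must lie in (0, %d) Hz", bad[1],
             NYQUIST_HZ, class = "usv44_validation_error")
  }
  bad <- which(!df$call_type %in% CALL_TYPES)
  if (length(bad)) {
    stop_usv("row %d: unknown call_type '%s'", bad[1], df$call_type[bad[1]],
             class = "usv44_validation_error")
  }
  has_sub <- !is.na(df$subtype) & nzchar(df$subtype)
  bad <- which(has_sub & !df$subtype %in% SUBTYPES)
  if (length(bad)) {
    stop_usv("row %d: unknown subtype '%s'", bad[1], df$subtype[bad[1]],
             class = "usv44_validation_error")
  }
  bad <- which(has_sub & df$call_type != "fortyfour")
  if (length(bad)) {
    stop_usv("row %d: subtype set on a non-fortyfour call", bad[1],
             class = "usv44_validation_error")
  }
  df$subtype[!has_sub] <- NA_character_

  ord <- order(df$onset)  # stable in R: ties keep file order
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- unique(c("call_table", class(df)))
  df
}

#' Call offsets (onset + duration)
#' @param records a `call_table`.
#' @return numeric vector of call end times in seconds.
#' @export
call_offset <- function(records) records$onset + records$duration

#' Construct a call contour
#'
#' A contour is the per-call time series of dominant frequency, sampled at
#' strictly increasing times relative to call onset (first time = 0).
#'
#' @param times seconds relative to call onset, strictly increasing, first 0.
#' @param frequencies Hz, same length, all in (0, 125000).
#' @param amplitudes optional dB values, same length.
#' @return a list of class `call_contour`.
#' @export
call_contour <- function(times, frequencies, amplitudes = NULL) {
  if (length(times) < 2) {
    stop_usv("contour needs at least 2 points", class = "usv44_validation_error")
  }
  if (length(frequencies) != length(times)) {
    stop_usv("contour times and frequencies differ in length",
             class = "usv44_validation_error")
  }
  if (any(diff(times) <= 0)) {
    stop_usv("contour times must be strictly increasing",
             class = "usv44_validation_error")
  }
  if (abs(times[1]) > 1e-9) {
    stop_usv("contour times are call-relative; first time must be 0",
             class = "usv44_validation_error")
  }
  if (any(frequencies <= 0 | frequencies >= NYQUIST_HZ)) {
    stop_usv("contour frequencies must lie in (0, %d) Hz", NYQUIST_HZ,
             class = "usv44_validation_error")
  }
  if (!is.null(amplitudes) && length(amplitudes) != length(times)) {
    stop_usv("contour amplitudes differ in length", class = "usv44_validation_error")
  }
  structure(list(times = as.numeric(times),
                 frequencies = as.numeric(frequencies),
                 amplitudes = if (is.null(amplitudes)) NULL else as.numeric(amplitudes)),
            class = "call_contour")
}

#' Session metadata
#'
#' @param rat_id,session_id identifiers.
#' @param phase one of `training`, `test`, `playback`.
#' @param shock_times foot-shock delivery times in seconds, ascending
#'   (possibly empty).
#' @param session_length session duration in seconds.
#' @param frame_rate video frame rate in frames per second (default 30).
#' @param attenuation_profile two-column matrix-like of (frequency Hz,
#'   offset dB) pairs with strictly increasing frequencies; default encodes a
#'   conservative +10 dB correction of 40-kHz relative to 20-kHz sound for a
#'   45-degree microphone angle.
#' @return a list of class `session_meta`.
#' @export
session_meta <- function(rat_id = "r1", session_id = "s1", phase = "training",
                         shock_times = numeric(), session_length = 3120,
                         frame_rate = 30,
                         attenuation_profile = default_attenuation_profile()) {
  phase <- match.arg(phase, c("training", "test", "playback"))
  shock_times <- as.numeric(shock_times)
  if (is.unsorted(shock_times)) {
    stop_usv("shock_times must be ascending", class = "usv44_validation_error")
  }
  if (length(shock_times) &&
      (min(shock_times) < 0 || max(shock_times) > session_length)) {
    stop_usv("shock_times must lie within [0, session_length]",
             class = "usv44_validation_error")
  }
  if (frame_rate <= 0) {
    stop_usv("frame_rate must be > 0", class = "usv44_validation_error")
  }
  ap <- as.matrix(attenuation_profile)
  if (ncol(ap) != 2 || any(diff(ap[, 1]) <= 0)) {
    stop_usv("attenuation_profile needs strictly increasing frequencies",
             class = "usv44_validation_error")
  }
  structure(list(rat_id = rat_id, session_id = session_id, phase = phase,
                 shock_times = shock_times,
                 session_length = as.numeric(session_length),
                 frame_rate = as.numeric(frame_rate),
                 attenuation_profile = ap),
            class = "session_meta")
}

#' Per-frame motion index series
#'
#' @param values non-negative per-frame motion index values.
#' @param frame_rate frames per second.
#' @return a list of class `motion_series`.
#' @export
motion_series <- function(values, frame_rate = 30) {
  values <- as.numeric(values)
  if (length(values) < 1) {
    stop_usv("motion series needs at least one frame", class = "usv44_validation_error")
  }
  if (any(!is.finite(values) | values < 0)) {
    stop_usv("motion index values must be non-negative",
             class = "usv44_validation_error")
  }
  if (frame_rate <= 0) {
    stop_usv("frame_rate must be > 0", class = "usv44_validation_error")
  }
  structure(list(values = values, frame_rate = as.numeric(frame_rate)),
            class = "motion_series")
}
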