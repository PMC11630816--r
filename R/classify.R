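# Rule-based call typing.
#
# The four-type partition of the (peak frequency, duration) plane:
#
#            duration <= t_long_high   duration > t_long_high
#   f >  32 kHz      fifty                  fortyfour
#
#            duration <= t_long_low    duration > t_long_low
#   f <= 32 kHz      short22                long22
#
# Boundary semantics are strict on the high/long side (">32 kHz", ">150 ms",
# ">300 ms"); a call exactly at a boundary falls to the low/short class.

#' Classification rules
#'
#' @param high_low_boundary frequency split between low (22-kHz family) and
#'   high (50-kHz / 44-kHz) calls, Hz. Default 32000.
#' @param long_high_min_duration duration above which a high call is
#'   `fortyfour` rather than `fifty`, seconds. Default 0.150.
#' @param long_low_min_duration duration above which a low call is `long22`
#'   rather than `short22`, seconds. Default 0.300.
#' @param flatness_veto_khz optional flatness veto: if non-`NULL`, a
#'   `fortyfour` call whose contour spans more than this many Hz (max - min)
#'   is demoted to `unknown`. Off (`NULL`) by default; the published
#'   descriptive ranges are not part of the definition.
#' @return a list of class `class_rules`.
#' @export
class_rules <- function(high_low_boundary = 32000,
                        long_high_min_duration = 0.150,
                        long_low_min_duration = 0.300,
                        flatness_veto_khz = NULL) {
  stopifnot(high_low_boundary > 0, long_high_min_duration > 0,
            long_low_min_duration > 0,
            long_high_min_duration < long_low_min_duration)
  structure(list(high_low_boundary = high_low_boundary,
                 long_high_min_duration = long_high_min_duration,
                 long_low_min_duration = long_low_min_duration,
                 flatness_veto_khz = flatness_veto_khz),
            class = "class_rules")
}

#' Classify a call from peak frequency and duration
#'
#' Total and exclusive: every positive (frequency, duration) pair receives
#' exactly one of the four labels.
#'
#' @param peak_frequency Hz (vectorized).
#' @param duration seconds (vectorized).
#' @param rules a [class_rules()].
#' @return character vector of call types.
#' @examples
#' classify_call(24400, 1.0)    # "long22"
#' classify_call(42400, 0.524)  # "fortyfour"
#' classify_call(60000, 0.05)   # "fifty"
#' @export
classify_call <- function(peak_frequency, duration, rules = class_rules()) {
  if (any(!is.finite(peak_frequency) | peak_frequency <= 0)) {
    stop_usv("peak_frequency must be > 0", class = "usv44_validation_error")
  }
  if (any(!is.finite(duration) | duration <= 0)) {
    stop_usv("duration must be > 0", class = "usv44_validation_error")
  }
  high <- peak_frequency > rules$high_low_boundary
  ifelse(high,
         ifelse(duration > rules$long_high_min_duration, "fortyfour", "fifty"),
         ifelse(duration > rules$long_low_min_duration, "long22", "short22"))
}

#' Classify every call in a table
#'
#' @param records a `call_table`.
#' @param rules a [class_rules()].
#' @param contours optional named list of contours (by `call_id`), used only
#'   when the rules enable the flatness veto.
#' @return list with `records` (typed `call_table`) and `counts` (named
#'   integer vector over the four types plus `unknown`).
#' @export
classify_table <- function(records, rules = class_rules(), contours = NULL) {
  records <- as_call_table(records)
  if (nrow(records)) {
    types <- tryCatch(
      classify_call(records$peak_frequency, records$duration, rules),
      error = function(e) {
        bad <- which(!is.finite(records$peak_frequency) |
                       records$peak_frequency <= 0 |
                       !is.finite(records$duration) | records$duration <= 0)
        id <- if (length(bad)) records$call_id[bad[1]] else "?"
        stop_usv("call '%s': %s", id, conditionMessage(e),
                 class = "usv44_validation_error")
      })
    if (!is.null(rules$flatness_veto_khz) && !is.null(contours)) {
      for (i in which(types == "fortyfour")) {
        ct <- contours[[records$call_id[i]]]
        if (!is.null(ct) &&
            diff(range(ct$frequencies)) > rules$flatness_veto_khz * 1000) {
          types[i] <- "unknown"
        }
      }
    }
    records$call_type <- types
    records$subtype[types != "fortyfour"] <- NA_character_
  }
  counts <- table(factor(records$call_type, levels = CALL_TYPES))
  counts <- stats::setNames(as.integer(counts), CALL_TYPES)
  list(records = records, counts = counts)
}

#' Per-ITI call-type profile
#'
#' Assigns every call (by its onset) to exactly one window: the pre-shock
#' window `[0, shock_1]`, or ITI-k, the half-open-from-the-left interval
#' `(shock_k, shock_{k+1}]` after the k-th foot-shock (the last ITI extends
#' to session end). Returns per-window counts of every type and the
#' proportion of `fortyfour` calls among all calls of the window.
#'
#' @param records a typed `call_table` of one session.
#' @param meta a [session_meta()].
#' @return data.frame with one row per window: `iti` (0 = pre-shock,
#'   1..n_shocks), per-type counts, `total`, and `prop_fortyfour` (`NaN`
#'   where the window has no calls).
#' @export
iti_profile <- function(records, meta) {
  records <- as_call_table(records)
  if (nrow(records) && any(records$onset > meta$session_length)) {
    stop_usv("call onset beyond session_length", class = "usv44_validation_error")
  }
  shocks <- meta$shock_times
  n_shock <- length(shocks)
  # window index: 0 = pre-shock (onset <= first shock), k = ITI-k
  win <- if (n_shock == 0) rep(0L, nrow(records)) else
    findInterval(records$onset, shocks, left.open = TRUE)
  out <- data.frame(iti = 0:n_shock)
  for (ty in setdiff(CALL_TYPES, "unknown")) {
    out[[ty]] <- vapply(0:n_shock, function(k)
      sum(win == k & records$call_type == ty), integer(1))
  }
  out$unknown <- vapply(0:n_shock, function(k)
    sum(win == k & records$call_type == "unknown"), integer(1))
  out$total <- vapply(0:n_shock, function(k) sum(win == k), integer(1))
  out$prop_fortyfour <- ifelse(out$total > 0, out$fortyfour / out$total, NaN)
  out
}

#' Pool per-ITI profiles across sessions
#'
#' @param profiles list of [iti_profile()] outputs with identical window
#'   structure.
#' @return a single pooled profile data.frame.
#' @export
pool_iti_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  out <- profiles[[1]]
  num <- setdiff(names(out), c("iti", "prop_fortyfour"))
  for (p in profiles[-1]) {
    stopifnot(nrow(p) == nrow(out))
    out[num] <- out[num] + p[num]
  }
  out$prop_fortyfour <- ifelse(out$total > 0, out$fortyfour / out$total, NaN)
  out
}
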