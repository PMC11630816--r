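# Call-table, contour, motion and session-config file IO.
#
# Column maps for the supported table dialects live in a versioned JSON spec
# shipped with the package (inst/extdata/dialects.json); the native dialect is
# lossless, the avisoft_like and deepsqueak_like dialects emulate the ms/kHz
# conventions of the corresponding acquisition software exports.

dialect_spec <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "dialects.json", package = "usv44")
      cache <<- jsonlite::fromJSON(path, simplifyVector = FALSE)
    }
    cache
  }
})

get_dialect <- function(dialect) {
  spec <- dialect_spec()
  d <- spec$dialects[[dialect]]
  if (is.null(d)) {
    stop_usv("unknown dialect '%s' (known: %s)", dialect,
             paste(names(spec$dialects), collapse = ", "),
             class = "usv44_format_error")
  }
  d
}

time_factor <- function(unit) switch(unit, s = 1, ms = 1e-3,
  stop_usv("unknown time unit '%s'", unit, class = "usv44_format_error"))
freq_factor <- function(unit) switch(unit, hz = 1, khz = 1e3,
  stop_usv("unknown frequency unit '%s'", unit, class = "usv44_format_error"))

#' Read a call table
#'
#' Reads one row per detected vocalization and normalizes units so that the
#' in-memory table is always seconds/Hz, whatever the dialect stores. Rows are
#' sorted by onset (stable for ties). Extra columns that the dialect does not
#' define are carried through unchanged as opaque annotations.
#'
#' @param path file path.
#' @param dialect one of `"native"`, `"avisoft_like"`, `"deepsqueak_like"`.
#' @return a `call_table`.
#' @seealso [write_call_table()]
#' @export
read_call_table <- function(path, dialect = "native") {
  if (!file.exists(path)) {
    stop_usv("file not found: %s", path, class = "usv44_io_error")
  }
  d <- get_dialect(dialect)
  sep <- d$separator %||% ","
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         check.names = FALSE)
  cols <- d$columns
  for (field in c("call_id", "onset", "duration", "peak_frequency")) {
    if (!cols[[field]] %in% names(raw)) {
      stop_usv("dialect '%s': missing mandatory column '%s'", dialect,
               cols[[field]], class = "usv44_format_error")
    }
  }
  tf <- time_factor(d$time_unit)
  onset_tf <- if (!is.null(d$onset_unit)) time_factor(d$onset_unit) else tf
  ff <- freq_factor(d$frequency_unit)

  out <- data.frame(call_id = as.character(raw[[cols$call_id]]),
                    stringsAsFactors = FALSE)
  out$onset <- as_numeric_col(raw[[cols$onset]], cols$onset) * onset_tf
  out$duration <- as_numeric_col(raw[[cols$duration]], cols$duration) * tf
  out$peak_frequency <- as_numeric_col(raw[[cols$peak_frequency]],
                                       cols$peak_frequency) * ff
  for (field in c("rat_id", "session_id", "call_type", "subtype")) {
    if (!is.null(cols[[field]]) && cols[[field]] %in% names(raw)) {
      out[[field]] <- as.character(raw[[cols[[field]]]])
    }
  }
  if (!is.null(cols$mean_power) && cols$mean_power %in% names(raw)) {
    out$mean_power <- suppressWarnings(as.numeric(raw[[cols$mean_power]]))
  }
  known <- unlist(cols)
  extra <- setdiff(names(raw), known)
  for (col in extra) out[[col]] <- raw[[col]]
  if ("call_type" %in% names(out)) out$call_type[out$call_type == ""] <- "unknown"
  as_call_table(out)
}

as_numeric_col <- function(x, name) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad)) {
    stop_usv("row %d: non-numeric value '%s' in column '%s'", bad[1],
             as.character(x[bad[1]]), name, class = "usv44_validation_error")
  }
  v
}

#' Write a call table
#'
#' The native dialect is lossless: `read_call_table(write_call_table(x))`
#' reproduces `x` field for field. Repeated writes of the same records are
#' byte-identical.
#'
#' @param records a `call_table`.
#' @param path output file path.
#' @param dialect output dialect (see [read_call_table()]).
#' @return `path`, invisibly.
#' @export
write_call_table <- function(records, path, dialect = "native") {
  records <- as_call_table(records)
  d <- get_dialect(dialect)
  cols <- d$columns
  tf <- time_factor(d$time_unit)
  onset_tf <- if (!is.null(d$onset_unit)) time_factor(d$onset_unit) else tf
  ff <- freq_factor(d$frequency_unit)
  out <- data.frame(row.names = seq_len(nrow(records)))
  for (field in names(cols)) {
    val <- switch(field,
      onset = records$onset / onset_tf,
      duration = records$duration / tf,
      peak_frequency = records$peak_frequency / ff,
      records[[field]])
    if (!is.null(val)) out[[cols[[field]]]] <- val
  }
  extra <- setdiff(names(records), CALLTABLE_COLUMNS)
  for (col in extra) out[[col]] <- records[[col]]
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                     na = "", eol = "\n")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop_usv("cannot write '%s': %s", path, conditionMessage(ok),
             class = "usv44_io_error")
  }
  if (!is.null(d$separator) && d$separator != ",") {
    txt <- readLines(path)
    writeLines(gsub(",", d$separator, txt, fixed = TRUE), path)
  }
  invisible(path)
}

#' Read/write contour sidecar tables
#'
#' Contours travel in a long-format sidecar CSV with columns
#' `call_id,t_s,freq_hz,amp_db` (`amp_db` may be empty).
#'
#' @param path sidecar CSV path.
#' @return a named list of [call_contour()] objects keyed by `call_id`.
#' @export
read_contours <- function(path) {
  if (!file.exists(path)) {
    stop_usv("file not found: %s", path, class = "usv44_io_error")
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("call_id", "t_s", "freq_hz")) {
    if (!col %in% names(raw)) {
      stop_usv("contour sidecar: missing column '%s'", col,
               class = "usv44_format_error")
    }
  }
  has_amp <- "amp_db" %in% names(raw) && any(is.finite(raw$amp_db))
  split_idx <- split(seq_len(nrow(raw)), raw$call_id)
  # preserve first-appearance order of call ids
  split_idx <- split_idx[unique(raw$call_id)]
  lapply(split_idx, function(i) {
    call_contour(raw$t_s[i], raw$freq_hz[i],
                 amplitudes = if (has_amp) raw$amp_db[i] else NULL)
  })
}

#' @rdname read_contours
#' @param contours named list of `call_contour` objects.
#' @export
write_contours <- function(contours, path) {
  rows <- lapply(names(contours), function(id) {
    ct <- contours[[id]]
    data.frame(call_id = id, t_s = ct$times, freq_hz = ct$frequencies,
               amp_db = if (is.null(ct$amplitudes)) NA_real_ else ct$amplitudes)
  })
  df <- do.call(rbind, rows) %||%
    data.frame(call_id = character(), t_s = numeric(), freq_hz = numeric(),
               amp_db = numeric())
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "",
                   eol = "\n")
  invisible(path)
}

#' Read a per-frame motion-index series
#'
#' Expects one numeric value per line (one line per video frame), a stand-in
#' for conditioning-software motion exports.
#'
#' @param path text file, one value per frame.
#' @param frame_rate frames per second to attach.
#' @return a [motion_series()].
#' @export
read_motion_series <- function(path, frame_rate = 30) {
  if (!file.exists(path)) {
    stop_usv("file not found: %s", path, class = "usv44_io_error")
  }
  lines <- readLines(path)
  blank <- which(!nzchar(trimws(lines)))
  if (length(blank)) {
    stop_usv("blank line %d in motion file '%s'", blank[1], path,
             class = "usv44_format_error")
  }
  vals <- suppressWarnings(as.numeric(lines))
  bad <- which(is.na(vals))
  if (length(bad)) {
    stop_usv("line %d: non-numeric motion value '%s'", bad[1], lines[bad[1]],
             class = "usv44_validation_error")
  }
  motion_series(vals, frame_rate)
}

#' @rdname read_motion_series
#' @param motion a `motion_series`.
#' @export
write_motion_series <- function(motion, path) {
  writeLines(format(motion$values, trim = TRUE, scientific = FALSE), path)
  invisible(path)
}

#' Read/write session metadata as a flat key-value config
#'
#' Keys: `rat_id`, `session_id`, `phase`, `session_length`, `frame_rate`,
#' `shock_times` (comma-separated seconds), `attenuation_profile`
#' (comma-separated `freq:offset` pairs).
#'
#' @param path config file path.
#' @return a [session_meta()].
#' @export
read_session_meta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  get <- function(k, default = NULL) if (k %in% keys) vals[match(k, keys)] else default
  num_list <- function(s) if (is.null(s) || !nzchar(s)) numeric() else
    as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])
  ap <- get("attenuation_profile")
  profile <- if (is.null(ap)) default_attenuation_profile() else {
    pairs <- strsplit(strsplit(ap, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
    m <- do.call(rbind, lapply(pairs, as.numeric))
    colnames(m) <- c("frequency_hz", "offset_db")
    m
  }
  session_meta(rat_id = get("rat_id", "r1"),
               session_id = get("session_id", "s1"),
               phase = get("phase", "training"),
               shock_times = num_list(get("shock_times", "")),
               session_length = as.numeric(get("session_length", "3120")),
               frame_rate = as.numeric(get("frame_rate", "30")),
               attenuation_profile = profile)
}

#' @rdname read_session_meta
#' @param meta a `session_meta`.
#' @export
write_session_meta <- function(meta, path) {
  ap <- paste(sprintf("%g:%g", meta$attenuation_profile[, 1],
                      meta$attenuation_profile[, 2]), collapse = ",")
  writeLines(c(
    sprintf("rat_id=%s", meta$rat_id),
    sprintf("session_id=%s", meta$session_id),
    sprintf("phase=%s", meta$phase),
    sprintf("session_length=%g", meta$session_length),
    sprintf("frame_rate=%g", meta$frame_rate),
    sprintf("shock_times=%s", paste(sprintf("%g", meta$shock_times), collapse = ",")),
    sprintf("attenuation_profile=%s", ap)
  ), path)
  invisible(path)
}
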