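# Short-time spectral analysis: spectrogram, peak frequency per the
# "highest power peak in the time-averaged spectrum of the entire call"
# definition, contour mean power, and the microphone-angle attenuation
# correction.
#
# Absolute dB levels are implementation-relative (acquisition FFT settings of
# the original software are unknown); only comparisons and corrections are
# meaningful. Power is expressed in dB relative to a full-scale sine.

#' Compute a spectrogram (STFT power in dB)
#'
#' Hann-tapered short-time Fourier transform. Defaults (512-sample window,
#' 75% overlap at 250 kHz sampling) give ~2.05 ms frames and ~488 Hz bins:
#' fine enough to resolve >=4 kHz element jumps while keeping a 150 ms call
#' ~70 frames long.
#'
#' @param waveform numeric vector, mono audio samples in [-1, 1].
#' @param fs sampling rate, Hz.
#' @param window_length analysis window, samples (>= 16).
#' @param overlap_fraction fractional window overlap in [0, 1).
#' @return a list of class `spectrogram` with `times` (frame centers, s),
#'   `frequencies` (bin centers, Hz, ascending) and `power` (dB matrix,
#'   frequency x time).
#' @export
compute_spectrogram <- function(waveform, fs, window_length = 512,
                                overlap_fraction = 0.75) {
  if (fs <= 0) stop_usv("fs must be > 0", class = "usv44_validation_error")
  if (window_length < 16) {
    stop_usv("window_length must be >= 16 samples", class = "usv44_validation_error")
  }
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop_usv("overlap_fraction must be in [0, 1)", class = "usv44_validation_error")
  }
  n <- length(waveform)
  if (n < window_length) {
    stop_usv("waveform (%d samples) shorter than window (%d)", n, window_length,
             class = "usv44_validation_error")
  }
  hop <- max(1L, as.integer(round(window_length * (1 - overlap_fraction))))
  n_frames <- floor((n - window_length) / hop) + 1L
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(window_length) / (window_length + 1))
  starts <- (seq_len(n_frames) - 1L) * hop
  frames <- vapply(starts, function(s) waveform[(s + 1):(s + window_length)] * win,
                   numeric(window_length))
  spec <- stats::mvfft(frames)
  n_bins <- window_length %/% 2 + 1L
  pow <- Mod(spec[seq_len(n_bins), , drop = FALSE])^2
  # reference: a full-scale sine concentrates (sum(win)/2)^2 in one bin
  ref <- (sum(win) / 2)^2
  pow_db <- 10 * log10(pmax(pow / ref, 1e-12))
  structure(list(
    times = (starts + window_length / 2) / fs,
    frequencies = (seq_len(n_bins) - 1L) * fs / window_length,
    power = pow_db
  ), class = "spectrogram")
}

#' Peak frequency of a call
#'
#' The frequency-bin center maximizing the *time-averaged* power over all
#' spectrogram frames whose centers fall within `[onset, offset)`. Ties are
#' broken toward the lower frequency bin (deterministic and conservative
#' toward the low-frequency call classes).
#'
#' @param spec a `spectrogram`.
#' @param onset,offset call boundaries in seconds.
#' @return peak frequency in Hz.
#' @export
peak_frequency <- function(spec, onset, offset) {
  idx <- which(spec$times >= onset & spec$times < offset)
  if (!length(idx)) {
    stop_usv("no spectrogram frames overlap [%g, %g)", onset, offset,
             class = "usv44_validation_error")
  }
  # average linear power over frames (averaging dB would over-weight the
  # noise floor of quiet frames), then peak over the averaged spectrum
  avg <- 10 * log10(rowMeans(10^(spec$power[, idx, drop = FALSE] / 10)))
  if (diff(range(avg)) < 1e-9) {
    stop_usv("no spectral peak (flat averaged spectrum)", class = "usv44_signal_error")
  }
  spec$frequencies[which.max(avg)]  # which.max: first max = lowest bin
}

#' Mean power along a call contour
#'
#' Mean of the spectrogram power sampled at the nearest (time, frequency)
#' cell of each contour point, as a stand-in for the "average spectral power
#' density of the vocalization contour".
#'
#' @param spec a `spectrogram`.
#' @param contour a [call_contour()] (times relative to call onset).
#' @param onset call onset in seconds (to place the contour on the
#'   spectrogram's absolute time axis).
#' @return mean power in dB.
#' @export
mean_power <- function(spec, contour, onset) {
  t_abs <- contour$times + onset
  if (min(t_abs) < min(spec$times) - 1e-9 || max(t_abs) > max(spec$times) + 1e-9 ||
      max(contour$frequencies) > max(spec$frequencies)) {
    stop_usv("contour outside spectrogram range", class = "usv44_validation_error")
  }
  ti <- vapply(t_abs, function(t) which.min(abs(spec$times - t)), integer(1))
  fi <- vapply(contour$frequencies,
               function(f) which.min(abs(spec$frequencies - f)), integer(1))
  mean(spec$power[cbind(fi, ti)])
}

#' Default microphone-angle attenuation profile
#'
#' Directional ultrasound microphones attenuate high frequencies recorded off
#' axis; at the ~45-degree emitter-microphone angle of the reference setup
#' this is a conservative 10 dB loss at 40 kHz relative to 20 kHz. The small
#' gain below 20 kHz is deliberately ignored (set to 0).
#'
#' @return a 2-column matrix of (frequency Hz, offset dB) anchors.
#' @export
default_attenuation_profile <- function() {
  m <- cbind(frequency_hz = c(20000, 40000), offset_db = c(0, 10))
  m
}

#' Angle-dependent attenuation correction
#'
#' Adds the frequency-dependent offset obtained by piecewise-linear
#' interpolation over the profile (constant extrapolation beyond its
#' endpoints) to the recorded power, estimating the emitted level.
#'
#' @param peak_frequency call peak frequency, Hz (vectorized).
#' @param power recorded mean power, dB.
#' @param profile 2-column (frequency Hz, offset dB) matrix.
#' @return corrected power in dB.
#' @export
attenuation_correction <- function(peak_frequency, power,
                                   profile = default_attenuation_profile()) {
  profile <- as.matrix(profile)
  if (nrow(profile) < 1) {
    stop_usv("attenuation profile must be non-empty", class = "usv44_validation_error")
  }
  offset <- if (nrow(profile) == 1) rep(profile[1, 2], length(peak_frequency)) else
    stats::approx(profile[, 1], profile[, 2], xout = peak_frequency,
                  rule = 2)$y
  power + offset
}

#' Read a mono PCM WAV file
#'
#' Minimal RIFF/WAVE reader for 16-bit mono PCM (the standard format of
#' 250 kHz ultrasound recordings). Samples are scaled to [-1, 1].
#'
#' @param path WAV file path.
#' @return list with `samples` (numeric vector) and `fs` (sampling rate, Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (rawToChar(readBin(con, "raw", 4)) != "RIFF") {
    stop_usv("not a RIFF file: %s", path, class = "usv44_format_error")
  }
  readBin(con, "integer", 1, 4, endian = "little")
  if (rawToChar(readBin(con, "raw", 4)) != "WAVE") {
    stop_usv("not a WAVE file: %s", path, class = "usv44_format_error")
  }
  fs <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id_raw <- readBin(con, "raw", 4)
    if (length(id_raw) < 4) break
    id <- rawToChar(id_raw)
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, 2, endian = "little", signed = FALSE)
      channels <- fmt[2]
      fs <- readBin(con, "integer", 1, 4, endian = "little")
      readBin(con, "integer", 1, 4, endian = "little")
      readBin(con, "integer", 1, 2, endian = "little")
      bits <- readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      if (size > 16) readBin(con, "raw", size - 16)
      if (fmt[1] != 1 || channels != 1 || bits != 16) {
        stop_usv("only 16-bit mono PCM WAV is supported", class = "usv44_format_error")
      }
    } else if (id == "data") {
      samples <- readBin(con, "integer", size / 2, 2, endian = "little",
                         signed = TRUE) / 32768
    } else {
      readBin(con, "raw", size)
    }
    if (size %% 2 == 1) readBin(con, "raw", 1)
  }
  if (is.null(fs) || is.null(samples)) {
    stop_usv("incomplete WAV file: %s", path, class = "usv44_format_error")
  }
  list(samples = samples, fs = fs)
}

#' @rdname read_wav
#' @param samples numeric samples in [-1, 1].
#' @param fs sampling rate, Hz.
#' @export
write_wav <- function(samples, fs, path) {
  pcm <- as.integer(pmax(pmin(round(samples * 32767), 32767), -32768))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, 1L), con, size = 2, endian = "little")        # PCM, mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2), con, size = 4, endian = "little")
  writeBin(c(2L, 16L), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
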