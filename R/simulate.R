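# Seeded synthetic session generator.
#
# Emulates the statistical structure of a 10-shock fear-conditioning USV
# session: four call classes drawn strictly inside their defining regions
# (margins keep every call off the classification boundaries, so classifier
# agreement with ground truth is exactly 100%), ITI-dependent emission with
# the low-pitch alarm calls peaking at ITI-3 and the high-pitch long calls
# rising through late ITIs, within-session upward frequency drift, a
# persistent (Markovian) call-type sequence arranged in bouts, near-3:2
# element ratios in step subtypes, and a motion-index series whose freezing
# probability is elevated around call emission (more around 44-kHz than
# around long 22-kHz calls).
#
# Every draw goes through R's RNG after a single set.seed per session, so a
# (config, rat_index, seed) triple is fully deterministic.

#' Synthetic cohort configuration
#'
#' Defaults state the emulated world: a 52-minute (3120 s) training session
#' with 10 foot-shocks evenly spaced after a 600 s pre-period, 46 rats, and
#' per-class feature distributions placed >= 500 Hz / >= 10 ms inside the
#' class boundaries.
#'
#' @param n_rats cohort size (default 46).
#' @param n_shocks foot-shocks per session (default 10).
#' @param session_length seconds (default 3120).
#' @param pre_period seconds before the first shock (default 600).
#' @param frame_rate video frames per second (default 30).
#' @param iti_rates matrix of expected call counts, rows = windows (pre,
#'   ITI-1..n), columns = types. The default plants the rising 44-kHz share
#'   (monotone over ITI-1..9) and the ITI-3 peak of long 22-kHz calls.
#' @param self_transition named per-type probability that the next call
#'   repeats the type (long22 0.95, fortyfour 0.85 by default).
#' @param drift_long22,drift_fortyfour 2-vectors: peak-frequency means (Hz)
#'   at ITI-1 and ITI-n (linear in between). Defaults 24500->27900 and
#'   37800->39600.
#' @param step_ratio_mean,step_ratio_sd element frequency ratio of step
#'   subtypes, Normal(1.5, 0.05) by default.
#' @param subtype_mix named probabilities of the five 44-kHz subtypes
#'   (flat-dominated by default).
#' @param p_within_bout probability that a consecutive call pair stays in the
#'   same bout (gap < 0.320 s).
#' @param freeze_base,freeze_pre,freeze_long22,freeze_fortyfour per-second
#'   freezing probabilities: after the first shock away from calls, before
#'   the first shock, within +/-5 s of a long-22 onset, and within +/-5 s of
#'   a 44-kHz onset.
#' @param seed master seed.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_rats = 46, n_shocks = 10, session_length = 3120,
                             pre_period = 600, frame_rate = 30,
                             iti_rates = default_iti_rates(n_shocks),
                             self_transition = c(long22 = 0.95, short22 = 0.50,
                                                 fifty = 0.60, fortyfour = 0.85),
                             drift_long22 = c(24500, 27900),
                             drift_fortyfour = c(37800, 39600),
                             step_ratio_mean = 1.5, step_ratio_sd = 0.05,
                             subtype_mix = c(flat = 0.55, step_up = 0.15,
                                             step_down = 0.14, insert = 0.08,
                                             complex = 0.08),
                             p_within_bout = 0.75,
                             freeze_base = 0.30, freeze_pre = 0.05,
                             freeze_long22 = 0.45, freeze_fortyfour = 0.75,
                             seed = 1) {
  stopifnot(nrow(iti_rates) == n_shocks + 1, all(iti_rates >= 0),
            all(self_transition >= 0 & self_transition < 1),
            abs(sum(subtype_mix) - 1) < 1e-9)
  structure(list(
    n_rats = n_rats, n_shocks = n_shocks, session_length = session_length,
    pre_period = pre_period, frame_rate = frame_rate, iti_rates = iti_rates,
    self_transition = self_transition, drift_long22 = drift_long22,
    drift_fortyfour = drift_fortyfour, step_ratio_mean = step_ratio_mean,
    step_ratio_sd = step_ratio_sd, subtype_mix = subtype_mix,
    p_within_bout = p_within_bout, freeze_base = freeze_base,
    freeze_pre = freeze_pre, freeze_long22 = freeze_long22,
    freeze_fortyfour = freeze_fortyfour, seed = seed
  ), class = "synthetic_config")
}

#' Default per-window expected call counts
#'
#' Row 1 is the pre-shock window (appetitive 50-kHz calling), rows 2..n+1
#' the ITIs. Long 22-kHz counts peak at ITI-3; 44-kHz counts rise late, so
#' the planted 44-kHz share of all calls is monotone over ITI-1..9 (about
#' 1.2% at ITI-1, 60% at ITI-9).
#'
#' @param n_shocks number of shocks (profile defined for 10).
#' @return (n_shocks + 1) x 4 matrix, columns long22/short22/fifty/fortyfour.
#' @export
default_iti_rates <- function(n_shocks = 10) {
  stopifnot(n_shocks == 10)
  m <- rbind(
    pre = c(0, 2, 8, 0),
    cbind(long22 = c(14, 20, 26, 22, 16, 12, 10, 8, 6, 6),
          short22 = rep(1.5, 10),
          fifty = rep(0.5, 10),
          fortyfour = c(0.2, 0.5, 1.0, 1.5, 4, 6, 8, 10, 12, 10))
  )
  colnames(m) <- c("long22", "short22", "fifty", "fortyfour")
  rownames(m) <- c("pre", paste0("iti", 1:10))
  m
}

#' Planted per-ITI 44-kHz share
#'
#' The share of 44-kHz calls among all calls implied by the configured
#' per-window rates (the jump-target distribution of the type chain is tilted
#' so that this is also the chain's per-window equilibrium share).
#'
#' @param config a [synthetic_config()].
#' @return numeric vector over windows (pre, ITI-1..n).
#' @export
planted_fortyfour_share <- function(config) {
  r <- config$iti_rates
  unname(r[, "fortyfour"] / rowSums(r))
}

# per-window class feature distributions, honoring boundary margins
# (>= 500 Hz / >= 10 ms away from the 32 kHz / 150 ms / 300 ms rules)
draw_features <- function(type, window, config, n) {
  k <- max(window, 1)  # pre-shock window uses the ITI-1 means
  frac <- (k - 1) / max(config$n_shocks - 1, 1)
  switch(type,
    long22 = list(
      freq = clamp(stats::rnorm(n, config$drift_long22[1] +
                                  frac * diff(config$drift_long22), 800),
                   18000, 31500),
      dur = clamp(stats::rnorm(n, 0.90, 0.15), 0.310, 2.5)),
    short22 = list(
      freq = clamp(stats::rnorm(n, 25000, 2000), 18000, 31500),
      dur = stats::runif(n, 0.030, 0.290)),
    fifty = list(
      freq = clamp(stats::rnorm(n, 60000, 6000), 33000, 80000),
      dur = stats::runif(n, 0.020, 0.140)),
    fortyfour = list(
      freq = clamp(stats::rnorm(n, config$drift_fortyfour[1] +
                                  frac * diff(config$drift_fortyfour), 2000),
                   33000, 51500),
      dur = clamp(stats::rnorm(n, 0.70, 0.15), 0.160, 2.0)),
    stop_usv("unknown type '%s'", type, class = "usv44_internal_error"))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# next type of the persistent chain: stay with the current type's
# self-transition probability, otherwise jump to another type with
# probability proportional to share * (1 - self), which makes the per-window
# equilibrium share equal to the configured share.
chain_next <- function(current, jump_weights, self_transition) {
  if (stats::runif(1) < self_transition[[current]]) return(current)
  w <- jump_weights
  w[current] <- 0
  if (sum(w) <= 0) return(current)
  sample(names(w), 1, prob = w)
}

#' Generate one synthetic session
#'
#' @param config a [synthetic_config()].
#' @param rat_index 1-based rat index (also keys the per-rat seed).
#' @param seed master seed; the session RNG seed is derived from
#'   `(seed, rat_index)` deterministically.
#' @return list with `meta` ([session_meta()]), `calls` (a `call_table` with
#'   hidden ground-truth columns `truth_type`, `truth_subtype`), `contours`
#'   (named list of [call_contour()]), `motion` ([motion_series()]).
#' @export
generate_session <- function(config, rat_index = 1, seed = config$seed) {
  set.seed(derive_seed(seed, rat_index))
  n_windows <- config$n_shocks + 1
  spacing <- (config$session_length - config$pre_period) / config$n_shocks
  shocks <- config$pre_period + (seq_len(config$n_shocks) - 1) * spacing
  win_start <- c(0, shocks)
  win_end <- c(shocks, config$session_length)
  types_all <- colnames(config$iti_rates)

  rows <- list()
  contours <- list()
  current <- NULL
  call_no <- 0L
  for (w in seq_len(n_windows)) {
    rates <- config$iti_rates[w, ]
    n_calls <- stats::rpois(1, sum(rates))
    if (n_calls == 0) { current <- NULL; next }
    share <- rates / sum(rates)
    jump_w <- share * (1 - config$self_transition[types_all])
    # fresh chain state at the pre-shock window and after silent windows;
    # otherwise the chain continues across the window boundary with a
    # regular transition, so every consecutive pair has self-probability
    # exactly equal to the planted self-transition
    fresh <- is.null(current)
    if (fresh) {
      current <- if (all(share == 0)) types_all[1] else
        sample(types_all, 1, prob = share)
    }
    t_cursor <- win_start[w] + stats::runif(1, 1, 5)
    for (i in seq_len(n_calls)) {
      if (i > 1 || !fresh) {
        current <- chain_next(current, jump_w, config$self_transition)
      }
      feat <- draw_features(current, w - 1, config, 1)
      if (t_cursor + feat$dur > win_end[w] - 0.5) break  # window full
      call_no <- call_no + 1L
      subtype <- if (current == "fortyfour")
        sample(names(config$subtype_mix), 1, prob = config$subtype_mix)
      else NA_character_
      id <- sprintf("r%03d_c%05d", rat_index, call_no)
      rows[[call_no]] <- data.frame(
        call_id = id, onset = t_cursor, duration = feat$dur,
        peak_frequency = feat$freq, truth_type = current,
        truth_subtype = subtype, stringsAsFactors = FALSE)
      contours[[id]] <- generate_contour(current, subtype, feat$dur, feat$freq,
                                         config)
      gap <- if (stats::runif(1) < config$p_within_bout)
        stats::runif(1, 0.02, 0.25) else stats::runif(1, 0.5, 2.5)
      t_cursor <- t_cursor + feat$dur + gap
    }
  }
  calls <- if (call_no) do.call(rbind, rows) else
    data.frame(call_id = character(), onset = numeric(), duration = numeric(),
               peak_frequency = numeric(), truth_type = character(),
               truth_subtype = character(), stringsAsFactors = FALSE)
  calls$rat_id <- sprintf("rat%03d", rat_index)
  calls$session_id <- sprintf("rat%03d_train", rat_index)
  meta <- session_meta(rat_id = calls$rat_id[1] %||% sprintf("rat%03d", rat_index),
                       session_id = sprintf("rat%03d_train", rat_index),
                       phase = "training", shock_times = shocks,
                       session_length = config$session_length,
                       frame_rate = config$frame_rate)
  motion <- simulate_motion(calls, meta, config)
  list(meta = meta, calls = as_call_table(calls), contours = contours,
       motion = motion)
}

derive_seed <- function(seed, rat_index) {
  (as.integer(seed) * 7919L + as.integer(rat_index) * 104729L) %% 2147483629L
}

#' Generate a ground-truth call contour
#'
#' Contours are sampled every 5 ms. Flat calls (and the 22-kHz classes) carry
#' bounded jitter (max - min < 2000 Hz); step subtypes hold two elements
#' whose frequency ratio is drawn from the configured Normal(1.5, 0.05);
#' inserts hold three elements (middle a 2:3 drop); complex calls 4-6
#' alternating elements; 50-kHz calls are sinusoidally frequency-modulated
#' well beyond the flatness tolerance. Element duration fractions are kept
#' above the 1/5th affix rule so the planted subtype is recoverable exactly.
#'
#' @param call_type type label.
#' @param subtype subtype label (44-kHz calls only, else `NA`).
#' @param duration call duration, seconds.
#' @param peak_frequency planted peak frequency, Hz (the dominant element).
#' @param config a [synthetic_config()] (for the step-ratio distribution).
#' @return a [call_contour()].
#' @export
generate_contour <- function(call_type, subtype, duration, peak_frequency,
                             config = synthetic_config()) {
  dt <- 0.005
  n <- max(3L, as.integer(round(duration / dt)) + 1L)
  tt <- seq(0, duration, length.out = n)
  jitter <- function(m) clamp(stats::rnorm(m, 0, 250), -900, 900)
  ratio <- function() clamp(stats::rnorm(1, config$step_ratio_mean,
                                         config$step_ratio_sd), 1.25, 1.75)
  piecewise <- function(fracs, freqs) {
    cuts <- cumsum(fracs) / sum(fracs)
    seg <- findInterval(tt / duration, c(-Inf, cuts[-length(cuts)]))
    freqs[seg] + jitter(n)
  }
  f <- if (call_type %in% c("long22", "short22", "fifty") ||
           is.na(subtype) || subtype == "flat") {
    if (call_type == "fifty") {
      peak_frequency + 5000 * sin(2 * pi * 2 * tt / duration) + jitter(n)
    } else {
      peak_frequency + jitter(n)
    }
  } else {
    switch(subtype,
      step_up = {
        u <- stats::runif(1, 0.35, 0.60)
        piecewise(c(u, 1 - u), c(peak_frequency / ratio(), peak_frequency))
      },
      step_down = {
        u <- stats::runif(1, 0.40, 0.65)
        piecewise(c(u, 1 - u), c(peak_frequency, peak_frequency / ratio()))
      },
      insert = {
        u <- stats::runif(1, 0.28, 0.36)
        piecewise(c(u, u, 1 - 2 * u),
                  c(peak_frequency, peak_frequency / 1.5, peak_frequency))
      },
      complex = {
        k <- sample(4:6, 1)
        alt <- rep(c(peak_frequency, peak_frequency / 1.5), length.out = k)
        piecewise(rep(1 / k, k), alt)
      },
      stop_usv("unknown subtype '%s'", subtype, class = "usv44_validation_error"))
  }
  call_contour(tt, clamp(f, 1000, 124000))
}

# Block freezing model: each 1-s block freezes independently with a
# probability set by session phase and call proximity; frozen blocks emit
# sub-threshold motion (U(0,10)), active blocks clearly supra-threshold
# motion (U(25,100)).
simulate_motion <- function(calls, meta, config) {
  fps <- meta$frame_rate
  n_frames <- as.integer(round(meta$session_length * fps))
  block_len <- as.integer(round(fps))  # 1-s blocks
  n_blocks <- ceiling(n_frames / block_len)
  block_t <- (seq_len(n_blocks) - 0.5) * (block_len / fps)
  first_shock <- if (length(meta$shock_times)) meta$shock_times[1] else Inf
  p <- ifelse(block_t < first_shock, config$freeze_pre, config$freeze_base)
  near <- function(onsets) {
    if (!length(onsets)) return(rep(FALSE, n_blocks))
    vapply(block_t, function(b) any(abs(b - onsets) <= 5), logical(1))
  }
  p[near(calls$onset[calls$truth_type == "long22"])] <- config$freeze_long22
  p[near(calls$onset[calls$truth_type == "fortyfour"])] <- config$freeze_fortyfour
  frozen_block <- stats::runif(n_blocks) < p
  vals <- numeric(n_blocks * block_len)
  idx_frozen <- rep(frozen_block, each = block_len)
  vals[idx_frozen] <- stats::runif(sum(idx_frozen), 0, 10)
  vals[!idx_frozen] <- stats::runif(sum(!idx_frozen), 25, 100)
  motion_series(vals[seq_len(n_frames)], fps)
}

#' Generate a synthetic cohort
#'
#' Per-rat seeds are derived deterministically from the master seed. The
#' manifest records the configuration hash and a content checksum per
#' session, making silent input changes detectable.
#'
#' @param config a [synthetic_config()].
#' @param seed master seed (default `config$seed`).
#' @return list of class `synthetic_cohort` with `sessions` (list of
#'   [generate_session()] bundles) and `manifest`.
#' @export
generate_cohort <- function(config, seed = config$seed) {
  sessions <- lapply(seq_len(config$n_rats), function(r)
    generate_session(config, r, seed))
  manifest <- list(
    config_hash = fnv1a(jsonlite::toJSON(unclass(config), digits = NA,
                                         auto_unbox = TRUE)),
    seed = seed,
    n_rats = config$n_rats,
    sessions = lapply(sessions, function(s) list(
      session_id = s$meta$session_id,
      n_calls = nrow(s$calls),
      checksum = fnv1a(paste(
        paste(s$calls$call_id, collapse = ","),
        paste(sprintf("%.6f", s$calls$onset), collapse = ","),
        sep = "|"))))
  )
  structure(list(sessions = sessions, manifest = manifest),
            class = "synthetic_cohort")
}

# 32-bit FNV-1a content hash (hex string); pure R, deterministic. The
# multiply is split into 16-bit halves to stay inside exact double range.
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(as.character(x), collapse = "")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    h <- (h - h %% 256) + bitwXor(as.integer(h %% 256), b)
    h0 <- h %% 65536
    h1 <- (h - h0) / 65536
    h <- (h0 * p + ((h1 * p) %% 65536) * 65536) %% 4294967296
  }
  h0 <- h %% 65536
  sprintf("%04x%04x", as.integer((h - h0) / 65536), as.integer(h0))
}

#' Write a cohort to native-dialect files
#'
#' One call table, contour sidecar, motion file and session config per rat,
#' plus a cohort manifest JSON. Ground-truth columns are stripped on export
#' unless `keep_truth = TRUE` (the pipeline must never read them).
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param keep_truth keep the hidden ground-truth columns.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, keep_truth = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort$sessions) {
    base <- file.path(dir, s$meta$session_id)
    calls <- s$calls
    if (!keep_truth) {
      calls <- calls[, setdiff(names(calls), c("truth_type", "truth_subtype")),
                     drop = FALSE]
    }
    write_call_table(as_call_table(calls), paste0(base, "_calls.csv"))
    write_contours(s$contours, paste0(base, "_contours.csv"))
    write_motion_series(s$motion, paste0(base, "_motion.csv"))
    write_session_meta(s$meta, paste0(base, "_session.cfg"))
  }
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
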