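# Shared fixture builders (all fixtures are generated in code).

make_calls <- function(onsets, durations, freqs, types = "unknown",
                       session_id = "s1", rat_id = "r1") {
  call_table(call_id = sprintf("c%03d", seq_along(onsets)),
             rat_id = rat_id, session_id = session_id,
             onset = onsets, duration = durations, peak_frequency = freqs,
             call_type = types)
}

# contour with a single constant-frequency segment plus optional jitter
flat_contour <- function(freq, duration = 0.5, dt = 0.005, jitter = 0) {
  tt <- seq(0, duration, by = dt)
  call_contour(tt, freq + jitter * sin(seq_along(tt)))
}

# contour of piecewise-constant elements; fracs are duration fractions
step_contour <- function(freqs, fracs = rep(1, length(freqs)),
                         duration = 0.6, dt = 0.005) {
  tt <- seq(0, duration, by = dt)
  cuts <- cumsum(fracs) / sum(fracs)
  seg <- findInterval(tt / duration, c(-Inf, cuts[-length(cuts)]))
  call_contour(tt, freqs[seg])
}

# pure tone waveform
tone <- function(freq, fs = 250000, dur = 0.1, amp = 1) {
  amp * sin(2 * pi * freq * seq(0, dur, by = 1 / fs))
}

# two well-separated planted Gaussian blobs (standardizable 2-D features)
planted_blobs <- function(n_each = 500, sep = 10, sd = 1, seed = 42) {
  set.seed(seed)
  x <- rbind(cbind(rnorm(n_each, 0, sd), rnorm(n_each, 0, sd)),
             cbind(rnorm(n_each, sep, sd), rnorm(n_each, sep, sd)))
  list(x = x, truth = rep(1:2, each = n_each))
}

small_cohort_config <- function(n_rats = 4, seed = 11) {
  synthetic_config(n_rats = n_rats, seed = seed)
}
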