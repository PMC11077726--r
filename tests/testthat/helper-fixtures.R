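# Fixtures built in code: minimal recordings and epoch sets that bypass the
# simulator where a test only exercises one stage.

# a bare two-channel recording around given channel vectors
fake_recording <- function(AC, FC = AC, sample_rate_hz = 1024,
                           events = data.frame(time_s = numeric(0),
                                               label = character(0),
                                               gap_width_ms = numeric(0),
                                               mod_depth_pct = numeric(0))) {
  structure(list(sample_rate_hz = sample_rate_hz,
                 channels = list(AC = AC, FC = FC),
                 events = events, session = "test",
                 subject = subject_spec("t1", "WT", "F", "p21"),
                 n_samples = length(AC)),
            class = "eeg_recording")
}

# an epoch_set from a trials x samples matrix (single channel "AC")
fake_epochs <- function(m, sample_rate_hz = 1024, t0_ms = -250,
                        events = NULL) {
  nt <- nrow(m); ns <- ncol(m)
  times <- t0_ms + (seq_len(ns) - 1) / sample_rate_hz * 1000
  structure(list(channels = list(AC = m), times_ms = times,
                 sample_rate_hz = sample_rate_hz,
                 events = events %||% data.frame(time_s = seq_len(nt)),
                 window_ms = c(t0_ms, times[ns] + 1000 / sample_rate_hz),
                 baselined = FALSE, detrended = FALSE,
                 rejected = rep(FALSE, nt), n_dropped = 0L),
            class = "epoch_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gaussian-bump ERP waveform on a regular grid (amplitudes uv, latencies ms)
bump_waveform <- function(time_ms, lat, amp, width) {
  y <- numeric(length(time_ms))
  for (i in seq_along(lat)) {
    y <- y + amp[i] * exp(-0.5 * ((time_ms - lat[i]) / width[i])^2)
  }
  y
}

# trials of a 40 Hz sinusoid with given phase offsets (trials x samples)
sin40_trials <- function(phi, n_samples = 512, sample_rate_hz = 1024,
                         amplitude = 1) {
  t <- (seq_len(n_samples) - 1) / sample_rate_hz
  t(vapply(phi, function(p) amplitude * cos(2 * pi * 40 * t + p),
           numeric(n_samples)))
}

# mean resultant length of van angle set
mrl <- function(theta) Mod(mean(exp(1i * theta)))
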