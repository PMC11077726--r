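# Preprocessing: anti-aliased down-sampling, TTL-based epoching, baseline
# correction, linear detrending and artifact screening (flag, don't drop).

# zero-phase FFT low-pass with a raised-cosine transition band
fft_lowpass <- function(x, sample_rate_hz, pass_hz, stop_hz) {
  n <- length(x)
  m <- stats::nextn(n)
  X <- stats::fft(c(x, numeric(m - n)))
  f <- (seq_len(m) - 1) * sample_rate_hz / m
  f <- pmin(f, sample_rate_hz - f)
  H <- numeric(m)
  H[f <= pass_hz] <- 1
  tr <- f > pass_hz & f < stop_hz
  H[tr] <- 0.5 * (1 + cos(pi * (f[tr] - pass_hz) / (stop_hz - pass_hz)))
  Re(stats::fft(X * H, inverse = TRUE))[seq_len(n)] / m
}

#' Down-sample a recording with anti-alias filtering
#'
#' A zero-phase FFT low-pass (unity gain up to 0.4 x the target rate,
#' raised-cosine roll-off to zero at the target Nyquist) is applied before
#' decimation by an integer factor; zero phase protects 40 Hz phase
#' estimates from filter delay.  Event times are in seconds and carry over
#' unchanged; they are re-quantized to the new sample grid at epoching.
#'
#' @param recording an `eeg_recording`.
#' @param target_rate_hz analysis rate in Hz (default 1024); must divide the
#'   native rate.
#' @return the down-sampled `eeg_recording`.
#' @export
downsample_recording <- function(recording, target_rate_hz = 1024) {
  fs <- recording$sample_rate_hz
  if (target_rate_hz > fs)
    stop_invalid("target_rate_hz exceeds the native rate")
  if (target_rate_hz == fs) return(recording)
  factor <- fs / target_rate_hz
  if (abs(factor - round(factor)) > 1e-9)
    stop_invalid("target_rate_hz must divide the native rate")
  factor <- as.integer(round(factor))
  keep <- seq(1L, recording$n_samples, by = factor)
  recording$channels <- lapply(recording$channels, function(x) {
    fft_lowpass(x, fs, 0.4 * target_rate_hz, 0.5 * target_rate_hz)[keep]
  })
  recording$sample_rate_hz <- target_rate_hz
  recording$n_samples <- length(keep)
  recording
}

#' Split a recording into event-locked epochs
#'
#' One epoch per event whose window lies fully inside the recording;
#' out-of-bounds events are dropped with a message.  Time 0 is the event
#' onset; the window is `[window_ms[1], window_ms[2])`.
#'
#' @param recording an `eeg_recording` (typically down-sampled).
#' @param events data frame with a `time_s` column (and optional pair label
#'   columns); defaults to the recording's own event table.
#' @param window_ms epoch window in ms relative to each event.
#' @return an object of class `epoch_set`: per-channel trials-x-samples
#'   matrices, a time axis, the retained event table and state flags.
#' @export
extract_epochs <- function(recording, events = NULL,
                           window_ms = c(-250, 750)) {
  events <- events %||% recording$events
  if (is.null(events) || nrow(events) == 0)
    stop_invalid("no events to epoch")
  fs <- recording$sample_rate_hz
  pre <- ms_to_samples(window_ms[1], fs)
  post <- ms_to_samples(window_ms[2], fs)
  if (post <= pre) stop_invalid("window_ms must be increasing")
  rel <- pre:(post - 1L)
  i0 <- round(events$time_s * fs) + 1L
  ok <- (i0 + rel[1]) >= 1L & (i0 + rel[length(rel)]) <= recording$n_samples
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message(n_dropped, " event(s) outside the recording were dropped")
  if (!any(ok)) stop_invalid("no usable events inside the recording")
  i0 <- i0[ok]
  idx <- outer(rel, i0, `+`)
  channels <- lapply(recording$channels, function(x) {
    t(matrix(x[idx], nrow = length(rel)))
  })
  structure(list(channels = channels,
                 times_ms = rel / fs * 1000,
                 sample_rate_hz = fs,
                 events = events[ok, , drop = FALSE],
                 window_ms = window_ms,
                 baselined = FALSE, detrended = FALSE,
                 rejected = rep(FALSE, sum(ok)),
                 n_dropped = n_dropped),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set: %d trials x %d samples, %d channel(s), [%g, %g) ms%s%s>\n",
              nrow(x$channels[[1]]), ncol(x$channels[[1]]), length(x$channels),
              x$window_ms[1], x$window_ms[2],
              if (x$baselined) ", baselined" else "",
              if (x$detrended) ", detrended" else ""))
  invisible(x)
}

#' Events marking gapped-segment onsets / ERP onsets
#'
#' Convenience selectors over a recording's event table.
#'
#' @param recording an `eeg_recording`.
#' @return data frame of events.
#' @export
assr_events <- function(recording) {
  ev <- recording$events
  ev[!is.na(ev$gap_width_ms), , drop = FALSE]
}

#' @rdname assr_events
#' @export
erp_events <- function(recording) {
  ev <- recording$events
  ev[ev$label == "erp", , drop = FALSE]
}

#' Baseline-correct epochs
#'
#' Subtracts each trial's mean over the baseline window from the whole
#' trial.  Idempotent.
#'
#' @param epochs an `epoch_set`.
#' @param baseline_ms baseline window in ms, inside the epoch window.
#' @return the corrected `epoch_set` with `baselined = TRUE`.
#' @export
baseline_correct <- function(epochs, baseline_ms = c(-250, 0)) {
  if (baseline_ms[1] < epochs$window_ms[1] ||
      baseline_ms[2] > epochs$window_ms[2])
    stop_invalid("baseline window must lie inside the epoch window")
  cols <- epochs$times_ms >= baseline_ms[1] & epochs$times_ms < baseline_ms[2]
  if (!any(cols)) stop_invalid("baseline window contains no samples")
  epochs$channels <- lapply(epochs$channels, function(m) {
    m - rowMeans(m[, cols, drop = FALSE])
  })
  epochs$baselined <- TRUE
  epochs$baseline_ms <- baseline_ms
  epochs
}

#' Remove a least-squares linear trend from every trial
#'
#' @param epochs an `epoch_set`.
#' @return the detrended `epoch_set` with `detrended = TRUE`.
#' @export
detrend_epochs <- function(epochs) {
  ns <- ncol(epochs$channels[[1]])
  X <- cbind(1, seq_len(ns))
  XtXinv_Xt <- solve(crossprod(X), t(X))        # 2 x ns
  epochs$channels <- lapply(epochs$channels, function(m) {
    coef <- m %*% t(XtXinv_Xt)                  # trials x 2
    m - coef %*% t(X)
  })
  epochs$detrended <- TRUE
  epochs
}

#' Flag artifact trials (nothing is deleted)
#'
#' Trials whose absolute amplitude exceeds `max_abs_uv`, or that contain a
#' flat run (consecutive samples differing by at most `flat_tol_uv`) of at
#' least `flatline_ms`, are flagged in the rejection mask.  Defaults are
#' permissive so clean recordings yield zero flags; flagged trials are only
#' excluded downstream when a strict mode is requested.
#'
#' @param epochs an `epoch_set`.
#' @param max_abs_uv absolute amplitude bound in microvolts.
#' @param flatline_ms minimum flat-run duration in ms.
#' @param flat_tol_uv sample-to-sample difference treated as flat.
#' @return the `epoch_set` with an updated `rejected` mask.
#' @export
screen_artifacts <- function(epochs, max_abs_uv = 2000, flatline_ms = 250,
                             flat_tol_uv = 1e-9) {
  if (max_abs_uv <= 0 || flatline_ms <= 0)
    stop_invalid("thresholds must be positive")
  min_run <- ms_to_samples(flatline_ms, epochs$sample_rate_hz)
  flagged <- rep(FALSE, nrow(epochs$channels[[1]]))
  for (m in epochs$channels) {
    over <- apply(abs(m) > max_abs_uv, 1, any)
    flat <- apply(m, 1, function(x) {
      r <- rle(abs(diff(x)) <= flat_tol_uv)
      any(r$lengths[r$values] + 1L >= min_run)
    })
    flagged <- flagged | over | flat
  }
  epochs$rejected <- flagged
  epochs
}
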