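# Stimulus construction: narrowband-noise ERP sessions and the 40 Hz
# gap-in-noise ASSR session.  Waveforms are peak-normalized and unitless;
# nominal sound level (75 dB SPL) is carried as metadata only.

#' ERP stimulation protocol
#'
#' Parameters of the auditory ERP session: repeated narrowband noise bursts
#' presented at a slow rate.  Defaults are 120 repetitions of a 100 ms,
#' 6-12 kHz noise burst with 5 ms rise/fall ramps at a 0.25 Hz repetition
#' rate, at a nominal level of 75 dB SPL.
#'
#' @param n_repetitions number of stimulus presentations (> 0).
#' @param stim_duration_ms burst duration in ms; must exceed `2 * ramp_ms`.
#' @param ramp_ms cosine-squared rise/fall time in ms.
#' @param repetition_rate_hz presentation rate in Hz (onset-to-onset spacing
#'   is `1 / repetition_rate_hz` seconds).
#' @param band_low_hz,band_high_hz noise passband edges in Hz.
#' @param level_db nominal sound level (dB SPL), metadata only.
#' @return an object of class `erp_protocol`.
#' @export
erp_protocol <- function(n_repetitions = 120, stim_duration_ms = 100,
                         ramp_ms = 5, repetition_rate_hz = 0.25,
                         band_low_hz = 6000, band_high_hz = 12000,
                         level_db = 75) {
  if (n_repetitions < 1) stop_invalid("n_repetitions must be positive")
  if (stim_duration_ms <= 2 * ramp_ms)
    stop_invalid("stim_duration_ms must exceed 2 * ramp_ms")
  if (band_low_hz >= band_high_hz)
    stop_invalid("band_low_hz must be below band_high_hz")
  if (repetition_rate_hz <= 0) stop_invalid("repetition_rate_hz must be positive")
  structure(list(n_repetitions = as.integer(n_repetitions),
                 stim_duration_ms = stim_duration_ms, ramp_ms = ramp_ms,
                 repetition_rate_hz = repetition_rate_hz,
                 band_low_hz = band_low_hz, band_high_hz = band_high_hz,
                 level_db = level_db),
            class = "erp_protocol")
}

#' Gap widths and modulation depths of the gap-ASSR paradigm
#'
#' The paradigm crosses six gap widths (2, 4, 6, 8, 10, 12 ms) with two
#' modulation depths (75 and 100 %), giving twelve parametric pairs.
#'
#' @return numeric vectors (`gap_widths_ms`, `mod_depths_pct`) or a
#'   data frame of all twelve pairs (`default_pairs`).
#' @export
gap_widths_ms <- function() c(2, 4, 6, 8, 10, 12)

#' @rdname gap_widths_ms
#' @export
mod_depths_pct <- function() c(75, 100)

#' @rdname gap_widths_ms
#' @export
default_pairs <- function() {
  out <- expand.grid(gap_width_ms = gap_widths_ms(),
                     mod_depth_pct = mod_depths_pct(),
                     KEEP.OUT.ATTRS = FALSE)
  out[order(out$mod_depth_pct, out$gap_width_ms), , drop = FALSE]
}

#' One (gap width, modulation depth) stimulus condition
#'
#' @param gap_width_ms gap duration in ms; must be positive and below the
#'   25 ms inter-gap interval.
#' @param mod_depth_pct percentage amplitude reduction inside the gap, in
#'   (0, 100]; 100 is full silence, 75 drops the amplitude to one quarter.
#' @return an object of class `parametric_pair`.
#' @export
parametric_pair <- function(gap_width_ms, mod_depth_pct) {
  if (!is.numeric(gap_width_ms) || gap_width_ms <= 0 || gap_width_ms >= 25)
    stop_invalid("gap_width_ms must lie in (0, 25) ms (inter-gap interval is 25 ms)")
  if (!is.numeric(mod_depth_pct) || mod_depth_pct <= 0 || mod_depth_pct > 100)
    stop_invalid("mod_depth_pct must lie in (0, 100]")
  structure(list(gap_width_ms = gap_width_ms, mod_depth_pct = mod_depth_pct),
            class = "parametric_pair")
}

#' Generate a peak-normalized narrowband noise burst
#'
#' Gaussian white noise is brickwall band-limited in the frequency domain,
#' shaped with cosine-squared onset/offset ramps and peak-normalized to 1.
#'
#' @param duration_ms burst duration in ms (must exceed `2 * ramp_ms`).
#' @param band_low_hz,band_high_hz passband edges in Hz; `band_high_hz` must
#'   be at or below the Nyquist frequency.
#' @param ramp_ms cosine-squared ramp duration in ms (0 for no ramp).
#' @param sample_rate_hz synthesis rate in Hz.
#' @param seed optional integer seed; the caller's RNG stream is untouched.
#' @return numeric vector of samples with `max(abs(.)) == 1`.
#' @export
make_narrowband_noise <- function(duration_ms, band_low_hz = 6000,
                                  band_high_hz = 12000, ramp_ms = 5,
                                  sample_rate_hz = 48000, seed = NULL) {
  if (duration_ms <= 2 * ramp_ms)
    stop_invalid("duration_ms must exceed 2 * ramp_ms")
  if (band_high_hz > sample_rate_hz / 2)
    stop_invalid("band_high_hz exceeds the Nyquist frequency")
  if (band_low_hz <= 0 || band_low_hz >= band_high_hz)
    stop_invalid("need 0 < band_low_hz < band_high_hz")
  n <- ms_to_samples(duration_ms, sample_rate_hz)
  x <- with_seed(seed, stats::rnorm(n))
  # brickwall bandpass by zeroing out-of-band DFT bins (fold to [0, fs/2])
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * sample_rate_hz / n
  f <- pmin(f, sample_rate_hz - f)
  X[f < band_low_hz | f > band_high_hz] <- 0 + 0i
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  if (ramp_ms > 0) {
    nr <- ms_to_samples(ramp_ms, sample_rate_hz)
    if (nr > 0) {
      ramp <- sin(pi / 2 * seq_len(nr) / nr)^2
      x[seq_len(nr)] <- x[seq_len(nr)] * ramp
      x[n - nr + seq_len(nr)] <- x[n - nr + seq_len(nr)] * rev(ramp)
    }
  }
  x / max(abs(x))
}

# gap onsets within one 250 ms gapped segment, in samples from segment start.
# Gaps recur every 25 ms (40 Hz); the first gap starts 25 ms in, the step
# after the 9th lands exactly on the next segment boundary.
gap_onset_samples <- function(sample_rate_hz) {
  step <- ms_to_samples(25, sample_rate_hz)
  step * seq_len(9)
}

#' Construct one gap-interrupted noise segment
#'
#' A 250 ms narrowband noise token in which nine gaps, 25 ms apart (a 40 Hz
#' presentation rate), scale the amplitude by `1 - mod_depth_pct/100`
#' (rectangular edges).  100 % depth yields exact silence inside the gaps.
#'
#' @param pair a [parametric_pair()] (or list with the same fields).
#' @param sample_rate_hz synthesis rate in Hz.
#' @param seed optional integer seed for the noise token.
#' @param noise optional pre-generated 250 ms noise vector to carve gaps into.
#' @return list with `waveform` and `gap_onsets_ms` (sample-quantized).
#' @export
make_gap_segment <- function(pair, sample_rate_hz = 48000, seed = NULL,
                             noise = NULL) {
  pair <- as_pair(pair)
  n <- ms_to_samples(250, sample_rate_hz)
  if (is.null(noise)) {
    noise <- make_narrowband_noise(250, ramp_ms = 0,
                                   sample_rate_hz = sample_rate_hz, seed = seed)
  }
  if (length(noise) != n) stop_invalid("noise must span exactly 250 ms")
  w <- noise
  gain <- 1 - pair$mod_depth_pct / 100
  on_samp <- gap_onset_samples(sample_rate_hz)
  wid <- ms_to_samples(pair$gap_width_ms, sample_rate_hz)
  for (s in on_samp) {
    idx <- (s + 1):min(s + wid, n)
    w[idx] <- w[idx] * gain
  }
  list(waveform = w, gap_onsets_ms = on_samp / sample_rate_hz * 1000)
}

as_pair <- function(pair) {
  if (inherits(pair, "parametric_pair")) return(pair)
  parametric_pair(pair$gap_width_ms, pair$mod_depth_pct)
}

#' Build a gap-ASSR session schedule
#'
#' Alternating 250 ms segments of plain noise and gap-interrupted noise.
#' Each gapped segment's parametric pair (gap width x modulation depth) is
#' drawn uniformly at random; the session is extended until every pair has
#' accumulated at least `n_trials_per_pair` gapped segments.
#'
#' @param n_trials_per_pair minimum gapped-segment count per parametric pair
#'   (default 101, so every pair exceeds 100 trials).
#' @param sample_rate_hz stimulus synthesis rate in Hz.
#' @param seed optional integer seed (schedules are reproducible under it).
#' @param pairs data frame of conditions (default: all twelve).
#' @param include_waveform generate the full audio waveform (off by default;
#'   the schedule alone drives EEG simulation and analysis).
#' @param lead_in_s silence before the first segment, seconds.
#' @return an object of class `stimulus_schedule`.
#' @export
make_gap_assr_session <- function(n_trials_per_pair = 101,
                                  sample_rate_hz = 48000, seed = NULL,
                                  pairs = default_pairs(),
                                  include_waveform = FALSE, lead_in_s = 0) {
  if (n_trials_per_pair < 1) stop_invalid("n_trials_per_pair must be >= 1")
  npairs <- nrow(pairs)
  with_seed(seed, {
    draws <- integer(0)
    repeat {
      draws <- c(draws, sample.int(npairs, size = max(64L, npairs * n_trials_per_pair),
                                   replace = TRUE))
      counts <- tabulate(draws, nbins = npairs)
      if (all(counts >= n_trials_per_pair)) break
    }
    # truncate at the first position where every pair has reached the target
    cut <- max(vapply(seq_len(npairs), function(i) {
      which(cumsum(draws == i) == n_trials_per_pair)[1]
    }, numeric(1)))
    draws <- draws[seq_len(cut)]
    n_gapped <- length(draws)

    seg_kind <- rep(c("noise", "gapped"), times = n_gapped)
    seg_start <- lead_in_s + (seq_along(seg_kind) - 1) * 0.25
    seg_gap <- rep(NA_real_, length(seg_kind))
    seg_depth <- rep(NA_real_, length(seg_kind))
    gapped_idx <- which(seg_kind == "gapped")
    seg_gap[gapped_idx] <- pairs$gap_width_ms[draws]
    seg_depth[gapped_idx] <- pairs$mod_depth_pct[draws]
    segments <- data.frame(kind = seg_kind, start_s = seg_start,
                           gap_width_ms = seg_gap, mod_depth_pct = seg_depth,
                           stringsAsFactors = FALSE)

    on_ms <- gap_onset_samples(sample_rate_hz) / sample_rate_hz * 1000
    gap_onsets <- data.frame(
      time_s = rep(seg_start[gapped_idx], each = length(on_ms)) +
        rep(on_ms / 1000, times = n_gapped),
      gap_width_ms = rep(seg_gap[gapped_idx], each = length(on_ms)),
      mod_depth_pct = rep(seg_depth[gapped_idx], each = length(on_ms)),
      segment = rep(gapped_idx, each = length(on_ms)))

    duration_s <- lead_in_s + length(seg_kind) * 0.25
    waveform <- NULL
    if (include_waveform) {
      nseg <- ms_to_samples(250, sample_rate_hz)
      waveform <- numeric(ms_to_samples(duration_s * 1000, sample_rate_hz))
      off <- ms_to_samples(lead_in_s * 1000, sample_rate_hz)
      for (i in seq_along(seg_kind)) {
        tok <- make_narrowband_noise(250, ramp_ms = 0,
                                     sample_rate_hz = sample_rate_hz)
        if (seg_kind[i] == "gapped") {
          tok <- make_gap_segment(parametric_pair(seg_gap[i], seg_depth[i]),
                                  sample_rate_hz, noise = tok)$waveform
        }
        waveform[off + (i - 1L) * nseg + seq_len(nseg)] <- tok
      }
    }
    structure(list(kind = "gap_assr", sample_rate_hz = sample_rate_hz,
                   segments = segments, gap_onsets = gap_onsets,
                   erp_onsets_s = numeric(0), pairs = pairs,
                   n_trials_per_pair = n_trials_per_pair,
                   duration_s = duration_s, level_db = 75,
                   waveform = waveform),
              class = "stimulus_schedule")
  })
}

#' Build an ERP session schedule
#'
#' `n_repetitions` narrowband-noise bursts spaced `1 / repetition_rate_hz`
#' seconds apart (4 s at the default 0.25 Hz).
#'
#' @param protocol an [erp_protocol()].
#' @param sample_rate_hz stimulus synthesis rate in Hz.
#' @param seed optional integer seed (used only for the waveform noise).
#' @param lead_in_s time before the first onset, seconds.
#' @param include_waveform generate the audio waveform (off by default).
#' @return an object of class `stimulus_schedule`.
#' @export
make_erp_session <- function(protocol = erp_protocol(),
                             sample_rate_hz = 48000, seed = NULL,
                             lead_in_s = 1, include_waveform = FALSE) {
  stopifnot(inherits(protocol, "erp_protocol"))
  period_s <- 1 / protocol$repetition_rate_hz
  onsets <- lead_in_s + (seq_len(protocol$n_repetitions) - 1) * period_s
  duration_s <- onsets[length(onsets)] + protocol$stim_duration_ms / 1000 + 1
  waveform <- NULL
  if (include_waveform) {
    waveform <- numeric(ms_to_samples(duration_s * 1000, sample_rate_hz))
    nb <- ms_to_samples(protocol$stim_duration_ms, sample_rate_hz)
    with_seed(seed, {
      for (t0 in onsets) {
        burst <- make_narrowband_noise(protocol$stim_duration_ms,
                                       protocol$band_low_hz, protocol$band_high_hz,
                                       protocol$ramp_ms, sample_rate_hz)
        i0 <- ms_to_samples(t0 * 1000, sample_rate_hz)
        waveform[i0 + seq_len(nb)] <- burst
      }
    })
  }
  structure(list(kind = "erp", sample_rate_hz = sample_rate_hz,
                 segments = data.frame(), gap_onsets = data.frame(),
                 erp_onsets_s = onsets, protocol = protocol,
                 duration_s = duration_s, level_db = protocol$level_db,
                 waveform = waveform),
            class = "stimulus_schedule")
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  cat(sprintf("<stimulus_schedule: %s, %.1f s, fs = %g Hz>\n",
              x$kind, x$duration_s, x$sample_rate_hz))
  if (x$kind == "gap_assr") {
    tab <- pair_counts(x)
    cat(sprintf("  %d segments (%d gapped); per-pair trial counts %d-%d\n",
                nrow(x$segments), sum(x$segments$kind == "gapped"),
                min(tab$n), max(tab$n)))
  } else {
    cat(sprintf("  %d stimulus onsets, %.2f Hz repetition rate\n",
                length(x$erp_onsets_s), x$protocol$repetition_rate_hz))
  }
  invisible(x)
}

#' Gapped-segment counts per parametric pair in a session
#'
#' @param schedule a gap-ASSR [make_gap_assr_session()] schedule.
#' @return data frame with `gap_width_ms`, `mod_depth_pct`, `n`.
#' @export
pair_counts <- function(schedule) {
  g <- schedule$segments[schedule$segments$kind == "gapped", , drop = FALSE]
  agg <- stats::aggregate(list(n = g$gap_width_ms),
                          by = list(gap_width_ms = g$gap_width_ms,
                                    mod_depth_pct = g$mod_depth_pct),
                          FUN = length)
  agg[order(agg$mod_depth_pct, agg$gap_width_ms), , drop = FALSE]
}

#' Export a schedule's events as a BED-like TSV table
#'
#' One row per event (`onset_s`, `duration_ms`, `label`): ERP onsets, gap
#' onsets and segment boundaries.
#'
#' @param schedule a [make_gap_assr_session()] / [make_erp_session()] schedule.
#' @param path output file path.
#' @return the written data frame, invisibly.
#' @export
write_schedule_events <- function(schedule, path) {
  rows <- list()
  if (nrow(schedule$segments) > 0) {
    lab <- ifelse(schedule$segments$kind == "gapped",
                  paste0("segment_", pair_key(schedule$segments$gap_width_ms,
                                              schedule$segments$mod_depth_pct)),
                  "segment_noise")
    rows$segments <- data.frame(onset_s = schedule$segments$start_s,
                                duration_ms = 250, label = lab)
  }
  if (nrow(schedule$gap_onsets) > 0) {
    rows$gaps <- data.frame(onset_s = schedule$gap_onsets$time_s,
                            duration_ms = schedule$gap_onsets$gap_width_ms,
                            label = paste0("gap_",
                                           pair_key(schedule$gap_onsets$gap_width_ms,
                                                    schedule$gap_onsets$mod_depth_pct)))
  }
  if (length(schedule$erp_onsets_s) > 0) {
    rows$erp <- data.frame(onset_s = schedule$erp_onsets_s,
                           duration_ms = schedule$protocol$stim_duration_ms,
                           label = "erp")
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$onset_s), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Serialize a schedule (without waveform) to JSON
#'
#' @inheritParams write_schedule_events
#' @return the JSON string, invisibly.
#' @export
write_schedule_json <- function(schedule, path) {
  x <- schedule[setdiff(names(schedule), "waveform")]
  x$protocol <- if (!is.null(x$protocol)) unclass(x$protocol)
  js <- jsonlite::toJSON(unclass(x), dataframe = "columns", auto_unbox = TRUE,
                         digits = NA, null = "null")
  writeLines(js, path)
  invisible(js)
}
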