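# ERP analysis: trial averaging and P1/N1/P2 peak extraction.

#' Average an epoch set into an ERP waveform
#'
#' Pointwise mean across trials (flagged trials are excluded only in strict
#' mode, mirroring an examine-but-keep artifact policy).
#'
#' @param epochs a baselined, detrended `epoch_set`.
#' @param channel channel name (e.g. `"AC"` or `"FC"`).
#' @param strict exclude trials flagged by [screen_artifacts()].
#' @return an object of class `erp_waveform` (`time_ms`, `mean_uv`,
#'   `n_trials`, `channel`).
#' @export
average_erp <- function(epochs, channel = "AC", strict = FALSE) {
  if (!channel %in% names(epochs$channels))
    stop_invalid("unknown channel ", channel)
  if (!isTRUE(epochs$baselined) || !isTRUE(epochs$detrended))
    warning("averaging epochs that are not baselined and detrended")
  keep <- if (strict) !epochs$rejected else rep(TRUE, length(epochs$rejected))
  if (!any(keep)) stop_invalid("no usable trials to average")
  m <- epochs$channels[[channel]][keep, , drop = FALSE]
  structure(list(channel = channel, time_ms = epochs$times_ms,
                 mean_uv = colMeans(m), n_trials = nrow(m)),
            class = "erp_waveform")
}

#' Default P1/N1/P2 search windows (ms after sound onset)
#'
#' @return named list of `c(start, end)` windows.
#' @export
default_peak_windows <- function() {
  list(P1 = c(10, 50), N1 = c(30, 100), P2 = c(80, 250))
}

#' Extract P1/N1/P2 amplitudes and latencies from an average ERP
#'
#' P1 is the maximum in its window, N1 the minimum, P2 the maximum;
#' amplitudes are read from the baseline-corrected average (baseline-to-peak
#' convention) and latency is the time of the extremum, ties broken toward
#' the earlier latency.  When user-supplied windows overlap, the ordering
#' P1 < N1 < P2 is enforced by starting each search strictly after the
#' previous peak.
#'
#' @param erp an `erp_waveform`.
#' @param windows named list of `c(start, end)` search windows in ms; must
#'   be ordered (increasing starts and ends) and inside the epoch.
#' @return an object of class `erp_peaks`: data frame with `wave`,
#'   `amplitude_uv`, `latency_ms`.
#' @export
detect_peaks <- function(erp, windows = default_peak_windows()) {
  stopifnot(inherits(erp, "erp_waveform"))
  if (!identical(names(windows), c("P1", "N1", "P2")))
    stop_invalid("windows must be named P1, N1, P2")
  starts <- vapply(windows, `[`, numeric(1), 1)
  ends <- vapply(windows, `[`, numeric(1), 2)
  if (any(diff(starts) <= 0) || any(diff(ends) <= 0) || any(ends <= starts))
    stop_invalid("windows must be increasing and non-degenerate")
  if (min(starts) < min(erp$time_ms) || max(ends) > max(erp$time_ms))
    stop_invalid("search windows fall outside the epoch")

  find <- function(win, fun, after_ms) {
    sel <- which(erp$time_ms >= max(win[1], after_ms) & erp$time_ms <= win[2])
    if (!length(sel)) stop_invalid("empty search window after ordering constraint")
    i <- sel[fun(erp$mean_uv[sel])]
    c(amp = erp$mean_uv[i], lat = erp$time_ms[i])
  }
  p1 <- find(windows$P1, which.max, -Inf)
  n1 <- find(windows$N1, which.min, p1["lat"] + 1e-9)
  p2 <- find(windows$P2, which.max, n1["lat"] + 1e-9)
  out <- data.frame(wave = c("P1", "N1", "P2"),
                    amplitude_uv = c(p1["amp"], n1["amp"], p2["amp"]),
                    latency_ms = c(p1["lat"], n1["lat"], p2["lat"]),
                    row.names = NULL)
  structure(out, class = c("erp_peaks", "data.frame"), windows = windows,
            channel = erp$channel)
}

#' Long-format ERP group table
#'
#' One row per subject x channel x wave, carrying the cohort factors;
#' subjects with missing peaks are excluded with a warning.
#'
#' @param results list with one element per subject: `list(spec =
#'   subject_spec, peaks = list(AC = erp_peaks, FC = erp_peaks))`.
#' @return data frame with columns `subject`, `genotype`, `sex`,
#'   `age_group`, `channel`, `wave`, `amplitude_uv`, `latency_ms`.
#' @export
erp_group_table <- function(results) {
  rows <- list()
  for (s in results) {
    if (is.null(s$peaks) || !length(s$peaks)) {
      warning("subject ", s$spec$subject_id, " has no peaks; excluded")
      next
    }
    for (ch in names(s$peaks)) {
      pk <- s$peaks[[ch]]
      rows[[length(rows) + 1L]] <-
        data.frame(subject = s$spec$subject_id, genotype = s$spec$genotype,
                   sex = s$spec$sex, age_group = s$spec$age_group,
                   channel = ch, wave = pk$wave,
                   amplitude_uv = pk$amplitude_uv, latency_ms = pk$latency_ms)
    }
  }
  do.call(rbind, rows)
}
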