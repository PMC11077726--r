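# Time-frequency decomposition via complex Morlet wavelets and inter-trial
# phase clustering (ITPC), grouped by parametric pair, with the 40 Hz
# summary statistic.

#' Morlet wavelet transform parameters
#'
#' The default frequency grid spans 10-100 Hz in `n_freqs` log-spaced steps
#' with the nearest step snapped to exactly 40 Hz.  The dynamic cycle rule
#' increases the wavelet cycle count linearly from 3 cycles at 10 Hz to 8 at
#' 100 Hz, trading temporal for spectral precision as frequency rises.
#'
#' @param freqs_hz frequencies in Hz (must include 40).
#' @param cycles per-frequency cycle counts; default: the dynamic rule.
#' @param edge_pad_ms margin at each epoch edge flagged invalid (wavelet
#'   bleed-in); the effective margin at each frequency is the larger of this
#'   and the wavelet half-support.
#' @param n_freqs grid size when `freqs_hz` is NULL.
#' @return an object of class `morlet_params`.
#' @export
morlet_params <- function(freqs_hz = NULL, cycles = NULL, edge_pad_ms = 100,
                          n_freqs = 31) {
  if (is.null(freqs_hz)) {
    freqs_hz <- exp(seq(log(10), log(100), length.out = n_freqs))
    freqs_hz[which.min(abs(freqs_hz - 40))] <- 40
  }
  if (any(freqs_hz <= 0)) stop_invalid("frequencies must be positive")
  if (!any(abs(freqs_hz - 40) < 1e-9))
    stop_invalid("the frequency grid must include 40 Hz")
  if (is.null(cycles)) cycles <- pmax(1, 3 + 5 * (freqs_hz - 10) / 90)
  if (length(cycles) == 1L) cycles <- rep(cycles, length(freqs_hz))
  if (length(cycles) != length(freqs_hz) || any(cycles < 1))
    stop_invalid("cycles must be >= 1, one per frequency")
  structure(list(freqs_hz = freqs_hz, cycles = cycles,
                 edge_pad_ms = edge_pad_ms),
            class = "morlet_params")
}

#' Complex Morlet wavelet transform of epoched data
#'
#' Convolves each trial with unit-energy complex Morlet wavelets (Gaussian
#' SD `cycles / (2 pi f)`, truncated at 4 SD).  Time-frequency points closer
#' to an epoch edge than the effective margin (`max(edge_pad, half
#' support)`) are flagged invalid.
#'
#' @param x an `epoch_set` (with `channel`) or a trials-x-samples numeric
#'   matrix (with `sample_rate_hz`).
#' @param params a [morlet_params()].
#' @param channel channel name when `x` is an `epoch_set`.
#' @param sample_rate_hz sampling rate when `x` is a matrix.
#' @return an object of class `morlet_coefs`: complex coefficients
#'   (trials x freqs x times), the axes, and a freqs-x-times validity mask.
#' @export
morlet_transform <- function(x, params = morlet_params(), channel = NULL,
                             sample_rate_hz = NULL) {
  if (inherits(x, "epoch_set")) {
    channel <- channel %||% names(x$channels)[1]
    m <- x$channels[[channel]]
    fs <- x$sample_rate_hz
    times_ms <- x$times_ms
  } else {
    m <- as.matrix(x)
    fs <- sample_rate_hz %||% stop_invalid("sample_rate_hz required for matrix input")
    times_ms <- (seq_len(ncol(m)) - 1) / fs * 1000
  }
  ntr <- nrow(m)
  ns <- ncol(m)
  sd_t <- params$cycles / (2 * pi * params$freqs_hz)
  half <- ceiling(4 * sd_t * fs)
  if (max(2 * half + 1) > ns)
    stop_invalid("epoch too short for the lowest frequency's wavelet support")
  nf <- length(params$freqs_hz)
  nfft <- stats::nextn(ns + max(2 * half + 1) - 1, 2)
  Xf <- stats::mvfft(rbind(t(m), matrix(0, nfft - ns, ntr)))
  pad_samp <- ms_to_samples(params$edge_pad_ms, fs)
  coefs <- array(NA_complex_, dim = c(ntr, nf, ns))
  valid <- matrix(FALSE, nf, ns)
  for (i in seq_len(nf)) {
    L <- half[i]
    tw <- (-L:L) / fs
    w <- exp(2i * pi * params$freqs_hz[i] * tw) * exp(-tw^2 / (2 * sd_t[i]^2))
    w <- w / sqrt(sum(Mod(w)^2))
    Wf <- stats::fft(c(w, rep(0 + 0i, nfft - length(w))))
    conv <- stats::mvfft(Xf * Wf, inverse = TRUE) / nfft
    coefs[, i, ] <- t(conv[L + seq_len(ns), , drop = FALSE])
    margin <- max(pad_samp, L)
    valid[i, ] <- seq_len(ns) > margin & seq_len(ns) <= ns - margin
  }
  structure(list(coefs = coefs, freqs_hz = params$freqs_hz,
                 times_ms = times_ms, valid = valid, channel = channel,
                 params = params),
            class = "morlet_coefs")
}

#' Phase angles of Morlet coefficients
#'
#' @param coefs a `morlet_coefs` object.
#' @return trials x freqs x times array of angles in `(-pi, pi]`, with the
#'   axes attached as attributes (class `phase_tensor`).
#' @export
phase_tensor <- function(coefs) {
  stopifnot(inherits(coefs, "morlet_coefs"))
  structure(Arg(coefs$coefs), freqs_hz = coefs$freqs_hz,
            times_ms = coefs$times_ms, valid = coefs$valid,
            class = "phase_tensor")
}

#' Inter-trial phase clustering
#'
#' `ITPC(t, f) = | mean_k exp(i phi_k(t, f)) |` over the `N` trials `k`: the
#' length of the mean of the unit phase vectors.  1 means every trial has
#' the same phase angle; uniform random phases give values near 0 (with a
#' small positive finite-sample bias of about `sqrt(pi) / (2 sqrt(N))`).
#' Independent of per-trial amplitude.
#'
#' @param phases a `morlet_coefs` or `phase_tensor` object, or a plain
#'   numeric array of phase angles whose first dimension indexes trials.
#' @return for wavelet-derived input, an `itpc_surface` (freqs-x-times ITPC
#'   matrix plus axes, validity mask and trial count); for plain numeric
#'   input, a numeric result with the trial dimension dropped.
#' @export
compute_itpc <- function(phases) {
  meta <- NULL
  if (inherits(phases, "morlet_coefs")) {
    meta <- phases
    tensor <- Arg(phases$coefs)
  } else if (inherits(phases, "phase_tensor")) {
    meta <- attributes(phases)
    tensor <- unclass(phases)
  } else {
    tensor <- phases
  }
  n <- if (is.null(dim(tensor))) length(tensor) else dim(tensor)[1]
  if (n < 2) stop_invalid("ITPC requires at least 2 trials")
  z <- exp(1i * tensor)
  r <- if (is.null(dim(tensor))) Mod(mean(z)) else Mod(colMeans(z))
  if (is.null(meta)) return(r)
  freqs <- if (inherits(meta, "morlet_coefs")) meta$freqs_hz else meta$freqs_hz
  times <- if (inherits(meta, "morlet_coefs")) meta$times_ms else meta$times_ms
  valid <- if (inherits(meta, "morlet_coefs")) meta$valid else meta$valid
  structure(list(itpc = matrix(r, nrow = length(freqs)), freqs_hz = freqs,
                 times_ms = times, valid = valid, n_trials = n,
                 channel = if (inherits(meta, "morlet_coefs")) meta$channel),
            class = "itpc_surface")
}

#' Summarize an ITPC surface at one frequency over a time window
#'
#' @param surface an `itpc_surface`.
#' @param freq_hz frequency row to read (default 40).
#' @param window_ms averaging window in ms; intersected with the valid
#'   (non-edge) region.
#' @param bias_correct apply the Rayleigh-based small-sample correction
#'   `sqrt(max(0, (N r^2 - 1) / (N - 1)))` before averaging (off by
#'   default; plain ITPC is reported).
#' @return mean ITPC (scalar).
#' @export
itpc_at <- function(surface, freq_hz = 40, window_ms = c(50, 250),
                    bias_correct = FALSE) {
  fi <- which.min(abs(surface$freqs_hz - freq_hz))
  if (abs(surface$freqs_hz[fi] - freq_hz) > 1e-6)
    stop_invalid("frequency ", freq_hz, " Hz is not on the grid")
  sel <- surface$valid[fi, ] & surface$times_ms >= window_ms[1] &
    surface$times_ms <= window_ms[2]
  if (!any(sel)) stop_invalid("no valid samples in the summary window")
  r <- surface$itpc[fi, sel]
  if (bias_correct) {
    n <- surface$n_trials
    r <- sqrt(pmax(0, (n * r^2 - 1) / (n - 1)))
  }
  mean(r)
}

#' Mean 40 Hz ITPC per parametric pair
#'
#' Groups trials by (gap width, modulation depth), computes the ITPC surface
#' for each group and averages the 40 Hz row over the response window.
#' Emits one warning listing any pair below the expected trial count.
#'
#' @param epochs an `epoch_set` of gapped-segment epochs whose event table
#'   carries `gap_width_ms` and `mod_depth_pct`.
#' @param channel channel to analyse.
#' @param params a [morlet_params()].
#' @param window_ms 40 Hz averaging window, ms from segment onset.
#' @param pairs data frame of pairs to report (default: all present);
#'   requesting a pair absent from the epochs is an error.
#' @param strict drop trials flagged by [screen_artifacts()].
#' @param min_trials_warn warn when a pair has fewer trials than this.
#' @param bias_correct see [itpc_at()].
#' @param keep_surfaces attach the per-pair `itpc_surface` objects.
#' @return an `itpc_summary` data frame: `gap_width_ms`, `mod_depth_pct`,
#'   `n_trials`, `itpc`.
#' @export
itpc_by_pair <- function(epochs, channel = "AC", params = morlet_params(),
                         window_ms = c(50, 250), pairs = NULL,
                         strict = FALSE, min_trials_warn = 100,
                         bias_correct = FALSE, keep_surfaces = FALSE) {
  ev <- epochs$events
  if (is.null(ev$gap_width_ms) || is.null(ev$mod_depth_pct))
    stop_invalid("epoch events carry no parametric-pair labels")
  keep <- if (strict) !epochs$rejected else rep(TRUE, nrow(ev))
  ev_key <- pair_key(ev$gap_width_ms, ev$mod_depth_pct)
  present <- unique(ev_key[keep])
  if (is.null(pairs)) {
    pairs <- unique(ev[keep, c("gap_width_ms", "mod_depth_pct")])
    pairs <- pairs[order(pairs$mod_depth_pct, pairs$gap_width_ms), , drop = FALSE]
  }
  want_key <- pair_key(pairs$gap_width_ms, pairs$mod_depth_pct)
  if (any(!want_key %in% present))
    stop_invalid("pair(s) absent from epochs: ",
                 paste(setdiff(want_key, present), collapse = ", "))

  m <- epochs$channels[[channel]]
  surfaces <- list()
  out <- pairs
  out$n_trials <- NA_integer_
  out$itpc <- NA_real_
  for (i in seq_len(nrow(pairs))) {
    idx <- which(keep & ev_key == want_key[i])
    sub <- epochs
    sub$channels <- list(m[idx, , drop = FALSE])
    names(sub$channels) <- channel
    sub$rejected <- rep(FALSE, length(idx))
    coefs <- morlet_transform(sub, params, channel = channel)
    surf <- compute_itpc(coefs)
    out$n_trials[i] <- length(idx)
    out$itpc[i] <- itpc_at(surf, 40, window_ms, bias_correct = bias_correct)
    if (keep_surfaces) surfaces[[want_key[i]]] <- surf
  }
  low <- out$n_trials < min_trials_warn
  if (any(low))
    warning("pair(s) below ", min_trials_warn, " trials: ",
            paste(sprintf("%s (n=%d)", want_key[low], out$n_trials[low]),
                  collapse = ", "))
  structure(out, class = c("itpc_summary", "data.frame"),
            channel = channel, window_ms = window_ms,
            bias_correct = bias_correct,
            surfaces = if (keep_surfaces) surfaces)
}

#' Long-format ITPC group table
#'
#' One row per subject x channel x parametric pair.
#'
#' @param results list with one element per subject: `list(spec =
#'   subject_spec, itpc = list(AC = itpc_summary, FC = itpc_summary))`.
#' @return data frame with the cohort factors, `gap_width_ms`,
#'   `mod_depth_pct`, `n_trials` and `itpc`.
#' @export
itpc_group_table <- function(results) {
  rows <- list()
  for (s in results) {
    for (ch in names(s$itpc)) {
      tab <- s$itpc[[ch]]
      rows[[length(rows) + 1L]] <-
        data.frame(subject = s$spec$subject_id, genotype = s$spec$genotype,
                   sex = s$spec$sex, age_group = s$spec$age_group,
                   channel = ch, gap_width_ms = tab$gap_width_ms,
                   mod_depth_pct = tab$mod_depth_pct,
                   n_trials = tab$n_trials, itpc = tab$itpc)
    }
  }
  do.call(rbind, rows)
}

#' Collapse an ITPC table across gap widths
#'
#' Per-subject mean ITPC over the six gap widths at fixed modulation depth
#' (the gap-collapsed summary used for age-wise group contrasts).
#'
#' @param itpc_table output of [itpc_group_table()].
#' @return data frame with one row per subject x channel x depth.
#' @export
collapse_gaps <- function(itpc_table) {
  agg <- stats::aggregate(
    list(itpc = itpc_table$itpc),
    by = list(subject = itpc_table$subject, genotype = itpc_table$genotype,
              sex = itpc_table$sex, age_group = itpc_table$age_group,
              channel = itpc_table$channel,
              mod_depth_pct = itpc_table$mod_depth_pct),
    FUN = mean)
  agg[order(agg$channel, agg$mod_depth_pct, agg$subject), , drop = FALSE]
}
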