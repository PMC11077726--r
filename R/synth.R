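# Synthetic two-channel EEG generator: 1/f background noise, Gaussian-windowed
# evoked components locked to ERP onsets, and 40 Hz oscillatory bursts locked
# to gapped segments with von Mises phase jitter across trials.

#' Subject metadata
#'
#' @param subject_id label.
#' @param genotype `"WT"` or `"KO"`.
#' @param sex `"M"` or `"F"`.
#' @param age_group `"p21"`, `"p30"` or `"p60"`.
#' @return an object of class `subject_spec`.
#' @export
subject_spec <- function(subject_id, genotype, sex, age_group) {
  genotype <- match.arg(genotype, c("WT", "KO"))
  sex <- match.arg(sex, c("M", "F"))
  age_group <- match.arg(age_group, c("p21", "p30", "p60"))
  structure(list(subject_id = as.character(subject_id), genotype = genotype,
                 sex = sex, age_group = age_group),
            class = "subject_spec")
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler.  `kappa = 0` reduces to the uniform
#' distribution on the circle.
#'
#' @param n number of draws.
#' @param mu mean direction in radians.
#' @param kappa concentration parameter, >= 0.
#' @return angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu = 0, kappa) {
  if (!is.numeric(kappa) || length(kappa) != 1L || is.na(kappa) || kappa < 0)
    stop_invalid("kappa must be a single non-negative number")
  if (n == 0) return(numeric(0))
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    z <- cos(pi * stats::runif(m))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(m)
    keep <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    f <- f[keep]
    if (length(f)) {
      th <- sign(stats::runif(length(f)) - 0.5) * acos(pmin(pmax(f, -1), 1))
      out[got + seq_along(th)] <- th
      got <- got + length(th)
    }
  }
  wrap_angle(mu + out)
}

#' Population mean resultant length of a von Mises distribution
#'
#' Returns `A(kappa) = I1(kappa) / I0(kappa)`, the expected length of the
#' mean unit phase vector; this is the asymptotic ITPC of trials whose
#' phases are von Mises with concentration `kappa`.  `A(0) = 0`, `A` is
#' strictly increasing and tends to 1 as `kappa` grows.
#'
#' @param kappa concentration parameter(s), >= 0 (may be `Inf`).
#' @return values in `[0, 1)` (1 at `kappa = Inf`).
#' @export
kappa_to_expected_itpc <- function(kappa) {
  if (!is.numeric(kappa) || any(is.na(kappa)) || any(kappa < 0))
    stop_invalid("kappa must be non-negative")
  out <- numeric(length(kappa))
  inf <- is.infinite(kappa)
  out[inf] <- 1
  pos <- !inf & kappa > 0 & kappa <= 1e4
  # exponentially scaled Bessel ratio is stable up to moderate kappa
  out[pos] <- besselI(kappa[pos], 1, expon.scaled = TRUE) /
    besselI(kappa[pos], 0, expon.scaled = TRUE)
  big <- !inf & kappa > 1e4   # asymptotic expansion beyond Bessel range
  out[big] <- 1 - 1 / (2 * kappa[big]) - 1 / (8 * kappa[big]^2)
  out
}

#' Concentration giving a target mean resultant length
#'
#' Numerical inverse of [kappa_to_expected_itpc()] (Best-Fisher series start,
#' refined by root finding).
#'
#' @param r target mean resultant length(s) in `[0, 1)`.
#' @return kappa values, >= 0.
#' @export
kappa_from_itpc <- function(r) {
  if (any(r < 0 | r >= 1)) stop_invalid("r must lie in [0, 1)")
  vapply(r, function(ri) {
    if (ri == 0) return(0)
    k0 <- if (ri < 0.53) 2 * ri + ri^3 + 5 * ri^5 / 6
          else if (ri < 0.85) -0.4 + 1.39 * ri + 0.43 / (1 - ri)
          else 1 / (ri^3 - 4 * ri^2 + 3 * ri)
    stats::uniroot(function(k) kappa_to_expected_itpc(k) - ri,
                   interval = c(max(k0 / 10, 1e-8), k0 * 10 + 1),
                   extendInt = "upX", tol = 1e-10)$root
  }, numeric(1))
}

#' Synthesize 1/f^alpha background noise
#'
#' Spectral shaping of Gaussian white noise: DFT amplitudes are scaled by
#' `f^(-alpha/2)` (DC removed) and the result rescaled to the requested RMS.
#'
#' @param n number of samples.
#' @param sample_rate_hz sampling rate in Hz.
#' @param alpha spectral exponent (power ~ 1/f^alpha); default 1.
#' @param rms_uv target root-mean-square amplitude in microvolts.
#' @param seed optional integer seed.
#' @return numeric vector of length `n`.
#' @export
one_over_f_noise <- function(n, sample_rate_hz, alpha = 1, rms_uv = 1,
                             seed = NULL) {
  with_seed(seed, one_over_f_noise_pair(n, sample_rate_hz, alpha, rms_uv))[[1]]
}

# two independent 1/f^alpha channels from one complex FFT: the real and
# imaginary parts of a circularly symmetric spectrum are independent
one_over_f_noise_pair <- function(n, sample_rate_hz, alpha = 1, rms_uv = 1) {
  m <- stats::nextn(n)   # FFT-friendly synthesis length, truncated to n
  z <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
  f <- (seq_len(m) - 1) * sample_rate_hz / m
  f <- pmin(f, sample_rate_hz - f)
  h <- numeric(m)
  h[f > 0] <- f[f > 0]^(-alpha / 2)
  w <- stats::fft(stats::fft(z) * h, inverse = TRUE)[seq_len(n)] / m
  lapply(list(Re(w), Im(w)), function(x) x * rms_uv / sqrt(mean(x^2)))
}

#' Neural forward-model parameters for one recording channel
#'
#' @param erp_components data frame with columns `wave` (P1/N1/P2),
#'   `polarity` (+1 or -1; P1 and P2 positive, N1 negative), `latency_ms`,
#'   `amplitude_uv` (>= 0), `width_ms` (Gaussian SD of the deflection, > 0)
#'   and `trial_jitter_sd` (SD of the multiplicative log-normal per-trial
#'   amplitude jitter).
#' @param assr_kappa data frame mapping (`gap_width_ms`, `mod_depth_pct`) to
#'   the von Mises concentration `kappa` (>= 0, finite) of the per-segment
#'   phase of the 40 Hz gap-evoked burst.
#' @param assr_amplitude_uv amplitude of the 40 Hz burst in microvolts.
#' @param noise_exponent spectral exponent alpha of the 1/f^alpha background.
#' @param noise_rms_uv background noise RMS in microvolts.
#' @return an object of class `channel_model`.
#' @export
channel_model <- function(erp_components, assr_kappa, assr_amplitude_uv = 4,
                          noise_exponent = 1, noise_rms_uv = 15) {
  stopifnot(is.data.frame(erp_components),
            all(c("wave", "polarity", "latency_ms", "amplitude_uv",
                  "width_ms", "trial_jitter_sd") %in% names(erp_components)))
  if (any(erp_components$width_ms <= 0)) stop_invalid("widths must be positive")
  if (any(erp_components$amplitude_uv < 0)) stop_invalid("amplitudes must be >= 0")
  pol_ok <- ifelse(erp_components$wave == "N1",
                   erp_components$polarity == -1, erp_components$polarity == 1)
  if (!all(pol_ok))
    stop_invalid("P1/P2 must have polarity +1 and N1 polarity -1")
  if (!is.null(assr_kappa)) {
    stopifnot(is.data.frame(assr_kappa),
              all(c("gap_width_ms", "mod_depth_pct", "kappa") %in% names(assr_kappa)))
    if (any(!is.finite(assr_kappa$kappa)) || any(assr_kappa$kappa < 0))
      stop_invalid("kappa values must be finite and >= 0")
  }
  structure(list(erp_components = erp_components, assr_kappa = assr_kappa,
                 assr_amplitude_uv = assr_amplitude_uv,
                 noise_exponent = noise_exponent, noise_rms_uv = noise_rms_uv),
            class = "channel_model")
}

#' @rdname channel_model
#' @param AC,FC `channel_model` objects for the auditory and frontal channel.
#' @export
neural_model_params <- function(AC, FC) {
  stopifnot(inherits(AC, "channel_model"), inherits(FC, "channel_model"))
  structure(list(AC = AC, FC = FC), class = "neural_model_params")
}

#' Default P1/N1/P2 component set
#'
#' Baseline adult auditory-cortex component parameters; amplitudes in
#' microvolts, latencies and Gaussian widths in ms.
#'
#' @param scale multiplier applied to all amplitudes.
#' @param n1_scale,p2_scale extra multipliers for N1 / P2.
#' @param jitter_sd per-trial log-normal amplitude jitter SD.
#' @return data frame suitable for [channel_model()].
#' @export
default_erp_components <- function(scale = 1, n1_scale = 1, p2_scale = 1,
                                   jitter_sd = 0.1) {
  data.frame(wave = c("P1", "N1", "P2"),
             polarity = c(1, -1, 1),
             latency_ms = c(25, 60, 150),
             amplitude_uv = c(12 * scale, 18 * scale * n1_scale,
                              9 * scale * p2_scale),
             width_ms = c(5, 10, 25),
             trial_jitter_sd = jitter_sd)
}

# target mean ITPC curves used to derive preset kappa values; a qualitative
# emulation of the study's direction of effects, not ground-truth values.
preset_target_itpc <- function(gap_width_ms, mod_depth_pct, age_group,
                               region, genotype, sex) {
  r <- 0.12 + 0.45 * (gap_width_ms / 12)^0.7
  r <- r * ifelse(mod_depth_pct == 100, 1, 0.85)
  r <- r * c(p21 = 0.70, p30 = 0.85, p60 = 1.00)[[age_group]]
  if (region == "FC") r <- r * 0.8
  deficit <- genotype == "KO" && region == "FC" &&
    ((sex == "F" && age_group == "p21") ||
     (sex == "M" && age_group %in% c("p21", "p30")))
  if (deficit) r <- r * 0.45
  r
}

#' Cohort parameter presets (qualitative emulation)
#'
#' Generator presets for the eight genotype x sex cells across the three
#' ages.  The presets qualitatively emulate the direction of the reported
#' group differences -- frontal-cortex phase-locking deficits in KO females
#' at p21 and KO males at p21/p30, no auditory-cortex genotype differences,
#' no WT sex differences, and ERP amplitudes that grow faster with age in
#' KO animals (largest KO-WT gap at p60, with adult KO females exceeding KO
#' males on N1/P2).  The numeric values are package conventions, not
#' measured group values.
#'
#' @return named list (`"WT.F.p21"`, ...) of [neural_model_params()].
#' @export
cohort_presets <- function() {
  cells <- expand.grid(genotype = c("WT", "KO"), sex = c("M", "F"),
                       age_group = c("p21", "p30", "p60"),
                       stringsAsFactors = FALSE)
  wt_age_scale <- c(p21 = 0.70, p30 = 0.85, p60 = 1.00)
  ko_age_scale <- c(p21 = 0.80, p30 = 1.10, p60 = 1.50)
  out <- list()
  for (i in seq_len(nrow(cells))) {
    g <- cells$genotype[i]; s <- cells$sex[i]; a <- cells$age_group[i]
    amp_scale <- if (g == "WT") wt_age_scale[[a]] else ko_age_scale[[a]]
    n1s <- p2s <- 1
    if (g == "KO" && s == "F" && a == "p60") n1s <- p2s <- 1.25
    chans <- lapply(c("AC", "FC"), function(region) {
      comp <- default_erp_components(scale = amp_scale *
                                       if (region == "FC") 0.9 else 1,
                                     n1_scale = n1s, p2_scale = p2s)
      grid <- default_pairs()
      r <- mapply(preset_target_itpc, grid$gap_width_ms, grid$mod_depth_pct,
                  MoreArgs = list(age_group = a, region = region,
                                  genotype = g, sex = s))
      grid$kappa <- kappa_from_itpc(r)
      channel_model(comp, grid)
    })
    out[[paste(g, s, a, sep = ".")]] <- neural_model_params(chans[[1]], chans[[2]])
  }
  out
}

#' @rdname cohort_presets
#' @param genotype,sex,age_group cell labels.
#' @param presets preset list (default [cohort_presets()]).
#' @export
preset_for <- function(genotype, sex, age_group, presets = cohort_presets()) {
  key <- paste(genotype, sex, age_group, sep = ".")
  if (is.null(presets[[key]])) stop_invalid("no preset for cell ", key)
  presets[[key]]
}

# look up kappa for each row of a (gap, depth) pair frame; configuration
# error if a pair present in the schedule has no kappa entry
lookup_kappa <- function(kappa_tab, gap, depth) {
  key <- pair_key(gap, depth)
  tab_key <- pair_key(kappa_tab$gap_width_ms, kappa_tab$mod_depth_pct)
  idx <- match(key, tab_key)
  if (any(is.na(idx)))
    stop_invalid("no kappa configured for pair(s): ",
                 paste(unique(key[is.na(idx)]), collapse = ", "))
  kappa_tab$kappa[idx]
}

#' Simulate a two-channel EEG recording for one session
#'
#' Each channel is the sum of 1/f background noise, Gaussian-windowed
#' P1/N1/P2 deflections at every ERP onset (with multiplicative log-normal
#' per-trial amplitude jitter), and one 40 Hz sinusoidal burst spanning each
#' gapped segment whose phase offset is drawn von Mises(0, kappa(pair)) --
#' so trial-to-trial phase jitter operates at the segment (= trial) level.
#' TTL-style event times are copied from the schedule.
#'
#' @param subject a [subject_spec()].
#' @param schedule a [make_gap_assr_session()] or [make_erp_session()] schedule.
#' @param params [neural_model_params()] for this subject.
#' @param seed optional integer seed.
#' @param sample_rate_hz native simulation rate in Hz (default 4096).
#' @param tail_s extra recording time after the last event, seconds.
#' @return an object of class `eeg_recording` with channels `AC`, `FC` (in
#'   microvolts), an `events` table and the subject metadata.
#' @export
simulate_recording <- function(subject, schedule, params, seed = NULL,
                               sample_rate_hz = 4096, tail_s = 1) {
  stopifnot(inherits(subject, "subject_spec"),
            inherits(schedule, "stimulus_schedule"),
            inherits(params, "neural_model_params"))
  n <- ceiling((schedule$duration_s + tail_s) * sample_rate_hz)
  gapped <- schedule$segments[schedule$segments$kind == "gapped", , drop = FALSE]
  if (nrow(gapped) > 0 && is.null(params$AC$assr_kappa))
    stop_invalid("schedule contains gapped segments but no kappa is configured")

  with_seed(seed, {
    # one complex FFT yields both channels' independent background noise
    # when the channels share a spectral exponent (the usual case)
    shared_noise <- NULL
    if (params$AC$noise_rms_uv > 0 && params$FC$noise_rms_uv > 0 &&
        params$AC$noise_exponent == params$FC$noise_exponent) {
      shared_noise <- one_over_f_noise_pair(n, sample_rate_hz,
                                            params$AC$noise_exponent)
    }
    channels <- lapply(seq_along(params), function(ci) {
      ch <- params[[ci]]
      x <- if (!is.null(shared_noise)) {
        shared_noise[[ci]] * ch$noise_rms_uv
      } else if (ch$noise_rms_uv > 0) {
        one_over_f_noise(n, sample_rate_hz, ch$noise_exponent, ch$noise_rms_uv)
      } else numeric(n)

      # evoked P1/N1/P2 deflections at ERP onsets
      for (t0 in schedule$erp_onsets_s) {
        i0 <- round(t0 * sample_rate_hz)
        for (j in seq_len(nrow(ch$erp_components))) {
          cmp <- ch$erp_components[j, ]
          sd_samp <- cmp$width_ms / 1000 * sample_rate_hz
          half <- ceiling(4 * sd_samp)
          centre <- i0 + round(cmp$latency_ms / 1000 * sample_rate_hz)
          idx <- max(1, centre - half):min(n, centre + half)
          amp <- cmp$polarity * cmp$amplitude_uv *
            exp(stats::rnorm(1, 0, cmp$trial_jitter_sd))
          x[idx] <- x[idx] + amp * exp(-0.5 * ((idx - centre) / sd_samp)^2)
        }
      }

      # 40 Hz bursts spanning each gapped segment, common phase per segment
      if (nrow(gapped) > 0 && ch$assr_amplitude_uv > 0) {
        kappa <- lookup_kappa(ch$assr_kappa, gapped$gap_width_ms,
                              gapped$mod_depth_pct)
        phi <- numeric(nrow(gapped))
        for (k in unique(kappa)) {
          sel <- kappa == k
          phi[sel] <- rvonmises(sum(sel), 0, k)
        }
        nseg <- ms_to_samples(250, sample_rate_hz)
        tloc <- (seq_len(nseg) - 1) / sample_rate_hz
        cw <- cos(2 * pi * 40 * tloc)
        sw <- sin(2 * pi * 40 * tloc)
        burst <- outer(cw, cos(phi)) - outer(sw, sin(phi))  # nseg x nsegments
        i0 <- round(gapped$start_s * sample_rate_hz)
        idx <- outer(seq_len(nseg), i0, `+`)
        x[idx] <- x[idx] + ch$assr_amplitude_uv * as.vector(burst)
      }
      x
    })
    names(channels) <- names(params)

    events <- rbind(
      if (length(schedule$erp_onsets_s) > 0)
        data.frame(time_s = schedule$erp_onsets_s, label = "erp",
                   gap_width_ms = NA_real_, mod_depth_pct = NA_real_),
      if (nrow(gapped) > 0)
        data.frame(time_s = gapped$start_s,
                   label = pair_key(gapped$gap_width_ms, gapped$mod_depth_pct),
                   gap_width_ms = gapped$gap_width_ms,
                   mod_depth_pct = gapped$mod_depth_pct))
    events <- events[order(events$time_s), , drop = FALSE]

    structure(list(sample_rate_hz = sample_rate_hz,
                   channels = channels, events = events,
                   session = schedule$kind, subject = subject,
                   n_samples = n),
              class = "eeg_recording")
  })
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording: %s %s/%s/%s, %s session, %.1f s @ %g Hz, %d events>\n",
              x$subject$subject_id, x$subject$genotype, x$subject$sex,
              x$subject$age_group, x$session,
              x$n_samples / x$sample_rate_hz, x$sample_rate_hz,
              nrow(x$events)))
  invisible(x)
}

#' Default cohort design
#'
#' Female cell sizes follow the study (WT 11/9/8 and KO 8/9/8 at
#' p21/p30/p60); male cell sizes default to 9 per cell (the male cohort is
#' described in a companion dataset whose per-cell sizes are not restated
#' here).
#'
#' @param sexes which sexes to include, subset of `c("F", "M")`.
#' @param male_n per-cell n for male cells.
#' @return data frame with `genotype`, `sex`, `age_group`, `n`.
#' @export
default_cohort_design <- function(sexes = "F", male_n = 9) {
  ages <- c("p21", "p30", "p60")
  out <- list()
  if ("F" %in% sexes) {
    out$f <- data.frame(genotype = rep(c("WT", "KO"), each = 3),
                        sex = "F", age_group = rep(ages, 2),
                        n = c(11, 9, 8, 8, 9, 8))
  }
  if ("M" %in% sexes) {
    out$m <- data.frame(genotype = rep(c("WT", "KO"), each = 3),
                        sex = "M", age_group = rep(ages, 2),
                        n = male_n)
  }
  do.call(rbind, out)
}

#' Simulate a full cohort of ERP and gap-ASSR recordings
#'
#' One ERP session and/or one gap-ASSR session per synthetic subject, with
#' per-subject sub-seeds derived deterministically from the master seed.
#'
#' @param design data frame with `genotype`, `sex`, `age_group`, `n`.
#' @param seed master integer seed.
#' @param sessions which sessions to simulate (`"erp"`, `"assr"` or both).
#' @param n_trials_per_pair gapped-segment count per parametric pair.
#' @param sample_rate_hz native simulation rate in Hz.
#' @param protocol ERP protocol (default [erp_protocol()]).
#' @param presets preset list (default [cohort_presets()]).
#' @return an object of class `eeg_cohort`: a list of subjects, each with
#'   `spec`, `erp` and `assr` recordings.
#' @export
simulate_cohort <- function(design = default_cohort_design(), seed = 1,
                            sessions = c("erp", "assr"),
                            n_trials_per_pair = 101, sample_rate_hz = 4096,
                            protocol = erp_protocol(),
                            presets = cohort_presets()) {
  sessions <- match.arg(sessions, several.ok = TRUE)
  if (any(design$n < 1)) stop_invalid("design cell sizes must be >= 1")
  total <- sum(design$n)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, total * 3L))
  subjects <- vector("list", total)
  k <- 0L
  for (i in seq_len(nrow(design))) {
    cell <- design[i, ]
    par <- preset_for(cell$genotype, cell$sex, cell$age_group, presets)
    for (j in seq_len(cell$n)) {
      k <- k + 1L
      spec <- subject_spec(sprintf("%s.%s.%s.%02d", cell$genotype, cell$sex,
                                   cell$age_group, j),
                           cell$genotype, cell$sex, cell$age_group)
      erp_rec <- assr_rec <- NULL
      if ("erp" %in% sessions) {
        sched <- make_erp_session(protocol)
        erp_rec <- simulate_recording(spec, sched, par, seed = seeds[3 * k - 2],
                                      sample_rate_hz = sample_rate_hz)
      }
      if ("assr" %in% sessions) {
        sched <- make_gap_assr_session(n_trials_per_pair, seed = seeds[3 * k - 1])
        assr_rec <- simulate_recording(spec, sched, par, seed = seeds[3 * k],
                                       sample_rate_hz = sample_rate_hz)
      }
      subjects[[k]] <- list(spec = spec, erp = erp_rec, assr = assr_rec)
    }
  }
  structure(subjects, class = "eeg_cohort", design = design, seed = seed)
}

#' Cohort manifest table
#'
#' @param cohort an [simulate_cohort()] result.
#' @return data frame with one row per subject.
#' @export
cohort_manifest <- function(cohort) {
  do.call(rbind, lapply(cohort, function(s) {
    data.frame(subject = s$spec$subject_id, genotype = s$spec$genotype,
               sex = s$spec$sex, age_group = s$spec$age_group)
  }))
}
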