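# Synthetic EEG generator: von Mises machinery, noise spectrum, presets,
# component superposition and cohort reproducibility.

test_that("Bessel-ratio expected ITPC matches Monte Carlo and limits", {
  expect_equal(kappa_to_expected_itpc(0), 0)
  expect_equal(kappa_to_expected_itpc(Inf), 1)
  expect_gt(kappa_to_expected_itpc(1e6), 0.999)
  expect_error(kappa_to_expected_itpc(-1), "non-negative")

  # strictly increasing
  grid <- c(0, 0.5, 1, 2, 4, 8, 16)
  expect_true(all(diff(kappa_to_expected_itpc(grid)) > 0))

  # Monte Carlo cross-check of the Bessel ratio at kappa = 2
  set.seed(301)
  th <- rvonmises(2e5, 0, 2)
  expect_equal(mrl(th), kappa_to_expected_itpc(2), tolerance = 0.01)

  # kappa = 0: circular variance of draws is ~1
  set.seed(302)
  expect_lt(mrl(rvonmises(2000, 0, 0)), 0.06)

  # numerical inverse round-trips
  r <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  expect_equal(kappa_to_expected_itpc(kappa_from_itpc(r)), r,
               tolerance = 1e-8)
})

test_that("noise-free traces equal the scheduled components exactly", {
  comp <- data.frame(wave = "P1", polarity = 1, latency_ms = 25,
                     amplitude_uv = 12, width_ms = 5, trial_jitter_sd = 0)
  ch <- channel_model(comp, assr_kappa = NULL, assr_amplitude_uv = 0,
                      noise_rms_uv = 0)
  par <- neural_model_params(ch, ch)
  sched <- make_erp_session(erp_protocol(n_repetitions = 1), lead_in_s = 0.5)
  spec <- subject_spec("s", "WT", "F", "p21")
  fs <- 1024
  rec <- simulate_recording(spec, sched, par, seed = 1, sample_rate_hz = fs)

  # independent reconstruction of the single Gaussian deflection
  n <- rec$n_samples
  centre <- round(0.5 * fs) + round(25 / 1000 * fs)
  sd_samp <- 5 / 1000 * fs
  idx <- (centre - ceiling(4 * sd_samp)):(centre + ceiling(4 * sd_samp))
  expected <- numeric(n)
  expected[idx] <- 12 * exp(-0.5 * ((idx - centre) / sd_samp)^2)
  expect_equal(rec$channels$AC, expected, tolerance = 1e-12)

  # bit-level reproducibility under the seed
  rec2 <- simulate_recording(spec, sched, par, seed = 1, sample_rate_hz = fs)
  expect_identical(rec$channels$AC, rec2$channels$AC)
})

test_that("gap-evoked burst phases follow the configured concentration", {
  one_pair <- data.frame(gap_width_ms = 6, mod_depth_pct = 100)
  extract_phases <- function(kappa, n_seg, seed) {
    ch <- channel_model(default_erp_components()[0, ],
                        cbind(one_pair, kappa = kappa),
                        assr_amplitude_uv = 5, noise_rms_uv = 0)
    par <- neural_model_params(ch, ch)
    sched <- make_gap_assr_session(n_seg, seed = seed, pairs = one_pair)
    rec <- simulate_recording(subject_spec("s", "WT", "F", "p21"), sched,
                              par, seed = seed + 1, sample_rate_hz = 256)
    g <- sched$segments[sched$segments$kind == "gapped", ]
    tloc <- (seq_len(round(0.25 * 256)) - 1) / 256
    ref <- exp(-2i * pi * 40 * tloc)
    vapply(g$start_s, function(s0) {
      seg <- rec$channels$AC[round(s0 * 256) + seq_along(tloc)]
      Arg(sum(seg * ref))
    }, numeric(1))
  }
  # phase-extraction oracle over >= 1000 segments: kappa = 0 gives circular
  # variance ~ 1, kappa = 3 recovers the Bessel-ratio resultant length
  ph0 <- extract_phases(0, 1000, seed = 401)
  expect_gt(length(ph0), 999)
  expect_lt(mrl(ph0), 3 * sqrt(pi) / (2 * sqrt(length(ph0))) + 0.02)

  ph3 <- extract_phases(3, 1000, seed = 402)
  se <- sqrt((1 - kappa_to_expected_itpc(3)^2) / length(ph3))
  expect_equal(mrl(ph3), kappa_to_expected_itpc(3), tolerance = 3 * se + 0.01)
})

test_that("background noise spectrum follows the configured 1/f slope", {
  fs <- 512
  x <- one_over_f_noise(60 * fs, fs, alpha = 1, rms_uv = 10, seed = 21)
  expect_equal(sqrt(mean(x^2)), 10, tolerance = 1e-9)
  P <- Mod(stats::fft(x))^2
  f <- (seq_along(x) - 1) * fs / length(x)
  sel <- f >= 1 & f <= 100
  # log-log regression on octave-binned power
  bins <- cut(log2(f[sel]), breaks = 14)
  lp <- tapply(P[sel], bins, mean)
  lf <- tapply(f[sel], bins, mean)
  slope <- stats::coef(stats::lm(log(lp) ~ log(lf)))[2]
  expect_equal(unname(slope), -1, tolerance = 0.2)
})

test_that("cohort presets encode the documented qualitative directions", {
  pr <- cohort_presets()
  kap <- function(g, s, a, region) pr[[paste(g, s, a, sep = ".")]][[region]]$assr_kappa

  # FC deficit cells: KO female p21; KO male p21 and p30
  expect_true(all(kap("KO", "F", "p21", "FC")$kappa <
                    kap("WT", "F", "p21", "FC")$kappa))
  expect_true(all(kap("KO", "M", "p21", "FC")$kappa <
                    kap("WT", "M", "p21", "FC")$kappa))
  expect_true(all(kap("KO", "M", "p30", "FC")$kappa <
                    kap("WT", "M", "p30", "FC")$kappa))
  # KO female normalizes by p30
  expect_equal(kap("KO", "F", "p30", "FC")$kappa,
               kap("WT", "F", "p30", "FC")$kappa)

  for (a in c("p21", "p30", "p60")) {
    # AC matched across genotypes and no WT sex differences anywhere
    expect_equal(kap("KO", "F", a, "AC")$kappa, kap("WT", "F", a, "AC")$kappa)
    expect_equal(kap("WT", "M", a, "AC")$kappa, kap("WT", "F", a, "AC")$kappa)
    expect_equal(kap("WT", "M", a, "FC")$kappa, kap("WT", "F", a, "FC")$kappa)
  }

  # kappa valid and nondecreasing in gap width and modulation depth
  for (key in names(pr)) for (region in c("AC", "FC")) {
    k <- pr[[key]][[region]]$assr_kappa
    expect_true(all(is.finite(k$kappa)) && all(k$kappa >= 0))
    for (d in unique(k$mod_depth_pct)) {
      ord <- k[k$mod_depth_pct == d, ]
      ord <- ord[order(ord$gap_width_ms), ]
      expect_true(all(diff(ord$kappa) >= 0))
    }
    wide <- merge(k[k$mod_depth_pct == 75, ], k[k$mod_depth_pct == 100, ],
                  by = "gap_width_ms")
    expect_true(all(wide$kappa.y >= wide$kappa.x))
  }

  # ERP amplitudes: KO-WT gap grows with age, largest at p60; adult KO
  # females exceed KO males on N1/P2
  amp <- function(g, s, a) pr[[paste(g, s, a, sep = ".")]]$AC$erp_components$amplitude_uv
  gap <- vapply(c("p21", "p30", "p60"),
                function(a) mean(amp("KO", "F", a) - amp("WT", "F", a)),
                numeric(1))
  expect_true(all(diff(gap) > 0))
  expect_true(all(amp("KO", "F", "p60")[2:3] > amp("KO", "M", "p60")[2:3]))
})

test_that("cohorts are reproducible and follow the study cell sizes", {
  des <- default_cohort_design("F")
  expect_equal(des$n[des$genotype == "WT"], c(11, 9, 8))
  expect_equal(des$n[des$genotype == "KO"], c(8, 9, 8))

  small <- data.frame(genotype = c("WT", "KO"), sex = "F",
                      age_group = "p21", n = 2)
  c1 <- simulate_cohort(small, seed = 7, sessions = "assr",
                        n_trials_per_pair = 2, sample_rate_hz = 256)
  expect_length(c1, 4)
  expect_equal(cohort_manifest(c1)$genotype, rep(c("WT", "KO"), each = 2))
  c2 <- simulate_cohort(small, seed = 7, sessions = "assr",
                        n_trials_per_pair = 2, sample_rate_hz = 256)
  expect_identical(c1[[1]]$assr$channels, c2[[1]]$assr$channels)
  c3 <- simulate_cohort(small, seed = 8, sessions = "assr",
                        n_trials_per_pair = 2, sample_rate_hz = 256)
  expect_false(identical(c1[[1]]$assr$channels, c3[[1]]$assr$channels))
})

test_that("kappa missing for a scheduled pair raises a configuration error", {
  one_pair <- data.frame(gap_width_ms = 6, mod_depth_pct = 100)
  ch <- channel_model(default_erp_components(),
                      data.frame(gap_width_ms = 2, mod_depth_pct = 100,
                                 kappa = 1))
  par <- neural_model_params(ch, ch)
  sched <- make_gap_assr_session(2, seed = 1, pairs = one_pair)
  expect_error(simulate_recording(subject_spec("s", "WT", "F", "p21"),
                                  sched, par, sample_rate_hz = 256),
               "no kappa")
})
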