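# Morlet transform and inter-trial phase clustering.

test_that("wavelet phase tracks the analytic phase of a 40 Hz sinusoid", {
  fs <- 1024
  x <- sin40_trials(0, n_samples = 1024, sample_rate_hz = fs)
  par <- morlet_params(freqs_hz = 40)
  co <- morlet_transform(x, par, sample_rate_hz = fs)
  fi <- 1
  sel <- which(co$valid[fi, ])
  ph <- Arg(co$coefs[1, fi, sel])
  dphi <- diff(ph) %% (2 * pi)
  expect_equal(dphi, rep(2 * pi * 40 / fs, length(dphi)), tolerance = 1e-3)

  # amplitude invariance of phase
  co3 <- morlet_transform(3 * x, par, sample_rate_hz = fs)
  expect_equal(Arg(co3$coefs[1, fi, sel]), ph, tolerance = 1e-9)

  # DC input: 40 Hz power < 1 % of the sinusoid case
  dc <- matrix(1, 1, 1024)
  codc <- morlet_transform(dc, par, sample_rate_hz = fs)
  expect_lt(mean(Mod(codc$coefs[1, fi, sel])^2),
            0.01 * mean(Mod(co$coefs[1, fi, sel])^2))

  # epoch shorter than the wavelet support errors
  expect_error(morlet_transform(x[, 1:64, drop = FALSE],
                                morlet_params(freqs_hz = c(10, 40)),
                                sample_rate_hz = fs), "too short")
})

test_that("ITPC is 1 for identical phases, 0 for antipodal pairs", {
  v <- stats::runif(50, -pi, pi)
  ph <- rbind(v, v)
  expect_equal(unname(compute_itpc(ph)), rep(1, 50), tolerance = 1e-12)
  anti <- rbind(ph[1, ], ph[1, ] + pi)
  expect_equal(compute_itpc(anti), rep(0, 50), tolerance = 1e-12)
  expect_error(compute_itpc(ph[1, , drop = FALSE]), "2 trials")
})

test_that("uniform phases give the Rayleigh mean of sqrt(pi)/(2 sqrt(N))", {
  set.seed(77)
  N <- 1000
  reps <- vapply(1:200, function(i) mrl(stats::runif(N, -pi, pi)),
                 numeric(1))
  se <- stats::sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - sqrt(pi) / (2 * sqrt(N))), 3 * se)
})

test_that("ITPC stays in [0, 1] and is invariant to rotation and scale", {
  set.seed(31)
  for (i in 1:5) {
    ph <- array(stats::runif(20 * 3 * 40, -pi, pi), c(20, 3, 40))
    r <- compute_itpc(ph)
    expect_true(all(r >= 0 & r <= 1))
    # global phase rotation leaves ITPC unchanged
    expect_equal(compute_itpc(ph + 1.2), r, tolerance = 1e-12)
  }
  # per-trial amplitude scaling through the wavelet path
  phis <- stats::runif(30, -pi, pi)
  x <- sin40_trials(phis)
  amps <- stats::runif(30, 0.5, 5)
  par <- morlet_params(freqs_hz = 40)
  s1 <- compute_itpc(morlet_transform(x, par, sample_rate_hz = 1024))
  s2 <- compute_itpc(morlet_transform(x * amps, par, sample_rate_hz = 1024))
  expect_equal(itpc_at(s2, 40, c(100, 400)), itpc_at(s1, 40, c(100, 400)),
               tolerance = 1e-9)
})

test_that("wavelet ITPC at 40 Hz agrees with a DFT-bin phase oracle", {
  set.seed(41)
  fs <- 1024
  phis <- rvonmises(200, 0, 2)
  x <- sin40_trials(phis, n_samples = 512, sample_rate_hz = fs)
  surf <- compute_itpc(morlet_transform(x, morlet_params(freqs_hz = 40),
                                        sample_rate_hz = fs))
  wav <- itpc_at(surf, 40, window_ms = c(150, 350))
  # DFT-bin oracle: phase of the exact 40 Hz bin over 20 whole cycles
  tt <- (0:511) / fs
  bin <- exp(-2i * pi * 40 * tt)
  dft_ph <- apply(x, 1, function(tr) Arg(sum(tr * bin)))
  expect_equal(wav, mrl(dft_ph), tolerance = 0.02)
})

test_that("von Mises concentration is recovered within 3 SE at N = 200", {
  set.seed(52)
  for (kappa in c(0.5, 1, 2, 4, 8)) {
    # Monte Carlo SE of the N = 200 mean resultant length
    mc <- vapply(1:100, function(i) mrl(rvonmises(200, 0, kappa)),
                 numeric(1))
    est <- mrl(rvonmises(200, 0, kappa))
    expect_lt(abs(est - kappa_to_expected_itpc(kappa)), 3 * stats::sd(mc),
              label = sprintf("kappa = %g recovery error", kappa))
  }
})

test_that("summary ITPC is nondecreasing in kappa in expectation", {
  set.seed(63)
  kap <- sort(unique(cohort_presets()$WT.F.p60$AC$assr_kappa$kappa))
  reps <- vapply(kap, function(k) {
    vapply(1:300, function(i) mrl(rvonmises(200, 0, k)), numeric(1))
  }, numeric(300))
  mean_itpc <- colMeans(reps)
  se_diff <- sqrt(apply(reps, 2, stats::var)[-1] / 300 +
                    apply(reps, 2, stats::var)[-length(kap)] / 300)
  expect_true(all(diff(mean_itpc) > -3 * se_diff))
})

test_that("per-pair grouping computes ITPC over each pair's own trials", {
  fs <- 1024
  ev <- data.frame(time_s = 1:40,
                   gap_width_ms = rep(c(4, 12), each = 20),
                   mod_depth_pct = 100)
  # pair 4 ms: random phases; pair 12 ms: identical phases
  x <- rbind(sin40_trials(stats::runif(20, -pi, pi), 512, fs),
             sin40_trials(rep(0.4, 20), 512, fs))
  ep <- fake_epochs(x, sample_rate_hz = fs, t0_ms = -100, events = ev)
  expect_warning(
    summ <- itpc_by_pair(ep, channel = "AC",
                         params = morlet_params(freqs_hz = 40),
                         window_ms = c(50, 250)),
    "below 100")
  expect_equal(summ$n_trials, c(20, 20))
  i12 <- summ$gap_width_ms == 12
  expect_equal(summ$itpc[i12], 1, tolerance = 1e-9)
  expect_lt(summ$itpc[!i12], 0.6)

  expect_error(itpc_by_pair(ep, channel = "AC",
                            params = morlet_params(freqs_hz = 40),
                            pairs = data.frame(gap_width_ms = 8,
                                               mod_depth_pct = 100),
                            min_trials_warn = 0),
               "absent")

  # identical trials across both pairs give 1 everywhere
  x1 <- rbind(sin40_trials(rep(1, 20), 512, fs),
              sin40_trials(rep(1, 20), 512, fs))
  ep1 <- fake_epochs(x1, sample_rate_hz = fs, t0_ms = -100, events = ev)
  s1 <- itpc_by_pair(ep1, channel = "AC",
                     params = morlet_params(freqs_hz = 40),
                     min_trials_warn = 0)
  expect_equal(s1$itpc, c(1, 1), tolerance = 1e-9)
})

test_that("group tables have full cardinality and collapse by recomputation", {
  fs <- 1024
  mk_summary <- function(seed) {
    set.seed(seed)
    tab <- default_pairs()
    tab$n_trials <- 101L
    tab$itpc <- stats::runif(12)
    structure(tab, class = c("itpc_summary", "data.frame"))
  }
  res <- lapply(1:2, function(i)
    list(spec = subject_spec(paste0("s", i), "WT", "F", "p21"),
         itpc = list(AC = mk_summary(i), FC = mk_summary(i + 10))))
  tab <- itpc_group_table(res)
  expect_equal(nrow(tab), 2 * 2 * 12)

  col <- collapse_gaps(tab)
  expect_equal(nrow(col), 2 * 2 * 2)
  one <- tab[tab$subject == "s1" & tab$channel == "AC" &
               tab$mod_depth_pct == 100, ]
  expect_equal(col$itpc[col$subject == "s1" & col$channel == "AC" &
                          col$mod_depth_pct == 100],
               mean(one$itpc))

  # CSV round trip at 6 decimals is bit-identical
  tab$itpc <- round(tab$itpc, 6)
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, f, row.names = FALSE)
  back <- utils::read.csv(f)
  expect_identical(back$itpc, tab$itpc)
})
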