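test_that("spiking band-pass preserves in-band tones and rejects out-of-band ones", {
  fs <- 44000
  t <- seq(1 / fs, 3, by = 1 / fs)
  inband <- sin(2 * pi * 1000 * t)
  y <- bandpass_spiking(inband, fs)
  mid <- seq(round(length(t) * 0.2), round(length(t) * 0.8))
  expect_equal(max(abs(y[mid])), 1, tolerance = 0.01)

  low <- sin(2 * pi * 50 * t)
  ylow <- bandpass_spiking(low, fs)
  expect_lt(20 * log10(max(abs(ylow[mid]))), -40)

  expect_identical(bandpass_spiking(numeric(100) , fs), numeric(100))
  expect_error(bandpass_spiking(inband, fs, low = 300, high = 30000), "band edges")
})

test_that("compute_rms has its closed forms", {
  expect_equal(compute_rms(rep(-3, 10)), 3)
  t <- seq(1 / 1000, 2, by = 1 / 1000) # integer periods of 5 Hz
  expect_equal(compute_rms(2.5 * sin(2 * pi * 5 * t)), 2.5 / sqrt(2),
               tolerance = 1e-6)
  x <- rnorm(500)
  expect_equal(compute_rms(c(x, x)), compute_rms(x))
  expect_error(compute_rms(numeric(0)), "empty")
})

test_that("NRMS normalization divides by the leading-site baseline", {
  expect_equal(normalize_rms(c(2, 2, 2, 2, 2, 4, 6)), c(1, 1, 1, 1, 1, 2, 3))
  x <- c(1.2, 0.9, 1.1, 1.0, 0.8, 2.5, 3.1)
  expect_equal(normalize_rms(7 * x), normalize_rms(x))
  expect_error(normalize_rms(c(1, 2, 3, 4)), "at least 5")
  expect_error(normalize_rms(c(0, 0, 0, 0, 0, 1)), "positive")
})

test_that("envelope PSD is a unit-sum, scale-invariant fraction spectrum", {
  fs <- 12500
  set.seed(3)
  x <- rnorm(3 * fs)
  p <- envelope_psd(x, fs)
  expect_equal(sum(p$fractions), 1, tolerance = 1e-6)
  expect_equal(diff(p$freqs)[1], 1 / 3, tolerance = 1e-9)
  p2 <- envelope_psd(10 * x, fs)
  expect_equal(p$fractions, p2$fractions, tolerance = 1e-9)
  expect_error(envelope_psd(x[1:fs], fs), "shorter")
})

test_that("an injected envelope modulation frequency is recovered as the PSD argmax", {
  # independent spike-train construction (not simulate_site): Poisson thinning
  # with a 20 Hz rate modulation, 1 ms biphasic waveform
  fs <- 44000; dur <- 4; rate <- 50; m <- 0.8; f0 <- 20
  peaks <- sapply(1:50, function(seed) {
    set.seed(seed + 100)
    n <- fs * dur
    ns <- rpois(1, rate * (1 + m) * dur * 8)
    ts <- sort(runif(ns, 0, dur))
    ts <- ts[runif(ns) < (1 + m * sin(2 * pi * f0 * ts)) / (1 + m)]
    x <- numeric(n)
    idx <- pmax(1, pmin(n, round(ts * fs)))
    for (i in idx) x[i] <- x[i] + 4
    wav <- stnmer:::spike_waveform(fs)
    x <- stats::filter(x, wav, method = "convolution", sides = 2)
    x[is.na(x)] <- 0
    x <- as.numeric(x) + rnorm(n, sd = 1)
    xf <- bandpass_spiking(x, fs)
    p <- envelope_psd(xf, fs)
    sel <- p$freqs >= 5 & p$freqs <= 45
    p$freqs[sel][which.max(p$fractions[sel])]
  })
  expect_lte(abs(median(peaks) - f0), 1 / 3 + 1e-9)
})

test_that("band fractions sum correctly and partition the spectrum", {
  freqs <- seq(0, 100, by = 1 / 3)
  fr <- numeric(length(freqs)); fr[which.min(abs(freqs - 20))] <- 1
  expect_equal(band_fraction(freqs, fr, c(13, 30)), 1.0)

  fr_u <- rep(1 / length(freqs), length(freqs))
  expect_equal(band_fraction(freqs, fr_u, c(13, 30)),
               sum(freqs >= 13 & freqs < 30) / length(freqs))

  set.seed(4); fr_r <- runif(length(freqs)); fr_r <- fr_r / sum(fr_r)
  expect_equal(band_fraction(freqs, fr_r, c(0, 13)) +
                 band_fraction(freqs, fr_r, c(13, 30)) +
                 band_fraction(freqs, fr_r, c(30, Inf)), 1)
  expect_error(band_fraction(freqs, fr_r, c(200, 300)), "no frequency bins")
})

test_that("beta time series passes 20 Hz envelopes and attenuates 50 Hz per design", {
  fs <- 12500
  t <- seq(1 / fs, 4, by = 1 / fs)
  carrier <- sign(sin(2 * pi * 3000 * t)) # |carrier| = 1 exactly
  mk <- function(f) (2 + sin(2 * pi * f * t)) * carrier
  bt20 <- beta_timeseries(mk(20), fs)
  mid <- seq(round(length(bt20$samples) * 0.25), round(length(bt20$samples) * 0.75))
  a20 <- max(abs(bt20$samples[mid]))
  expect_equal(a20, 1, tolerance = 0.1)

  bt50 <- beta_timeseries(mk(50), fs)
  a50 <- max(abs(bt50$samples[mid]))
  # expected attenuation from the designed four-pole response
  bf <- signal::butter(2, c(13, 30) / (bt20$fs / 2), type = "pass")
  H <- signal::freqz(bf$b, bf$a, n = 8192, Fs = bt20$fs)
  mag <- function(f) abs(H$h[which.min(abs(H$f - f))])^2 # forward-backward
  expect_equal(a50 / a20, mag(50) / mag(20), tolerance = 0.25)
  expect_lt(a50 / a20, 0.2)

  expect_equal(max(abs(beta_timeseries(numeric(fs * 3), fs)$samples)), 0)
})

test_that("featurize_trajectory composes the per-site chain coherently", {
  cfg <- short_pd(seed = 31)
  sim <- simulate_trajectory(cfg)
  prof <- featurize_trajectory(sim$trajectory)
  expect_equal(mean(prof$sites$nrms[1:5]), 1, tolerance = 1e-12)
  expect_true(all(abs(rowSums(prof$psd) - 1) < 1e-6))

  # amplitude-scale invariance of every normalized feature
  scaled <- sim$trajectory
  scaled$sites <- lapply(scaled$sites, function(s) { s$samples <- 3.7 * s$samples; s })
  prof2 <- featurize_trajectory(scaled)
  expect_equal(prof2$sites$nrms, prof$sites$nrms, tolerance = 1e-9)
  expect_equal(prof2$psd, prof$psd, tolerance = 1e-9)
  expect_equal(prof2$sites$frac_beta, prof$sites$frac_beta, tolerance = 1e-9)

  # identical sites -> NRMS identically 1
  site <- sim$trajectory$sites[[1]]
  same <- lapply(1:7, function(i) { s <- site; s$depth <- 10 - 0.1 * (i - 1); s })
  prof3 <- featurize_trajectory(same)
  expect_equal(prof3$sites$nrms, rep(1, 7))

  expect_error(featurize_trajectory(list()), "empty")
})

test_that("DLOR beta fraction exceeds the pre-STN fraction in beta-modulated trajectories", {
  diffs <- sapply(1:8, function(s) {
    sim <- simulate_trajectory(short_pd(), seed = 200 + s)
    prof <- featurize_trajectory(sim$trajectory)
    lab <- sim$ground_truth$state
    mean(prof$sites$frac_beta[lab == "DLOR"]) -
      mean(prof$sites$frac_beta[lab == "PRE"])
  })
  expect_gt(mean(diffs), 0)
  expect_true(all(diffs > 0))
})

test_that("band fractions are invariant to the envelope decimation rate", {
  cfg <- fast_pd(seed = 51)
  s <- stnmer:::with_local_seed(51, simulate_site(1, "DLOR", cfg))
  xf <- bandpass_spiking(s$samples, cfg$sampling_rate)
  p1k <- envelope_psd(xf, cfg$sampling_rate, decimate_to = 1000)
  pfull <- envelope_psd(xf, cfg$sampling_rate, decimate_to = Inf)
  b1 <- band_fraction(p1k$freqs, p1k$fractions, c(13, 30))
  b2 <- band_fraction(pfull$freqs, pfull$fractions, c(13, 30))
  # fractions renormalize over different Nyquist ranges; compare within the
  # common 0-200 Hz envelope range
  n1 <- b1 / band_fraction(p1k$freqs, p1k$fractions, c(0, 200))
  n2 <- b2 / band_fraction(pfull$freqs, pfull$fractions, c(0, 200))
  expect_equal(n1, n2, tolerance = 0.05)
})
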