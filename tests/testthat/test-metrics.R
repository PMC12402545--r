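# shared fixture: 6 mm STN (entry 4, exit -2) on a regular grid with enough
# pre-entrance coverage for the half-length segment
metric_fixture <- function(nrms_stn = NULL, psd = NULL) {
  depths <- round(seq(10, -3, by = -0.25), 6)
  rms <- rep(1, length(depths))
  if (!is.null(nrms_stn)) {
    inside <- depths <= 4 & depths >= -2
    rms[inside] <- nrms_stn(( 4 - depths[inside]) / 6)
  }
  prof <- toy_profile(depths, rms = rms, psd = psd)
  seg <- apply_manual_segmentation(prof, 4, 1, -2)
  list(prof = prof, seg = seg)
}

test_that("depth normalization maps sites onto the common grid exactly", {
  fx <- metric_fixture()
  np <- normalize_depths(fx$prof, fx$seg)
  expect_equal(np$grid, seq(-0.5, 1, length.out = 151))
  # x = (entry - depth) / (entry - exit): 1.0 mm -> 0.5, 7.0 mm -> -0.5
  expect_equal(np$nrms[which.min(abs(np$grid - 0.5))],
               fx$prof$sites$nrms[fx$prof$sites$depth == 1])
  expect_equal(np$nrms[which.min(abs(np$grid + 0.5))],
               fx$prof$sites$nrms[fx$prof$sites$depth == 7])

  # a piecewise-linear NRMS in depth is reproduced exactly at grid points
  fx2 <- metric_fixture(nrms_stn = function(x) 1 + x)
  np2 <- normalize_depths(fx2$prof, fx2$seg)
  inside <- np2$grid >= 0 & np2$grid <= 1
  expect_equal(np2$nrms[inside], 1 + np2$grid[inside], tolerance = 1e-9)

  # insufficient pre-entrance coverage warns and truncates, never extrapolates
  shallow <- toy_profile(round(seq(5, -3, by = -0.25), 6))
  seg_s <- apply_manual_segmentation(shallow, 4, 1, -2)
  expect_warning(np3 <- normalize_depths(shallow, seg_s), "truncated")
  expect_true(is.na(np3$nrms[1]))
})

test_that("group averaging is pointwise and ignores missing values", {
  fx <- metric_fixture(nrms_stn = function(x) 1 + x)
  np <- normalize_depths(fx$prof, fx$seg)
  avg <- group_average(list(np, np))
  expect_equal(avg$nrms, np$nrms)
  expect_equal(avg$spectrogram, np$spectrogram)

  flip <- np; flip$nrms <- 2 - np$nrms
  expect_equal(group_average(list(np, flip))$nrms, rep(1, length(np$grid)))

  short <- np; short$grid <- np$grid[-1]; short$nrms <- np$nrms[-1]
  expect_error(group_average(list(np, short)), "grid")
  expect_error(group_average(list()), "empty")
})

test_that("beta ratio compares DLOR to the pre-entrance segment", {
  fx <- metric_fixture() # identical flat PSDs everywhere
  expect_equal(beta_ratio(fx$prof, fx$seg), 1.0)

  # DLOR beta fraction double the pre-STN fraction -> ratio 2
  depths <- fx$prof$sites$depth
  freqs <- fx$prof$freqs
  psd <- t(sapply(depths, function(d) {
    if (d <= 4 && d > 1) psd_with_band(freqs, c(13, 30), 0.4)
    else psd_with_band(freqs, c(13, 30), 0.2)
  }))
  fx2 <- metric_fixture(psd = psd)
  expect_equal(beta_ratio(fx2$prof, fx2$seg), 2.0, tolerance = 1e-12)
})

test_that("mean band power averages the per-site fractions over the region", {
  depths <- round(seq(10, -3, by = -0.25), 6)
  freqs <- seq(0, 100, by = 1 / 3)
  psd <- t(sapply(seq_along(depths), function(i)
    psd_with_band(freqs, c(13, 30), 0.2)))
  prof <- toy_profile(depths, psd = psd)
  seg <- apply_manual_segmentation(prof, 4, 1, -2)
  expect_equal(mean_band_power(prof, seg, c(13, 30)), 0.2, tolerance = 1e-12)

  # brute-force oracle: site-by-site band_fraction, then mean
  set.seed(9)
  psd_r <- t(apply(psd, 1, function(p) { q <- p * runif(length(p)); q / sum(q) }))
  prof_r <- toy_profile(depths, psd = psd_r)
  dlor <- which(as.character(seg$labels) == "DLOR")
  brute <- mean(sapply(dlor, function(i)
    band_fraction(freqs, psd_r[i, ], c(13, 30))))
  expect_equal(mean_band_power(prof_r, seg, c(13, 30)), brute, tolerance = 1e-12)

  one <- apply_manual_segmentation(prof_r, 4, 3.75, 3.5)
  expect_equal(mean_band_power(prof_r, one, c(13, 30), region = "dlor"),
               band_fraction(freqs, psd_r[which(depths == 4), ], c(13, 30)))
})

test_that("NRMS peak and AUC have their closed forms", {
  fx1 <- metric_fixture() # nrms == 1 inside the STN
  expect_equal(unname(nrms_peak_auc(fx1$prof, fx1$seg)), c(1, 1))

  fx2 <- metric_fixture(nrms_stn = function(x) rep(2, length(x)))
  expect_equal(unname(nrms_peak_auc(fx2$prof, fx2$seg)), c(2, 2))

  tri <- metric_fixture(nrms_stn = function(x) 1 + 2 * (1 - abs(2 * x - 1)))
  pa <- nrms_peak_auc(tri$prof, tri$seg)
  expect_equal(unname(pa["peak"]), 3)
  expect_equal(unname(pa["auc"]), 2, tolerance = 1e-9)
})

test_that("metrics are invariant to reparameterization and voltage scale", {
  sim <- simulate_trajectory(short_pd(), seed = 61)
  prof <- featurize_trajectory(sim$trajectory)
  seg <- segment_profile(prof)
  m1 <- trajectory_metrics(prof, seg)

  # metrics are defined on sites: depth normalization must not change them
  np <- normalize_depths(prof, seg)
  expect_equal(max(np$nrms[np$grid >= 0 & np$grid <= 1], na.rm = TRUE),
               m1$nrms_peak, tolerance = 0.05) # grid interpolation only

  scaled <- sim$trajectory
  scaled$sites <- lapply(scaled$sites, function(s) { s$samples <- 0.2 * s$samples; s })
  prof2 <- featurize_trajectory(scaled)
  m2 <- trajectory_metrics(prof2, segment_profile(prof2))
  expect_equal(m2$beta_ratio, m1$beta_ratio, tolerance = 1e-9)
  expect_equal(m2$nrms_peak, m1$nrms_peak, tolerance = 1e-9)
  expect_equal(m2$nrms_auc, m1$nrms_auc, tolerance = 1e-9)
  expect_equal(m2$mean_beta_power, m1$mean_beta_power, tolerance = 1e-9)
})

test_that("every scalar metric matches brute-force recomputation from the site table", {
  sim <- simulate_trajectory(short_pd(), seed = 62)
  prof <- featurize_trajectory(sim$trajectory)
  seg <- segment_profile(prof)
  m <- trajectory_metrics(prof, seg)

  tab <- prof$sites
  lab <- as.character(seg$labels)
  half <- 0.5 * (seg$entry_depth - seg$exit_depth)
  pre <- lab == "PRE" & tab$depth <= seg$entry_depth + half
  expect_equal(m$beta_ratio,
               mean(tab$frac_beta[lab == "DLOR"]) / mean(tab$frac_beta[pre]),
               tolerance = 1e-12)
  expect_equal(m$mean_beta_power, mean(tab$frac_beta[lab == "DLOR"]),
               tolerance = 1e-12)
  expect_equal(m$mean_gamma_power,
               mean(tab$frac_gamma[lab %in% c("DLOR", "VMNR")]),
               tolerance = 1e-12)
  expect_equal(m$nrms_peak,
               max(tab$nrms[tab$depth <= seg$entry_depth &
                              tab$depth > seg$exit_depth]))
  expect_equal(m$stn_length, seg$entry_depth - seg$exit_depth)
})
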