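test_that("pure-noise site has the configured standard deviation", {
  cfg <- sim_config(unit_rate_baseline = 0, baseline_noise_sd = 1)
  s <- stnmer:::with_local_seed(41, simulate_site(5, "PRE", cfg))
  expect_equal(sd(s$samples), 1, tolerance = 0.03)
  expect_length(s$samples, round(cfg$sampling_rate * cfg$site_duration))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(start_depth = 1, entry_depth = 4), "geometry")
  expect_error(sim_config(dlor_fraction = 1.2), "dlor_fraction")
  expect_error(sim_config(sampling_rate = 8000), "12500")
  expect_error(sim_config(beta_mod_depth = 1.5), "modulation")
  expect_error(simulate_site(5, "NOWHERE", fast_pd()))
})

test_that("trajectory geometry matches the recording protocol", {
  cfg <- sim_config(entry_depth = 4, exit_depth = -2, dlor_fraction = 0.5)
  geo <- stnmer:::trajectory_geometry(cfg)
  expect_equal(geo$dlor_exit_depth, 1.0)
  # inclusive 0.1 mm grid through the STN
  expect_equal(sum(geo$depths <= 4 & geo$depths >= -2 &
                     geo$state %in% c("DLOR", "VMNR", "POST")), 61)
  # six baseline sites 0.1 mm apart at the top of the track
  expect_equal(geo$depths[1:6], 10 - 0.1 * (0:5))
  expect_equal(diff(geo$depths[7:8]), -0.4)
  # state sequence is monotone PRE -> DLOR -> VMNR -> POST
  codes <- match(geo$state, c("PRE", "DLOR", "VMNR", "POST"))
  expect_true(all(diff(codes) >= 0))
})

test_that("identical seeds give bit-identical trajectories and cohorts", {
  cfg <- short_pd(seed = 7)
  a <- simulate_trajectory(cfg)
  b <- simulate_trajectory(cfg)
  expect_identical(a$trajectory$sites[[10]]$samples, b$trajectory$sites[[10]]$samples)
  expect_identical(a$ground_truth, b$ground_truth)

  c1 <- simulate_cohort(2, 2, short_pd(), short_et(), seed = 5)
  c2 <- simulate_cohort(2, 2, short_pd(), short_et(), seed = 5)
  expect_identical(c1$trajectories[[3]]$sites[[5]]$samples,
                   c2$trajectories[[3]]$sites[[5]]$samples)
  expect_equal(table(c1$groups), table(factor(c(rep("PD", 2), rep("ET", 2)))))
})

test_that("unmodulated DLOR and VMNR are spectrally indistinguishable", {
  cfg <- fast_pd(beta_mod_depth = 0)
  beta_fracs <- stnmer:::with_local_seed(11, {
    sapply(1:24, function(i) {
      st <- if (i %% 2 == 0) "DLOR" else "VMNR"
      s <- simulate_site(1, st, cfg)
      xf <- bandpass_spiking(s$samples, cfg$sampling_rate)
      p <- envelope_psd(xf, cfg$sampling_rate)
      band_fraction(p$freqs, p$fractions, c(13, 30))
    })
  })
  ht <- wilcox.test(beta_fracs[c(TRUE, FALSE)], beta_fracs[c(FALSE, TRUE)])
  expect_gt(ht$p.value, 0.01)
})

test_that("beta fraction increases with modulation depth", {
  mean_beta <- sapply(c(0, 0.4, 0.8), function(m) {
    cfg <- fast_pd(beta_mod_depth = m)
    stnmer:::with_local_seed(17, mean(sapply(1:15, function(i) {
      s <- simulate_site(1, "DLOR", cfg)
      xf <- bandpass_spiking(s$samples, cfg$sampling_rate)
      p <- envelope_psd(xf, cfg$sampling_rate)
      band_fraction(p$freqs, p$fractions, c(13, 30))
    })))
  })
  expect_true(all(diff(mean_beta) > 0))
})

test_that("in-STN raw RMS exceeds pre-STN RMS and is higher with larger noise gain", {
  coh <- simulate_cohort(6, 6, short_pd(stn_noise_gain = 2),
                         short_et(stn_noise_gain = 1.3), seed = 23,
                         depth_jitter = 0.3)
  stn_rms <- function(i) {
    gt <- coh$ground_truth[[i]]
    d <- vapply(coh$trajectories[[i]]$sites, `[[`, numeric(1), "depth")
    inside <- d <= gt$entry_depth & d > gt$exit_depth
    mean(vapply(coh$trajectories[[i]]$sites[inside], function(s)
      compute_rms(s$samples), numeric(1)))
  }
  pre_rms <- function(i) {
    gt <- coh$ground_truth[[i]]
    d <- vapply(coh$trajectories[[i]]$sites, `[[`, numeric(1), "depth")
    mean(vapply(coh$trajectories[[i]]$sites[d > gt$entry_depth], function(s)
      compute_rms(s$samples), numeric(1)))
  }
  rms_pd <- sapply(which(coh$groups == "PD"), stn_rms)
  rms_et <- sapply(which(coh$groups == "ET"), stn_rms)
  expect_gt(mean(rms_pd), mean(rms_et))
  expect_true(all(sapply(seq_along(coh$groups), function(i)
    stn_rms(i) > pre_rms(i))))
})
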