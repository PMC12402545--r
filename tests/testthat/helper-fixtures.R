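# Shared fixtures: reduced-size simulation configs and hand-built profiles.
# Simulations in the tests run at 12.5 kHz with 3 s sites (the shortest
# windows compatible with the 300-6000 Hz band and the 1/3 Hz PSD bins);
# geometry is shortened where many replicates are needed.

# Full default anatomy (6 mm STN) at reduced rate/duration.
fast_pd <- function(...) pd_config(sampling_rate = 12500, site_duration = 3, ...)
fast_et <- function(...) et_config(sampling_rate = 12500, site_duration = 3, ...)

# Shortened trajectory (1.5 mm STN, ~26 sites) for replicate-heavy checks.
short_pd <- function(...) fast_pd(start_depth = 4.5, entry_depth = 2.5,
                                  exit_depth = 1.0, post_extent = 0.8, ...)
short_et <- function(...) fast_et(start_depth = 4.5, entry_depth = 2.5,
                                  exit_depth = 1.0, post_extent = 0.8, ...)

# Minimal trajectory (1.2 mm STN, ~19 sites) for the null-calibration
# replicates; pair with depth_jitter = 0.15 so the half-length pre-segment
# always contains a pre-entrance site.
null_et <- function(...) fast_et(start_depth = 3.4, entry_depth = 2.4,
                                 exit_depth = 1.2, post_extent = 0.4,
                                 dlor_fraction = 0.5, ...)

# Build a mer_profile directly from numbers (no signals), for closed-form
# metric tests. psd rows default to a flat spectrum.
toy_profile <- function(depths, rms = rep(1, length(depths)), psd = NULL,
                        freqs = seq(0, 100, by = 1 / 3), n_baseline = 5,
                        bands = mer_bands()) {
  n <- length(depths)
  if (is.null(psd)) psd <- matrix(1 / length(freqs), n, length(freqs))
  nrms <- normalize_rms(rms, n_baseline)
  df <- data.frame(depth = depths, rms = rms, nrms = nrms)
  bm <- stnmer:::band_matrix(freqs, bands)
  fr <- psd %*% bm
  for (bn in names(bands)) df[[paste0("frac_", bn)]] <- fr[, bn]
  structure(list(sites = df, psd = psd, freqs = freqs,
                 baseline_rms = mean(rms[seq_len(n_baseline)]),
                 n_baseline = n_baseline, bands = bands, id = "toy",
                 metadata = list()),
            class = "mer_profile")
}

# PSD row with a given fraction of power concentrated uniformly in one band,
# the rest spread uniformly elsewhere.
psd_with_band <- function(freqs, band, frac) {
  inb <- freqs >= band[1] & freqs < band[2]
  p <- numeric(length(freqs))
  p[inb] <- frac / sum(inb)
  p[!inb] <- (1 - frac) / sum(!inb)
  p
}

# Exhaustive-enumeration Mann-Whitney oracle (untied samples): distribution of
# U over all assignments of the pooled values to the two groups.
mw_enumerate <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(length(pooled), na)
  us <- apply(combos, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  list(u = min(u_obs, na * length(b) - u_obs),
       p = min(1, 2 * min(p_le, p_ge)))
}

# Boundary-recovery errors of the decoder on one simulated trajectory.
recovery_errors <- function(cfg, seed) {
  sim <- simulate_trajectory(cfg, seed = seed)
  prof <- featurize_trajectory(sim$trajectory)
  seg <- suppressWarnings(segment_profile(prof))
  gt <- sim$ground_truth
  if (seg$degenerate) return(c(entry = NA_real_, dlor = NA_real_, exit = NA_real_))
  c(entry = abs(seg$entry_depth - gt$entry_depth),
    dlor = abs(seg$dlor_exit_depth - gt$dlor_exit_depth),
    exit = abs(seg$exit_depth - gt$exit_depth))
}
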