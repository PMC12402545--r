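#' Simulation configuration for synthetic MER trajectories
#'
#' Bundles the geometric and signal parameters of the synthetic
#' microelectrode-recording generator. Geometry follows the clinical recording
#' protocol: the electrode starts 10 mm above the planned target, advances in
#' 0.4 mm steps before the STN and 0.1 mm steps within it, and each site
#' contributes a 4 s analysis window. The signal at each site is Gaussian
#' background noise plus multi-unit spike trains; inside the STN the noise floor
#' steps up by `stn_noise_gain` and firing is dense, and in the motor subregion
#' (DLOR) the firing rate is sinusoidally modulated at a beta frequency
#' (Parkinson-like) or a tremor frequency, with modulation depth 0 elsewhere.
#'
#' @param sampling_rate sampling rate in Hz (>= 12500 so the 6000 Hz band edge
#'   stays below Nyquist).
#' @param site_duration analysis-window duration per site, seconds.
#' @param pre_stn_step,in_stn_step electrode step sizes (mm) outside/inside the
#'   STN.
#' @param start_depth,entry_depth,exit_depth trajectory geometry in mm above the
#'   planned target (descending: `start_depth > entry_depth > exit_depth`).
#' @param dlor_fraction fraction of the STN span (from entry) labelled DLOR,
#'   in (0, 1).
#' @param baseline_noise_sd background-noise standard deviation outside the STN
#'   (arbitrary voltage units).
#' @param stn_noise_gain multiplicative noise step-up inside the STN (> 1 for a
#'   detectable entry).
#' @param unit_rate_baseline,unit_rate_stn per-unit firing rate (spikes/s)
#'   outside/inside the STN.
#' @param n_units number of simulated units contributing spikes at each site.
#' @param spike_amp,spike_amp_cv mean spike amplitude (in units of
#'   `baseline_noise_sd`) and the log-normal coefficient of variation of
#'   per-unit amplitudes.
#' @param beta_mod_depth,beta_freq firing-rate modulation depth in \[0, 1\] and
#'   frequency (Hz, 13-30) applied in the DLOR; 0 disables beta modulation
#'   (essential-tremor-like).
#' @param tremor_mod_depth,tremor_freq optional tremor-band modulation (depth in
#'   \[0, 1\], frequency in 6-12 Hz) used in the DLOR when beta modulation is
#'   disabled.
#' @param env_mod_depth,env_cutoff slow multiplicative fluctuation of the
#'   background-noise amplitude (relative depth, and the low-pass corner in Hz
#'   of the fluctuation process). Present in every state and group, it gives
#'   the rectified-signal spectrum the low-frequency-dominated shape of real
#'   multi-unit envelopes; 0 disables it.
#' @param stn_env_gain multiplier on `env_mod_depth` inside the STN, emulating
#'   the rise of delta/theta-band envelope power at STN entry seen in both
#'   patient groups.
#' @param post_extent length (mm) of the post-exit segment with pre-STN-like
#'   signal, giving the exit detector contrast.
#' @param seed optional integer seed making `simulate_trajectory()` calls
#'   reproducible.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_trajectory()], [simulate_cohort()], [pd_config()],
#'   [et_config()]
#' @export
#' @examples
#' cfg <- sim_config(entry_depth = 4, exit_depth = -2, seed = 1)
#' cfg
sim_config <- function(sampling_rate = 44000,
                       site_duration = 4,
                       pre_stn_step = 0.4,
                       in_stn_step = 0.1,
                       start_depth = 10,
                       entry_depth = 4,
                       exit_depth = -2,
                       dlor_fraction = 0.57,
                       baseline_noise_sd = 1,
                       stn_noise_gain = 2,
                       unit_rate_baseline = 5,
                       unit_rate_stn = 60,
                       n_units = 8,
                       spike_amp = 2,
                       spike_amp_cv = 0.3,
                       beta_mod_depth = 0.8,
                       beta_freq = 20,
                       tremor_mod_depth = 0,
                       tremor_freq = 8,
                       env_mod_depth = 0.35,
                       env_cutoff = 4,
                       stn_env_gain = 1.8,
                       post_extent = 2,
                       seed = NULL) {
  cfg <- list(sampling_rate = sampling_rate, site_duration = site_duration,
              pre_stn_step = pre_stn_step, in_stn_step = in_stn_step,
              start_depth = start_depth, entry_depth = entry_depth,
              exit_depth = exit_depth, dlor_fraction = dlor_fraction,
              baseline_noise_sd = baseline_noise_sd,
              stn_noise_gain = stn_noise_gain,
              unit_rate_baseline = unit_rate_baseline,
              unit_rate_stn = unit_rate_stn, n_units = n_units,
              spike_amp = spike_amp, spike_amp_cv = spike_amp_cv,
              beta_mod_depth = beta_mod_depth, beta_freq = beta_freq,
              tremor_mod_depth = tremor_mod_depth, tremor_freq = tremor_freq,
              env_mod_depth = env_mod_depth, env_cutoff = env_cutoff,
              stn_env_gain = stn_env_gain,
              post_extent = post_extent, seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  with(cfg, {
    if (!(start_depth > entry_depth && entry_depth > exit_depth))
      stop("geometry must satisfy start_depth > entry_depth > exit_depth")
    if (!(dlor_fraction > 0 && dlor_fraction < 1))
      stop("dlor_fraction must be in (0, 1)")
    if (sampling_rate < 12500)
      stop("sampling_rate must be >= 12500 Hz (6000 Hz band edge below Nyquist)")
    if (site_duration <= 0) stop("site_duration must be positive")
    if (unit_rate_baseline < 0 || unit_rate_stn < 0)
      stop("firing rates must be non-negative")
    if (beta_mod_depth < 0 || beta_mod_depth > 1 ||
        tremor_mod_depth < 0 || tremor_mod_depth > 1)
      stop("modulation depths must lie in [0, 1]")
    if (stn_noise_gain <= 0 || baseline_noise_sd <= 0)
      stop("noise parameters must be positive")
    if (env_mod_depth < 0 || env_mod_depth >= 1 || env_cutoff <= 0)
      stop("env_mod_depth must be in [0, 1) with a positive env_cutoff")
    if (stn_env_gain <= 0) stop("stn_env_gain must be positive")
    if (pre_stn_step <= 0 || in_stn_step <= 0) stop("step sizes must be positive")
    if (post_extent < 0) stop("post_extent must be non-negative")
  })
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("MER simulation config\n")
  cat(sprintf("  fs %g Hz, %g s/site; depths %g -> %g (entry) -> %g mm, DLOR fraction %.2f\n",
              x$sampling_rate, x$site_duration, x$start_depth, x$entry_depth,
              x$exit_depth, x$dlor_fraction))
  cat(sprintf("  noise sd %g (STN gain %.2f); %d units @ %g/%g spk/s; beta m=%.2f f=%g Hz\n",
              x$baseline_noise_sd, x$stn_noise_gain, x$n_units,
              x$unit_rate_baseline, x$unit_rate_stn,
              x$beta_mod_depth, x$beta_freq))
  invisible(x)
}

#' Canonical Parkinson-like and essential-tremor-like configurations
#'
#' `pd_config()` gives a Parkinson-like trajectory: a 6 mm STN with strong
#' beta-band rate modulation in the DLOR and a 2x noise step-up at entry.
#' `et_config()` gives an essential-tremor-like trajectory: a 4.6 mm STN, no
#' beta modulation and a weaker noise step-up, reflecting the attenuated
#' regional spiking activity of that group.
#'
#' @param ... overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
pd_config <- function(...) {
  args <- modifyList(list(entry_depth = 4, exit_depth = -2,
                          dlor_fraction = 0.57, stn_noise_gain = 2,
                          beta_mod_depth = 0.8), list(...))
  do.call(sim_config, args)
}

#' @rdname pd_config
#' @export
et_config <- function(...) {
  args <- modifyList(list(entry_depth = 3.3, exit_depth = -1.3,
                          dlor_fraction = 0.55, stn_noise_gain = 1.4,
                          beta_mod_depth = 0), list(...))
  do.call(sim_config, args)
}

# Biphasic extracellular spike waveform (~1 ms), difference of Gaussians,
# normalized to unit peak amplitude.
spike_waveform <- function(fs) {
  tw <- seq(-0.75e-3, 0.75e-3, by = 1 / fs)
  w <- exp(-((tw - 0.12e-3) / 0.10e-3)^2) - 0.9 * exp(-((tw + 0.12e-3) / 0.18e-3)^2)
  w / max(abs(w))
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
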