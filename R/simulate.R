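#' Simulate one microelectrode recording site
#'
#' Generates a raw voltage trace for a single depth-stamped site. The trace is
#' Gaussian background noise (sd `baseline_noise_sd`, multiplied by
#' `stn_noise_gain` inside the STN) plus `n_units` independent
#' inhomogeneous-Poisson spike trains convolved with a biphasic ~1 ms waveform.
#' The per-unit rate is
#' \deqn{\lambda(t) = r\,(1 + m \sin(2\pi f t)),}
#' with `r = unit_rate_stn` inside the STN and `unit_rate_baseline` outside;
#' in the DLOR `m = beta_mod_depth` at `f = beta_freq` (or the tremor
#' parameters when beta modulation is disabled and `tremor_mod_depth > 0`),
#' and `m = 0` in PRE/VMNR/POST.
#'
#' @param depth site depth, mm above the planned target.
#' @param state region label, one of `"PRE"`, `"DLOR"`, `"VMNR"`, `"POST"`.
#' @param cfg a [sim_config()].
#' @return A `mer_site`: list with `depth`, `sampling_rate`, `duration` and the
#'   raw `samples`.
#' @export
#' @examples
#' s <- simulate_site(5, "PRE", sim_config(sampling_rate = 12500, site_duration = 1))
#' sd(s$samples)
simulate_site <- function(depth, state, cfg) {
  state <- match.arg(state, c("PRE", "DLOR", "VMNR", "POST"))
  validate_sim_config(cfg)
  fs <- cfg$sampling_rate
  dur <- cfg$site_duration
  n <- round(fs * dur)
  if (n <= 0) stop("non-positive site duration")
  in_stn <- state %in% c("DLOR", "VMNR")
  noise_sd <- cfg$baseline_noise_sd * if (in_stn) cfg$stn_noise_gain else 1
  r <- if (in_stn) cfg$unit_rate_stn else cfg$unit_rate_baseline

  m <- 0; f <- 0
  if (state == "DLOR") {
    if (cfg$beta_mod_depth > 0) { m <- cfg$beta_mod_depth; f <- cfg$beta_freq }
    else if (cfg$tremor_mod_depth > 0) { m <- cfg$tremor_mod_depth; f <- cfg$tremor_freq }
  }

  # slow multiplicative gain shared by background noise and firing rate,
  # synthesized at a low rate and linearly interpolated to the sample grid
  env_c <- numeric(0)
  env_step <- 0
  env_fs <- 0
  env_max <- 1
  env_depth <- min(0.9, cfg$env_mod_depth * if (in_stn) cfg$stn_env_gain else 1)
  if (env_depth > 0) {
    env_fs <- max(8 * cfg$env_cutoff, 50)
    ne <- ceiling(dur * env_fs) + 8
    s <- rnorm(ne)
    lp <- cached(sprintf("envlp_%g_%g", env_fs, cfg$env_cutoff),
                 signal::butter(2, cfg$env_cutoff / (env_fs / 2), type = "low"))
    s <- cpp_filtfilt(lp$b, lp$a, s)
    s <- (s - mean(s)) / max(sd(s), 1e-12)
    # unit-power normalization: baseline_noise_sd stays the marginal trace sd
    env_c <- pmax(1 + env_depth * s, 0.05) / sqrt(1 + env_depth^2)
    env_step <- fs / env_fs
    env_max <- max(env_c)
  }

  idx <- integer(0); amp <- numeric(0)
  if (r > 0 && cfg$n_units > 0) {
    sigma_l <- sqrt(log(1 + cfg$spike_amp_cv^2))
    for (u in seq_len(cfg$n_units)) {
      # spike amplitude tracks the local background level
      a_u <- cfg$spike_amp * noise_sd *
        rlnorm(1, meanlog = -sigma_l^2 / 2, sdlog = sigma_l)
      lam_max <- r * (1 + m) * env_max
      ns <- rpois(1, lam_max * dur)
      if (ns == 0) next
      t_s <- runif(ns, 0, dur)
      # thinning to the oscillation-modulated, slow-gain-modulated rate
      p_keep <- rep(1, length(t_s))
      if (m > 0) p_keep <- (1 + m * sin(2 * pi * f * t_s)) / (1 + m)
      if (length(env_c)) {
        pos <- pmin(length(env_c) - 1, t_s * env_fs)
        i0 <- floor(pos)
        e_t <- env_c[i0 + 1] + (env_c[pmin(length(env_c), i0 + 2)] - env_c[i0 + 1]) * (pos - i0)
        p_keep <- p_keep * e_t / env_max
      }
      t_s <- t_s[runif(length(t_s)) < p_keep]
      if (!length(t_s)) next
      idx <- c(idx, pmin(n, 1L + as.integer(floor(t_s * fs))))
      amp <- c(amp, rep(a_u, length(t_s)))
    }
  }
  samples <- cpp_noise_spikes(n, noise_sd, idx, amp,
                              cached(sprintf("wav_%g", fs), spike_waveform(fs)),
                              env_c, env_step)
  structure(list(depth = depth, sampling_rate = fs, duration = dur,
                 samples = samples),
            class = "mer_site")
}

# Site depth grid and true state labels for one trajectory. The first six
# top-of-track sites are 0.1 mm apart (the NRMS baseline), then 0.4 mm steps
# until STN entry, 0.1 mm steps through the STN, and 0.4 mm steps for the
# post-exit segment. The entry / DLOR-exit / exit depths are the depths of the
# first site of the DLOR / VMNR / POST state respectively.
trajectory_geometry <- function(cfg) {
  eps <- 1e-9
  baseline <- round(cfg$start_depth - cfg$in_stn_step * (0:5), 6)
  d <- baseline[6] - cfg$pre_stn_step
  pre <- numeric(0)
  while (d > cfg$entry_depth + eps) {
    pre <- c(pre, d)
    d <- d - cfg$pre_stn_step
  }
  pre <- round(pre, 6)
  n_in <- floor((cfg$entry_depth - cfg$exit_depth) / cfg$in_stn_step + eps)
  stn <- round(cfg$entry_depth - cfg$in_stn_step * (0:n_in), 6)
  entry <- stn[1]
  exit_site <- stn[length(stn)] # first site at/below the ventral border
  post <- numeric(0)
  if (cfg$post_extent > 0) {
    d <- exit_site - cfg$pre_stn_step
    while (d > exit_site - cfg$post_extent - eps) {
      post <- c(post, d)
      d <- d - cfg$pre_stn_step
    }
  }
  depths <- c(baseline, pre, stn, round(post, 6))
  dlor_target <- entry - cfg$dlor_fraction * (entry - exit_site)
  # snap the DLOR exit to the in-STN grid (first VMNR site)
  dlor_exit <- stn[which.min(abs(stn - dlor_target))]
  state <- ifelse(depths > entry + eps, "PRE",
           ifelse(depths > dlor_exit + eps, "DLOR",
           ifelse(depths > exit_site + eps, "VMNR", "POST")))
  list(depths = depths, state = state,
       entry_depth = entry, dlor_exit_depth = dlor_exit,
       exit_depth = exit_site)
}

#' Simulate a full MER trajectory with ground truth
#'
#' Emits the ordered site grid of one electrode pass (six 0.1 mm-spaced
#' baseline sites at the top of the track, 0.4 mm pre-STN steps, 0.1 mm in-STN
#' steps, and a short post-exit segment) and simulates every site with
#' [simulate_site()].
#'
#' @param cfg a [sim_config()]; `cfg$seed` (or the `seed` argument) makes the
#'   result reproducible.
#' @param seed optional integer overriding `cfg$seed`.
#' @param id,group,side trajectory metadata.
#' @return A list with `trajectory` (a `mer_trajectory`) and `ground_truth`
#'   (a `mer_ground_truth` with the true entry / DLOR-exit / exit depths and
#'   per-site state labels).
#' @export
simulate_trajectory <- function(cfg, seed = cfg$seed, id = "traj1",
                                group = NA_character_, side = NA_character_) {
  validate_sim_config(cfg)
  geo <- trajectory_geometry(cfg)
  sites <- with_local_seed(seed, lapply(seq_along(geo$depths), function(i)
    simulate_site(geo$depths[i], geo$state[i], cfg)))
  traj <- structure(list(id = id, sites = sites,
                         metadata = list(subject = id, side = side,
                                         group = group, seed = seed)),
                    class = "mer_trajectory")
  gt <- structure(list(entry_depth = geo$entry_depth,
                       dlor_exit_depth = geo$dlor_exit_depth,
                       exit_depth = geo$exit_depth,
                       depths = geo$depths, state = geo$state),
                  class = "mer_ground_truth")
  list(trajectory = traj, ground_truth = gt)
}

#' @export
print.mer_trajectory <- function(x, ...) {
  d <- vapply(x$sites, `[[`, numeric(1), "depth")
  cat(sprintf("MER trajectory '%s' (%s): %d sites, %.1f to %.1f mm above target, fs %g Hz\n",
              x$id, ifelse(is.na(x$metadata$group), "ungrouped", x$metadata$group),
              length(x$sites), max(d), min(d), x$sites[[1]]$sampling_rate))
  invisible(x)
}

#' @export
print.mer_ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth: entry %.2f, DLOR exit %.2f, exit %.2f mm (%d sites)\n",
              x$entry_depth, x$dlor_exit_depth, x$exit_depth, length(x$depths)))
  invisible(x)
}

#' Simulate a labelled two-group MER cohort
#'
#' Draws `n_pd` Parkinson-like and `n_et` essential-tremor-like trajectories.
#' Between-trajectory variability is introduced by jittering the entry and exit
#' depths uniformly within +/- `depth_jitter` mm of the config values and by
#' scaling the firing rates log-normally with coefficient of variation
#' `rate_cv`, mirroring the spread of recorded STN lengths across patients.
#'
#' @param n_pd,n_et group sizes (>= 1).
#' @param cfg_pd,cfg_et group-level configurations (defaults [pd_config()],
#'   [et_config()]).
#' @param seed integer seed; the cohort is reproducible given the seed.
#' @param depth_jitter half-width (mm) of the uniform entry/exit jitter.
#' @param rate_cv log-normal coefficient of variation of the per-trajectory
#'   firing-rate multiplier.
#' @param env_cv log-normal coefficient of variation of the per-trajectory
#'   slow-envelope fluctuation depth (between-patient variability of the
#'   low-frequency envelope power).
#' @return A `mer_cohort`: list of trajectories with parallel `ground_truth`
#'   and a `groups` label vector (`"PD"` / `"ET"`).
#' @export
#' @examples
#' coh <- simulate_cohort(2, 2, seed = 1,
#'                        cfg_pd = pd_config(sampling_rate = 12500, site_duration = 3),
#'                        cfg_et = et_config(sampling_rate = 12500, site_duration = 3))
#' coh
simulate_cohort <- function(n_pd, n_et, cfg_pd = pd_config(), cfg_et = et_config(),
                            seed = NULL, depth_jitter = 1, rate_cv = 0.2,
                            env_cv = 0.25) {
  if (n_pd < 1 || n_et < 1) stop("n_pd and n_et must be >= 1")
  validate_sim_config(cfg_pd); validate_sim_config(cfg_et)
  n <- n_pd + n_et
  groups <- c(rep("PD", n_pd), rep("ET", n_et))
  ids <- c(sprintf("PD%02d", seq_len(n_pd)), sprintf("ET%02d", seq_len(n_et)))
  sigma_l <- sqrt(log(1 + rate_cv^2))
  sigma_e <- sqrt(log(1 + env_cv^2))
  res <- with_local_seed(seed, {
    traj_seeds <- sample.int(.Machine$integer.max, n)
    de <- runif(n, -depth_jitter, depth_jitter)
    dx <- runif(n, -depth_jitter, depth_jitter)
    rmul <- rlnorm(n, meanlog = -sigma_l^2 / 2, sdlog = sigma_l)
    emul <- rlnorm(n, meanlog = -sigma_e^2 / 2, sdlog = sigma_e)
    lapply(seq_len(n), function(i) {
      base <- if (groups[i] == "PD") cfg_pd else cfg_et
      cfg_i <- base
      cfg_i$entry_depth <- base$entry_depth + de[i]
      cfg_i$exit_depth <- base$exit_depth + dx[i]
      if (cfg_i$entry_depth >= cfg_i$start_depth - 0.6)
        cfg_i$entry_depth <- base$entry_depth
      if (cfg_i$exit_depth >= cfg_i$entry_depth - 5 * cfg_i$in_stn_step)
        cfg_i$exit_depth <- cfg_i$entry_depth - 5 * cfg_i$in_stn_step
      cfg_i$unit_rate_stn <- base$unit_rate_stn * rmul[i]
      cfg_i$unit_rate_baseline <- base$unit_rate_baseline * rmul[i]
      cfg_i$env_mod_depth <- min(0.9, base$env_mod_depth * emul[i])
      cfg_i$seed <- traj_seeds[i]
      simulate_trajectory(cfg_i, id = ids[i], group = groups[i])
    })
  })
  structure(list(trajectories = lapply(res, `[[`, "trajectory"),
                 ground_truth = lapply(res, `[[`, "ground_truth"),
                 groups = groups, ids = ids, seed = seed,
                 configs = list(PD = cfg_pd, ET = cfg_et)),
            class = "mer_cohort")
}

#' @export
print.mer_cohort <- function(x, ...) {
  cat(sprintf("MER cohort: %d trajectories (%s)\n", length(x$trajectories),
              paste(sprintf("%s: %d", names(table(x$groups)), table(x$groups)),
                    collapse = ", ")))
  invisible(x)
}
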