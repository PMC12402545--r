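---
title: "Depth-resolved MER analysis of subthalamic beta oscillations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-resolved MER analysis of subthalamic beta oscillations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis

During deep-brain-stimulation surgery a microelectrode is advanced toward the
subthalamic nucleus (STN) while short extracellular recordings are taken at
successive depths: 0.4 mm steps before the nucleus, 0.1 mm steps within it,
each site contributing a 4 s analysis window after a 2 s stabilization pause.
The electrophysiological signatures along such a trajectory localize the STN
(a step-up in background noise and dense multi-unit firing at entry, a drop at
exit) and split it into its motor subregion — the dorsolateral oscillating
region (DLOR), marked by elevated beta-band (13–30 Hz) and lower-frequency
envelope power — and the ventromedial non-oscillating region (VMNR) with
broad-band gamma activity. In Parkinson's disease the DLOR carries a
pathologically elevated beta rhythm; in essential tremor it does not. stnmer
implements the complete quantitative chain behind that comparison:

1. **Per-site features** (`featurize_trajectory`). The raw trace is band-passed
   to the spiking band, 300–6000 Hz (zero-phase four-pole Butterworth), and its
   RMS computed. The RMS profile is normalized (NRMS) to the mean RMS of the
   first five closely spaced sites recorded 10 mm above target — internal
   capsule territory, giving a quiet within-trajectory reference — so the
   baseline mean NRMS is exactly 1 and the profile is independent of electrode
   impedance and amplifier gain. The band-passed trace is rectified with the
   absolute operator; the power spectrum of this envelope is estimated by Welch
   averaging (3 s Hamming windows hopped by 1 s — the shortest window giving
   1/3 Hz bins, with two windows per 4 s site) and divided by its total so each
   bin is a *fraction* of envelope power. Band powers (delta 1–4, theta 4–7,
   alpha 8–13, beta 13–30, gamma 31–100 Hz) are sums of these fractions.

2. **Boundary decoding** (`segment_profile`). A left-to-right four-state
   decoding (PRE → DLOR → VMNR → POST) over three per-site features: log-NRMS,
   the alpha+beta envelope fraction, and the gamma fraction. Emissions are
   Gaussian with moments estimated from the profile itself — PRE/POST moments
   from the baseline sites, the in-STN NRMS level from an upper quantile, the
   DLOR/VMNR spectral contrast from quantiles among high-NRMS sites — and only
   forward transitions are allowed; the maximum-likelihood monotone path is
   found by dynamic programming over the three boundary positions. Boundaries
   sit at the first site of each new state (segments half-open in depth).

3. **Trajectory metrics** (`trajectory_metrics`). The beta ratio (mean DLOR
   beta fraction over the mean in the pre-entrance segment), mean band-power
   fractions, the NRMS peak, and the trapezoidal NRMS AUC over the
   length-normalized STN.

4. **Group analysis** (`normalize_depths`, `group_average`, `compare_groups`,
   `multiband_compare`). Each trajectory is mapped to a normalized coordinate
   (0 = entry, 1 = exit) including a pre-entrance segment of half its own STN
   length; NRMS curves and spectrograms are interpolated onto a common grid
   and averaged. Scalar metrics are compared between groups with an unpaired
   t-test when both samples pass a Shapiro–Wilk screen (α = 0.05) and a
   Mann–Whitney U test otherwise; the four non-beta band comparisons carry a
   Bonferroni-adjusted level α = 0.05/4 = 0.0125.

## Design choices where the procedure was open

* **Welch details.** Only the 1/3 Hz resolution is inherent to the analysis;
  window shape and overlap are not. We use 3 s Hamming windows with a 1 s hop:
  3 s is the minimum for 1/3 Hz bins, and the second (overlapping) window in a
  4 s site reduces variance without changing resolution.
* **DC handling.** The rectified envelope has a large mean that carries no
  oscillatory information; it is removed before the PSD so the 0 Hz bin does
  not dominate the normalization. This changes all fractions and is therefore
  stated prominently: fraction values from pipelines that keep the DC bin are
  not comparable.
* **Envelope decimation.** The rectified trace is low-pass filtered and
  decimated to ~1 kHz before spectral estimation; envelope content of interest
  is far below 200 Hz and the band fractions are insensitive to the decimation
  rate (tested against the undecimated estimate).
* **"Four-pole" filters** are realized as order-4 Butterworth designs (two
  poles per edge) applied forward–backward, the common zero-phase practice for
  offline MER work.
* **Baseline count.** "First five to six sites" is a parameter with default 5;
  the synthetic generator always emits six baseline sites so the default has
  headroom.
* **Beta-ratio denominator.** "Beta power outside the STN" is resolved as the
  half-length pre-entrance segment — the same segment used in the normalized
  visualizations — keeping the denominator's extent proportionate across
  trajectories.
* **AUC range.** The NRMS AUC integrates over the STN proper (normalized
  x ∈ [0, 1]) by the trapezoid rule on site positions.
* **Mean beta power.** Per-site spectra exist only in normalized form, so
  "mean beta power" is the mean normalized beta fraction over the DLOR; gamma,
  a broad-band whole-nucleus feature, averages over all STN sites (both
  regions configurable).
* **Decoder.** The clinical reference detector is a proprietary hidden Markov
  model whose parameters are not public; the decoder here is self-contained
  and estimates its emission moments from each profile rather than pretending
  to replicate that tool. Degenerate decodings (no contrast) are flagged, not
  silently accepted; at least two DLOR sites are required so zero-length motor
  regions cannot arise from noise. Delta and theta are excluded from the
  decoder's oscillatory feature because slow envelope fluctuations dominate
  those bands at every depth; the DLOR-specific contrast lives in alpha+beta.
* **Mann–Whitney convention.** The reported statistic is min(U₁, U₂); p-values
  are exact for small untied samples and tie-corrected normal approximations
  otherwise (`stats::wilcox.test` underneath). The unpaired t-test is the
  classical equal-variance form.
* **Container.** Cohorts are stored as a directory with a JSON manifest
  (schema-tagged), one native trace blob per trajectory, and CSV sidecars for
  ground truth and features, so every flat table is directly readable outside
  R.

## The synthetic cohort generator

Patient recordings are not distributable, so `simulate_trajectory` /
`simulate_cohort` generate trajectories with the statistical structure the
analysis assumes, and nothing more:

* Gaussian background noise whose amplitude steps up by `stn_noise_gain`
  inside the STN (default 2.0 Parkinson-like, 1.4 tremor-like, expressing the
  attenuated regional spiking activity of the tremor group);
* `n_units` = 8 Poisson multi-unit spike trains (biphasic ~1 ms
  difference-of-Gaussians waveforms, amplitudes ~2x the local noise floor,
  log-normal across units) at 5 spikes/s/unit outside and 60 inside the
  nucleus;
* a slow multiplicative gain (low-pass Gaussian process, corner 4 Hz, depth
  0.35, raised 1.8x inside the STN) shared by the noise amplitude and the
  firing rate. This gives the rectified envelope the low-frequency-dominated
  spectrum of real multi-unit recordings, reproduces the delta/theta rise at
  STN entry, and calibrates the generator so an *unmodulated* STN has a beta
  ratio near 1 — the meaningful "no beta elevation" baseline for the
  tremor-like group;
* in the DLOR only, a sinusoidal firing-rate modulation
  λ(t) = r(1 + m sin 2πft): m = 0.8 at 20 Hz for Parkinson-like subjects,
  m = 0 for tremor-like subjects (an optional 6–12 Hz tremor-band modulation
  exists but is off by default);
* geometry per the recording protocol: six 0.1 mm baseline sites at the top of
  the track, 0.4 mm pre-STN steps, an inclusive 0.1 mm grid through the STN
  (default entry 4 mm, exit −2 mm above target for the 6 mm Parkinson-like
  nucleus; 3.3 to −1.3 mm for the 4.6 mm tremor-like one; DLOR fraction 0.57
  and 0.55), and 2 mm of pre-STN-like signal after exit so exit detection has
  contrast. The substantia nigra signature below the STN is *not* simulated.
* cohort-level variability: entry/exit jitter uniform ±1 mm, firing rates
  log-normal with 20 % CV, slow-envelope depth log-normal with 25 % CV. The
  jitter half-width shrinks proportionally when shortened test geometries are
  used.

What the generator does **not** emulate — tremor cells, movement and
stimulation artefacts, sedation effects, non-stationary impedance drift,
substantia nigra activity, spike-sorting-level unit structure — bounds what
green tests mean: they validate the pipeline's arithmetic, invariances,
boundary decoding and statistical behaviour under the assumed signal model,
not clinical performance on patient data.

## Numerical choices and degenerate inputs

Sampling rates must be ≥ 12.5 kHz (the 6000 Hz band edge must stay below
Nyquist) and sites ≥ 3 s (one full PSD window). Zero-variance samples make the
t-test error rather than return p = 0. Fewer than `n_baseline` sites, or a
non-positive baseline RMS, are hard errors. Boundary depths supplied manually
are snapped to the nearest site, ties to the shallower one. Depth
normalization never extrapolates: grid points outside a trajectory's coverage
are missing and group averages track per-point counts. The trajectory grids
round depths to 10⁻⁶ mm so boundary sites label deterministically.

## Problem sizes used by the test-suite and acceptance script

Simulation-heavy checks run at 12.5 kHz with 3 s sites (4 s where the two-
window Welch path matters). Single-trajectory and boundary-recovery checks use
the full default anatomy (~85 sites). The replicate-heavy checks (100-cohort
discrimination, 500-replicate null calibration) use shortened trajectories
(1.2–1.5 mm STN, ~20–26 sites) with proportionally reduced depth jitter —
the per-trajectory metric definitions are length-free, so these shortened
cohorts exercise exactly the same code path at a fraction of the cost.
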