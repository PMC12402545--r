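#' Depth-normalize a trajectory profile onto the common STN grid
#'
#' Maps site depths to the normalized coordinate
#' \deqn{x = (entry - depth)/(entry - exit),}
#' so 0 is the STN entry and 1 the exit, and linearly interpolates the NRMS
#' and every PSD frequency column onto a fixed grid over \[-0.5, 1\]: each
#' trajectory contributes its STN scaled to unit length plus a pre-entrance
#' segment equal to half its own STN length. Grid points outside the
#' trajectory's depth coverage are set to `NA` (never extrapolated); an
#' insufficient pre-entrance segment triggers a truncation warning.
#'
#' @param profile a `mer_profile`.
#' @param seg a `mer_segmentation` for the same profile.
#' @param n_grid number of grid points over \[-0.5, 1\] (default 151,
#'   step 0.01).
#' @return A `mer_nprofile`: `grid`, `nrms`, `spectrogram` (grid x frequency),
#'   `freqs` and per-point availability `n`.
#' @export
normalize_depths <- function(profile, seg, n_grid = 151) {
  if (seg$degenerate || is.na(seg$entry_depth)) stop("segmentation has no STN")
  len <- seg$entry_depth - seg$exit_depth
  x <- (seg$entry_depth - profile$sites$depth) / len
  grid <- seq(-0.5, 1, length.out = n_grid)
  if (min(x) > -0.5 + 1e-9)
    warning(sprintf("pre-entrance coverage starts at x = %.2f; pre-segment truncated",
                    min(x)))
  nrms_g <- approx(x, profile$sites$nrms, xout = grid, rule = 1)$y
  spec <- apply(profile$psd, 2, function(col) approx(x, col, xout = grid, rule = 1)$y)
  structure(list(grid = grid, nrms = nrms_g, spectrogram = spec,
                 freqs = profile$freqs, n = as.integer(!is.na(nrms_g)),
                 id = profile$id),
            class = "mer_nprofile")
}

#' Average depth-normalized profiles across a group
#'
#' Pointwise mean over profiles on an identical grid, ignoring missing values;
#' the per-point contributing count is retained in `n`.
#'
#' @param profiles list of `mer_nprofile` objects on the same grid.
#' @return A `mer_nprofile` holding the group average.
#' @export
group_average <- function(profiles) {
  if (!length(profiles)) stop("empty profile list")
  g <- profiles[[1]]$grid
  f <- profiles[[1]]$freqs
  for (p in profiles) {
    if (length(p$grid) != length(g) || max(abs(p$grid - g)) > 1e-9)
      stop("profiles are not on an identical grid")
    if (length(p$freqs) != length(f)) stop("profiles have mismatched PSD grids")
  }
  nr <- sapply(profiles, `[[`, "nrms")
  sp <- lapply(profiles, `[[`, "spectrogram")
  cnt <- rowSums(!is.na(nr))
  mean_na <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  spec_sum <- Reduce(`+`, lapply(sp, function(m) ifelse(is.na(m), 0, m)))
  spec_n <- Reduce(`+`, lapply(sp, function(m) !is.na(m)))
  structure(list(grid = g, nrms = apply(nr, 1, mean_na),
                 spectrogram = ifelse(spec_n > 0, spec_sum / spec_n, NA_real_),
                 freqs = f, n = cnt, id = "group average"),
            class = "mer_nprofile")
}

#' @export
print.mer_nprofile <- function(x, ...) {
  cat(sprintf("Normalized profile '%s': %d grid points over [%.1f, %.1f], %d freq bins\n",
              x$id, length(x$grid), min(x$grid), max(x$grid), length(x$freqs)))
  invisible(x)
}

# Indices of DLOR sites and of pre-entrance sites within the half-length
# pre-segment, given a profile + segmentation.
region_indices <- function(profile, seg) {
  d <- profile$sites$depth
  dlor <- which(seg$labels == "DLOR")
  half <- 0.5 * (seg$entry_depth - seg$exit_depth)
  pre <- which(seg$labels == "PRE" & d <= seg$entry_depth + half)
  stn <- which(seg$labels %in% c("DLOR", "VMNR"))
  list(dlor = dlor, pre = pre, stn = stn)
}

#' Beta ratio of a trajectory
#'
#' Mean beta-band (13-30 Hz) envelope-power fraction over the DLOR sites
#' divided by the mean over the pre-entrance sites within the half-length
#' pre-segment — the per-trajectory measure of how much beta power rises in
#' the motor subregion relative to just outside the STN.
#'
#' @param profile a `mer_profile`.
#' @param seg a `mer_segmentation`.
#' @param band band edges, Hz.
#' @return Scalar ratio (`NA` with a warning when the DLOR is empty).
#' @export
beta_ratio <- function(profile, seg, band = c(13, 30)) {
  idx <- region_indices(profile, seg)
  if (!length(idx$dlor)) { warning("empty DLOR; beta ratio undefined"); return(NA_real_) }
  if (!length(idx$pre)) stop("no pre-entrance sites in the half-length segment")
  bf <- apply(profile$psd, 1, function(fr) band_fraction(profile$freqs, fr, band))
  denom <- mean(bf[idx$pre])
  if (denom <= 0) stop("zero pre-entrance beta power")
  mean(bf[idx$dlor]) / denom
}

#' Mean band-power fraction over an STN region
#'
#' Mean normalized envelope-PSD fraction of `band` over the DLOR sites
#' (appropriate for beta and lower bands) or over all STN sites (used for the
#' broad gamma band).
#'
#' @param profile a `mer_profile`.
#' @param seg a `mer_segmentation`.
#' @param band band edges, Hz.
#' @param region `"dlor"` or `"stn"`.
#' @return Scalar mean fraction.
#' @export
mean_band_power <- function(profile, seg, band, region = c("dlor", "stn")) {
  region <- match.arg(region)
  idx <- region_indices(profile, seg)[[region]]
  if (!length(idx)) stop(sprintf("empty %s region", region))
  bf <- apply(profile$psd[idx, , drop = FALSE], 1, function(fr)
    band_fraction(profile$freqs, fr, band))
  mean(bf)
}

#' NRMS peak and area under the curve
#'
#' `peak` is the maximum NRMS over the STN sites (entry >= depth > exit);
#' `auc` is the trapezoidal integral of the NRMS over the normalized
#' coordinate x in \[0, 1\] evaluated at the site positions, so a flat NRMS of
#' 1 across the STN gives peak 1 and AUC 1.
#'
#' @param profile a `mer_profile`.
#' @param seg a `mer_segmentation`.
#' @return Named vector `c(peak, auc)`.
#' @export
nrms_peak_auc <- function(profile, seg) {
  d <- profile$sites$depth
  len <- seg$entry_depth - seg$exit_depth
  inside <- d <= seg$entry_depth & d > seg$exit_depth
  if (!any(inside)) stop("no sites inside the STN")
  peak <- max(profile$sites$nrms[inside])
  span <- d <= seg$entry_depth & d >= seg$exit_depth
  x <- (seg$entry_depth - d[span]) / len
  y <- profile$sites$nrms[span]
  o <- order(x)
  x <- x[o]; y <- y[o]
  auc <- sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  c(peak = peak, auc = auc)
}

#' Per-trajectory scalar metrics
#'
#' Computes the full per-trajectory metric row: beta ratio, mean band-power
#' fractions (beta/delta/theta/alpha over the DLOR, gamma over the whole STN),
#' NRMS peak and AUC, and the STN/DLOR lengths.
#'
#' @param profile a `mer_profile`.
#' @param seg a `mer_segmentation`.
#' @param bands named band list (defaults [mer_bands()]).
#' @return One-row data frame.
#' @export
trajectory_metrics <- function(profile, seg, bands = mer_bands()) {
  pa <- nrms_peak_auc(profile, seg)
  l <- stn_lengths(seg)
  out <- data.frame(id = profile$id,
                    beta_ratio = beta_ratio(profile, seg, bands$beta),
                    nrms_peak = pa["peak"], nrms_auc = pa["auc"],
                    stn_length = l["stn_length"], dlor_length = l["dlor_length"],
                    percent_dlor = l["percent_dlor"],
                    row.names = NULL)
  for (bn in intersect(c("delta", "theta", "alpha", "beta"), names(bands)))
    out[[paste0("mean_", bn, "_power")]] <-
      mean_band_power(profile, seg, bands[[bn]], region = "dlor")
  if ("gamma" %in% names(bands))
    out$mean_gamma_power <- mean_band_power(profile, seg, bands$gamma, region = "stn")
  out
}

#' Metric table for a cohort
#'
#' @param profiles list of `mer_profile` objects.
#' @param segs parallel list of `mer_segmentation` objects.
#' @param groups group label per trajectory.
#' @param bands named band list.
#' @return Data frame, one row per trajectory, with a `group` column
#'   (the GroupTable consumed by [compare_groups()] / [multiband_compare()]).
#' @export
cohort_metrics <- function(profiles, segs, groups = NULL, bands = mer_bands()) {
  stopifnot(length(profiles) == length(segs))
  rows <- mapply(function(p, s) {
    if (s$degenerate) return(NULL)
    trajectory_metrics(p, s, bands)
  }, profiles, segs, SIMPLIFY = FALSE)
  keep <- !vapply(rows, is.null, logical(1))
  out <- do.call(rbind, rows[keep])
  if (!is.null(groups)) out$group <- groups[keep]
  out
}
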