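#' Segmentation parameters
#'
#' Tuning knobs for the left-to-right state decoder in [segment_profile()].
#'
#' @param min_dlor minimum number of DLOR sites when an STN is detected.
#' @param min_vmnr minimum number of VMNR sites.
#' @param nrms_sd_floor,frac_sd_floor lower bounds on the emission standard
#'   deviations (log-NRMS and band-fraction features), guarding against
#'   degenerate moment estimates on quiet profiles.
#' @param stn_quantile quantile of log-NRMS used as the in-STN location
#'   estimate.
#' @param min_evidence minimum log-likelihood advantage (nats) the best
#'   structured path must have over the no-STN path; below it the decoding is
#'   flagged degenerate.
#' @param low_band,gamma_band frequency bands (Hz) of the two spectral
#'   emission features: the oscillatory alpha-beta band that rises in the
#'   DLOR and the broad gamma band that dominates the VMNR. Delta and theta
#'   are excluded from the oscillatory feature because slow envelope
#'   fluctuations dominate them at every depth, in and outside the STN.
#' @return A list of class `seg_params`.
#' @export
seg_params <- function(min_dlor = 2, min_vmnr = 1,
                       nrms_sd_floor = 0.06, frac_sd_floor = 0.02,
                       stn_quantile = 0.85, min_evidence = 2,
                       low_band = c(8, 30), gamma_band = c(31, 100)) {
  structure(list(min_dlor = min_dlor, min_vmnr = min_vmnr,
                 nrms_sd_floor = nrms_sd_floor, frac_sd_floor = frac_sd_floor,
                 stn_quantile = stn_quantile, min_evidence = min_evidence,
                 low_band = low_band, gamma_band = gamma_band),
            class = "seg_params")
}

new_segmentation <- function(depths, labels, source, degenerate = FALSE) {
  i_d <- which(labels == "DLOR")[1]
  i_v <- which(labels == "VMNR")[1]
  i_p <- which(labels == "POST")[1]
  exit_depth <- if (is.na(i_p)) depths[length(depths)] else depths[i_p]
  # an empty VMNR means the DLOR reaches the ventral border
  dlor_exit <- if (!is.na(i_v)) depths[i_v] else if (!is.na(i_d)) exit_depth else NA_real_
  structure(list(entry_depth = if (is.na(i_d)) NA_real_ else depths[i_d],
                 dlor_exit_depth = dlor_exit,
                 exit_depth = exit_depth,
                 depths = depths,
                 labels = factor(labels, levels = c("PRE", "DLOR", "VMNR", "POST")),
                 source = source, degenerate = degenerate),
            class = "mer_segmentation")
}

#' @export
print.mer_segmentation <- function(x, ...) {
  if (x$degenerate) {
    cat("STN segmentation (", x$source, "): DEGENERATE - no STN detected\n", sep = "")
  } else {
    cat(sprintf("STN segmentation (%s): entry %.2f, DLOR exit %.2f, exit %.2f mm\n",
                x$source, x$entry_depth, x$dlor_exit_depth, x$exit_depth))
    l <- stn_lengths(x)
    cat(sprintf("  STN %.2f mm, DLOR %.2f mm (%.1f%%)\n",
                l["stn_length"], l["dlor_length"], l["percent_dlor"]))
  }
  invisible(x)
}

# Per-state Gaussian log-likelihoods of site features, with moments estimated
# from the profile itself: PRE/POST from the baseline sites, in-STN location
# from an upper quantile of log-NRMS, and the DLOR/VMNR split from the spread
# of the low-band fraction among high-NRMS sites.
seg_emissions <- function(profile, params) {
  z1 <- log(profile$sites$nrms)
  bm <- band_matrix(profile$freqs, list(low = params$low_band,
                                        gamma = params$gamma_band))
  zf <- profile$psd %*% bm
  z2 <- zf[, "low"]
  z3 <- zf[, "gamma"]
  nb <- profile$n_baseline
  bidx <- seq_len(nb)

  mu0 <- mean(z1[bidx])
  s0 <- max(sd(z1[bidx]), params$nrms_sd_floor)
  mu1 <- quantile(z1, params$stn_quantile, names = FALSE)
  s1 <- max(s0, params$nrms_sd_floor)

  mu2_pre <- mean(z2[bidx])
  mu3_pre <- mean(z3[bidx])
  hi <- z1 > (mu0 + mu1) / 2
  if (sum(hi) >= 4) {
    mu2_d <- quantile(z2[hi], 0.85, names = FALSE)
    mu2_v <- quantile(z2[hi], 0.15, names = FALSE)
    mu3_d <- quantile(z3[hi], 0.15, names = FALSE)
    mu3_v <- quantile(z3[hi], 0.85, names = FALSE)
    s2 <- max(sd(z2[hi]) / 2, params$frac_sd_floor)
    s3 <- max(sd(z3[hi]) / 2, params$frac_sd_floor)
  } else {
    mu2_d <- mu2_v <- mean(z2); mu3_d <- mu3_v <- mean(z3)
    s2 <- s3 <- params$frac_sd_floor
  }

  ll_state <- function(m1, m2, m3)
    dnorm(z1, m1, s1, log = TRUE) + dnorm(z2, m2, s2, log = TRUE) +
      dnorm(z3, m3, s3, log = TRUE)
  cbind(PRE = dnorm(z1, mu0, s0, log = TRUE) +
          dnorm(z2, mu2_pre, s2, log = TRUE) + dnorm(z3, mu3_pre, s3, log = TRUE),
        DLOR = ll_state(mu1, mu2_d, mu3_d),
        VMNR = ll_state(mu1, mu2_v, mu3_v),
        POST = dnorm(z1, mu0, s0, log = TRUE) +
          dnorm(z2, mu2_pre, s2, log = TRUE) + dnorm(z3, mu3_pre, s3, log = TRUE))
}

#' Decode STN entry, DLOR→VMNR transition and exit from a feature profile
#'
#' Left-to-right four-state decoding (PRE → DLOR → VMNR → POST) over per-site
#' emission features: log-NRMS (the background-noise and firing-density
#' step-up at entry and drop at exit), the low/oscillatory-band envelope
#' fraction (elevated in the motor DLOR) and the broad gamma fraction
#' (dominant in the non-motor VMNR). State-conditional emissions are Gaussian
#' with moments estimated from the profile itself (baseline sites for
#' PRE/POST, robust quantiles for in-STN states); only forward transitions are
#' allowed and the maximum-likelihood monotone state path is returned.
#' Boundaries are reported at the first site of each new state, so segments
#' are half-open in depth.
#'
#' If no structured path beats the no-STN path by `params$min_evidence`
#' log-likelihood units, the result is flagged degenerate (all-PRE labels,
#' `degenerate = TRUE`) with a warning.
#'
#' @param profile a `mer_profile` from [featurize_trajectory()].
#' @param params a [seg_params()] list.
#' @return A `mer_segmentation` with `source = "detected"`.
#' @export
segment_profile <- function(profile, params = seg_params()) {
  n <- nrow(profile$sites)
  if (n < profile$n_baseline + 5)
    stop("profile too short: need the baseline plus >= 5 candidate STN sites")
  ll <- seg_emissions(profile, params)
  depths <- profile$sites$depth

  # Path score for boundaries (i, j, k): PRE on 1..i-1, DLOR on i..j-1,
  # VMNR on j..k-1, POST on k..n. Cumulative sums make each candidate O(1).
  cs <- apply(ll, 2, cumsum)
  cs <- rbind(0, cs) # cs[t+1, s] = sum of ll[1..t, s]
  seg_sum <- function(state, from, to) # sum over sites from..to (may be empty)
    cs[to + 1, state] - cs[from, state]

  best <- -Inf; best_ijk <- NULL
  i_min <- 2L
  for (i in i_min:(n - params$min_dlor - params$min_vmnr + 1L)) {
    j_lo <- i + params$min_dlor
    j_hi <- n - params$min_vmnr + 1L
    if (j_lo > j_hi) next
    for (j in j_lo:j_hi) {
      # best k in j+min_vmnr .. n+1 (k = n+1 means the profile ends in VMNR)
      k_lo <- j + params$min_vmnr
      ks <- k_lo:(n + 1L)
      sc <- seg_sum("PRE", 1L, i - 1L) + seg_sum("DLOR", i, j - 1L) +
        (cs[ks, "VMNR"] - cs[j, "VMNR"]) + (cs[n + 1L, "POST"] - cs[ks, "POST"])
      w <- which.max(sc)
      if (sc[w] > best) { best <- sc[w]; best_ijk <- c(i, j, ks[w]) }
    }
  }
  null_score <- seg_sum("PRE", 1L, n)
  if (is.null(best_ijk) || best < null_score + params$min_evidence) {
    warning("degenerate decoding: no STN contrast found in the profile")
    return(new_segmentation(depths, rep("PRE", n), "detected", degenerate = TRUE))
  }
  labels <- rep("PRE", n)
  i <- best_ijk[1]; j <- best_ijk[2]; k <- best_ijk[3]
  labels[i:(j - 1)] <- "DLOR"
  labels[j:min(k - 1, n)] <- "VMNR"
  if (k <= n) labels[k:n] <- "POST"
  new_segmentation(depths, labels, "detected")
}

#' Apply an expert-supplied (manual) segmentation
#'
#' Snaps the given boundary depths to the nearest profile sites (ties go to
#' the shallower site) and labels the profile accordingly, modelling the
#' expert-correction step of intraoperative border identification.
#'
#' @param profile a `mer_profile`.
#' @param entry,dlor_exit,exit boundary depths, mm above target, with
#'   `entry > dlor_exit >= exit`, inside the profile's depth range.
#' @return A `mer_segmentation` with `source = "manual"`.
#' @export
apply_manual_segmentation <- function(profile, entry, dlor_exit, exit) {
  if (!(entry > dlor_exit && dlor_exit >= exit))
    stop("boundaries must satisfy entry > dlor_exit >= exit")
  depths <- profile$sites$depth
  if (entry > max(depths) || exit < min(depths))
    stop("boundaries outside the profile depth range")
  snap <- function(d) {
    dist <- abs(depths - d)
    cand <- which(dist == min(dist))
    cand[which.max(depths[cand])] # tie -> shallower site
  }
  i <- snap(entry); j <- snap(dlor_exit); k <- snap(exit)
  if (!(i < j && j <= k)) stop("snapped boundaries are not properly ordered")
  labels <- rep("PRE", length(depths))
  labels[i:(j - 1)] <- "DLOR"
  if (j < k) labels[j:(k - 1)] <- "VMNR"
  labels[k:length(depths)] <- "POST"
  new_segmentation(depths, labels, "manual")
}

#' STN and DLOR lengths from a segmentation
#'
#' @param seg a `mer_segmentation`.
#' @return Named vector: `stn_length` (entry - exit, mm), `dlor_length`
#'   (entry - DLOR exit, mm) and `percent_dlor` (DLOR as % of STN length).
#' @export
#' @examples
#' # entry 4, DLOR exit 1, exit -2  ->  6 mm STN, 3 mm DLOR, 50%
stn_lengths <- function(seg) {
  stn <- seg$entry_depth - seg$exit_depth
  dlor <- seg$entry_depth - seg$dlor_exit_depth
  c(stn_length = stn, dlor_length = dlor, percent_dlor = 100 * dlor / stn)
}
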