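#' Plot a depth-normalized NRMS profile
#'
#' NRMS against the normalized trajectory coordinate (0 = STN entry,
#' 1 = exit), with the STN span marked.
#'
#' @param x a `mer_nprofile`.
#' @param ... passed to [plot()].
#' @export
plot.mer_nprofile <- function(x, ...) {
  plot(x$grid, x$nrms, type = "l", lwd = 2,
       xlab = "normalized depth (0 = STN entry, 1 = exit)", ylab = "NRMS",
       main = x$id, ...)
  abline(v = c(0, 1), lty = 2, col = "grey40")
  abline(h = 1, lty = 3, col = "grey70")
  invisible(x)
}

#' Depth-normalized group spectrogram heat map
#'
#' Envelope-power fraction as a function of normalized depth (x axis) and
#' frequency (y axis), the standard group-averaged spectrogram view; use
#' `flim = c(10, 45)` to zoom on the beta band.
#'
#' @param np a `mer_nprofile` (typically a [group_average()]).
#' @param flim frequency limits in Hz.
#' @param main title.
#' @export
plot_spectrogram <- function(np, flim = c(1, 200), main = np$id) {
  sel <- np$freqs >= flim[1] & np$freqs <= flim[2]
  z <- np$spectrogram[, sel, drop = FALSE]
  image(np$grid, np$freqs[sel], z, col = hcl.colors(64, "viridis"),
        xlab = "normalized depth", ylab = "frequency (Hz)", main = main,
        useRaster = TRUE)
  abline(v = c(0, 1), lty = 2, col = "white")
  invisible(np)
}

#' Plot a raw-depth feature profile
#'
#' NRMS against depth (mm above target, descending along the x axis),
#' optionally with decoded boundaries.
#'
#' @param x a `mer_profile`.
#' @param seg optional `mer_segmentation` whose boundaries are drawn.
#' @param ... passed to [plot()].
#' @export
plot.mer_profile <- function(x, seg = NULL, ...) {
  d <- x$sites$depth
  plot(d, x$sites$nrms, type = "o", pch = 16, cex = 0.5, xlim = rev(range(d)),
       xlab = "depth (mm above target)", ylab = "NRMS", main = x$id, ...)
  abline(h = 1, lty = 3, col = "grey70")
  if (!is.null(seg) && !seg$degenerate) {
    abline(v = c(seg$entry_depth, seg$dlor_exit_depth, seg$exit_depth),
           lty = 2, col = c("forestgreen", "orange", "firebrick"))
    legend("topright", legend = c("entry", "DLOR exit", "exit"), lty = 2,
           col = c("forestgreen", "orange", "firebrick"), bty = "n", cex = 0.8)
  }
  invisible(x)
}
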