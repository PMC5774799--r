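#' Plot SNR/CNR traces against the task regressor
#'
#' @param x a `bold_metrics` object from [snr_cnr()].
#' @param regressor optional [regressor] overlaid (scaled to the metric
#'   range) to show stimulus locking.
#' @param ... passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.bold_metrics <- function(x, regressor = NULL, ...) {
  graphics::matplot(x$t, cbind(x$snr, x$cnr), type = "l", lty = 1,
                    col = c("steelblue", "firebrick"),
                    xlab = "volume", ylab = "ratio", ...)
  if (!is.null(regressor)) {
    sc <- max(c(x$snr, x$cnr), na.rm = TRUE)
    graphics::lines(seq_along(regressor$values), regressor$values * sc,
                    col = "grey60", lty = 2)
  }
  graphics::legend("topright", c("SNR", "CNR"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Overlay a thresholded correlation map on a background slice
#'
#' Greyscale background (e.g. reconstructed chi0) with positive
#' suprathreshold voxels in warm and negative ones in cool colours — the
#' usual activation-blob display for bidirectional responses.
#'
#' @param map a `corr_map` with z-scores filled in.
#' @param background 3D array (same grid) used as the underlay.
#' @param slice z-slice index (default: middle slice).
#' @param z_threshold display threshold on |z| (default 5).
#' @param png_path optional path; when given the plot is written as a PNG.
#' @return Invisibly, the number of suprathreshold voxels on the slice.
#' @export
plot_fmap_overlay <- function(map, background, slice = NULL, z_threshold = 5,
                              png_path = NULL) {
  stopifnot(inherits(map, "corr_map"))
  if (is.null(map$z)) stop("run tcorr_significance() first")
  n <- dim(map$z)
  if (is.null(slice)) slice <- n[3] %/% 2 + 1
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 640, height = 640)
    on.exit(grDevices::dev.off())
  }
  bg <- background[, , slice]
  graphics::image(seq_len(n[1]), seq_len(n[2]), bg,
                  col = grDevices::grey.colors(128), xlab = "x", ylab = "y",
                  main = sprintf("tcorr overlay, slice %d, |z| >= %.3g",
                                 slice, z_threshold), useRaster = TRUE)
  z <- map$z[, , slice]
  pos <- which(z >= z_threshold, arr.ind = TRUE)
  neg <- which(z <= -z_threshold, arr.ind = TRUE)
  if (nrow(pos)) graphics::points(pos, pch = 15, col = "orangered", cex = 0.6)
  if (nrow(neg)) graphics::points(neg, pch = 15, col = "dodgerblue", cex = 0.6)
  invisible(nrow(pos) + nrow(neg))
}
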