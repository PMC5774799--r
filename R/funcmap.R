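#' Voxel-wise task-correlation map
#'
#' Pearson correlation of every voxel timecourse in a 4D dataset (magnitude
#' A, reconstructed chi, or reconstructed dchi) against the HRF-convolved
#' task regressor task*. Collapses the 4D spatiotemporal data into a 3D
#' spatial map; positive r marks correlated (activated) voxels, negative r
#' anti-correlated ones. Voxels with constant timecourses (air, background)
#' get r = 0 by convention.
#'
#' @param series 4D numeric array or [chi_series] / [t2s_series] (magnitude
#'   view used for the latter).
#' @param regressor a [regressor] whose length matches the series; at least
#'   3 timepoints.
#' @param grid optional [vox_grid] for bare arrays.
#' @return An object of class `corr_map`: list with `grid`, `r` (3D array in
#'   \[-1, 1\]), `p`, `z` (filled by [tcorr_significance()], here p = 1 and
#'   z = 0 placeholders for constant voxels and NA otherwise until computed),
#'   and `n_t`.
#' @export
tcorr_map <- function(series, regressor, grid = NULL) {
  stopifnot(inherits(regressor, "regressor"))
  if (inherits(series, "chi_series")) {
    grid <- series$grid
    x <- series$values_ppm
  } else if (inherits(series, "t2s_series")) {
    grid <- series$grid
    x <- t2s_magnitude(series)
  } else {
    x <- series
    if (is.null(grid)) grid <- attr(series, "grid")
    if (is.null(grid)) grid <- vox_grid(dim(x)[1:3])
  }
  nt <- dim(x)[4]
  g <- regressor$values
  if (length(g) != nt)
    stop("regressor length (", length(g), ") does not match series length (",
         nt, ")")
  if (nt < 3L) stop("need at least 3 timepoints")
  nvox <- prod(dim(x)[1:3])
  m <- matrix(x, nrow = nvox, ncol = nt)
  m <- m - rowMeans(m)
  gc_ <- g - mean(g)
  gnorm <- sqrt(sum(gc_^2))
  if (gnorm == 0) stop("regressor is constant; correlation undefined")
  num <- as.vector(m %*% gc_)
  den <- sqrt(rowSums(m^2)) * gnorm
  r <- numeric(nvox)
  ok <- den > 0
  r[ok] <- num[ok] / den[ok]
  r <- pmin(pmax(r, -1), 1)
  dim(r) <- dim(x)[1:3]
  structure(list(grid = grid, r = r, p = NULL, z = NULL, n_t = nt),
            class = "corr_map")
}

#' Significance transforms for a correlation map
#'
#' Two-sided p-values via the t-transform t = r sqrt((n-2)/(1-r^2)) with
#' n - 2 degrees of freedom, and Fisher z-scores z = atanh(r) sqrt(n-3).
#' |r| = 1 voxels underflow to the smallest representable positive p; r is
#' clamped infinitesimally inside (-1, 1) before atanh so z stays finite.
#' Constant voxels (r = 0) get p = 1 and z = 0. No multiple-comparison
#' correction is applied; the maps are raw voxel-wise statistics.
#'
#' @param map a `corr_map` from [tcorr_map()].
#' @return The map with `p` and `z` filled in.
#' @export
tcorr_significance <- function(map) {
  stopifnot(inherits(map, "corr_map"))
  n <- map$n_t
  if (n < 4L) stop("need at least 4 timepoints for significance transforms")
  r <- map$r
  rc <- pmin(pmax(r, -(1 - 1e-15)), 1 - 1e-15)
  tstat <- rc * sqrt((n - 2) / (1 - rc^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p <- pmax(p, .Machine$double.xmin)
  p <- pmin(p, 1)
  z <- atanh(rc) * sqrt(n - 3)
  map$p <- p
  map$z <- z
  map
}

#' Rectangular ROI pair for SNR/CNR measurement
#'
#' @param act_box,inact_box lists with integer ranges `x`, `y`, `z`
#'   (each `c(lo, hi)`, 1-based inclusive). Conventional size 5 x 5 x 3.
#' @param grid optional [vox_grid] to validate against.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(act_box, inact_box, grid = NULL) {
  chk <- function(b, nm) {
    if (!all(c("x", "y", "z") %in% names(b))) stop(nm, " needs x, y, z ranges")
    for (ax in c("x", "y", "z")) {
      r <- b[[ax]]
      if (length(r) != 2L || r[1] > r[2] || r[1] < 1) stop(nm, " has an invalid ", ax, " range")
    }
  }
  chk(act_box, "act_box"); chk(inact_box, "inact_box")
  if (!is.null(grid)) {
    for (b in list(act_box, inact_box))
      for (i in 1:3)
        if (b[[c("x", "y", "z")[i]]][2] > grid$shape[i])
          stop("ROI box exceeds grid extent")
  }
  ov <- function(a, b) a[1] <= b[2] && b[1] <= a[2]
  if (ov(act_box$x, inact_box$x) && ov(act_box$y, inact_box$y) &&
      ov(act_box$z, inact_box$z))
    stop("act and inact boxes must be disjoint")
  structure(list(act_box = act_box, inact_box = inact_box), class = "roi_spec")
}

roi_values <- function(frame, box) {
  frame[box$x[1]:box$x[2], box$y[1]:box$y[2], box$z[1]:box$z[2]]
}

#' Dynamic SNR and CNR metrics
#'
#' Per frame: SNR\[t\] = |mean(ROI_act)| / sd(ROI_inact) and
#' CNR\[t\] = |mean(ROI_act) - mean(ROI_inact)| / sd(ROI_inact). The time
#' averages optionally exclude the reference frame (the N_t - 1 convention:
#' the complex-division reference frame is identically zero and carries no
#' signal). Frames with zero inactive-ROI spread are flagged and dropped
#' from the averages.
#'
#' @param series 4D numeric array or [chi_series].
#' @param roi a [roi_spec]; the inactive box needs at least 2 voxels.
#' @param exclude_index optional 1-based frame index excluded from the time
#'   averages (typically the complex-division reference frame).
#' @return An object of class `bold_metrics`: a data.frame with columns
#'   `t`, `snr`, `cnr`, `included`, plus attributes `snr_mean`, `cnr_mean`,
#'   `excluded_ref_index`.
#' @export
snr_cnr <- function(series, roi, exclude_index = NULL) {
  stopifnot(inherits(roi, "roi_spec"))
  x <- if (inherits(series, "chi_series")) series$values_ppm else series
  if (length(dim(x)) != 4L) stop("series must be 4D")
  nin <- prod(sapply(roi$inact_box, function(r) r[2] - r[1] + 1))
  if (nin < 2L) stop("inactive ROI needs at least 2 voxels")
  nt <- dim(x)[4]
  snr <- cnr <- numeric(nt)
  valid <- logical(nt)
  for (t in seq_len(nt)) {
    act <- roi_values(x[, , , t], roi$act_box)
    ina <- roi_values(x[, , , t], roi$inact_box)
    s <- stats::sd(ina)
    if (s == 0) {
      snr[t] <- NA_real_; cnr[t] <- NA_real_; valid[t] <- FALSE
      warning("frame ", t, ": zero spread in inactive ROI; excluded from averages")
    } else {
      snr[t] <- abs(mean(act)) / s
      cnr[t] <- abs(mean(act) - mean(ina)) / s
      valid[t] <- TRUE
    }
  }
  included <- valid
  if (!is.null(exclude_index)) included[exclude_index] <- FALSE
  out <- data.frame(t = seq_len(nt), snr = snr, cnr = cnr,
                    included = included)
  attr(out, "snr_mean") <- mean(snr[included])
  attr(out, "cnr_mean") <- mean(cnr[included])
  attr(out, "excluded_ref_index") <- exclude_index
  class(out) <- c("bold_metrics", "data.frame")
  out
}

#' Threshold a z-map into labeled activation blobs
#'
#' Connected components (26-connectivity) of |z| >= threshold, each labeled
#' with its dominant sign and peak-|z| voxel — the thresholded blob display
#' used to summarise bidirectional activation patterns.
#'
#' @param map a `corr_map` with z-scores (run [tcorr_significance()] first).
#' @param z_threshold positive threshold on |z|.
#' @return List with `labels` (3D integer array, 0 = background) and `blobs`
#'   (data.frame: label, sign, n_voxels, peak_abs_z, peak_x/y/z).
#' @export
threshold_blobs <- function(map, z_threshold) {
  stopifnot(inherits(map, "corr_map"))
  if (is.null(map$z)) stop("run tcorr_significance() before thresholding")
  if (z_threshold <= 0) stop("z_threshold must be positive")
  mask <- abs(map$z) >= z_threshold
  lab <- label_components_26(mask)
  nlab <- max(lab)
  if (nlab == 0L)
    return(list(labels = lab,
                blobs = data.frame(label = integer(0), sign = integer(0),
                                   n_voxels = integer(0), peak_abs_z = numeric(0),
                                   peak_x = integer(0), peak_y = integer(0),
                                   peak_z = integer(0))))
  rows <- lapply(seq_len(nlab), function(l) {
    idx <- which(lab == l)
    zv <- map$z[idx]
    pk <- idx[which.max(abs(zv))]
    co <- arrayInd(pk, dim(lab))
    data.frame(label = l, sign = sign(map$z[pk]), n_voxels = length(idx),
               peak_abs_z = max(abs(zv)), peak_x = co[1], peak_y = co[2],
               peak_z = co[3])
  })
  list(labels = lab, blobs = do.call(rbind, rows))
}

# Connected-component labeling of a 3D logical mask, 26-connectivity,
# iterative flood fill.
label_components_26 <- function(mask) {
  n <- dim(mask)
  lab <- array(0L, dim = n)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  nxt <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      co <- arrayInd(cur, n)
      nb <- sweep(off, 2, as.integer(co), `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= n[1] & nb[, 2] >= 1 & nb[, 2] <= n[2] &
        nb[, 3] >= 1 & nb[, 3] <= n[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * n[1] + (nb[, 3] - 1L) * n[1] * n[2]
      lin <- lin[mask[lin] & lab[lin] == 0L]
      if (length(lin)) {
        lab[lin] <- nxt
        queue <- c(queue, lin)
      }
    }
  }
  lab
}
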