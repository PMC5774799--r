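#' Dipole-inversion configuration
#'
#' Hyperparameters for susceptibility reconstruction. `tkd` is truncated
#' k-space division (filter-truncation regularisation of the divide-by-zero
#' dipole cone); `tvb` is total-variation-regularised split-Bregman
#' iteration, which multiplies by D(k) instead of dividing (the
#' multiply-by-zero reformulation).
#'
#' @param method `"tvb"` or `"tkd"`.
#' @param tkd_threshold truncation threshold on |D(k)|, in (0, 2/3);
#'   default 0.1.
#' @param tv_weight TV regularisation weight relative to the unit-normalised
#'   field; default 2e-3.
#' @param bregman_penalty split-Bregman quadratic penalty; default
#'   10 x tv_weight.
#' @param max_iters maximum split-Bregman iterations; default 100.
#' @param rel_tol relative-change stopping tolerance; default 1e-4.
#' @param zero_pad logical: zero-pad 2x before the inversion FFTs (default
#'   FALSE: the operator is then exactly diagonal in Fourier space).
#' @return An object of class `inversion_config`.
#' @export
inversion_config <- function(method = c("tvb", "tkd"), tkd_threshold = 0.1,
                             tv_weight = 2e-3,
                             bregman_penalty = 10 * tv_weight,
                             max_iters = 100L, rel_tol = 1e-4,
                             zero_pad = FALSE) {
  method <- match.arg(method)
  if (tkd_threshold <= 0 || tkd_threshold >= 2 / 3)
    stop("tkd_threshold must lie in (0, 2/3)")
  if (tv_weight <= 0 || bregman_penalty <= 0)
    stop("tv_weight and bregman_penalty must be positive")
  max_iters <- as.integer(max_iters)
  if (max_iters < 1L) stop("max_iters must be >= 1")
  if (rel_tol <= 0) stop("rel_tol must be positive")
  structure(list(method = method, tkd_threshold = tkd_threshold,
                 tv_weight = tv_weight, bregman_penalty = bregman_penalty,
                 max_iters = max_iters, rel_tol = rel_tol,
                 zero_pad = isTRUE(zero_pad)),
            class = "inversion_config")
}

# Normalise field input to a ppm-equivalent array f = b / (B0 1e-6) so that
# the forward operator is plain multiplication by D(k) and {B0, T_E} cancel.
field_to_ppm_units <- function(field, acq) {
  stopifnot(inherits(field, "field_map"))
  if (!all(is.finite(field$values_tesla))) stop("field must be finite")
  field$values_tesla / (acq$b0_tesla * 1e-6)
}

#' Truncated k-space division (TKD) inversion
#'
#' chi_hat(k) = b_hat(k) / (B0 D(k)) wherever |D(k)| >= threshold, 0 in the
#' truncated cone. Exact for spectra supported in the passband; the magic-
#' angle cone content is irrecoverably zeroed.
#'
#' @param field a [field_map] in tesla.
#' @param acq an [acq_params].
#' @param config an [inversion_config].
#' @return A [chi_volume] in ppm with attribute `converged = TRUE`.
#' @export
tkd_inversion <- function(field, acq, config = inversion_config("tkd")) {
  f <- field_to_ppm_units(field, acq)
  grid <- field$grid
  if (config$zero_pad) {
    wgrid <- pad_grid(grid)
    f <- pad_array(f, wgrid$shape)
  } else wgrid <- grid
  d <- dipole_kernel_kspace(wgrid)$values
  inv_d <- array(0, dim = wgrid$shape)
  keep <- abs(d) >= config$tkd_threshold
  inv_d[keep] <- 1 / d[keep]
  chi <- Re(ifft3(fft(f) * inv_d))
  if (config$zero_pad) chi <- crop_array(chi, grid$shape)
  out <- chi_volume(grid, chi)
  attr(out, "converged") <- TRUE
  out
}

# Forward differences with periodic wrap, per axis.
fdiff <- function(x, axis) {
  n <- dim(x)[axis]
  idx <- c(seq_len(n)[-1], 1L)
  switch(axis,
         x[idx, , , drop = FALSE] - x,
         x[, idx, , drop = FALSE] - x,
         x[, , idx, drop = FALSE] - x)
}

# Adjoint (negative backward divergence) pieces: -div of a vector field.
neg_div <- function(vx, vy, vz) {
  bshift <- function(x, axis) {
    n <- dim(x)[axis]
    idx <- c(n, seq_len(n - 1L))
    switch(axis,
           x[idx, , , drop = FALSE],
           x[, idx, , drop = FALSE],
           x[, , idx, drop = FALSE])
  }
  (bshift(vx, 1) - vx) + (bshift(vy, 2) - vy) + (bshift(vz, 3) - vz)
}

#' Total-variation split-Bregman (TVB) dipole inversion
#'
#' Approximately solves
#' argmin over chi of || D(k) chi_hat - f_hat ||^2 + lambda TV(chi)
#' (isotropic TV, forward differences, periodic boundary) by split-Bregman
#' iteration: the quadratic chi-subproblem is solved exactly in Fourier
#' space by multiplication with D(k) — never division, so the dipole cone is
#' a multiply-by-zero rather than a divide-by-zero — followed by isotropic
#' soft-threshold shrinkage of the gradient field and a Bregman update. The
#' field is internally scaled to unit maximum so `tv_weight` is scale-free,
#' and the acquisition pair \{B0, T_E\} cancels between the forward and
#' inverse models. Warm-started from the TKD solution.
#'
#' @param field a [field_map] in tesla.
#' @param acq an [acq_params].
#' @param config an [inversion_config].
#' @return A [chi_volume] in ppm with attributes `converged` (logical),
#'   `iterations`, and `residuals` (data-fidelity residual per iterate).
#' @export
tvb_inversion <- function(field, acq, config = inversion_config("tvb")) {
  f <- field_to_ppm_units(field, acq)
  grid <- field$grid
  if (config$zero_pad) {
    wgrid <- pad_grid(grid)
    f <- pad_array(f, wgrid$shape)
  } else wgrid <- grid
  scale <- max(abs(f))
  if (scale == 0) {
    out <- chi_volume(grid, array(0, dim = grid$shape))
    attr(out, "converged") <- TRUE
    attr(out, "iterations") <- 1L
    attr(out, "residuals") <- 0
    return(out)
  }
  fn <- f / scale
  d <- dipole_kernel_kspace(wgrid)$values
  fhat <- fft(fn)
  lambda <- config$tv_weight
  mu <- config$bregman_penalty
  # Fourier spectrum of the forward-difference Laplacian (grad^T grad)
  n <- wgrid$shape
  gsp <- function(nn) abs(exp(2i * pi * seq(0, nn - 1) / nn) - 1)^2
  lx <- gsp(n[1]); ly <- gsp(n[2]); lz <- gsp(n[3])
  lap <- array(lx, dim = n) + array(rep(ly, each = n[1]), dim = n) +
    array(rep(lz, each = n[1] * n[2]), dim = n)
  denom <- d^2 + mu * lap
  denom[denom == 0] <- 1  # DC bin: numerator is 0 there too (mean-free)
  dtf <- d * fhat         # D is real: conj(D) = D

  # warm start: TKD on the normalised field
  inv_d <- array(0, dim = n)
  keep <- abs(d) >= config$tkd_threshold
  inv_d[keep] <- 1 / d[keep]
  chi <- Re(ifft3(fhat * inv_d))

  zero <- array(0, dim = n)
  dx <- zero; dy <- zero; dz <- zero
  bx <- zero; by <- zero; bz <- zero
  residuals <- numeric(0)
  converged <- FALSE
  iterations <- config$max_iters
  for (it in seq_len(config$max_iters)) {
    chi_prev <- chi
    w <- neg_div(dx - bx, dy - by, dz - bz)
    chihat <- (dtf + mu * fft(w)) / denom
    chihat[1, 1, 1] <- 0
    chi <- Re(ifft3(chihat))
    residuals <- c(residuals, sqrt(sum(Mod(d * chihat - fhat)^2)) /
                     sqrt(length(fn)))
    gx <- fdiff(chi, 1) + bx
    gy <- fdiff(chi, 2) + by
    gz <- fdiff(chi, 3) + bz
    mag <- sqrt(gx^2 + gy^2 + gz^2)
    shrink <- pmax(mag - lambda / mu, 0)
    nzm <- mag > 0
    fac <- zero; fac[nzm] <- shrink[nzm] / mag[nzm]
    dx <- fac * gx; dy <- fac * gy; dz <- fac * gz
    bx <- gx - dx; by <- gy - dy; bz <- gz - dz
    rel <- sqrt(sum((chi - chi_prev)^2)) / max(sqrt(sum(chi^2)), 1e-30)
    if (rel < config$rel_tol) {
      converged <- TRUE
      iterations <- it
      break
    }
  }
  chi <- chi * scale
  if (config$zero_pad) chi <- crop_array(chi, grid$shape)
  out <- chi_volume(grid, chi)
  attr(out, "converged") <- converged
  attr(out, "iterations") <- iterations
  attr(out, "residuals") <- residuals * scale
  out
}

invert_field_frame <- function(field, acq, config) {
  if (config$method == "tkd") tkd_inversion(field, acq, config)
  else tvb_inversion(field, acq, config)
}

#' Full susceptibility series reconstruction from wrapped phase
#'
#' Per frame: Laplacian unwrapping, linear field-from-phase conversion, then
#' dipole inversion — the QSM pipeline repeated along time.
#'
#' @param phase_series 4D wrapped phase array or [t2s_series].
#' @param acq an [acq_params].
#' @param config an [inversion_config].
#' @param grid optional [vox_grid] for bare arrays.
#' @param tr_s repetition time for the output series (default `acq$tr_s`).
#' @return A [chi_series] in ppm with attribute `converged` (per frame).
#' @export
reconstruct_chi_series <- function(phase_series, acq,
                                   config = inversion_config(),
                                   grid = NULL, tr_s = acq$tr_s) {
  if (inherits(phase_series, "t2s_series")) {
    grid <- phase_series$grid
    p <- t2s_phase(phase_series)
  } else {
    p <- phase_series
    if (length(dim(p)) == 3L) dim(p) <- c(dim(p), 1L)
    if (is.null(grid)) grid <- attr(phase_series, "grid")
    if (is.null(grid)) grid <- vox_grid(dim(p)[1:3])
  }
  nt <- dim(p)[4]
  out <- array(0, dim = c(grid$shape, nt))
  conv <- logical(nt)
  for (t in seq_len(nt)) {
    unw <- laplacian_unwrap(phase_volume(grid, p[, , , t], TRUE))
    fld <- phase_to_field(unw, acq)
    rec <- invert_field_frame(fld, acq, config)
    out[, , , t] <- rec$values_ppm
    conv[t] <- isTRUE(attr(rec, "converged"))
  }
  res <- chi_series(grid, out, tr_s)
  attr(res, "converged") <- conv
  if (!all(conv))
    message("dipole inversion: ", sum(!conv), " of ", nt,
            " frame(s) stopped at max_iters before reaching rel_tol")
  res
}

#' BOLD perturbation series reconstruction from phase differences
#'
#' Per frame: linear field-from-phase conversion of dP (no unwrapping is
#' needed — complex division guarantees |dP| < pi), then dipole inversion.
#' The reference frame reconstructs to (numerically) zero.
#'
#' @param dphase a [dphase_series].
#' @param acq an [acq_params].
#' @param config an [inversion_config].
#' @param tr_s repetition time for the output series (default `acq$tr_s`).
#' @return A [chi_series] of dchi in ppm with attribute `converged`.
#' @export
reconstruct_dchi_series <- function(dphase, acq, config = inversion_config(),
                                    tr_s = acq$tr_s) {
  stopifnot(inherits(dphase, "dphase_series"))
  grid <- dphase$grid
  nt <- dim(dphase$values_rad)[4]
  scale <- 1 / (acq$gamma_rad_per_s_per_tesla * acq$te_s)
  out <- array(0, dim = c(grid$shape, nt))
  conv <- logical(nt)
  for (t in seq_len(nt)) {
    b <- dphase$values_rad[, , , t] * scale
    fld <- structure(list(grid = grid, values_tesla = b - mean(b)),
                     class = "field_map")
    rec <- invert_field_frame(fld, acq, config)
    out[, , , t] <- rec$values_ppm
    conv[t] <- isTRUE(attr(rec, "converged"))
  }
  res <- chi_series(grid, out, tr_s)
  attr(res, "converged") <- conv
  if (!all(conv))
    message("dipole inversion: ", sum(!conv), " of ", nt,
            " frame(s) stopped at max_iters before reaching rel_tol")
  res
}

#' Isotropic total variation of a 3D array
#'
#' Sum over voxels of the Euclidean norm of the forward-difference gradient
#' (periodic boundary) — the regulariser used by [tvb_inversion()], exposed
#' for diagnostics such as smoothness comparisons between reconstruction
#' and input phase.
#'
#' @param x 3D numeric array.
#' @return Scalar TV value.
#' @export
total_variation <- function(x) {
  sum(sqrt(fdiff(x, 1)^2 + fdiff(x, 2)^2 + fdiff(x, 3)^2))
}
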