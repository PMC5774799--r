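#' Complex-division extraction of BOLD phase perturbations
#'
#' Computes dP\[r, t\] = Arg(exp(i P\[r, t\]) / exp(i P_ref\[r\])), the wrapped
#' phase difference of each frame against a reference frame. The static
#' (possibly severely wrapped) phase background cancels exactly, so the
#' result equals the true phase change whenever that change lies in
#' (-pi, pi) — no spatial unwrapping is needed on this pathway.
#'
#' @param phase_series 4D numeric array of wrapped phases (x, y, z, t), or a
#'   [t2s_series] (its phase view is used).
#' @param ref_index 1-based index of the reference frame (default 1).
#' @return A [dphase_series].
#' @export
complex_divide_phase <- function(phase_series, ref_index = 1L) {
  if (inherits(phase_series, "t2s_series")) {
    grid <- phase_series$grid
    p <- t2s_phase(phase_series)
  } else {
    p <- phase_series
    if (length(dim(p)) != 4L) stop("phase_series must be a 4D array")
    grid <- attr(p, "grid")
    if (is.null(grid)) grid <- vox_grid(dim(p)[1:3])
  }
  nt <- dim(p)[4]
  ref_index <- as.integer(ref_index)
  if (ref_index < 1L || ref_index > nt)
    stop("ref_index out of range [1, ", nt, "]")
  pref <- p[, , , ref_index]
  out <- array(0, dim = dim(p))
  for (t in seq_len(nt))
    out[, , , t] <- wrap_phase(p[, , , t] - as.vector(pref))
  out[, , , ref_index] <- 0
  dphase_series(grid, out, ref_index)
}

#' Laplacian 3D phase unwrapping
#'
#' Fourier-domain Laplacian unwrapping of a wrapped 3D phase volume:
#' \deqn{P_{unwrap} = F^{-1}\{ F\{\cos P \cdot F^{-1}(k^2 F(\sin P)) -
#'   \sin P \cdot F^{-1}(k^2 F(\cos P))\} / k^2 \}}
#' with the zero-frequency coefficient of the final division set to 0, so
#' the output is mean-free. Besides removing 2 pi wraps, the operator
#' annihilates harmonic phase components (Laplacian of exp(iP) zero), which
#' largely removes harmonic background phase.
#'
#' @param wrapped a [phase_volume] flagged wrapped, or a bare 3D array.
#' @param mask optional logical 3D array: voxels outside are zeroed before
#'   unwrapping (default: none).
#' @return A [phase_volume] flagged unwrapped (mean-free).
#' @export
laplacian_unwrap <- function(wrapped, mask = NULL) {
  if (inherits(wrapped, "phase_volume")) {
    if (!wrapped$wrapped) stop("input must be flagged wrapped")
    grid <- wrapped$grid
    p <- wrapped$values_rad
  } else {
    p <- wrapped
    grid <- vox_grid(dim(p))
  }
  if (!all(is.finite(p))) stop("phase must be finite")
  if (!is.null(mask)) p[!mask] <- 0
  k2 <- freq_sq(grid)
  sp <- sin(p); cp <- cos(p)
  num <- cp * Re(ifft3(k2 * fft(sp))) - sp * Re(ifft3(k2 * fft(cp)))
  nhat <- fft(num)
  inv_k2 <- array(0, dim = grid$shape)
  nz <- k2 > 0
  inv_k2[nz] <- 1 / k2[nz]          # DC coefficient -> 0: mean-free output
  out <- Re(ifft3(nhat * inv_k2))
  phase_volume(grid, out, wrapped = FALSE)
}

#' Frame-wise Laplacian unwrapping of a 4D phase series
#'
#' Applies [laplacian_unwrap()] independently to each frame; frames never
#' couple, so the operation commutes with any frame permutation.
#'
#' @param phase_series 4D numeric array of wrapped phases, or a
#'   [t2s_series].
#' @param grid optional [vox_grid] when a bare array is given.
#' @param mask optional 3D logical mask shared by all frames.
#' @return 4D numeric array of unwrapped phases with attribute `grid`.
#' @export
unwrap_series <- function(phase_series, grid = NULL, mask = NULL) {
  if (inherits(phase_series, "t2s_series")) {
    grid <- phase_series$grid
    p <- t2s_phase(phase_series)
  } else {
    p <- phase_series
    if (is.null(grid)) grid <- vox_grid(dim(p)[1:3])
  }
  out <- array(0, dim = dim(p))
  for (t in seq_len(dim(p)[4]))
    out[, , , t] <- laplacian_unwrap(phase_volume(grid, p[, , , t], TRUE),
                                     mask = mask)$values_rad
  attr(out, "grid") <- grid
  out
}

#' Linear field-from-phase conversion
#'
#' b = P / (gamma T_E): the linear (first-order) T2* phase imaging model
#' inverted. Valid for unwrapped phase volumes and for complex-division
#' phase-difference series (which need no unwrapping).
#'
#' @param phase a [phase_volume] (unwrapped), a [dphase_series], or a bare
#'   numeric array (trusted to be unwrapped).
#' @param acq an [acq_params].
#' @return A [field_map] for 3D input, a [field_series] for 4D input.
#' @export
phase_to_field <- function(phase, acq) {
  stopifnot(inherits(acq, "acq_params"))
  if (acq$te_s <= 0) stop("te_s must be positive")
  scale <- 1 / (acq$gamma_rad_per_s_per_tesla * acq$te_s)
  if (inherits(phase, "phase_volume")) {
    if (phase$wrapped) stop("phase must be unwrapped before field conversion")
    b <- phase$values_rad * scale
    return(structure(list(grid = phase$grid, values_tesla = b),
                     class = "field_map"))
  }
  if (inherits(phase, "dphase_series"))
    return(field_series(phase$grid, phase$values_rad * scale))
  if (is.numeric(phase)) {
    nd <- length(dim(phase))
    grid <- attr(phase, "grid")
    if (is.null(grid)) grid <- vox_grid(dim(phase)[1:3])
    if (nd == 3L)
      return(structure(list(grid = grid, values_tesla = phase * scale),
                       class = "field_map"))
    if (nd == 4L) return(field_series(grid, phase * scale))
  }
  stop("phase must be a phase_volume, dphase_series, or 3D/4D array")
}
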