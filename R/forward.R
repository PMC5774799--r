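#' Spatial dipole kernel value
#'
#' Field pattern of a unit point magnetic dipole at a spatial offset:
#' (3 z^2 - r^2) / (4 pi r^5), with z the offset component along the main
#' field direction. Singular at zero offset.
#'
#' @param offset_mm numeric 3-vector, offset from the dipole in mm (any
#'   consistent length unit works; the kernel scales as 1/length^3).
#' @param b0_direction unit vector of the main-field direction.
#' @return Kernel value (units 1/length^3).
#' @export
dipole_kernel_spatial <- function(offset_mm, b0_direction = c(0, 0, 1)) {
  r2 <- sum(offset_mm^2)
  if (r2 == 0) stop("dipole kernel is singular at zero offset")
  z <- sum(offset_mm * b0_direction)
  (3 * z^2 - r2) / (4 * pi * r2^2.5)
}

#' k-space dipole kernel D(k)
#'
#' Fourier representation of the point-dipole field kernel on the grid's
#' discrete frequency lattice: D(k) = 1/3 - k_z^2 / |k|^2, with k_z the
#' frequency component along the main-field direction. The undefined
#' zero-frequency coefficient is set to 0, which makes every computed field
#' mean-free (the uniform susceptibility offset is unobservable in phase
#' differences).
#'
#' @param grid a [vox_grid].
#' @return List with `grid` and `values` (3D array in \[-2/3, 1/3\]), class
#'   `dipole_kernel_k`.
#' @export
dipole_kernel_kspace <- function(grid) {
  k <- freq_components(grid)
  kz <- grid$b0_direction[1] * k$kx + grid$b0_direction[2] * k$ky +
    grid$b0_direction[3] * k$kz
  k2 <- k$kx^2 + k$ky^2 + k$kz^2
  d <- array(0, dim = grid$shape)
  nz <- k2 > 0
  d[nz] <- 1 / 3 - kz[nz]^2 / k2[nz]
  structure(list(grid = grid, values = d), class = "dipole_kernel_k")
}

pad_grid <- function(grid, factor = 2L) {
  vox_grid(grid$shape * factor, grid$voxel_size_mm, grid$b0_direction)
}

pad_array <- function(x, shape_out) {
  out <- array(0, dim = shape_out)
  n <- dim(x)
  out[seq_len(n[1]), seq_len(n[2]), seq_len(n[3])] <- x
  out
}

crop_array <- function(x, shape_out) {
  x[seq_len(shape_out[1]), seq_len(shape_out[2]), seq_len(shape_out[3]),
    drop = FALSE]
}

# Core Fourier-domain dipole convolution of a ppm chi array -> field in tesla.
field_from_chi_array <- function(vals_ppm, grid, b0_tesla, zero_pad = TRUE) {
  if (!all(is.finite(vals_ppm))) stop("chi values must be finite")
  if (zero_pad) {
    pgrid <- pad_grid(grid)
    work <- pad_array(vals_ppm, pgrid$shape)
  } else {
    pgrid <- grid
    work <- vals_ppm
  }
  d <- dipole_kernel_kspace(pgrid)$values
  b <- Re(ifft3(fft(work) * d)) * b0_tesla * 1e-6
  if (zero_pad) b <- crop_array(b, grid$shape)
  b - mean(b)  # mean-free convention (D(0) = 0; exact after cropping too)
}

#' Susceptibility-to-field forward convolution
#'
#' Computes the z-component field perturbation b = B0 (chi x 1e-6) * h_dipole
#' by Fourier multiplication with D(k). Applied frame-by-frame to a series.
#'
#' @param chi a [chi_volume] or [chi_series] in ppm.
#' @param acq an [acq_params] (only `b0_tesla` is used here).
#' @param zero_pad logical: zero-pad 2x per axis before the FFT to suppress
#'   periodic wrap-around (default TRUE).
#' @return A [field_map] (or [field_series]) in tesla.
#' @export
chi_to_field <- function(chi, acq, zero_pad = TRUE) {
  stopifnot(inherits(acq, "acq_params"))
  if (inherits(chi, "chi_volume")) {
    b <- field_from_chi_array(chi$values_ppm, chi$grid, acq$b0_tesla, zero_pad)
    return(field_map(chi$grid, b))
  }
  if (inherits(chi, "chi_series")) {
    nt <- dim(chi$values_ppm)[4]
    out <- array(0, dim = dim(chi$values_ppm))
    for (t in seq_len(nt))
      out[, , , t] <- field_from_chi_array(chi$values_ppm[, , , t], chi$grid,
                                           acq$b0_tesla, zero_pad)
    return(field_series(chi$grid, out))
  }
  stop("chi must be a chi_volume or chi_series")
}

#' Analytic field of a uniform susceptibility sphere
#'
#' Closed-form exterior dipole field of a uniformly perturbed sphere:
#' b = B0 (dchi/3) (a/r)^3 (3 cos^2 theta - 1) outside, 0 inside (the
#' Lorentz-corrected interior, consistent with the mean-free D(0) = 0
#' convention). Serves as the independent oracle for [chi_to_field()].
#'
#' @param grid a [vox_grid].
#' @param center_mm sphere centre in mm relative to the grid centre.
#' @param radius_mm sphere radius in mm.
#' @param dchi_ppm susceptibility contrast of the sphere in ppm.
#' @param acq an [acq_params].
#' @return A 3D numeric array of field values in tesla (not mean-free: the
#'   raw closed form, for oracle comparisons).
#' @export
sphere_field_analytic <- function(grid, center_mm, radius_mm, dchi_ppm, acq) {
  if (radius_mm <= 0) stop("radius must be positive")
  b <- blob_spec(center_mm, radius_mm, dchi_ppm, "static")
  if (!blob_inside_grid(b, grid)) stop("sphere extends outside the grid")
  co <- coord_components(grid)
  dx <- co$x - center_mm[1]; dy <- co$y - center_mm[2]; dz <- co$z - center_mm[3]
  zz <- grid$b0_direction[1] * dx + grid$b0_direction[2] * dy +
    grid$b0_direction[3] * dz
  r2 <- dx^2 + dy^2 + dz^2
  out <- array(0, dim = grid$shape)
  ext <- r2 > radius_mm^2
  # 3 cos^2(theta) - 1 with cos(theta) = z/r
  out[ext] <- acq$b0_tesla * (dchi_ppm * 1e-6 / 3) *
    (radius_mm^2 / r2[ext])^1.5 * (3 * zz[ext]^2 / r2[ext] - 1)
  out
}

# Block-average a fine array down to the coarse grid (supersample s per axis).
block_average <- function(fine, shape_coarse, s) {
  n <- shape_coarse
  dim(fine) <- c(s[1], n[1], s[2], n[2], s[3], n[3])
  fine <- aperm(fine, c(1, 3, 5, 2, 4, 6))
  dim(fine) <- c(prod(s), prod(n))
  out <- colMeans(fine)
  dim(out) <- n
  out
}

#' Intravoxel dephasing of a fine-grid field snapshot
#'
#' Averages unit phasors exp(i gamma T_E b) over each coarse voxel's block of
#' supersampled field values: C\[r\] = (1/|Omega|) sum over the block. With
#' supersample 1 this reduces to a single phasor per voxel (|C| = 1).
#'
#' @param field_fine a [field_map] on the supersampled grid.
#' @param acq an [acq_params]; `acq$supersample` relates the fine grid to the
#'   coarse one.
#' @return 3D complex array on the coarse grid.
#' @export
dephase_to_complex <- function(field_fine, acq) {
  stopifnot(inherits(field_fine, "field_map"), inherits(acq, "acq_params"))
  s <- rep(acq$supersample, 3)
  nf <- field_fine$grid$shape
  if (any(nf %% s != 0))
    stop("fine grid shape must be an integer multiple of the supersample factor")
  nc <- nf %/% s
  phasors <- exp(1i * acq$gamma_rad_per_s_per_tesla * acq$te_s *
                   field_fine$values_tesla)
  block_average(phasors, nc, s)
}

upsample_nn <- function(vals, s) {
  n <- dim(vals)
  vals[rep(seq_len(n[1]), each = s), rep(seq_len(n[2]), each = s),
       rep(seq_len(n[3]), each = s), drop = FALSE]
}

fine_grid_of <- function(grid, s) {
  vox_grid(grid$shape * s, grid$voxel_size_mm / s, grid$b0_direction)
}

#' Forward T2* simulation of a susceptibility series
#'
#' Per frame: upsample chi to the fine grid (nearest neighbour, exact for
#' piecewise-constant phantoms), compute the fine-scale dipole field, average
#' unit phasors over each voxel (intravoxel dephasing), and optionally add
#' i.i.d. complex Gaussian noise. Magnitude and wrapped-phase views of the
#' result are available via [t2s_magnitude()] / [t2s_phase()].
#'
#' @param chi_series_obj a [chi_series] (typically chi0 + dchi).
#' @param acq an [acq_params]; `supersample` controls intravoxel sampling.
#' @param noise_sd complex-noise standard deviation per real/imaginary
#'   channel (on the unit-normalised signal); 0 disables.
#' @param seed integer seed, required when noise_sd > 0.
#' @param zero_pad passed to the field convolution (default TRUE).
#' @return A [t2s_series].
#' @export
simulate_t2star_series <- function(chi_series_obj, acq, noise_sd = 0,
                                   seed = NULL, zero_pad = TRUE) {
  stopifnot(inherits(chi_series_obj, "chi_series"), inherits(acq, "acq_params"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  grid <- chi_series_obj$grid
  s <- acq$supersample
  fgrid <- fine_grid_of(grid, s)
  nt <- dim(chi_series_obj$values_ppm)[4]
  out <- array(0i, dim = c(grid$shape, nt))
  for (t in seq_len(nt)) {
    frame <- chi_series_obj$values_ppm[, , , t]
    fine <- if (s > 1L) upsample_nn(frame, s) else frame
    b <- field_from_chi_array(fine, fgrid, acq$b0_tesla, zero_pad)
    out[, , , t] <- dephase_to_complex(field_map(fgrid, b), acq)
  }
  if (noise_sd > 0) {
    if (is.null(seed)) stop("a seed is required when noise is enabled")
    n <- length(out)
    noise <- with_seed(seed, complex(real = stats::rnorm(n, 0, noise_sd),
                                     imaginary = stats::rnorm(n, 0, noise_sd)))
    dim(noise) <- dim(out)
    out <- out + noise
    # renormalise so the |C| <= 1 container contract still holds
    mx <- max(Mod(out))
    if (mx > 1) out <- out / mx
  }
  t2s_series(grid, out, acq)
}

#' First-order magnitude approximation (diagnostic)
#'
#' Evaluates the first-order Taylor expansion of the intravoxel magnitude
#' verbatim: A ~ 1 + (gamma T_E)^2 / (2 |Omega|) sum over the block of b^2.
#' Note the expansion grows above 1 while the exact phasor average satisfies
#' A <= 1; the sign of this discrepancy is a documented property of the
#' truncated expansion and this function is a diagnostic, not a surrogate
#' for [dephase_to_complex()].
#'
#' @param field_fine a [field_map] on the supersampled grid.
#' @param acq an [acq_params].
#' @return 3D numeric array of approximate magnitudes (>= 1).
#' @export
magnitude_first_order <- function(field_fine, acq) {
  stopifnot(inherits(field_fine, "field_map"))
  s <- rep(acq$supersample, 3)
  nc <- field_fine$grid$shape %/% s
  g <- acq$gamma_rad_per_s_per_tesla * acq$te_s
  m2 <- block_average(field_fine$values_tesla^2, nc, s)
  1 + g^2 / 2 * m2
}

#' Taylor-order phase approximations (diagnostic)
#'
#' Order 1: gamma T_E <b> (voxel-mean field). Order 2:
#' arctan(gamma T_E <b> / (1 - (gamma T_E)^2 <b^2> / 2)).
#'
#' @param field_fine a [field_map] on the supersampled grid.
#' @param acq an [acq_params].
#' @param order 1 or 2.
#' @return 3D numeric array of approximate phases in radians.
#' @export
phase_taylor <- function(field_fine, acq, order = 1L) {
  stopifnot(inherits(field_fine, "field_map"))
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2")
  s <- rep(acq$supersample, 3)
  nc <- field_fine$grid$shape %/% s
  g <- acq$gamma_rad_per_s_per_tesla * acq$te_s
  m1 <- block_average(field_fine$values_tesla, nc, s)
  if (order == 1L) return(g * m1)
  m2 <- block_average(field_fine$values_tesla^2, nc, s)
  atan(g * m1 / (1 - g^2 * m2 / 2))
}

#' Partial-volume rasterization of a uniform sphere
#'
#' Builds a sphere on the voxel grid with anti-aliased edges: each voxel
#' holds the fraction of its supersampled subvoxel centres falling inside
#' the sphere, times the amplitude. The soft one-voxel surface shell
#' suppresses the Gibbs ringing that a binary rasterization injects into
#' FFT-based field computations, which matters when comparing against the
#' closed-form sphere field.
#'
#' @param grid a [vox_grid].
#' @param center_mm sphere centre in mm relative to the grid centre.
#' @param radius_mm sphere radius in mm.
#' @param amplitude_ppm interior amplitude in ppm.
#' @param supersample subvoxel sampling factor per axis (default 4).
#' @return A [chi_volume].
#' @export
rasterize_sphere <- function(grid, center_mm, radius_mm, amplitude_ppm,
                             supersample = 4L) {
  if (radius_mm <= 0) stop("radius must be positive")
  s <- as.integer(supersample)
  if (s < 1L) stop("supersample must be >= 1")
  n <- grid$shape; d <- grid$voxel_size_mm
  axco <- function(i) (seq_len(n[i]) - (n[i] %/% 2 + 1)) * d[i]
  offs <- function(i) ((seq_len(s) - (s + 1) / 2) / s) * d[i]
  fx <- rep(axco(1), each = s) + rep(offs(1), times = n[1])
  fy <- rep(axco(2), each = s) + rep(offs(2), times = n[2])
  fz <- rep(axco(3), each = s) + rep(offs(3), times = n[3])
  nf <- n * s
  X <- array(fx, nf)
  Y <- array(rep(fy, each = nf[1]), nf)
  Z <- array(rep(fz, each = nf[1] * nf[2]), nf)
  inside <- (X - center_mm[1])^2 + (Y - center_mm[2])^2 +
    (Z - center_mm[3])^2 <= radius_mm^2
  frac <- if (s > 1L) block_average(inside + 0, n, rep(s, 3)) else inside + 0
  chi_volume(grid, frac * amplitude_ppm)
}
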