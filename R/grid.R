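#' Voxel grid geometry
#'
#' Defines the geometry contract shared by every volume in the package: the
#' array shape, the physical voxel size, and the direction of the main field
#' B0 relative to the array axes. All FFT-based operators (dipole convolution,
#' Laplacian unwrapping, dipole inversion) derive their discrete frequency
#' grids from this object, so two volumes interoperate only if their grids
#' are equal.
#'
#' @param shape integer vector of length 3, array dimensions (nx, ny, nz);
#'   each entry must be >= 8 so the FFT-based operators are well sampled.
#' @param voxel_size_mm numeric vector of length 3, voxel edge lengths in mm.
#' @param b0_direction numeric unit 3-vector giving the main-field direction
#'   in array coordinates. Default is the third array axis.
#' @return An object of class `vox_grid`.
#' @export
vox_grid <- function(shape, voxel_size_mm = c(1, 1, 1),
                     b0_direction = c(0, 0, 1)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stop("grid shape must be 3 integers, each >= 8 (FFT-based operators)")
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be 3 positive reals")
  b0_direction <- as.numeric(b0_direction)
  nrm <- sqrt(sum(b0_direction^2))
  if (abs(nrm - 1) > 1e-6) stop("b0_direction must be a unit vector")
  b0_direction <- b0_direction / nrm
  if (abs(sqrt(sum(b0_direction^2)) - 1) > 1e-12)
    stop("b0_direction normalisation failed")
  structure(list(shape = shape, voxel_size_mm = as.numeric(voxel_size_mm),
                 b0_direction = b0_direction),
            class = "vox_grid")
}

#' @export
print.vox_grid <- function(x, ...) {
  cat(sprintf("<vox_grid> %d x %d x %d voxels, %.3g x %.3g x %.3g mm, B0 = (%.3g, %.3g, %.3g)\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3],
              x$b0_direction[1], x$b0_direction[2], x$b0_direction[3]))
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-9) {
  identical(a$shape, b$shape) &&
    max(abs(a$voxel_size_mm - b$voxel_size_mm)) < tol &&
    max(abs(a$b0_direction - b$b0_direction)) < tol
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!grids_equal(a, b))
    stop(sprintf("grid mismatch between %s: (%s) vs (%s)", what,
                 paste(a$shape, collapse = "x"),
                 paste(b$shape, collapse = "x")))
  invisible(TRUE)
}

# DFT sample frequencies in cycles/mm for one axis (numpy fftfreq convention)
fft_freq <- function(n, d) {
  i <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L))
  i / (n * d)
}

# Physical frequency component arrays (cycles/mm) for a grid, x fastest.
freq_components <- function(grid) {
  n <- grid$shape; d <- grid$voxel_size_mm
  kx <- fft_freq(n[1], d[1]); ky <- fft_freq(n[2], d[2]); kz <- fft_freq(n[3], d[3])
  list(
    kx = array(kx, dim = n),
    ky = array(rep(ky, each = n[1]), dim = n),
    kz = array(rep(kz, each = n[1] * n[2]), dim = n)
  )
}

# |k|^2 array in (cycles/mm)^2; zero at the DC bin.
freq_sq <- function(grid) {
  k <- freq_components(grid)
  k$kx^2 + k$ky^2 + k$kz^2
}

# World coordinates (mm) of voxel centres relative to the grid centre.
# Centre convention: voxel (n %/% 2 + 1) sits at 0 on each axis, matching the
# FFT origin after fftshift-free indexing.
coord_components <- function(grid) {
  n <- grid$shape; d <- grid$voxel_size_mm
  cx <- (seq_len(n[1]) - (n[1] %/% 2 + 1)) * d[1]
  cy <- (seq_len(n[2]) - (n[2] %/% 2 + 1)) * d[2]
  cz <- (seq_len(n[3]) - (n[3] %/% 2 + 1)) * d[3]
  list(
    x = array(cx, dim = n),
    y = array(rep(cy, each = n[1]), dim = n),
    z = array(rep(cz, each = n[1] * n[2]), dim = n)
  )
}

ifft3 <- function(x) fft(x, inverse = TRUE) / length(x)

# Wrap angles into [-pi, pi)
wrap_phase <- function(x) ((x + pi) %% (2 * pi)) - pi
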