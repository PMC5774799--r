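#' Susceptibility volume (3D, ppm)
#'
#' Container for a static susceptibility map chi0 (or any single-snapshot
#' chi). Values are stored in parts per million of dimensionless SI
#' susceptibility; the 1e-6 factor is applied only inside the forward field
#' computation.
#'
#' @param grid a [vox_grid].
#' @param values_ppm 3D numeric array matching the grid shape.
#' @return An object of class `chi_volume`.
#' @export
chi_volume <- function(grid, values_ppm) {
  check_values(values_ppm, grid$shape, "chi_volume values_ppm")
  structure(list(grid = grid, values_ppm = values_ppm), class = "chi_volume")
}

#' Susceptibility series (4D, ppm)
#'
#' Container for a dynamic susceptibility source chi(r, t) or its
#' perturbation component dchi(r, t), sampled once per repetition time.
#'
#' @param grid a [vox_grid].
#' @param values_ppm 4D numeric array (x, y, z, t).
#' @param tr_s repetition time in seconds.
#' @return An object of class `chi_series`.
#' @export
chi_series <- function(grid, values_ppm, tr_s) {
  check_values(values_ppm, c(grid$shape, dim(values_ppm)[4]), "chi_series values_ppm")
  if (length(dim(values_ppm)) != 4L) stop("chi_series needs a 4D array")
  if (!is.numeric(tr_s) || tr_s <= 0) stop("tr_s must be positive")
  structure(list(grid = grid, values_ppm = values_ppm, tr_s = tr_s),
            class = "chi_series")
}

#' Field map (3D, tesla)
#'
#' z-component of the susceptibility-induced field perturbation. The package
#' convention is mean-free: the spatially uniform field offset is
#' unobservable in phase differences and the dipole kernel's DC coefficient
#' is set to zero, so every field map averages to (numerically) zero.
#'
#' @param grid a [vox_grid].
#' @param values_tesla 3D numeric array in tesla.
#' @return An object of class `field_map`.
#' @export
field_map <- function(grid, values_tesla) {
  check_values(values_tesla, grid$shape, "field_map values_tesla")
  m <- mean(values_tesla); peak <- max(abs(values_tesla))
  if (peak > 0 && abs(m) > 1e-9 * peak)
    stop("field_map violates the mean-free convention: |mean| = ",
         format(abs(m)), " vs max|b| = ", format(peak))
  structure(list(grid = grid, values_tesla = values_tesla), class = "field_map")
}

#' Field map series (4D, tesla)
#' @param grid a [vox_grid].
#' @param values_tesla 4D numeric array in tesla (x, y, z, t).
#' @return An object of class `field_series`.
#' @export
field_series <- function(grid, values_tesla) {
  if (length(dim(values_tesla)) != 4L) stop("field_series needs a 4D array")
  if (!all(is.finite(values_tesla))) stop("field values must be finite")
  if (!identical(dim(values_tesla)[1:3], as.integer(grid$shape)))
    stop("field_series shape does not match grid")
  structure(list(grid = grid, values_tesla = values_tesla), class = "field_series")
}

#' Acquisition parameters
#'
#' Gradient-echo acquisition parameters used by the intravoxel dephasing
#' forward model and by the linear phase-to-field inverse.
#'
#' @param b0_tesla main field strength in tesla.
#' @param te_s echo time in seconds (must be < `tr_s`).
#' @param tr_s repetition time in seconds.
#' @param gamma_rad_per_s_per_tesla proton gyromagnetic ratio; default
#'   2.6752218744e8 rad s^-1 T^-1.
#' @param supersample positive integer: subvoxel sampling factor per axis for
#'   intravoxel dephasing. 1 means one field sample per voxel.
#' @return An object of class `acq_params`.
#' @export
acq_params <- function(b0_tesla = 7, te_s = 0.029, tr_s = 3,
                       gamma_rad_per_s_per_tesla = 2.6752218744e8,
                       supersample = 1L) {
  if (b0_tesla <= 0 || te_s <= 0 || tr_s <= 0 || gamma_rad_per_s_per_tesla <= 0)
    stop("acquisition parameters must be positive")
  if (te_s >= tr_s) stop("te_s must be smaller than tr_s")
  supersample <- as.integer(supersample)
  if (supersample < 1L) stop("supersample must be >= 1")
  structure(list(b0_tesla = b0_tesla, te_s = te_s, tr_s = tr_s,
                 gamma_rad_per_s_per_tesla = gamma_rad_per_s_per_tesla,
                 supersample = supersample),
            class = "acq_params")
}

#' Complex T2* series
#'
#' 4D complex-valued gradient-echo image series C\[r, t\], normalised so that
#' a zero echo time gives C = 1 everywhere. Magnitude and wrapped phase views
#' are available through [t2s_magnitude()] and [t2s_phase()].
#'
#' @param grid a [vox_grid].
#' @param complex_values 4D complex array (x, y, z, t).
#' @param acq an [acq_params].
#' @return An object of class `t2s_series`.
#' @export
t2s_series <- function(grid, complex_values, acq) {
  if (length(dim(complex_values)) != 4L) stop("t2s_series needs a 4D array")
  if (!identical(dim(complex_values)[1:3], as.integer(grid$shape)))
    stop("t2s_series shape does not match grid")
  if (max(Mod(complex_values)) > 1 + 1e-9)
    stop("|C| exceeds 1: dephasing average of unit phasors cannot")
  structure(list(grid = grid, complex_values = complex_values, acq = acq),
            class = "t2s_series")
}

#' Magnitude view A[r, t] of a complex T2* series
#' @param x a [t2s_series].
#' @return 4D numeric array of magnitudes.
#' @export
t2s_magnitude <- function(x) {
  stopifnot(inherits(x, "t2s_series"))
  Mod(x$complex_values)
}

#' Wrapped-phase view P[r, t] of a complex T2* series
#' @param x a [t2s_series].
#' @return 4D numeric array of phases in \[-pi, pi).
#' @export
t2s_phase <- function(x) {
  stopifnot(inherits(x, "t2s_series"))
  wrap_phase(Arg(x$complex_values))
}

#' Phase volume (3D, radians)
#' @param grid a [vox_grid].
#' @param values_rad 3D numeric array of phases in radians.
#' @param wrapped logical: TRUE if values are folded into \[-pi, pi).
#' @return An object of class `phase_volume`.
#' @export
phase_volume <- function(grid, values_rad, wrapped) {
  check_values(values_rad, grid$shape, "phase_volume values_rad")
  if (isTRUE(wrapped) && (min(values_rad) < -pi || max(values_rad) >= pi))
    stop("wrapped phase must lie in [-pi, pi)")
  structure(list(grid = grid, values_rad = values_rad, wrapped = isTRUE(wrapped)),
            class = "phase_volume")
}

#' BOLD phase-perturbation series (4D, radians)
#'
#' Output of the complex-division extraction: per-frame phase differences
#' relative to a reference frame, each guaranteed to lie in \[-pi, pi). The
#' reference frame itself is identically zero.
#'
#' @param grid a [vox_grid].
#' @param values_rad 4D numeric array of phase differences.
#' @param ref_index 1-based index of the reference frame.
#' @return An object of class `dphase_series`.
#' @export
dphase_series <- function(grid, values_rad, ref_index) {
  if (length(dim(values_rad)) != 4L) stop("dphase_series needs a 4D array")
  if (min(values_rad) < -pi || max(values_rad) >= pi)
    stop("phase differences must lie in [-pi, pi)")
  nt <- dim(values_rad)[4]
  ref_index <- as.integer(ref_index)
  if (ref_index < 1L || ref_index > nt) stop("ref_index out of range")
  if (max(abs(values_rad[, , , ref_index])) != 0)
    stop("reference frame must be identically zero")
  structure(list(grid = grid, values_rad = values_rad, ref_index = ref_index),
            class = "dphase_series")
}

check_values <- function(x, shape, what) {
  if (!is.numeric(x)) stop(what, " must be numeric")
  if (!all(is.finite(x))) stop(what, " must be finite everywhere")
  if (!identical(as.integer(dim(x)), as.integer(shape)))
    stop(what, " shape (", paste(dim(x), collapse = "x"),
         ") does not match expected (", paste(shape, collapse = "x"), ")")
  invisible(TRUE)
}
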