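#' Spherical blob specification
#'
#' A piecewise-constant spherical susceptibility feature. `static` blobs form
#' part of the tissue background chi0; `task_locked` blobs carry the dynamic
#' BOLD perturbation dchi, whose amplitude is modulated by the HRF-convolved
#' task regressor.
#'
#' @param center_mm numeric 3-vector, blob centre in mm relative to the grid
#'   centre.
#' @param radius_mm positive sphere radius in mm.
#' @param amplitude_ppm signed susceptibility amplitude in ppm. Positive
#'   mimics paramagnetic content (ferritin, deoxyhaemoglobin), negative
#'   diamagnetic (water, oxyhaemoglobin).
#' @param kind `"static"` or `"task_locked"`.
#' @return An object of class `blob_spec`.
#' @export
blob_spec <- function(center_mm, radius_mm, amplitude_ppm,
                      kind = c("static", "task_locked")) {
  kind <- match.arg(kind)
  if (length(center_mm) != 3L) stop("center_mm must be a 3-vector")
  if (radius_mm <= 0) stop("radius_mm must be positive")
  if (!is.finite(amplitude_ppm)) stop("amplitude_ppm must be finite")
  structure(list(center_mm = as.numeric(center_mm), radius_mm = radius_mm,
                 amplitude_ppm = amplitude_ppm, kind = kind),
            class = "blob_spec")
}

blob_inside_grid <- function(blob, grid) {
  half <- grid$shape * grid$voxel_size_mm / 2
  all(abs(blob$center_mm) + blob$radius_mm <= half)
}

blob_support <- function(blob, grid, coords = coord_components(grid)) {
  d2 <- (coords$x - blob$center_mm[1])^2 + (coords$y - blob$center_mm[2])^2 +
    (coords$z - blob$center_mm[3])^2
  d2 <= blob$radius_mm^2
}

#' Static susceptibility background chi0
#'
#' Builds the bipolar static tissue background: an ellipsoidal "brain"
#' envelope containing spherical inclusions of positive (iron-rich,
#' deoxygenated-blood-like) and negative (water-like) susceptibility, zero
#' outside the envelope. Amplitudes of the default demo phantom stay within
#' the roughly +/- 0.5 ppm range typical of in vivo tissue maps.
#'
#' @param grid a [vox_grid].
#' @param blobs list of `static` [blob_spec] objects (may be empty).
#' @param envelope_semiaxes_mm numeric 3-vector of ellipsoid semi-axes in mm,
#'   or NULL for no envelope clipping.
#' @param envelope_ppm baseline susceptibility of the envelope interior, ppm.
#' @return A [chi_volume] holding chi0 in ppm.
#' @export
make_background_chi <- function(grid, blobs = list(),
                                envelope_semiaxes_mm = NULL,
                                envelope_ppm = 0) {
  vals <- array(0, dim = grid$shape)
  coords <- coord_components(grid)
  env_mask <- NULL
  if (!is.null(envelope_semiaxes_mm)) {
    a <- envelope_semiaxes_mm
    if (length(a) != 3L || any(a <= 0)) stop("envelope semi-axes must be 3 positive reals")
    env_mask <- (coords$x / a[1])^2 + (coords$y / a[2])^2 + (coords$z / a[3])^2 <= 1
    vals[env_mask] <- envelope_ppm
  }
  for (b in blobs) {
    if (!inherits(b, "blob_spec")) stop("blobs must be blob_spec objects")
    if (b$kind != "static") stop("background blobs must have kind = 'static'")
    if (!blob_inside_grid(b, grid))
      stop(sprintf("blob at (%s) mm with radius %.3g mm extends outside the grid",
                   paste(signif(b$center_mm, 3), collapse = ", "), b$radius_mm))
    vals[blob_support(b, grid, coords)] <- b$amplitude_ppm
  }
  if (!is.null(env_mask)) vals[!env_mask] <- 0
  chi_volume(grid, vals)
}

#' Block task paradigm
#'
#' Binary ON/OFF block design: task\[t\] = 1 during ON blocks, 0 during OFF.
#'
#' @param pattern list of `c(state, n)` pairs where state is `"ON"`/`"OFF"`
#'   and n a positive block length in volumes, e.g.
#'   `rep(list(c("ON", 5), c("OFF", 5)), 5)` for the 50-volume 7T-style
#'   design.
#' @param tr_s repetition time in seconds.
#' @return An object of class `task_paradigm` with elements `task`
#'   (binary series), `tr_s`, `n_volumes_total`, `block_pattern`.
#' @export
make_task_paradigm <- function(pattern, tr_s) {
  if (length(pattern) == 0L) stop("pattern must be nonempty")
  if (tr_s <= 0) stop("tr_s must be positive")
  task <- integer(0)
  for (blk in pattern) {
    state <- toupper(as.character(blk[[1]]))
    n <- as.integer(blk[[2]])
    if (!state %in% c("ON", "OFF")) stop("block state must be ON or OFF")
    if (is.na(n) || n < 1L) stop("block length must be >= 1")
    task <- c(task, rep(if (state == "ON") 1L else 0L, n))
  }
  structure(list(task = task, tr_s = tr_s, n_volumes_total = length(task),
                 block_pattern = pattern),
            class = "task_paradigm")
}

#' Canonical double-gamma HRF parameters
#'
#' @param peak_delay_s delay of the response peak (default 6 s).
#' @param undershoot_delay_s delay of the post-stimulus undershoot (16 s).
#' @param peak_dispersion_s dispersion of the peak gamma (1 s).
#' @param undershoot_dispersion_s dispersion of the undershoot gamma (1 s).
#' @param peak_undershoot_ratio ratio of peak to undershoot amplitude (6);
#'   `Inf` gives a pure single-gamma response.
#' @param kernel_length_s duration of the sampled kernel (32 s).
#' @return An object of class `hrf_params`.
#' @export
hrf_params <- function(peak_delay_s = 6, undershoot_delay_s = 16,
                       peak_dispersion_s = 1, undershoot_dispersion_s = 1,
                       peak_undershoot_ratio = 6, kernel_length_s = 32) {
  if (peak_dispersion_s <= 0 || undershoot_dispersion_s <= 0)
    stop("dispersions must be positive")
  if (peak_delay_s <= 0 || undershoot_delay_s <= 0 || kernel_length_s <= 0)
    stop("delays and kernel length must be positive")
  if (peak_undershoot_ratio <= 0) stop("peak_undershoot_ratio must be positive")
  if (kernel_length_s < undershoot_delay_s)
    stop("kernel_length_s must cover the undershoot delay")
  structure(list(peak_delay_s = peak_delay_s,
                 undershoot_delay_s = undershoot_delay_s,
                 peak_dispersion_s = peak_dispersion_s,
                 undershoot_dispersion_s = undershoot_dispersion_s,
                 peak_undershoot_ratio = peak_undershoot_ratio,
                 kernel_length_s = kernel_length_s),
            class = "hrf_params")
}

# Continuous double-gamma HRF value at time t (seconds), unnormalised.
hrf_density <- function(t, p) {
  a1 <- p$peak_delay_s / p$peak_dispersion_s
  a2 <- p$undershoot_delay_s / p$undershoot_dispersion_s
  main <- stats::dgamma(t, shape = a1, scale = p$peak_dispersion_s)
  under <- if (is.finite(p$peak_undershoot_ratio))
    stats::dgamma(t, shape = a2, scale = p$undershoot_dispersion_s) /
      p$peak_undershoot_ratio
  else 0
  main - under
}

#' Sampled canonical HRF kernel
#'
#' Causal double-gamma hemodynamic response kernel sampled at the repetition
#' time and peak-normalised to 1. The first sample sits at lag 0.
#'
#' @param params an [hrf_params].
#' @param tr_s sampling interval (repetition time) in seconds.
#' @return Numeric vector of kernel samples with attribute `tr_s`.
#' @export
canonical_hrf <- function(params = hrf_params(), tr_s) {
  if (tr_s <= 0) stop("tr_s must be positive")
  lags <- seq(0, params$kernel_length_s, by = tr_s)
  h <- hrf_density(lags, params)
  pk <- max(h)
  if (pk <= 0) stop("HRF kernel has non-positive peak")
  h <- h / pk
  attr(h, "tr_s") <- tr_s
  h
}

#' HRF-convolved task regressor task*
#'
#' Causal discrete convolution of the binary task series with the sampled
#' HRF kernel, truncated to the paradigm length and peak-normalised to 1
#' (unless identically zero).
#'
#' @param paradigm a [task_paradigm].
#' @param hrf sampled kernel from [canonical_hrf()] (must share the TR).
#' @return An object of class `regressor`: list with `values` (length N_t)
#'   and `tr_s`.
#' @export
effective_regressor <- function(paradigm, hrf) {
  stopifnot(inherits(paradigm, "task_paradigm"))
  htr <- attr(hrf, "tr_s")
  if (is.null(htr) || abs(htr - paradigm$tr_s) > 1e-12)
    stop("paradigm and HRF kernel must share the same TR")
  nt <- paradigm$n_volumes_total
  nh <- length(hrf)
  task <- paradigm$task
  # direct causal convolution: exact zeros before the first ON block
  vals <- vapply(seq_len(nt), function(t) {
    ks <- seq.int(max(1L, t - nh + 1L), t)
    sum(task[ks] * hrf[t - ks + 1L])
  }, numeric(1))
  pk <- max(vals)
  if (pk > 0) vals <- vals / pk
  # rectify the small post-block undershoot so task* stays in [0, 1]
  vals <- pmin(pmax(vals, 0), 1)
  structure(list(values = vals, tr_s = paradigm$tr_s), class = "regressor")
}

#' ON/OFF state classification of a regressor
#'
#' ON states are the timepoints where the normalised regressor task* is at
#' least 0.5; everything below is OFF.
#'
#' @param regressor a [regressor].
#' @return Character vector of `"ON"`/`"OFF"` labels, one per timepoint.
#' @export
classify_states <- function(regressor) {
  stopifnot(inherits(regressor, "regressor"))
  ifelse(regressor$values >= 0.5, "ON", "OFF")
}

#' Dynamic BOLD susceptibility perturbation dchi
#'
#' dchi\[r, t\] = sum over task-locked blobs of amplitude x support(r) x
#' task*\[t\], plus optional i.i.d. Gaussian source noise per voxel-time.
#' Default amplitudes of the demo phantom keep |dchi| within about
#' +/- 0.03 ppm, an order of magnitude below the chi0 background, matching
#' the weak-perturbation premise |dchi| << |chi0|.
#'
#' @param grid a [vox_grid].
#' @param blobs list of `task_locked` [blob_spec] objects.
#' @param regressor a [regressor] (task*).
#' @param noise_sd_ppm standard deviation of source-domain Gaussian noise in
#'   ppm; 0 disables it.
#' @param seed integer RNG seed; required whenever noise_sd_ppm > 0 so runs
#'   are reproducible.
#' @return A [chi_series] of dchi in ppm.
#' @export
make_bold_perturbation <- function(grid, blobs, regressor, noise_sd_ppm = 0,
                                   seed = NULL) {
  stopifnot(inherits(regressor, "regressor"))
  if (noise_sd_ppm < 0) stop("noise_sd_ppm must be >= 0")
  nt <- length(regressor$values)
  base <- array(0, dim = grid$shape)
  coords <- coord_components(grid)
  for (b in blobs) {
    if (!inherits(b, "blob_spec")) stop("blobs must be blob_spec objects")
    if (b$kind != "task_locked")
      stop("perturbation blobs must have kind = 'task_locked'")
    if (!blob_inside_grid(b, grid)) stop("blob extends outside the grid")
    base[blob_support(b, grid, coords)] <- b$amplitude_ppm
  }
  vals <- array(0, dim = c(grid$shape, nt))
  for (t in seq_len(nt))
    vals[, , , t] <- base * regressor$values[t]
  if (noise_sd_ppm > 0) {
    if (is.null(seed)) stop("a seed is required when noise is enabled")
    vals <- vals + with_seed(seed, array(stats::rnorm(length(vals), 0, noise_sd_ppm),
                                         dim = dim(vals)))
  }
  chi_series(grid, vals, regressor$tr_s)
}

#' Compose the full susceptibility series chi = chi0 + dchi
#'
#' @param chi0 a [chi_volume] (static background).
#' @param dchi a [chi_series] (dynamic perturbation) on the same grid.
#' @return A [chi_series] of chi in ppm.
#' @export
compose_chi_series <- function(chi0, dchi) {
  stopifnot(inherits(chi0, "chi_volume"), inherits(dchi, "chi_series"))
  stop_if_grid_mismatch(chi0$grid, dchi$grid, "chi0 and dchi")
  vals <- dchi$values_ppm + as.vector(chi0$values_ppm)
  chi_series(dchi$grid, vals, dchi$tr_s)
}

# Evaluate expr with a local, restored RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Default demonstration phantom specification
#'
#' The stock study conditions used throughout the examples and tests: a
#' 7T-style 50-volume block paradigm (5 cycles of 5 ON / 5 OFF at TR = 3 s),
#' a bipolar chi0 background within +/- 0.5 ppm, and one positive plus one
#' negative task-locked perturbation blob of +/- 0.02 ppm (bidirectional
#' BOLD response, |dchi| <= 0.03 ppm).
#'
#' @param n grid size per axis (default 64).
#' @param voxel_mm voxel edge length in mm (default 1).
#' @return List with elements `grid`, `chi0_blobs`, `envelope_semiaxes_mm`,
#'   `task_blobs`, `pattern`, `tr_s`, `hrf`.
#' @export
demo_phantom_spec <- function(n = 64, voxel_mm = 1) {
  grid <- vox_grid(c(n, n, n), rep(voxel_mm, 3))
  ext <- n * voxel_mm
  list(
    grid = grid,
    chi0_blobs = list(
      blob_spec(c(-0.17, 0.09, 0.06) * ext, 0.09 * ext, 0.4, "static"),
      blob_spec(c(0.14, -0.11, -0.05) * ext, 0.11 * ext, -0.35, "static"),
      blob_spec(c(0.05, 0.16, -0.12) * ext, 0.06 * ext, 0.5, "static"),
      blob_spec(c(-0.08, -0.17, 0.10) * ext, 0.07 * ext, -0.5, "static")
    ),
    envelope_semiaxes_mm = c(0.42, 0.42, 0.40) * ext,
    envelope_ppm = 0.05,
    task_blobs = list(
      blob_spec(c(0.16, 0.14, 0.08) * ext, 0.055 * ext, 0.02, "task_locked"),
      blob_spec(c(-0.15, -0.08, -0.09) * ext, 0.055 * ext, -0.02, "task_locked")
    ),
    pattern = rep(list(list("ON", 5L), list("OFF", 5L)), 5),
    tr_s = 3,
    hrf = hrf_params()
  )
}
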