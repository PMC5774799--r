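#' Write a volume or series to NIfTI
#'
#' Stores 3D/4D numeric data with the voxel size (and TR for 4D data) in the
#' NIfTI header. Complex T2* data are stored as paired magnitude/phase files
#' via [write_complex_nifti()].
#'
#' @param data 3D/4D numeric array, or a [chi_volume] / [chi_series] /
#'   [field_map] / [phase_volume].
#' @param path output file path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm voxel size, taken from the container when available.
#' @param tr_s repetition time for 4D data (seconds).
#' @return The path, invisibly.
#' @export
write_nifti_volume <- function(data, path, voxel_size_mm = NULL, tr_s = NULL) {
  if (inherits(data, "chi_volume")) {
    voxel_size_mm <- data$grid$voxel_size_mm; data <- data$values_ppm
  } else if (inherits(data, "chi_series")) {
    voxel_size_mm <- data$grid$voxel_size_mm
    if (is.null(tr_s)) tr_s <- data$tr_s
    data <- data$values_ppm
  } else if (inherits(data, "field_map")) {
    voxel_size_mm <- data$grid$voxel_size_mm; data <- data$values_tesla
  } else if (inherits(data, "phase_volume")) {
    voxel_size_mm <- data$grid$voxel_size_mm; data <- data$values_rad
  }
  if (is.null(voxel_size_mm)) voxel_size_mm <- c(1, 1, 1)
  nd <- length(dim(data))
  pd <- if (nd == 4L) c(voxel_size_mm, if (is.null(tr_s)) 1 else tr_s)
  else voxel_size_mm
  attr(data, "pixdim") <- pd
  RNifti::writeNifti(RNifti::asNifti(data), path, datatype = "double")
  invisible(path)
}

#' Read a NIfTI volume or series
#'
#' @param path a NIfTI-1 file.
#' @param expect_shape optional integer vector; mismatch raises an error
#'   naming both shapes.
#' @return List with `data` (plain array), `voxel_size_mm`, `tr_s` (NULL for
#'   3D), and `wrapped` (TRUE when all values fit in \[-pi, pi), the
#'   wrapped-phase inference rule).
#' @export
read_nifti_volume <- function(path, expect_shape = NULL) {
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img), dim = dim(img))
  nd <- length(dim(data))
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(img)
  if (!is.null(expect_shape) &&
      !identical(as.integer(dim(data)), as.integer(expect_shape)))
    stop("NIfTI shape (", paste(dim(data), collapse = "x"),
         ") does not match expected (", paste(expect_shape, collapse = "x"), ")")
  list(data = data,
       voxel_size_mm = as.numeric(pd[1:3]),
       tr_s = if (nd == 4L) as.numeric(pd[4]) else NULL,
       wrapped = min(data) >= -pi && max(data) < pi)
}

#' Write a complex T2* series as a magnitude/phase NIfTI pair
#'
#' @param t2s a [t2s_series].
#' @param prefix output path prefix; writes `<prefix>_mag.nii` and
#'   `<prefix>_phs.nii` plus a JSON sidecar `<prefix>_meta.json` echoing the
#'   acquisition parameters.
#' @return Character vector of the three paths, invisibly.
#' @export
write_complex_nifti <- function(t2s, prefix) {
  stopifnot(inherits(t2s, "t2s_series"))
  magp <- paste0(prefix, "_mag.nii")
  phsp <- paste0(prefix, "_phs.nii")
  metap <- paste0(prefix, "_meta.json")
  vs <- t2s$grid$voxel_size_mm
  write_nifti_volume(t2s_magnitude(t2s), magp, vs, t2s$acq$tr_s)
  write_nifti_volume(t2s_phase(t2s), phsp, vs, t2s$acq$tr_s)
  meta <- c(unclass(t2s$acq), list(phase_wrapped = TRUE, phase_units = "rad"))
  jsonlite::write_json(meta, metap, auto_unbox = TRUE, digits = NA)
  invisible(c(magp, phsp, metap))
}

#' Read a magnitude/phase NIfTI pair into a complex T2* series
#'
#' @param mag_path,phs_path magnitude and phase files; shapes must agree.
#' @param acq an [acq_params] describing the acquisition.
#' @param b0_direction main-field direction for the reconstructed grid.
#' @return A [t2s_series].
#' @export
read_complex_nifti <- function(mag_path, phs_path, acq,
                               b0_direction = c(0, 0, 1)) {
  mag <- read_nifti_volume(mag_path)
  phs <- read_nifti_volume(phs_path, expect_shape = dim(mag$data))
  grid <- vox_grid(dim(mag$data)[1:3], mag$voxel_size_mm, b0_direction)
  vals <- mag$data * exp(1i * phs$data)
  mx <- max(Mod(vals))
  if (mx > 1 + 1e-9) vals <- vals / mx
  t2s_series(grid, vals, acq)
}

#' Default pipeline configuration
#'
#' The full study-condition schema with every numeric default in one place:
#' grid and phantom geometry, 7T-style block paradigm and HRF, acquisition,
#' inversion hyperparameters, and functional-mapping settings.
#'
#' @param n grid size per axis (default 64).
#' @param seed integer RNG seed for the stochastic stages.
#' @param output_dir directory for pipeline outputs.
#' @return Nested configuration list of class `pipeline_config`.
#' @export
default_config <- function(n = 64, seed = 1L, output_dir = tempfile("boldpert_")) {
  spec <- demo_phantom_spec(n)
  blob_to_list <- function(b) list(center_mm = b$center_mm,
                                   radius_mm = b$radius_mm,
                                   amplitude_ppm = b$amplitude_ppm,
                                   kind = b$kind)
  structure(list(
    grid = list(shape = spec$grid$shape,
                voxel_size_mm = spec$grid$voxel_size_mm,
                b0_direction = spec$grid$b0_direction),
    phantom = list(
      chi0_blobs = lapply(spec$chi0_blobs, blob_to_list),
      envelope_semiaxes_mm = spec$envelope_semiaxes_mm,
      envelope_ppm = spec$envelope_ppm,
      task_blobs = lapply(spec$task_blobs, blob_to_list),
      noise_sd_ppm = 0
    ),
    paradigm = list(pattern = spec$pattern, tr_s = spec$tr_s),
    hrf = unclass(spec$hrf),
    acquisition = list(b0_tesla = 7, te_s = 0.029, tr_s = spec$tr_s,
                       gamma_rad_per_s_per_tesla = 2.6752218744e8,
                       supersample = 1L, noise_sd = 0, zero_pad = TRUE),
    inversion = list(method = "tvb", tkd_threshold = 0.1, tv_weight = 2e-3,
                     bregman_penalty = 2e-2, max_iters = 100L,
                     rel_tol = 1e-4, zero_pad = FALSE),
    fmap = list(ref_index = 1L, z_threshold = 5,
                roi = NULL, chi_pathway = TRUE),
    seed = as.integer(seed),
    output_dir = output_dir
  ), class = "pipeline_config")
}

#' Read and validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), merges it over [default_config()]
#' defaults section by section, and validates the schema before any stage
#' runs.
#'
#' @param x path to a YAML config file, or a named list.
#' @return Validated `pipeline_config`.
#' @export
read_pipeline_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  if (!is.list(cfg)) stop("config must be a list or a YAML file path")
  n <- if (!is.null(cfg$grid$shape)) cfg$grid$shape[1] else 64
  base <- default_config(n = n,
                         seed = if (is.null(cfg$seed)) 1L else cfg$seed,
                         output_dir = if (is.null(cfg$output_dir))
                           tempfile("boldpert_") else cfg$output_dir)
  merged <- utils::modifyList(unclass(base), cfg)
  class(merged) <- "pipeline_config"
  validate_config(merged)
}

validate_config <- function(cfg) {
  required <- c("grid", "phantom", "paradigm", "hrf", "acquisition",
                "inversion", "fmap", "seed", "output_dir")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("config is missing section(s): ", paste(missing, collapse = ", "))
  vox_grid(cfg$grid$shape, cfg$grid$voxel_size_mm, cfg$grid$b0_direction)
  do.call(acq_params, cfg$acquisition[setdiff(names(cfg$acquisition),
                                              c("noise_sd", "zero_pad"))])
  do.call(inversion_config, cfg$inversion)
  if (length(cfg$paradigm$pattern) == 0L) stop("paradigm pattern is empty")
  if (!is.numeric(cfg$seed)) stop("seed must be an integer")
  cfg
}

config_grid <- function(cfg)
  vox_grid(cfg$grid$shape, cfg$grid$voxel_size_mm, cfg$grid$b0_direction)

config_acq <- function(cfg)
  do.call(acq_params, cfg$acquisition[setdiff(names(cfg$acquisition),
                                              c("noise_sd", "zero_pad"))])

config_inversion <- function(cfg) do.call(inversion_config, cfg$inversion)

config_blobs <- function(lst, kind) {
  lapply(lst, function(b)
    blob_spec(b$center_mm, b$radius_mm, b$amplitude_ppm, kind))
}

#' Write a regressor (or task series) as a two-column text file
#' @param values numeric series.
#' @param path output path; columns are index and value.
#' @return The path, invisibly.
#' @export
write_series_txt <- function(values, path) {
  utils::write.table(data.frame(index = seq_along(values), value = values),
                     path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

# Manifest: stage records with file hashes and parameter echoes.
new_manifest <- function(config) {
  list(created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       config = unclass(config), stages = list())
}

manifest_add_stage <- function(manifest, name, files = character(0),
                               params = list(), info = list()) {
  hashes <- if (length(files)) as.list(tools::md5sum(files)) else list()
  manifest$stages[[name]] <- list(files = hashes, params = params, info = info)
  manifest
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Collect the deterministic file hashes from a run manifest
#' @param path manifest JSON path.
#' @return Named character vector of md5 hashes keyed by basename.
#' @export
manifest_hashes <- function(path) {
  m <- jsonlite::read_json(path)
  out <- character(0)
  for (st in m$stages)
    for (f in names(st$files))
      out[basename(f)] <- st$files[[f]]
  out
}
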