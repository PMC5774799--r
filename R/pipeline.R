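#' Run the forward pipeline: phantom -> field -> complex T2* series
#'
#' Builds the phantom (chi0 background, task paradigm, HRF-convolved
#' regressor, task-locked dchi), composes chi = chi0 + dchi, simulates the
#' complex T2* timeseries by dipole convolution and intravoxel dephasing,
#' and writes the dataset bundle (NIfTI volumes, regressor/paradigm text
#' files, JSON manifest with per-file hashes) to `config$output_dir`.
#' Deterministic under a fixed seed.
#'
#' @param config a `pipeline_config` (see [default_config()] /
#'   [read_pipeline_config()]).
#' @return Invisible list with the in-memory objects (`chi0`, `dchi`, `chi`,
#'   `t2s`, `regressor`, `paradigm`) and `files` (named paths).
#' @export
run_forward <- function(config) {
  config <- validate_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- config_grid(config)
  acq <- config_acq(config)

  chi0 <- make_background_chi(
    grid, config_blobs(config$phantom$chi0_blobs, "static"),
    envelope_semiaxes_mm = config$phantom$envelope_semiaxes_mm,
    envelope_ppm = config$phantom$envelope_ppm)
  paradigm <- make_task_paradigm(config$paradigm$pattern, config$paradigm$tr_s)
  hrf <- canonical_hrf(do.call(hrf_params, config$hrf), paradigm$tr_s)
  reg <- effective_regressor(paradigm, hrf)
  dchi <- make_bold_perturbation(
    grid, config_blobs(config$phantom$task_blobs, "task_locked"), reg,
    noise_sd_ppm = config$phantom$noise_sd_ppm, seed = config$seed)
  chi <- compose_chi_series(chi0, dchi)
  t2s <- simulate_t2star_series(chi, acq,
                                noise_sd = config$acquisition$noise_sd,
                                seed = config$seed + 1L,
                                zero_pad = isTRUE(config$acquisition$zero_pad))

  od <- config$output_dir
  files <- c(chi0 = file.path(od, "chi0.nii"),
             dchi = file.path(od, "dchi.nii"),
             chi = file.path(od, "chi.nii"),
             regressor = file.path(od, "regressor.txt"),
             paradigm = file.path(od, "paradigm.txt"))
  write_nifti_volume(chi0, files["chi0"])
  write_nifti_volume(dchi, files["dchi"])
  write_nifti_volume(chi, files["chi"])
  write_series_txt(reg$values, files["regressor"])
  write_series_txt(paradigm$task, files["paradigm"])
  t2s_files <- write_complex_nifti(t2s, file.path(od, "t2s"))
  files <- c(files, mag = t2s_files[1], phs = t2s_files[2],
             meta = t2s_files[3])

  manifest <- new_manifest(config)
  manifest <- manifest_add_stage(manifest, "phantom",
                                 files[c("chi0", "dchi", "chi", "regressor", "paradigm")],
                                 params = list(seed = config$seed,
                                               noise_sd_ppm = config$phantom$noise_sd_ppm),
                                 info = list(chi0_range_ppm = range(chi0$values_ppm),
                                             dchi_range_ppm = range(dchi$values_ppm)))
  manifest <- manifest_add_stage(manifest, "forward",
                                 files[c("mag", "phs")],
                                 params = unclass(acq),
                                 info = list(phase_range_rad = range(t2s_phase(t2s))))
  manifest_path <- file.path(od, "manifest_forward.json")
  write_manifest(manifest, manifest_path)
  files <- c(files, manifest = manifest_path)

  invisible(list(chi0 = chi0, dchi = dchi, chi = chi, t2s = t2s,
                 regressor = reg, paradigm = paradigm, files = files))
}

#' Run the inverse pipeline: phase -> field -> susceptibility -> fmap
#'
#' From a 4D magnitude/phase pair (files or a [t2s_series]): extracts the
#' BOLD phase perturbation by complex division (no unwrapping needed on the
#' dchi pathway), reconstructs the dchi series by dipole inversion, and —
#' on the full-chi pathway — Laplacian-unwraps each frame and reconstructs
#' the chi series. Then computes the task-correlation map of the dchi
#' series against the regressor, SNR/CNR metrics when an ROI pair is
#' configured, and writes the bundle plus a JSON manifest.
#'
#' @param config a `pipeline_config`.
#' @param input a [t2s_series], or a character vector
#'   `c(mag = ..., phs = ...)` of NIfTI paths.
#' @param regressor a [regressor]; if NULL it is rebuilt from the config's
#'   paradigm and HRF sections.
#' @return Invisible list with `dP`, `dchi`, `chi` (NULL when the chi
#'   pathway is disabled), `fmap`, `metrics` (NULL without an ROI),
#'   `files`.
#' @export
run_inverse <- function(config, input, regressor = NULL) {
  config <- validate_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  acq <- config_acq(config)
  inv <- config_inversion(config)
  if (inherits(input, "t2s_series")) {
    t2s <- input
  } else {
    t2s <- read_complex_nifti(input[["mag"]], input[["phs"]], acq,
                              b0_direction = config$grid$b0_direction)
  }
  grid <- t2s$grid
  expected <- config_grid(config)
  stop_if_grid_mismatch(grid, expected, "input data and config")

  if (is.null(regressor)) {
    paradigm <- make_task_paradigm(config$paradigm$pattern, config$paradigm$tr_s)
    hrf <- canonical_hrf(do.call(hrf_params, config$hrf), paradigm$tr_s)
    regressor <- effective_regressor(paradigm, hrf)
  }

  ref_index <- config$fmap$ref_index
  dP <- complex_divide_phase(t2s, ref_index = ref_index)
  dchi <- reconstruct_dchi_series(dP, acq, inv, tr_s = acq$tr_s)
  chi <- NULL
  if (isTRUE(config$fmap$chi_pathway))
    chi <- reconstruct_chi_series(t2s, acq, inv)

  fmap <- tcorr_significance(tcorr_map(dchi, regressor))

  metrics <- NULL
  if (!is.null(config$fmap$roi)) {
    roi <- roi_spec(config$fmap$roi$act_box, config$fmap$roi$inact_box, grid)
    metrics <- snr_cnr(dchi, roi, exclude_index = ref_index)
  }

  od <- config$output_dir
  files <- c(dP = file.path(od, "dP.nii"),
             dchi_recon = file.path(od, "dchi_recon.nii"),
             fmap_r = file.path(od, "fmap_r.nii"),
             fmap_p = file.path(od, "fmap_p.nii"),
             fmap_z = file.path(od, "fmap_z.nii"))
  write_nifti_volume(dP$values_rad, files["dP"], grid$voxel_size_mm, acq$tr_s)
  write_nifti_volume(dchi, files["dchi_recon"])
  write_nifti_volume(fmap$r, files["fmap_r"], grid$voxel_size_mm)
  write_nifti_volume(fmap$p, files["fmap_p"], grid$voxel_size_mm)
  write_nifti_volume(fmap$z, files["fmap_z"], grid$voxel_size_mm)
  if (!is.null(chi)) {
    files <- c(files, chi_recon = file.path(od, "chi_recon.nii"))
    write_nifti_volume(chi, files["chi_recon"])
  }
  if (!is.null(metrics)) {
    files <- c(files, metrics = file.path(od, "metrics.csv"))
    utils::write.csv(as.data.frame(metrics), files["metrics"], row.names = FALSE)
  }

  manifest <- new_manifest(config)
  manifest <- manifest_add_stage(manifest, "complex_division", files["dP"],
                                 params = list(ref_index = ref_index))
  manifest <- manifest_add_stage(manifest, "dchi_reconstruction",
                                 files["dchi_recon"],
                                 params = unclass(inv),
                                 info = list(converged = all(attr(dchi, "converged")),
                                             dchi_range_ppm = range(dchi$values_ppm)))
  if (!is.null(chi))
    manifest <- manifest_add_stage(manifest, "chi_reconstruction",
                                   files["chi_recon"], params = unclass(inv),
                                   info = list(chi_range_ppm = range(chi$values_ppm)))
  manifest <- manifest_add_stage(manifest, "fmap",
                                 files[c("fmap_r", "fmap_p", "fmap_z")],
                                 params = list(n_t = fmap$n_t),
                                 info = list(r_range = range(fmap$r)))
  if (!is.null(metrics))
    manifest <- manifest_add_stage(manifest, "metrics", files["metrics"],
                                   params = list(exclude_index = ref_index),
                                   info = list(snr_mean = attr(metrics, "snr_mean"),
                                               cnr_mean = attr(metrics, "cnr_mean")))
  manifest_path <- file.path(od, "manifest_inverse.json")
  write_manifest(manifest, manifest_path)
  files <- c(files, manifest = manifest_path)

  invisible(list(dP = dP, dchi = dchi, chi = chi, fmap = fmap,
                 metrics = metrics, files = files))
}

#' Run the closed forward + inverse loop
#'
#' Executes [run_forward()] and feeds its simulated T2* series straight into
#' [run_inverse()]. With a fixed seed the whole loop is deterministic:
#' repeated runs produce bit-identical output files (equal manifest hashes).
#'
#' @param config a `pipeline_config`.
#' @return Invisible list with elements `forward` and `inverse`.
#' @export
run_all <- function(config) {
  fwd <- run_forward(config)
  inv <- run_inverse(config, fwd$t2s, regressor = fwd$regressor)
  invisible(list(forward = fwd, inverse = inv))
}
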