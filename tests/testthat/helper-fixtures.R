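# Shared fixture builders: everything is generated in code, no stored data.

# logical mask of a blob's support on a grid
blob_mask <- function(grid, blob) {
  co <- boldpert:::coord_components(grid)
  (co$x - blob$center_mm[1])^2 + (co$y - blob$center_mm[2])^2 +
    (co$z - blob$center_mm[3])^2 <= blob$radius_mm^2
}

radius_array <- function(grid, center = c(0, 0, 0)) {
  co <- boldpert:::coord_components(grid)
  sqrt((co$x - center[1])^2 + (co$y - center[2])^2 + (co$z - center[3])^2)
}

# small 7T-style regressor (50 volumes, 5 cycles of 5 ON / 5 OFF, TR 3 s)
fixture_regressor <- function() {
  paradigm <- make_task_paradigm(rep(list(list("ON", 5L), list("OFF", 5L)), 5), 3)
  effective_regressor(paradigm, canonical_hrf(hrf_params(), 3))
}

# single ON/OFF pair of frames (OFF reference first), for round trips
fixture_onoff_regressor <- function() {
  structure(list(values = c(0, 1), tr_s = 3), class = "regressor")
}

wrapv <- boldpert:::wrap_phase

config_blobs_for_test <- function(cfg) {
  lapply(cfg$phantom$task_blobs, function(b)
    blob_spec(b$center_mm, b$radius_mm, b$amplitude_ppm, "task_locked"))
}
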