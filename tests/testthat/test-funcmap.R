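test_that("tcorr map has exact values on constructed timecourses", {
  grid <- vox_grid(c(8, 8, 8))
  reg <- fixture_regressor()
  nt <- length(reg$values)
  set.seed(5)
  x <- array(stats::rnorm(512 * nt, sd = 0.1), c(8, 8, 8, nt))
  x[2, 2, 2, ] <- reg$values                      # perfect correlation
  x[3, 3, 3, ] <- -2 * reg$values + 7             # perfect anticorrelation
  x[4, 4, 4, ] <- 5                               # constant voxel
  fm <- tcorr_map(x, reg, grid)
  expect_equal(fm$r[2, 2, 2], 1)
  expect_equal(fm$r[3, 3, 3], -1)
  expect_equal(fm$r[4, 4, 4], 0)
  expect_true(all(abs(fm$r) <= 1))
  expect_identical(fm$n_t, nt)

  expect_error(tcorr_map(x[, , , 1:10], reg, grid), "length")
})

test_that("tcorr is affine-invariant and sign-flips under negation", {
  grid <- vox_grid(c(8, 8, 8))
  reg <- fixture_regressor()
  set.seed(6)
  x <- array(stats::rnorm(512 * 50), c(8, 8, 8, 50))
  r0 <- tcorr_map(x, reg, grid)$r
  r_affine <- tcorr_map(3.2 * x + 11, reg, grid)$r
  expect_equal(r_affine, r0, tolerance = 1e-12)
  r_neg <- tcorr_map(-x, reg, grid)$r
  expect_equal(r_neg, -r0, tolerance = 1e-12)
  # rescaling the regressor (positive slope) leaves r unchanged
  reg2 <- structure(list(values = 0.25 * reg$values, tr_s = reg$tr_s),
                    class = "regressor")
  expect_equal(tcorr_map(x, reg2, grid)$r, r0, tolerance = 1e-12)
})

test_that("significance transforms match the t and Fisher forms", {
  grid <- vox_grid(c(8, 8, 8))
  reg <- fixture_regressor()
  set.seed(7)
  x <- array(stats::rnorm(512 * 50), c(8, 8, 8, 50))
  x[2, 2, 2, ] <- reg$values
  x[4, 4, 4, ] <- 1
  fm <- tcorr_significance(tcorr_map(x, reg, grid))
  n <- 50
  # independent recomputation for an arbitrary voxel
  r <- fm$r[5, 5, 5]
  t_ <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(fm$p[5, 5, 5], 2 * stats::pt(-abs(t_), n - 2), tolerance = 1e-12)
  expect_equal(fm$z[5, 5, 5], atanh(r) * sqrt(n - 3), tolerance = 1e-12)
  # r = 0 voxel: p = 1, z = 0
  expect_equal(fm$p[4, 4, 4], 1)
  expect_equal(fm$z[4, 4, 4], 0)
  # |r| = 1 voxel: p underflows to the smallest positive double, z finite
  expect_equal(fm$p[2, 2, 2], .Machine$double.xmin)
  expect_true(is.finite(fm$z[2, 2, 2]))
  # r = 0.9, n = 50 is far below the 1e-2 significance level
  r9 <- 0.9; t9 <- r9 * sqrt(48 / (1 - r9^2))
  expect_lt(2 * stats::pt(-t9, 48), 1e-2)
  # antisymmetry of z in r
  expect_equal(tcorr_significance(tcorr_map(-x, reg, grid))$z, -fm$z,
               tolerance = 1e-12)
})

test_that("SNR/CNR metrics have their closed-form values and invariances", {
  grid <- vox_grid(c(12, 12, 12))
  roi <- roi_spec(act_box = list(x = c(2, 6), y = c(2, 6), z = c(5, 7)),
                  inact_box = list(x = c(8, 12), y = c(8, 12), z = c(5, 7)),
                  grid = grid)
  nt <- 6
  set.seed(8)
  x <- array(stats::rnorm(12^3 * nt), c(12, 12, 12, nt))
  x[2:6, 2:6, 5:7, ] <- x[2:6, 2:6, 5:7, ] + 2

  m <- snr_cnr(x, roi)
  # brute-force per-frame recomputation
  for (t in seq_len(nt)) {
    act <- x[2:6, 2:6, 5:7, t]; ina <- x[8:12, 8:12, 5:7, t]
    expect_equal(m$snr[t], abs(mean(act)) / stats::sd(ina), tolerance = 1e-12)
    expect_equal(m$cnr[t], abs(mean(act) - mean(ina)) / stats::sd(ina),
                 tolerance = 1e-12)
  }
  expect_equal(attr(m, "snr_mean"), mean(m$snr), tolerance = 1e-12)

  # CNR is offset-invariant, SNR shifts with the offset
  m_off <- snr_cnr(x + 5, roi)
  expect_equal(m_off$cnr, m$cnr, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(m_off$snr, m$snr)))
  # both invariant under positive global scaling
  m_sc <- snr_cnr(x * 3.7, roi)
  expect_equal(m_sc$snr, m$snr, tolerance = 1e-10)
  expect_equal(m_sc$cnr, m$cnr, tolerance = 1e-10)

  # reference-frame exclusion (N_t - 1 convention)
  m_ex <- snr_cnr(x, roi, exclude_index = 1)
  expect_equal(attr(m_ex, "snr_mean"), mean(m$snr[-1]), tolerance = 1e-12)
  expect_equal(attr(m_ex, "cnr_mean"), mean(m$cnr[-1]), tolerance = 1e-12)
  expect_false(m_ex$included[1])

  # zero-spread frame flagged and excluded
  x0 <- x; x0[8:12, 8:12, 5:7, 2] <- 0
  expect_warning(m0 <- snr_cnr(x0, roi), "zero spread")
  expect_false(m0$included[2])
  expect_equal(attr(m0, "snr_mean"), mean(m0$snr[-2]), tolerance = 1e-12)

  expect_error(roi_spec(act_box = list(x = c(2, 6), y = c(2, 6), z = c(5, 7)),
                        inact_box = list(x = c(4, 8), y = c(4, 8), z = c(5, 7))),
               "disjoint")
})

test_that("thresholded blob labeling separates bidirectional components", {
  grid <- vox_grid(c(16, 16, 16))
  fm <- structure(list(grid = grid, r = array(0, grid$shape),
                       p = array(1, grid$shape), z = array(0, grid$shape),
                       n_t = 50L), class = "corr_map")
  # all-zero map -> no blobs
  tb0 <- threshold_blobs(fm, 3)
  expect_identical(nrow(tb0$blobs), 0L)

  # one positive and one negative blob, disjoint
  fm$z[3:5, 3:5, 3:5] <- 8
  fm$z[10:12, 10:12, 10:12] <- -6
  fm$z[4, 4, 4] <- 9       # peak of the positive blob
  tb <- threshold_blobs(fm, 3)
  expect_identical(nrow(tb$blobs), 2L)
  expect_setequal(tb$blobs$sign, c(1, -1))
  pos <- tb$blobs[tb$blobs$sign == 1, ]
  expect_identical(c(pos$peak_x, pos$peak_y, pos$peak_z), c(4L, 4L, 4L))
  expect_identical(pos$n_voxels, 27L)
  # diagonal touching counts as connected under 26-connectivity
  fm2 <- fm; fm2$z[] <- 0; fm2$z[3, 3, 3] <- 5; fm2$z[4, 4, 4] <- 5
  expect_identical(nrow(threshold_blobs(fm2, 3)$blobs), 1L)

  expect_error(threshold_blobs(fm, -1), "positive")
})

test_that("planted blobs occupy the top correlation ranks at CNR ~ 5", {
  grid <- vox_grid(c(24, 24, 24))
  reg <- fixture_regressor()
  blobs <- list(blob_spec(c(4, 4, 2), 3, 0.02, "task_locked"),
                blob_spec(c(-4, -4, -2), 3, -0.02, "task_locked"))
  dchi <- make_bold_perturbation(grid, blobs, reg, noise_sd_ppm = 0.004,
                                 seed = 21)
  fm <- tcorr_significance(tcorr_map(dchi, reg))
  supp_pos <- blob_mask(grid, blobs[[1]])
  supp_neg <- blob_mask(grid, blobs[[2]])
  supp <- supp_pos | supp_neg
  # global |r| maximum inside a blob; signs separate the two blobs
  expect_true(supp[which.max(abs(fm$r))])
  expect_gt(stats::median(fm$r[supp_pos]), 0.5)
  expect_lt(stats::median(fm$r[supp_neg]), -0.5)
  # zero-false-positive threshold still detects >= 90% of blob voxels
  z_thr <- max(abs(fm$z[!supp]))
  expect_gte(mean(abs(fm$z[supp]) > z_thr), 0.9)
})

test_that("plotting helpers render overlays and metric traces", {
  grid <- vox_grid(c(12, 12, 12))
  fm <- structure(list(grid = grid, r = array(0, grid$shape),
                       p = array(1, grid$shape), z = array(0, grid$shape),
                       n_t = 20L), class = "corr_map")
  fm$z[4:6, 4:6, 6:7] <- 8
  fm$z[9:10, 9:10, 6:7] <- -7
  png_path <- tempfile(fileext = ".png")
  n_hot <- plot_fmap_overlay(fm, array(0.5, grid$shape), slice = 6,
                             z_threshold = 5, png_path = png_path)
  expect_true(file.exists(png_path))
  expect_identical(n_hot, 9L + 4L)

  roi <- roi_spec(act_box = list(x = c(2, 4), y = c(2, 4), z = c(5, 7)),
                  inact_box = list(x = c(8, 10), y = c(8, 10), z = c(5, 7)))
  set.seed(40)
  x <- array(stats::rnorm(12^3 * 5), c(grid$shape, 5))
  m <- snr_cnr(x, roi)
  pf <- tempfile(fileext = ".png")
  grDevices::png(pf)
  expect_no_error(plot(m, regressor = structure(list(values = runif(5), tr_s = 1),
                                                class = "regressor")))
  grDevices::dev.off()
})
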