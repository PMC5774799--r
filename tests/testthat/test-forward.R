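test_that("spatial dipole kernel matches its closed form", {
  expect_equal(dipole_kernel_spatial(c(0, 0, 1)), 1 / (2 * pi))
  expect_equal(dipole_kernel_spatial(c(1, 0, 0)), -1 / (4 * pi))
  # magic angle: z^2 / r^2 = 1/3
  off <- c(sqrt(2), 0, 1)  # r^2 = 3, z^2 = 1
  expect_equal(dipole_kernel_spatial(off), 0, tolerance = 1e-15)
  expect_error(dipole_kernel_spatial(c(0, 0, 0)), "singular")
})

test_that("k-space dipole kernel has the right limits, bounds and DC zero", {
  grid <- vox_grid(c(16, 16, 16))
  d <- dipole_kernel_kspace(grid)$values
  expect_equal(d[1, 1, 1], 0)
  expect_equal(d[1, 1, 2], -2 / 3)   # purely axial frequency
  expect_equal(d[2, 1, 1], 1 / 3)    # purely transverse
  expect_gte(min(d), -2 / 3 - 1e-12)
  expect_lte(max(d), 1 / 3 + 1e-12)
})

test_that("Fourier kernel agrees with brute-force spatial convolution", {
  # a compact smooth source on a 17^3 grid: the FFT field must match the
  # direct spatial-kernel sum away from the source bulk and the boundary
  grid <- vox_grid(c(17, 17, 17))
  acq <- acq_params()
  co <- boldpert:::coord_components(grid)
  chi <- exp(-(co$x^2 + co$y^2 + co$z^2) / (2 * 2^2))
  fld <- chi_to_field(chi_volume(grid, chi), acq, zero_pad = TRUE)$values_tesla
  vox <- prod(grid$voxel_size_mm)
  src <- which(chi > 1e-8, arr.ind = TRUE)
  brute_at <- function(idx) {
    tgt <- c(co$x[idx[1], 1, 1], co$y[1, idx[2], 1], co$z[1, 1, idx[3]])
    s <- 0
    for (i in seq_len(nrow(src))) {
      sv <- src[i, ]
      off <- tgt - c(co$x[sv[1], 1, 1], co$y[1, sv[2], 1], co$z[1, 1, sv[3]])
      if (sum(off^2) > 0)
        s <- s + chi[sv[1], sv[2], sv[3]] * dipole_kernel_spatial(off)
    }
    s * acq$b0_tesla * 1e-6 * vox
  }
  for (idx in list(c(9, 9, 14), c(14, 9, 9), c(9, 14, 14), c(13, 13, 9))) {
    bv <- brute_at(idx)
    expect_equal(fld[idx[1], idx[2], idx[3]], bv, tolerance = 0.05)
  }
})

test_that("chi-to-field is linear and kills uniform offsets", {
  grid <- vox_grid(c(16, 16, 16))
  acq <- acq_params()
  # uniform chi on the periodic (unpadded) operator: D(0) = 0 kills it
  uni <- chi_to_field(chi_volume(grid, array(0.3, grid$shape)), acq,
                      zero_pad = FALSE)
  expect_equal(max(abs(uni$values_tesla)), 0, tolerance = 1e-15)

  set.seed(1)
  a <- array(stats::rnorm(16^3), grid$shape)
  b <- array(stats::rnorm(16^3), grid$shape)
  fa <- chi_to_field(chi_volume(grid, a), acq)$values_tesla
  fb <- chi_to_field(chi_volume(grid, b), acq)$values_tesla
  fab <- chi_to_field(chi_volume(grid, a + b), acq)$values_tesla
  expect_equal(fab, fa + fb, tolerance = 1e-12)
})

test_that("analytic sphere field has its closed-form values", {
  grid <- vox_grid(c(32, 32, 32))
  acq <- acq_params(b0_tesla = 3)
  a <- 4
  fld <- sphere_field_analytic(grid, c(0, 0, 0), a, 1, acq)
  cx <- 17L
  iz <- cx + 2L * a   # on-axis r = 2a
  expect_equal(fld[cx, cx, iz], acq$b0_tesla * 1e-6 / 12, tolerance = 1e-12)
  ix <- cx + 2L * a   # equatorial r = 2a: 3 cos^2 - 1 = -1
  expect_equal(fld[ix, cx, cx], -acq$b0_tesla * 1e-6 / 24, tolerance = 1e-12)
  # magic angle exterior zero: cos^2 theta = 1/3
  z <- 8 / sqrt(3); x <- 8 * sqrt(2 / 3)
  expect_equal(acq$b0_tesla * (1e-6 / 3) * (a / 8)^3 * (3 * (z / 8)^2 - 1), 0,
               tolerance = 1e-15)
  expect_error(sphere_field_analytic(grid, c(0, 0, 0), -1, 1, acq), "positive")
})

test_that("forward sphere field matches the analytic oracle", {
  grid <- vox_grid(c(64, 64, 64))
  acq <- acq_params()
  a <- 8
  chi <- rasterize_sphere(grid, c(0, 0, 0), a, 1)
  fld <- chi_to_field(chi, acq, zero_pad = TRUE)$values_tesla
  oracle <- sphere_field_analytic(grid, c(0, 0, 0), a, 1, acq)
  r <- radius_array(grid)
  ext <- r > 1.5 * a
  rel_rmse <- sqrt(mean((fld[ext] - oracle[ext])^2)) / sqrt(mean(oracle[ext]^2))
  expect_lt(rel_rmse, 0.05)
})

test_that("intravoxel dephasing averages unit phasors correctly", {
  acq <- acq_params(supersample = 2L)
  g <- acq$gamma_rad_per_s_per_tesla * acq$te_s
  fine <- vox_grid(c(16, 16, 16), rep(0.5, 3))

  # uniform field in every voxel: C = exp(i g b), |C| = 1
  # (built directly: a uniform field is not mean-free, the container would
  # reject it, but the dephasing operator itself is offset-agnostic)
  bval <- 0.05 / g
  fm <- structure(list(grid = fine, values_tesla = array(bval, fine$shape)),
                  class = "field_map")
  C <- dephase_to_complex(fm, acq)
  expect_equal(C, array(exp(1i * 0.05), c(8, 8, 8)), tolerance = 1e-12)

  # two half-voxels at +/- phi/(g): C = cos(phi), real
  phi <- 0.7
  vals <- array(0, fine$shape)
  vals[seq(1, 16, by = 2), , ] <- phi / g
  vals[seq(2, 16, by = 2), , ] <- -phi / g
  C2 <- dephase_to_complex(structure(list(grid = fine,
                                          values_tesla = vals),
                                     class = "field_map"), acq)
  expect_equal(C2, array(complex(real = cos(phi), imaginary = 0), c(8, 8, 8)),
               tolerance = 1e-12)

  # T_E = 0 -> C = 1 everywhere
  acq0 <- acq_params(te_s = 1e-300, supersample = 2L)
  C3 <- dephase_to_complex(structure(list(grid = fine, values_tesla = vals),
                                     class = "field_map"), acq0)
  expect_equal(C3, array(1 + 0i, c(8, 8, 8)), tolerance = 1e-12)

  # non-multiple shape rejected
  acq3 <- acq_params(supersample = 3L)
  expect_error(dephase_to_complex(fm, acq3), "integer multiple")
})

test_that("simulated T2* series respects |C| <= 1 and static inputs", {
  grid <- vox_grid(c(12, 12, 12))
  acq <- acq_params(supersample = 2L)
  chi0 <- array(0, grid$shape); chi0[5:8, 5:8, 5:8] <- 0.4
  series <- chi_series(grid, array(chi0, c(grid$shape, 3)), 3)
  t2s <- simulate_t2star_series(series, acq)
  expect_lte(max(Mod(t2s$complex_values)), 1 + 1e-9)
  # dchi = 0 -> all frames identical
  expect_equal(t2s$complex_values[, , , 1], t2s$complex_values[, , , 3])
  # |C| = 1 iff intravoxel field constant: interior of the cube dephases
  expect_lt(min(Mod(t2s$complex_values)), 1 - 1e-4)
})

test_that("7T demo conditions produce severely wrapped phase", {
  spec <- demo_phantom_spec(32)
  chi0 <- make_background_chi(spec$grid, spec$chi0_blobs,
                              spec$envelope_semiaxes_mm, spec$envelope_ppm)
  series <- chi_series(spec$grid, array(chi0$values_ppm, c(spec$grid$shape, 1)), 3)
  t2s <- simulate_t2star_series(series, acq_params(b0_tesla = 7, te_s = 0.029))
  p <- t2s_phase(t2s)
  expect_lt(min(p), -0.9 * pi)
  expect_gt(max(p), 0.9 * pi)
  expect_gte(min(p), -pi)
  expect_lt(max(p), pi)
})

test_that("Taylor diagnostics follow the printed expansions", {
  acq <- acq_params(supersample = 2L)
  g <- acq$gamma_rad_per_s_per_tesla * acq$te_s
  fine <- vox_grid(c(8, 8, 8), rep(0.5, 3))
  # two subvoxel values with g*b = +/- 0.1
  vals <- array(0, fine$shape)
  vals[seq(1, 8, 2), , ] <- 0.1 / g
  vals[seq(2, 8, 2), , ] <- -0.1 / g
  fm <- structure(list(grid = fine, values_tesla = vals), class = "field_map")

  A <- magnitude_first_order(fm, acq)
  expect_equal(A, array(1.005, c(4, 4, 4)), tolerance = 1e-12)
  # exact dephasing gives cos(0.1): the expansion overshoots 1, the exact
  # average stays below it — the documented discrepancy of the printed form
  C <- dephase_to_complex(fm, acq)
  expect_equal(Mod(C), array(cos(0.1), c(4, 4, 4)), tolerance = 1e-12)
  expect_true(all(A >= 1) && all(Mod(C) <= 1))

  # order-1 phase is the voxel-mean scaled by gamma T_E
  vals2 <- array(0, fine$shape)
  vals2[seq(1, 8, 2), , ] <- 0.05 / g
  vals2[seq(2, 8, 2), , ] <- 0.15 / g
  fm2 <- structure(list(grid = fine, values_tesla = vals2), class = "field_map")
  expect_equal(phase_taylor(fm2, acq, 1), array(0.1, c(4, 4, 4)),
               tolerance = 1e-12)
  # the symmetric pair's exact phase is also the mean (phasor symmetry)
  expect_equal(wrapv(Arg(dephase_to_complex(fm2, acq))), array(0.1, c(4, 4, 4)),
               tolerance = 1e-12)
  # zero field -> zero phase at both orders
  zf <- structure(list(grid = fine, values_tesla = array(0, fine$shape)),
                  class = "field_map")
  expect_equal(phase_taylor(zf, acq, 1), array(0, c(4, 4, 4)))
  expect_equal(phase_taylor(zf, acq, 2), array(0, c(4, 4, 4)))
  expect_error(phase_taylor(zf, acq, 3), "order")
})
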