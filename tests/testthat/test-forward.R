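test_that("dipole field of a sphere matches the analytic solution", {
  g <- tiny_grid(c(64, 64, 64))
  a <- 4
  chi <- sphere_chi(g, c(0, 0, 0), a, 1)
  fld <- forward_field(chi, g, pad = 2)
  co <- grid_coords(g)
  r <- sqrt(rowSums(co^2))
  cth2 <- (co[, 3] / pmax(r, 1e-9))^2
  analytic <- (1 / 3) * (a / r)^3 * (3 * cth2 - 1) / 2 * 2
  sel <- r >= 3 * a & r <= 20 & abs(analytic) > 1e-4
  expect_lt(max(abs(fld[sel] - analytic[sel]) / abs(analytic[sel])), 0.05)
  # inside the sphere the Lorentz-corrected field vanishes
  expect_lt(max(abs(fld[r < 0.6 * a])), 0.02)
  # uniform (periodic) chi gives exactly zero field: D(0) = 0.  Padding
  # is disabled because zero-padding would turn the uniform volume into a
  # finite box with edges.
  expect_equal(forward_field(array(2, dim = c(8, 8, 8)),
                             grid_meta(c(8, 8, 8), c(1, 1, 1)), pad = 1),
               array(0, dim = c(8, 8, 8)), tolerance = 1e-12)
})

test_that("forward field is linear and mirror-symmetric", {
  g <- tiny_grid(c(24, 24, 24))
  set.seed(3)
  c1 <- array(rnorm(prod(g$shape)), g$shape)
  c2 <- array(rnorm(prod(g$shape)), g$shape)
  f12 <- forward_field(2 * c1 - 3 * c2, g)
  expect_equal(f12, 2 * forward_field(c1, g) - 3 * forward_field(c2, g),
               tolerance = 1e-10)
  # mirroring chi through the grid center mirrors the field
  mir <- function(x) x[dim(x)[1]:1, dim(x)[2]:1, dim(x)[3]:1]
  chi <- sphere_chi(g, c(3, -2, 1), 3, 1)
  expect_equal(forward_field(mir(chi), g), mir(forward_field(chi, g)),
               tolerance = 1e-8)
})

test_that("dephasing map follows the intra-voxel field spread", {
  g <- grid_meta(c(16, 16, 8), c(1, 1, 2), origin = -c(7.5, 7.5, 7),
                 b0 = 1.5)
  os <- 4L
  # uniform (periodic) chi -> uniform field -> no intra-voxel spread
  uni <- array(1, dim = g$shape * os)
  expect_equal(dephasing_map(uni, g, os, pad = 1),
               array(0, dim = g$shape), tolerance = 1e-8)
  # marker: neighbors dephase much faster than distant voxels
  g_os <- grid_meta(g$shape * os, g$voxel_size / os, g$origin,
                    b0_axis = 3L, b0 = g$b0)
  chi_os <- sphere_chi(g_os, c(0, 0, 0), 1.5, -36, oversample = 2L)
  r2p <- dephasing_map(chi_os, g, os)
  ctr <- c(9, 9, 4)
  near <- r2p[ctr[1] + 2, ctr[2], ctr[3]]
  far <- r2p[ctr[1] + 7, ctr[2], ctr[3]]
  expect_gt(near, far * 5)
  # doubling B0 doubles the rate
  g2 <- grid_meta(g$shape, g$voxel_size, g$origin, b0_axis = 3L, b0 = 3.0)
  expect_equal(dephasing_map(chi_os, g2, os), 2 * r2p, tolerance = 1e-8)
})

test_that("echo simulation obeys the closed-form signal model", {
  g <- grid_meta(c(4, 4, 2), c(1, 1, 2), b0 = 1.5)
  tes <- default_tes()
  m0 <- array(1, g$shape); r2 <- array(30, g$shape)
  fld0 <- array(0, g$shape)
  gre <- simulate_echoes(m0, r2, fld0, g, tes, noise_sigma = 0)
  for (j in seq_along(tes)) {
    expect_equal(unname(gre_magnitude(gre)[1, 1, 1, j]), exp(-30 * tes[j]),
                 tolerance = 1e-12)
    expect_equal(unname(gre_phase(gre)[1, 1, 1, j]), 0)
  }
  # 10 Hz off-resonance: phase wraps as 2*pi*f*TE
  f_ppm <- array(10 / hz_per_ppm(g), g$shape)
  gre2 <- simulate_echoes(m0, r2, f_ppm, g, tes, noise_sigma = 0)
  for (j in seq_along(tes)) {
    expect_equal(unname(gre_phase(gre2)[2, 2, 1, j]),
                 qsmfid:::wrap_phase(2 * pi * 10 * tes[j]), tolerance = 1e-9)
  }
  expect_error(simulate_echoes(m0, r2, fld0, g, c(0.003, 0.003)),
               "strictly increasing")
})

test_that("echo noise is seed-deterministic", {
  g <- grid_meta(c(6, 6, 4), c(1, 1, 1))
  m0 <- array(1, g$shape); r2 <- array(20, g$shape)
  fld <- array(0, g$shape)
  a <- simulate_echoes(m0, r2, fld, g, noise_sigma = 0.05, seed = 11)
  b <- simulate_echoes(m0, r2, fld, g, noise_sigma = 0.05, seed = 11)
  c <- simulate_echoes(m0, r2, fld, g, noise_sigma = 0.05, seed = 12)
  expect_identical(a$signal, b$signal)
  expect_false(identical(a$signal, c$signal))
})

test_that("noiseless phantom phase equals 2*pi*f*TE exactly", {
  spec <- default_phantom(compact = TRUE, noise_sigma = 0)
  spec$grid <- grid_meta(c(48, 48, 16), c(1, 1, 2),
                         -(c(48, 48, 16) - 1) / 2 * c(1, 1, 2))
  spec$body <- inclusion_spec("ellipsoid", c(0, 0, 0), c(22, 20, 14),
                              label = "tissue")
  spec$prostate <- inclusion_spec("ellipsoid", c(0, 0, 0), c(12, 10, 8),
                                  label = "tissue")
  spec$inclusions <- list(inclusion_spec("sphere", c(0.5, 0.5, 1), 2,
                                         chi = -36, m0 = 0,
                                         label = "gold"))
  ph <- simulate_phantom(spec)
  f_hz <- ph$field * hz_per_ppm(spec$grid)
  sel <- ph$gre$signal[, , , 3] != 0
  expect_equal(Arg(ph$gre$signal[, , , 3])[sel],
               qsmfid:::wrap_phase(2 * pi * f_hz * ph$gre$tes[3])[sel],
               tolerance = 1e-9)
})
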