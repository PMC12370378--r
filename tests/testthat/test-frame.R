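# Rasterize bright rods into a T2w-like volume.
rod_volume <- function(grid, rod_centers_mm, length_mm = 100,
                       radius_mm = 2, axis = 3L, intensity = 100) {
  vol <- array(stats::rnorm(prod(grid$shape), 10, 1), grid$shape)
  for (ctr in rod_centers_mm) {
    inc <- inclusion_spec("cylinder", ctr, c(radius_mm, length_mm, axis),
                          label = "rod")
    fr <- qsmfid:::inclusion_fraction(inc, grid, 2L)
    ix <- lapply(1:3, function(a) seq.int(fr$range[1, a], fr$range[2, a]))
    vol[ix[[1]], ix[[2]], ix[[3]]] <-
      vol[ix[[1]], ix[[2]], ix[[3]]] + intensity * fr$frac
  }
  vol
}

test_that("rod detection localizes bright elongated components", {
  set.seed(2)
  shape <- c(60, 60, 60); vox <- c(2, 2, 2)
  g <- grid_meta(shape, vox, -(shape - 1) / 2 * vox)
  # rods in the inferior quarter of axis 2 (y < -29)
  centers <- list(c(-40, -45, 0), c(0, -50, 0), c(40, -45, 0))
  vol <- rod_volume(g, centers)
  rods <- suppressWarnings(detect_rods(vol, g, intensity_percentile = 97,
                                       expected_count = 3L))
  expect_equal(nrow(rods), 3)
  for (i in 1:3)
    expect_lt(sqrt(sum((rods[i, ] - centers[[i]])^2)), 1.0)
  # left-to-right ordering
  expect_true(all(diff(rods[, 1]) > 0))
})

test_that("rod detection errors on featureless input and trims extras", {
  set.seed(3)
  g <- grid_meta(c(30, 30, 30), c(2, 2, 2), -c(29, 29, 29))
  flat <- array(rnorm(27000, 10, 0.1), g$shape)
  expect_error(detect_rods(flat, g), "component")
  shape <- c(60, 60, 60)
  g2 <- grid_meta(shape, c(2, 2, 2), -(shape - 1))
  centers <- list(c(-40, -45, 0), c(-15, -50, 0), c(15, -50, 0),
                  c(40, -45, 0))
  vol <- rod_volume(g2, centers)
  expect_warning(rods <- detect_rods(vol, g2, intensity_percentile = 97,
                                     expected_count = 3L),
                 "keeping")
  expect_equal(nrow(rods), 3)
})

test_that("Kabsch fit is exact on congruent point sets", {
  pts <- rbind(c(-100, 0, -150), c(0, 0, -170), c(100, 0, -150),
               c(20, 30, -160))
  tf <- fit_rigid(pts, pts)
  expect_equal(tf$rotation, diag(3), tolerance = 1e-12)
  expect_equal(tf$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_lt(tf$rms_residual, 1e-9)
  tf2 <- fit_rigid(pts, sweep(pts, 2, c(10, 0, 0), `+`))
  expect_equal(tf2$translation, c(10, 0, 0), tolerance = 1e-10)
  expect_equal(tf2$rotation, diag(3), tolerance = 1e-12)
  expect_lt(tf2$rms_residual, 1e-9)
  # exactness on a rotated congruent set
  th <- 0.4
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  tf3 <- fit_rigid(pts, sweep(pts %*% t(R), 2, c(1, 2, 3), `+`))
  expect_lt(tf3$rms_residual, 1e-9)
  expect_equal(tf3$rotation, R, tolerance = 1e-10)
})

test_that("jittered fit matches the quaternion grid-search oracle", {
  set.seed(12)
  src <- rbind(c(-100, 0, -150), c(0, 0, -170), c(100, 0, -150))
  ang <- 0.3
  ax <- c(1, 2, 0.5); ax <- ax / sqrt(sum(ax^2))
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
  t <- c(5, -3, 8)
  tgt <- sweep(src %*% t(R), 2, t, `+`) + matrix(rnorm(9, 0, 0.1), 3)
  tf <- fit_rigid(src, tgt)
  expect_lt(tf$rms_residual, 0.3)
  oracle <- quaternion_grid_fit(src, tgt)
  expect_lt(abs(tf$rms_residual - oracle$rms), 0.02)
  expect_lt(max(abs(tf$rotation - oracle$rotation)), 0.02)
})

test_that("point mapping preserves geometry and composes with its inverse", {
  src <- rbind(c(-100, 0, -150), c(0, 0, -170), c(100, 0, -150))
  tgt <- rbind(c(-98, 5, -149), c(2, 4, -171), c(101, 6, -148))
  tf <- fit_rigid(src, tgt)
  # rod reference points map onto their counterparts within the residual
  mapped <- map_point(tf, src)
  for (i in 1:3)
    expect_lte(sqrt(sum((mapped[i, ] - tgt[i, ])^2)),
               tf$rms_residual * sqrt(3) + 1e-9)
  # pairwise distances preserved to 1e-9
  d0 <- dist(src); d1 <- dist(mapped)
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)
  # identity and inverse composition
  p <- c(12, -7, 40)
  id <- rigid_transform(diag(3), c(0, 0, 0))
  expect_equal(map_point(id, p), p)
  expect_equal(map_point(tf, map_point(invert_transform(tf), p)), p,
               tolerance = 1e-9)
  expect_error(fit_rigid(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                         rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))),
               "collinear")
})
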