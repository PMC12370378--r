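# Small noiseless phantom with resolvable sources for inversion tests:
# three 1 mm gold spheres centered on voxel centers, one calcification,
# on a 64x64x24 grid at the acquisition voxel size.
.inv_fx_cache <- new.env(parent = emptyenv())

inversion_fixture <- function() {
  if (!is.null(.inv_fx_cache$fx)) return(.inv_fx_cache$fx)
  shape <- c(64, 64, 24); vox <- c(1, 1, 2)
  g <- grid_meta(shape, vox, -(shape - 1) / 2 * vox)
  body <- inclusion_spec("ellipsoid", c(0, 0, 0), c(30, 28, 20),
                         label = "tissue")
  pros <- inclusion_spec("ellipsoid", c(0, 0, 0), c(16, 14, 12),
                         label = "tissue")
  gold <- list(c(-7.5, -3.5, -5), c(7.5, 1.5, 3), c(-0.5, 6.5, 5))
  incs <- c(lapply(gold, function(ctr)
    inclusion_spec("sphere", ctr, 1, chi = -36, r2star = 0, m0 = 0,
                   label = "gold")),
    list(inclusion_spec("sphere", c(4.5, -7.5, -1), 2, chi = -21,
                        r2star = 100, m0 = 0.4, label = "calcification")))
  spec <- phantom_spec(g, body, pros, incs, noise_sigma = 0)
  ras <- rasterize_phantom(spec)
  field <- forward_field(ras$chi, g, pad = 2)
  .inv_fx_cache$fx <- list(grid = g, ras = ras, field = field,
                           mask = ras$truth$masks$body)
  .inv_fx_cache$fx
}

test_that("TKD inverts a smooth blob within the documented error", {
  g <- tiny_grid(c(48, 48, 32))
  co <- grid_coords(g)
  blob <- array(2 * exp(-rowSums(co^2) / (2 * 16)), g$shape)
  f <- forward_field(blob, g, pad = 2)
  tk <- invert_tkd(f, array(TRUE, g$shape), g, delta = 0.1,
                   reference_mask = array(TRUE, g$shape))
  core <- blob > 0.5
  expect_lt(max(abs(tk$chi[core] - blob[core])) / max(blob), 0.20)
  # zero field maps to zero chi; scaling is exact
  z <- invert_tkd(array(0, g$shape), array(TRUE, g$shape), g)
  expect_equal(z$chi, array(0, g$shape))
  tk2 <- invert_tkd(2 * f, array(TRUE, g$shape), g, delta = 0.1,
                    reference_mask = array(TRUE, g$shape))
  expect_equal(tk2$chi, 2 * tk$chi, tolerance = 1e-9)
})

test_that("regularized inversion recovers marker and calcification chi", {
  fx <- inversion_fixture()
  md <- suppressWarnings(
    invert_medi0(fx$field * fx$mask, fx$ras$m0, fx$mask, NULL,
                 fx$grid, exclude_mask = fx$ras$truth$masks$prostate,
                 outer_iter = 8L, inner_iter = 8L))
  tk <- invert_tkd(fx$field * fx$mask, fx$mask, fx$grid)
  masks <- fx$ras$truth$masks
  gold_means <- vapply(grep("^gold", names(masks), value = TRUE),
                       function(nm) mean(md$chi[masks[[nm]]]), 0)
  calc_mean <- mean(md$chi[masks$calcification_4])
  expect_true(all(gold_means >= -48 & gold_means <= -24))
  expect_true(calc_mean >= -28 && calc_mean <= -12)
  expect_true(all(gold_means <= calc_mean - 8))
  # the TKD baseline agrees on the ordering gold < calcification < tissue
  gold_tkd <- vapply(grep("^gold", names(masks), value = TRUE),
                     function(nm) mean(tk$chi[masks[[nm]]]), 0)
  expect_true(all(gold_tkd < mean(tk$chi[masks$calcification_4])))
  expect_lt(mean(tk$chi[masks$calcification_4]),
            mean(tk$chi[masks$prostate & !masks$calcification_4]))
})

test_that("zero-referencing is exact and shift-invariant", {
  fx <- inversion_fixture()
  md <- suppressWarnings(
    invert_medi0(fx$field * fx$mask, fx$ras$m0, fx$mask, NULL,
                 fx$grid, exclude_mask = fx$ras$truth$masks$prostate,
                 outer_iter = 3L))
  expect_lt(abs(mean(md$chi[md$reference_mask])), 1e-6)
  # adding a constant to the field leaves zero-referenced contrasts alone
  md2 <- suppressWarnings(
    invert_medi0((fx$field + 0.05) * fx$mask, fx$ras$m0, fx$mask,
                 md$reference_mask, fx$grid, outer_iter = 3L))
  md1 <- suppressWarnings(
    invert_medi0(fx$field * fx$mask, fx$ras$m0, fx$mask,
                 md$reference_mask, fx$grid, outer_iter = 3L))
  i <- which(fx$mask)[c(10, 5000)]
  expect_equal(md2$chi[i[1]] - md2$chi[i[2]],
               md1$chi[i[1]] - md1$chi[i[2]], tolerance = 0.02)
})

test_that("IRLS objective is non-increasing across outer iterations", {
  fx <- inversion_fixture()
  md <- invert_medi0(fx$field * fx$mask, fx$ras$m0, fx$mask, NULL,
                     fx$grid, exclude_mask = fx$ras$truth$masks$prostate,
                     robust_fidelity = FALSE, outer_iter = 6L)
  obj <- md$params$objective
  expect_true(all(diff(obj) <= 1e-8))
})

test_that("zero field inverts to zero chi in both methods", {
  g <- tiny_grid(c(24, 24, 16))
  mask <- array(TRUE, g$shape)
  zero <- array(0, g$shape)
  expect_equal(invert_tkd(zero, mask, g)$chi, zero)
  md <- invert_medi0(zero, array(1, g$shape), mask, mask, g,
                     outer_iter = 2L)
  expect_equal(md$chi, zero, tolerance = 1e-8)
})

test_that("inversion validates the reference mask", {
  g <- tiny_grid(c(16, 16, 8))
  zero <- array(0, g$shape)
  expect_error(invert_medi0(zero, array(1, g$shape), array(TRUE, g$shape),
                            array(FALSE, g$shape), g), "empty")
})
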