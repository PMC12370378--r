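test_that("temporal initializer is exact, offset-invariant, and aliases as documented", {
  tes <- default_tes()
  g15 <- grid_meta(c(2, 2, 2), c(1, 1, 1), b0 = 1.5)
  gre <- voxel_gre(model_signal(1, 0, 10, 40, tes), tes)
  expect_equal(temporal_field_init(gre)[1, 1, 1] * hz_per_ppm(g15), 10,
               tolerance = 1e-9)
  # a static phase offset cancels in the echo-to-echo products
  gre_off <- voxel_gre(model_signal(1, 1.0, 0, 40, tes), tes)
  expect_equal(temporal_field_init(gre_off)[1, 1, 1], 0, tolerance = 1e-12)
  # beyond the temporal Nyquist the estimate aliases by 1/dTE
  dte <- 4.3e-3
  gre_hi <- voxel_gre(model_signal(1, 0, 120, 0, tes), tes)
  expect_equal(temporal_field_init(gre_hi)[1, 1, 1] * hz_per_ppm(g15),
               120 - 1 / dte, tolerance = 1e-6)
})

test_that("complex field fit recovers all four parameters exactly without noise", {
  tes <- default_tes()
  truth <- c(A = 1, phi0 = 0.3, f = 25, r2 = 60)
  gre <- voxel_gre(model_signal(truth["A"], truth["phi0"], truth["f"],
                                truth["r2"], tes), tes)
  fm <- fit_complex_field(gre, temporal_field_init(gre))
  expect_equal(fm$amplitude[1, 1, 1], unname(truth["A"]), tolerance = 1e-6)
  expect_equal(fm$phi0[1, 1, 1], unname(truth["phi0"]), tolerance = 1e-6)
  expect_equal(fm$field_hz[1, 1, 1], unname(truth["f"]), tolerance = 1e-6)
  expect_equal(fm$r2star[1, 1, 1], unname(truth["r2"]), tolerance = 1e-4)
  expect_equal(fm$reliability[1, 1, 1], 1)
})

test_that("field fit flags signal voids instead of failing", {
  tes <- default_tes()
  g <- grid_meta(c(3, 3, 2), c(1, 1, 1))
  sig <- array(0i, dim = c(3, 3, 2, length(tes)))
  for (j in seq_along(tes))
    sig[, , , j] <- model_signal(1, 0, 15, 50, tes[j])
  sig[2, 2, 1, ] <- 0i           # dead voxel
  gre <- multi_echo_gre(sig, tes, g)
  fm <- fit_complex_field(gre)
  expect_equal(fm$reliability[2, 2, 1], 0)
  expect_true(all(is.finite(fm$field)))
})

test_that("field fit is invariant to a global phase offset of the data", {
  tes <- default_tes()
  g <- grid_meta(c(3, 3, 2), c(1, 1, 1))
  set.seed(5)
  sig <- array(0i, dim = c(3, 3, 2, length(tes)))
  for (j in seq_along(tes))
    sig[, , , j] <- model_signal(1, 0.2, 20, 45, tes[j]) +
      complex(real = rnorm(18, 0, 0.01), imaginary = rnorm(18, 0, 0.01))
  gre_a <- multi_echo_gre(sig, tes, g)
  gre_b <- multi_echo_gre(sig * exp(1i * 0.8), tes, g)
  fa <- fit_complex_field(gre_a)
  fb <- fit_complex_field(gre_b)
  expect_equal(fa$field_hz, fb$field_hz, tolerance = 1e-6)
})

test_that("fit precision is within 2x the Cramer-Rao bound at sigma = 0.01", {
  tes <- default_tes()
  sigma <- 0.01
  truth <- list(A = 1, phi0 = 0.3, f = 25, r2 = 60)
  s0 <- model_signal(truth$A, truth$phi0, truth$f, truth$r2, tes)
  # numerical Fisher information (central differences on the model)
  dpar <- c(1e-6, 1e-6, 1e-4, 1e-4)
  J <- matrix(0i, length(tes), 4)
  for (p in 1:4) {
    up <- truth; dn <- truth
    up[[p]] <- up[[p]] + dpar[p]; dn[[p]] <- dn[[p]] - dpar[p]
    J[, p] <- (model_signal(up$A, up$phi0, up$f, up$r2, tes) -
                 model_signal(dn$A, dn$phi0, dn$f, dn$r2, tes)) /
      (2 * dpar[p])
  }
  FIM <- Re(Conj(t(J)) %*% J) / sigma^2
  crb_f <- sqrt(solve(FIM)[3, 3])
  set.seed(99)
  n_mc <- 200
  f_hat <- numeric(n_mc)
  for (k in seq_len(n_mc)) {
    sig <- s0 + complex(real = rnorm(length(tes), 0, sigma),
                        imaginary = rnorm(length(tes), 0, sigma))
    gre <- voxel_gre(sig, tes)
    fm <- fit_complex_field(gre, temporal_field_init(gre))
    f_hat[k] <- fm$field_hz[1, 1, 1]
  }
  expect_lt(abs(mean(f_hat) - truth$f), 0.2)
  expect_lt(sd(f_hat), 2 * crb_f)
})

test_that("Laplacian unwrap recovers a 6pi quadratic ramp", {
  g <- grid_meta(c(48, 48, 16), c(1, 1, 2))
  x <- (0:47) / 47; z <- (0:15) / 15
  truth <- 6 * pi * (outer(outer((x - 0.5)^2, (x - 0.5)^2, `+`),
                           (z - 0.5)^2, `+`))
  wrapped <- qsmfid:::wrap_phase(truth)
  uw <- laplacian_unwrap(wrapped, g)
  interior <- array(FALSE, dim = dim(truth))
  interior[3:46, 3:46, 3:14] <- TRUE
  err <- uw - truth
  err <- err - mean(err[interior])
  expect_lt(max(abs(err[interior])), 0.1)
  # smooth unwrapped input comes back unchanged up to a constant
  sm <- truth / 10
  uw2 <- laplacian_unwrap(sm, g)
  d2 <- uw2 - sm
  expect_lt(max(abs(d2 - mean(d2))), 1e-8)
  # adding whole wraps before wrapping changes nothing
  uw3 <- laplacian_unwrap(qsmfid:::wrap_phase(truth + 6 * pi), g)
  expect_equal(uw3, uw, tolerance = 1e-9)
})

test_that("alias correction restores fields beyond the temporal Nyquist", {
  g <- grid_meta(c(32, 32, 8), c(1, 1, 2), origin = -c(15.5, 15.5, 7))
  tes <- default_tes()
  # smooth field crossing the Nyquist limit (116 Hz): a broad Gaussian
  co <- grid_coords(g)
  f_true_hz <- array(200 * exp(-rowSums(co^2) / (2 * 64)), g$shape)
  m0 <- array(1, g$shape); r2 <- array(30, g$shape)
  gre <- simulate_echoes(m0, r2, f_true_hz / hz_per_ppm(g), g, tes,
                         noise_sigma = 0)
  fm <- fit_complex_field(gre, temporal_field_init(gre))
  # the raw fit aliases at the center...
  expect_lt(fm$field_hz[16, 16, 4], 0)
  # ...and unwrap_field recovers it
  f_corr <- unwrap_field(fm, g)
  expect_equal(f_corr, f_true_hz, tolerance = 1e-3)
})
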