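# Shared fixtures, all generated in code.

# Small isotropic grid centered at the origin.
tiny_grid <- function(shape = c(48, 48, 32), voxel = c(1, 1, 1), b0 = 1.5) {
  grid_meta(shape, voxel, origin = -(shape - 1) / 2 * voxel,
            b0_axis = 3L, b0 = b0)
}

# Susceptibility volume holding a single sphere.
sphere_chi <- function(grid, center, radius, chi, oversample = 4L) {
  inc <- inclusion_spec("sphere", center, radius, chi = chi,
                        label = "other")
  fr <- qsmfid:::inclusion_fraction(inc, grid, oversample)
  vol <- array(0, dim = grid$shape)
  ix <- lapply(1:3, function(a) seq.int(fr$range[1, a], fr$range[2, a]))
  vol[ix[[1]], ix[[2]], ix[[3]]] <- chi * fr$frac
  vol
}

# mm coordinates of every voxel center as an n x 3 matrix.
grid_coords <- function(grid) {
  voxel_to_world(grid, as.matrix(expand.grid(seq_len(grid$shape[1]),
                                             seq_len(grid$shape[2]),
                                             seq_len(grid$shape[3]))))
}

# Single-voxel multi-echo signal for the mono-exponential model.
model_signal <- function(A, phi0, f_hz, r2star, tes) {
  A * exp(1i * phi0) * exp((1i * 2 * pi * f_hz - r2star) * tes)
}

# Wrap a per-voxel signal vector into a 2x2x2 multi_echo_gre.
voxel_gre <- function(sig, tes, b0 = 1.5) {
  g <- grid_meta(c(2, 2, 2), c(1, 1, 1), b0 = b0)
  arr <- array(rep(sig, each = 8), dim = c(2, 2, 2, length(tes)))
  multi_echo_gre(arr, tes, g)
}

# Brute-force optimal one-to-one assignment (for n <= 6) by enumerating
# permutations; oracle for the Hungarian solver.
brute_force_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  k <- min(n, m)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- NULL; best_cost <- Inf
  rows <- utils::combn(seq_len(n), k, simplify = FALSE)
  cols <- utils::combn(seq_len(m), k, simplify = FALSE)
  for (rs in rows) for (cs in cols) for (p in perms(cs)) {
    tc <- sum(cost[cbind(rs, p)])
    if (tc < best_cost) { best_cost <- tc; best <- cbind(rs, p) }
  }
  list(pairs = best, total = best_cost)
}

# Quaternion grid-search rigid-fit oracle: coarse search over rotations
# followed by local refinement, independent of the SVD solution path.
quaternion_grid_fit <- function(source, target, n_grid = 12) {
  s0 <- sweep(source, 2, colMeans(source))
  d0 <- sweep(target, 2, colMeans(target))
  q2R <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  obj <- function(q) {
    R <- q2R(q)
    sum((s0 %*% t(R) - d0)^2)
  }
  # coarse random search (fixed seed) + Nelder-Mead polish
  set.seed(7)
  qs <- matrix(rnorm(4 * 2000), ncol = 4)
  vals <- apply(qs, 1, obj)
  q0 <- qs[which.min(vals), ]
  opt <- stats::optim(q0, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  R <- q2R(opt$par)
  t <- colMeans(target) - drop(R %*% colMeans(source))
  list(rotation = R, translation = t,
       rms = sqrt(opt$value / nrow(source)))
}
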