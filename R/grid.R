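#' Acquisition grid metadata
#'
#' Describes the voxel grid of a gradient-echo acquisition: matrix size,
#' voxel size, world-space origin, the axis parallel to the main field B0,
#' the field strength and the (reduced) gyromagnetic ratio.
#'
#' World coordinates follow the convention
#' `world_mm = origin + (index - 1) * voxel_size` with 1-based voxel indices,
#' so voxel `(1,1,1)` sits at `origin`.  Files written by the package store
#' 0-based indices for interoperability; the conversion happens at the I/O
#' boundary only.
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param voxel_size numeric length 3, voxel edge length in mm (all > 0).
#' @param origin numeric length 3, world-mm position of the first voxel
#'   center.
#' @param b0_axis which axis (1, 2 or 3) is parallel to B0.  Defaults to the
#'   third (slice) axis, matching an axial pelvis acquisition with B0 along
#'   superior-inferior.
#' @param b0 main field strength in tesla.
#' @param gamma_bar reduced gyromagnetic ratio in MHz/T (proton: 42.577).
#' @return An object of class `grid_meta`.
#' @export
grid_meta <- function(shape, voxel_size, origin = c(0, 0, 0),
                      b0_axis = 3L, b0 = 1.5, gamma_bar = 42.577) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L),
            length(voxel_size) == 3L, all(voxel_size > 0),
            length(origin) == 3L,
            b0_axis %in% 1:3, b0 > 0, gamma_bar > 0)
  structure(list(shape = shape, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin), b0_axis = as.integer(b0_axis),
                 b0 = b0, gamma_bar = gamma_bar),
            class = "grid_meta")
}

#' @export
print.grid_meta <- function(x, ...) {
  cat(sprintf("grid_meta: %s voxels, %s mm, B0 = %g T along axis %d\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$voxel_size), collapse = "x"),
              x$b0, x$b0_axis))
  invisible(x)
}

#' Hz per ppm of B0 for a grid's field strength
#' @param grid a [grid_meta()].
#' @return Scalar: `gamma_bar [MHz/T] * b0 [T]`, i.e. Hz per ppm.
#' @export
hz_per_ppm <- function(grid) grid$gamma_bar * grid$b0

#' World-mm coordinates of voxel centers
#'
#' @param grid a [grid_meta()].
#' @param index n-by-3 matrix of (possibly fractional) 1-based voxel indices.
#' @return n-by-3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(grid, index) {
  index <- matrix(as.numeric(index), ncol = 3)
  sweep(sweep(index - 1, 2, grid$voxel_size, `*`), 2, grid$origin, `+`)
}

#' @rdname voxel_to_world
#' @param world n-by-3 matrix of world coordinates in mm.
#' @export
world_to_voxel <- function(grid, world) {
  world <- matrix(as.numeric(world), ncol = 3)
  sweep(sweep(world, 2, grid$origin, `-`), 2, grid$voxel_size, `/`) + 1
}

# FFT sample frequencies in cycles per sample, matching R's fft() ordering.
fft_freq <- function(n) {
  k <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L))
  k / n
}

# Next integer >= n whose prime factors are all in {2, 3, 5}; mixed-radix
# FFTs are fast at these sizes.
fast_fft_size <- function(n) {
  n <- as.integer(n)
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

#' Unit dipole kernel on the discrete frequency grid
#'
#' Fourier-domain kernel `D(k) = 1/3 - k_b0^2 / |k|^2` relating a
#' susceptibility distribution (ppm) to the field perturbation it induces
#' along B0 (ppm of B0), in the Lorentz-sphere convention.  `D(0)` is set to
#' 0: the mean field of a periodic susceptibility distribution is absorbed
#' into the reference.
#'
#' @param shape grid size (3 ints).
#' @param voxel_size mm per axis; scales the frequency axes.
#' @param b0_axis axis (1-3) parallel to B0.
#' @return Array of dimension `shape` with values in `[-2/3, 1/3]`.
#' @export
dipole_kernel <- function(shape, voxel_size, b0_axis = 3L) {
  kx <- fft_freq(shape[1]) / voxel_size[1]
  ky <- fft_freq(shape[2]) / voxel_size[2]
  kz <- fft_freq(shape[3]) / voxel_size[3]
  k2 <- outer(outer(kx^2, ky^2, `+`), kz^2, `+`)
  kb <- switch(b0_axis,
               outer(outer(kx^2, 0 * ky, `+`), 0 * kz, `+`),
               outer(outer(0 * kx, ky^2, `+`), 0 * kz, `+`),
               outer(outer(0 * kx, 0 * ky, `+`), kz^2, `+`))
  D <- 1 / 3 - kb / k2
  D[1, 1, 1] <- 0
  D
}

# Zero-pad a 3D array to `shape_out` (content kept in the low corner) or
# crop back down.  Padding position is irrelevant for circular convolution;
# what matters is the guard band separating periodic copies.
pad_volume <- function(vol, shape_out) {
  d <- dim(vol)
  if (all(d == shape_out)) return(vol)
  out <- array(0, dim = shape_out)
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- vol
  out
}

crop_volume <- function(vol, shape_out) {
  vol[seq_len(shape_out[1]), seq_len(shape_out[2]), seq_len(shape_out[3]),
      drop = FALSE]
}

# Reusable dipole convolution operator: precomputes the kernel on a padded
# grid and returns a function mapping a chi volume to its induced field.
# The kernel is real and even, so the operator is self-adjoint; iterative
# solvers reuse it many times without rebuilding the kernel.
dipole_operator <- function(grid, shape = grid$shape, pad = 2) {
  shape <- as.integer(shape)
  if (pad > 1) {
    shape_p <- vapply(as.integer(ceiling(shape * pad)), fast_fft_size,
                      integer(1))
  } else {
    shape_p <- shape
  }
  D <- dipole_kernel(shape_p, grid$voxel_size, grid$b0_axis)
  np <- prod(shape_p)
  function(vol) {
    out <- Re(fft(fft(pad_volume(vol, shape_p)) * D, inverse = TRUE)) / np
    crop_volume(out, shape)
  }
}

# Circular convolution with the dipole kernel, optionally on a zero-padded
# grid to suppress wrap-around from the dipole's slow r^-3 decay.
# `pad` multiplies each axis before rounding up to a fast FFT size.
convolve_dipole <- function(vol, grid, pad = 2) {
  dipole_operator(grid, dim(vol), pad)(vol)
}
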