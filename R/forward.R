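#' Field induced by a susceptibility distribution
#'
#' Forward dipole model of QSM: the off-resonance field along B0 (in ppm of
#' B0, Lorentz-sphere convention) is the circular convolution of the
#' susceptibility volume with the unit dipole kernel, evaluated in k-space
#' as `field = IFT( D(k) * FT(chi) )` with `D(k) = 1/3 - k_b0^2/|k|^2` and
#' `D(0) = 0`.  The grid is zero-padded (default 2x per axis, rounded up to
#' fast FFT sizes) to suppress wrap-around of the slowly decaying dipole
#' tails.
#'
#' @param chi susceptibility volume in ppm.
#' @param grid a [grid_meta()].
#' @param pad padding factor per axis (>= 1; 1 disables padding).
#' @return Field volume in ppm of B0, same dimensions as `chi`.
#' @export
forward_field <- function(chi, grid, pad = 2) {
  stopifnot(all(is.finite(chi)))
  convolve_dipole(chi, grid, pad = pad)
}

#' Intra-voxel static dephasing rate from a supersampled field
#'
#' Susceptibility sources create field gradients within an acquisition
#' voxel; under the static dephasing approximation the resulting extra
#' signal decay is proportional to the intra-voxel field spread.  Given the
#' susceptibility volume at supersampled resolution (`oversample` subvoxels
#' per axis), this computes the induced field at that resolution and
#' returns, per acquisition voxel,
#' `r2' = 2 * pi * gamma_bar * 1e6 * b0 * sd(field_ppm * 1e-6)`
#' i.e. `2 * pi` times the standard deviation of the local frequency in Hz
#' (population standard deviation over the `oversample^3` subvoxels).
#' This is what makes a sub-millimeter gold marker appear as a signal void
#' larger than its physical size.
#'
#' @param chi_os susceptibility (ppm) at supersampled resolution; dimensions
#'   must be `grid$shape * oversample`.
#' @param grid acquisition [grid_meta()].
#' @param oversample subvoxels per axis (> 1).
#' @param pad FFT padding factor for the forward field.
#' @return Volume of R2' rates (1/s) at acquisition resolution.
#' @export
dephasing_map <- function(chi_os, grid, oversample, pad = 2) {
  oversample <- as.integer(oversample)
  stopifnot(oversample > 1L,
            all(dim(chi_os) == grid$shape * oversample))
  grid_os <- grid_meta(grid$shape * oversample,
                       grid$voxel_size / oversample,
                       grid$origin, grid$b0_axis, grid$b0, grid$gamma_bar)
  field_os <- forward_field(chi_os, grid_os, pad = pad)
  sd_ppm <- block_sd(field_os, oversample)
  2 * pi * hz_per_ppm(grid) * sd_ppm
}

# Population standard deviation over non-overlapping os^3 blocks.
block_sd <- function(vol, os) {
  d <- dim(vol)
  n <- d %/% os
  dim(vol) <- c(os, n[1], os, n[2], os, n[3])
  vol <- aperm(vol, c(1, 3, 5, 2, 4, 6))
  dim(vol) <- c(os^3, prod(n))
  mu <- colMeans(vol)
  musq <- colMeans(vol^2)
  out <- sqrt(pmax(musq - mu^2, 0))
  dim(out) <- n
  out
}

#' Multi-echo gradient-echo container
#'
#' @param signal complex 4D array `[x, y, z, echo]` (or a list of per-echo
#'   complex volumes).
#' @param tes echo times in seconds, strictly increasing.
#' @param grid a [grid_meta()].
#' @return Object of class `multi_echo_gre`.
#' @export
multi_echo_gre <- function(signal, tes, grid) {
  if (is.list(signal))
    signal <- array(unlist(signal), dim = c(dim(signal[[1]]), length(signal)))
  stopifnot(length(dim(signal)) == 4L,
            all(dim(signal)[1:3] == grid$shape),
            dim(signal)[4] == length(tes),
            length(tes) >= 2L, all(tes > 0), all(diff(tes) > 0))
  structure(list(signal = signal, tes = as.numeric(tes), grid = grid),
            class = "multi_echo_gre")
}

#' @export
print.multi_echo_gre <- function(x, ...) {
  cat(sprintf("multi_echo_gre: %s voxels, %d echoes, TE %s ms\n",
              paste(x$grid$shape, collapse = "x"), length(x$tes),
              paste(format(x$tes * 1e3), collapse = "/")))
  invisible(x)
}

#' @rdname multi_echo_gre
#' @param gre a `multi_echo_gre`.
#' @export
gre_magnitude <- function(gre) Mod(gre$signal)

#' @rdname multi_echo_gre
#' @export
gre_phase <- function(gre) Arg(gre$signal)

#' Default internal-marker echo train
#'
#' Six echoes, first TE 3.1 ms, echo spacing 4.3 ms (3.1-24.6 ms), the
#' multi-echo T2* protocol used for marker detection at 1.5 T.
#' @return Echo times in seconds.
#' @export
default_tes <- function() (3.1 + 4.3 * (0:5)) / 1e3

#' Simulate multi-echo GRE signal from tissue parameter maps
#'
#' Image-domain signal model per voxel and echo:
#' `s_j = m0 * exp(-r2star * TE_j) * exp(i * 2 * pi * f * TE_j)` with
#' `f [Hz] = gamma_bar * 1e6 * b0 * field_ppm * 1e-6`, plus independent
#' complex Gaussian noise (`noise_sigma` per real/imaginary channel).
#' Deterministic given `seed`; the caller's RNG state is preserved.
#'
#' @param m0 proton-density volume.
#' @param r2star total R2* volume (intrinsic + dephasing), 1/s.
#' @param field off-resonance field in ppm of B0.
#' @param grid a [grid_meta()].
#' @param tes echo times in seconds, strictly increasing.
#' @param noise_sigma complex noise sd per channel.
#' @param seed RNG seed for the noise.
#' @return A [multi_echo_gre()].
#' @export
simulate_echoes <- function(m0, r2star, field, grid, tes = default_tes(),
                            noise_sigma = 0, seed = 1L) {
  stopifnot(all(tes > 0))
  if (any(diff(tes) <= 0)) stop("echo times must be strictly increasing")
  f_hz <- hz_per_ppm(grid) * field
  nt <- length(tes)
  sig <- array(0i, dim = c(grid$shape, nt))
  for (j in seq_len(nt)) {
    sig[, , , j] <- m0 * exp(-r2star * tes[j]) *
      exp(1i * 2 * pi * f_hz * tes[j])
  }
  if (noise_sigma > 0) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    n <- length(sig)
    sig <- sig + complex(real = rnorm(n, 0, noise_sigma),
                         imaginary = rnorm(n, 0, noise_sigma))
    dim(sig) <- c(grid$shape, nt)
  }
  multi_echo_gre(sig, tes, grid)
}

# Supersampled susceptibility raster over an index window, compositing all
# inclusions in painter order; used for windowed dephasing.
rasterize_window_os <- function(spec, range, oversample) {
  grid <- spec$grid
  nd <- range[2, ] - range[1, ] + 1L
  os_shape <- nd * oversample
  # subvoxel center coordinates along each axis
  ax <- lapply(1:3, function(a) {
    base <- grid$origin[a] + (seq.int(range[1, a], range[2, a]) - 1) *
      grid$voxel_size[a]
    off <- ((seq_len(oversample) - 0.5) / oversample - 0.5) *
      grid$voxel_size[a]
    as.vector(outer(off, base, `+`))
  })
  chi <- array(spec$background_chi, dim = os_shape)
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  for (inc in c(list(spec$body, spec$prostate), spec$inclusions)) {
    bb <- inclusion_bbox(inc)
    if (any(bb[1, ] > sapply(ax, max)) || any(bb[2, ] < sapply(ax, min)))
      next
    inside <- inclusion_inside(inc, pts)
    chi[inside] <- inc$chi  # binary membership at subvoxel scale
  }
  chi
}

# R2' from susceptibility sources, computed in cropped windows around the
# inclusions that carry susceptibility contrast.  The dipole field decays
# as r^-3, so intra-voxel field spread is significant only near a source;
# computing the supersampled field in local windows (with FFT padding)
# instead of over the whole supersampled grid makes the simulation
# tractable without changing the physics where it matters.  Overlapping
# windows are combined voxelwise by maximum since each window already
# contains every local source.
dephase_windows <- function(spec, chi_threshold = 0.5, margin_vox = 6L) {
  grid <- spec$grid
  r2p <- array(0, dim = grid$shape)
  if (spec$oversample <= 1L) return(r2p)
  for (inc in spec$inclusions) {
    if (abs(inc$chi - spec$background_chi) < chi_threshold) next
    range <- bbox_index_range(grid, inclusion_bbox(inc),
                              margin_vox = margin_vox)
    if (is.null(range)) next
    nd <- range[2, ] - range[1, ] + 1L
    sub_grid <- grid_meta(nd, grid$voxel_size,
                          grid$origin + (range[1, ] - 1) * grid$voxel_size,
                          grid$b0_axis, grid$b0, grid$gamma_bar)
    chi_os <- rasterize_window_os(spec, range, spec$oversample)
    w <- dephasing_map(chi_os, sub_grid, spec$oversample, pad = 2)
    ix <- lapply(1:3, function(a) seq.int(range[1, a], range[2, a]))
    r2p[ix[[1]], ix[[2]], ix[[3]]] <-
      pmax(r2p[ix[[1]], ix[[2]], ix[[3]]], w)
  }
  r2p
}

#' Simulate a full multi-echo acquisition of a digital phantom
#'
#' Runs the forward chain: partial-volume rasterization, dipole field,
#' intra-voxel dephasing (R2'), and multi-echo complex signal synthesis
#' with noise.  The result carries the ground truth needed to score
#' detection.
#'
#' @param spec a [phantom_spec()].
#' @param tes echo times in seconds.
#' @return Object of class `qsm_phantom`: a list with `gre`
#'   ([multi_echo_gre()]), `truth`, `chi` (ppm), `field` (ppm), `r2prime`
#'   (1/s), `masks` and the originating `spec`.
#' @export
simulate_phantom <- function(spec, tes = default_tes()) {
  stopifnot(inherits(spec, "phantom_spec"))
  ras <- rasterize_phantom(spec)
  field <- forward_field(ras$chi, spec$grid, pad = 2)
  r2p <- dephase_windows(spec)
  # noise_sigma is expressed relative to the background tissue signal
  gre <- simulate_echoes(ras$m0, ras$r2star + r2p, field, spec$grid,
                         tes = tes,
                         noise_sigma = spec$noise_sigma * spec$background_m0,
                         seed = spec$seed)
  structure(list(gre = gre, truth = ras$truth, chi = ras$chi, field = field,
                 r2prime = r2p, masks = ras$truth$masks, spec = spec),
            class = "qsm_phantom")
}

#' @export
print.qsm_phantom <- function(x, ...) {
  nm <- if (is.null(x$truth$marker_positions)) 0L
        else nrow(x$truth$marker_positions)
  cat(sprintf(
    "qsm_phantom: %s voxels, %d gold marker(s), %d confounder(s), noise sd %g\n",
    paste(x$spec$grid$shape, collapse = "x"), nm,
    length(x$truth$confounders), x$spec$noise_sigma))
  invisible(x)
}
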