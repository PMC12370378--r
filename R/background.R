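#' Background field removal by projection onto the dipole field
#'
#' Fields measured inside the body contain contributions from sources
#' outside the region of interest (air around the patient, distant
#' anatomy).  PDF estimates an exterior susceptibility distribution
#' `chi_out`, supported on the complement of the mask, whose induced field
#' best matches the measured total field inside the mask:
#' `min || W * M * (total_field - D chi_out) ||^2`,
#' solved by conjugate gradients on the normal equations (the dipole
#' operator is self-adjoint).  The fitted dipole field is subtracted,
#' leaving the local field generated by sources inside the mask.
#'
#' The mask is eroded (default 2 voxels) before solving: voxels at the
#' boundary cannot be separated reliably from exterior sources and would
#' ring.
#'
#' @param total_field total field in ppm.
#' @param mask logical body/ROI volume; must be non-empty and must not
#'   cover the whole grid.
#' @param reliability optional per-voxel weights in `[0, 1]` (e.g. from
#'   [fit_complex_field()]); defaults to 1 inside the mask.
#' @param grid a [grid_meta()].
#' @param erode_vox erosion radius in voxels applied to the mask.
#' @param tol relative residual for the conjugate-gradient stop.
#' @param max_iter conjugate-gradient iteration cap.
#' @param pad FFT padding factor for the dipole convolutions.
#' @param damp_rel Tikhonov damping of the exterior-source estimate,
#'   relative to the mean squared fidelity weight (damped-LSQR practice):
#'   exterior susceptibility far from the mask influences the interior
#'   field only weakly, so the undamped normal equations have
#'   near-singular modes that stall conjugate gradients without changing
#'   the fitted background field appreciably.
#' @return List with `local_field` (ppm, masked to the eroded mask),
#'   `background_field` (ppm, whole grid), `mask_eroded`, `n_iter` and
#'   `rel_residual`.
#' @export
pdf_remove <- function(total_field, mask, reliability = NULL, grid,
                       erode_vox = 2L, tol = 1e-3, max_iter = 100L,
                       pad = 1.5, damp_rel = 1e-4) {
  stopifnot(all(is.finite(total_field)), is.logical(mask) || all(mask %in% c(0, 1)))
  mask <- array(mask > 0, dim = dim(total_field))
  if (!any(mask)) stop("mask is empty")
  if (all(mask)) stop("mask covers the whole grid: no background support")
  me <- erode_box(mask, rep(as.integer(erode_vox), 3))
  if (!any(me)) stop("mask vanished after erosion")
  if (is.null(reliability)) reliability <- array(1, dim = dim(mask))
  w <- reliability * me
  support <- !mask

  D <- dipole_operator(grid, dim(total_field), pad = pad)
  damp <- damp_rel * mean(w[w > 0]^2)
  if (!is.finite(damp)) damp <- 0
  apply_normal <- function(x) {
    y <- D(x * support)
    support * D(w^2 * y) + damp * x
  }
  b <- support * D(w^2 * total_field)

  cg <- cg_solve(apply_normal, b, tol = tol, max_iter = max_iter)
  background <- D(cg$x * support)
  local <- (total_field - background) * me
  list(local_field = local, background_field = background,
       mask_eroded = me, n_iter = cg$n_iter, rel_residual = cg$rel_residual)
}

# Binary erosion by a box structuring element (complement of dilation).
erode_box <- function(mask, r) !dilate_box(!mask, r)

# Plain conjugate gradients for a symmetric positive semidefinite operator.
cg_solve <- function(apply_op, b, x0 = NULL, tol = 1e-3, max_iter = 100L) {
  x <- if (is.null(x0)) array(0, dim = dim(b)) else x0
  r <- b - if (is.null(x0)) 0 else apply_op(x)
  p <- r
  rs <- sum(r * r)
  b0 <- sqrt(sum(b * b))
  if (b0 == 0) return(list(x = x, n_iter = 0L, rel_residual = 0))
  it <- 0L
  while (it < max_iter && sqrt(rs) / b0 > tol) {
    Ap <- apply_op(p)
    alpha <- rs / sum(p * Ap)
    if (!is.finite(alpha)) break
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r * r)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
    it <- it + 1L
  }
  list(x = x, n_iter = it, rel_residual = sqrt(rs) / b0)
}
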