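#' Stereotactic frame model
#'
#' Reference geometry of the MR-visible rods embedded in the SBRT
#' immobilization frame, in native frame coordinates.  The frame's native
#' coordinate values are institution-specific hardware configuration; a
#' worked example geometry ships with the package
#' (`system.file("extdata", "frame_example.yaml", package = "qsmfid")`).
#'
#' @param rod_reference_points matrix (>= 3 rows) of rod reference points
#'   (mm) in frame coordinates; must not be collinear.
#' @param description free-text label.
#' @return Object of class `frame_model`.
#' @export
frame_model <- function(rod_reference_points, description = "") {
  pts <- matrix(as.numeric(rod_reference_points), ncol = 3)
  if (nrow(pts) < 3) stop("need at least 3 rod reference points")
  ctr <- sweep(pts, 2, colMeans(pts))
  sv <- svd(ctr)$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop("rod reference points are collinear")
  structure(list(rod_reference_points = pts, description = description),
            class = "frame_model")
}

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 mm vector.
#' @param rms_residual RMS fit residual in mm.
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation, translation, rms_residual = 0) {
  rotation <- matrix(rotation, 3, 3)
  stopifnot(max(abs(crossprod(rotation) - diag(3))) < 1e-6,
            abs(det(rotation) - 1) < 1e-6, rms_residual >= 0)
  structure(list(rotation = rotation,
                 translation = as.numeric(translation),
                 rms_residual = rms_residual),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(pmax((sum(diag(x$rotation)) - 1) / 2, -1), 1)) * 180 / pi
  cat(sprintf(
    "rigid_transform: rotation %.2f deg, translation (%.2f, %.2f, %.2f) mm, rms residual %.3g mm\n",
    ang, x$translation[1], x$translation[2], x$translation[3],
    x$rms_residual))
  invisible(x)
}

#' Detect frame rods in a T2-weighted volume
#'
#' The silicone rods at the bottom of the frame appear bright on
#' T2-weighted images.  Voxels above the intensity percentile within the
#' inferior quarter of the volume (lowest quarter of the second array
#' axis, the posterior/table side in the package convention) are
#' 26-connected-labeled; the `expected_count` largest elongated components
#' (principal axis at least 3x the second axis) are kept and summarized by
#' their centroid, sorted left to right (first world axis).
#'
#' @param t2w intensity volume.
#' @param grid a [grid_meta()].
#' @param intensity_percentile threshold percentile (default 99.5).
#' @param expected_count number of rods (>= 3).
#' @param inferior_axis array axis along which the frame sits in the
#'   lowest quarter (default 2).
#' @param centroid_mode "centroid" (default) or "endpoints" (returns both
#'   rod endpoints projected on the principal axis).
#' @return `expected_count`-by-3 matrix of rod reference points (mm),
#'   sorted by the first coordinate; or a list of endpoint pairs when
#'   `centroid_mode = "endpoints"`.
#' @export
detect_rods <- function(t2w, grid, intensity_percentile = 99.5,
                        expected_count = 3L, inferior_axis = 2L,
                        centroid_mode = c("centroid", "endpoints")) {
  centroid_mode <- match.arg(centroid_mode)
  stopifnot(expected_count >= 3L)
  d <- dim(t2w)
  thr <- stats::quantile(t2w, intensity_percentile / 100, names = FALSE)
  bright <- t2w > thr
  # restrict to the inferior quarter
  n_inf <- max(1L, d[inferior_axis] %/% 4L)
  keep <- array(FALSE, dim = d)
  idx <- lapply(d, seq_len)
  idx[[inferior_axis]] <- seq_len(n_inf)
  keep[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
  bright <- bright & keep
  lbl <- label_components(bright)
  n <- max(lbl)
  if (n == 0L) stop("detect_rods: found 0 qualifying components")
  comps <- vector("list", n)
  elong <- logical(n)
  sizes <- tabulate(lbl[lbl > 0L], n)
  for (k in seq_len(n)) {
    vox <- arrayInd(which(lbl == k), d)
    mm <- voxel_to_world(grid, vox)
    ctr <- sweep(mm, 2, colMeans(mm))
    sv <- svd(ctr)$d / sqrt(max(nrow(mm) - 1, 1))
    elong[k] <- nrow(mm) >= 3 && sv[1] >= 3 * max(sv[2], 1e-9)
    comps[[k]] <- mm
  }
  cand <- which(elong)
  if (length(cand) < expected_count)
    stop(sprintf("detect_rods: found %d elongated component(s), expected %d",
                 length(cand), expected_count))
  if (length(cand) > expected_count) {
    warning(sprintf("detect_rods: %d qualifying components, keeping the %d largest",
                    length(cand), expected_count))
    cand <- cand[order(sizes[cand], decreasing = TRUE)[seq_len(expected_count)]]
  }
  if (centroid_mode == "endpoints") {
    out <- lapply(comps[cand], function(mm) {
      ctr <- colMeans(mm)
      pr <- svd(sweep(mm, 2, ctr))$v[, 1]
      t <- sweep(mm, 2, ctr) %*% pr
      rbind(ctr + min(t) * pr, ctr + max(t) * pr)
    })
    return(out[order(vapply(out, function(e) mean(e[, 1]), 0))])
  }
  pts <- do.call(rbind, lapply(comps[cand], colMeans))
  pts[order(pts[, 1]), , drop = FALSE]
}

#' Least-squares rigid registration of paired points (Kabsch)
#'
#' Finds the rotation and translation minimizing
#' `sum_i || R s_i + t - d_i ||^2` via SVD of the cross-covariance of the
#' centered point sets; a reflection solution is corrected by flipping the
#' smallest singular direction.
#'
#' @param source,target matched n-by-3 point sets (mm), n >= 3,
#'   non-collinear.
#' @return A [rigid_transform()] with the RMS residual of the fit.
#' @export
fit_rigid <- function(source, target) {
  s <- matrix(as.numeric(source), ncol = 3)
  d <- matrix(as.numeric(target), ncol = 3)
  stopifnot(nrow(s) == nrow(d), nrow(s) >= 3)
  cs <- colMeans(s); cd <- colMeans(d)
  s0 <- sweep(s, 2, cs); d0 <- sweep(d, 2, cd)
  if (svd(s0)$d[2] < 1e-9 * max(svd(s0)$d[1], 1))
    stop("source points are collinear")
  H <- crossprod(s0, d0)
  sv <- svd(H)
  f <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% f %*% t(sv$u)
  t <- cd - drop(R %*% cs)
  res <- sweep(s %*% t(R), 2, t, `+`) - d
  rigid_transform(R, t, sqrt(mean(rowSums(res^2))))
}

#' Apply a rigid transform to points
#'
#' Maps MRI-space points into frame coordinates (or any target space of
#' the fitted transform): `R p + t`.
#'
#' @param transform a [rigid_transform()].
#' @param point length-3 vector or n-by-3 matrix (mm).
#' @return Transformed point(s), same shape as the input.
#' @export
map_point <- function(transform, point) {
  vec_in <- !is.matrix(point)
  p <- matrix(as.numeric(point), ncol = 3)
  out <- sweep(p %*% t(transform$rotation), 2, transform$translation, `+`)
  if (vec_in && nrow(out) == 1) drop(out) else out
}

#' Invert a rigid transform
#'
#' @param transform a [rigid_transform()].
#' @return The inverse [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -drop(Rt %*% transform$translation),
                  transform$rms_residual)
}
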