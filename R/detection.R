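#' Detection parameters
#'
#' Tunable settings of the marker-extraction chain.  Defaults follow the
#' reported material susceptibilities: gold -36 +/- 4 ppm, calcification
#' -21 +/- 3 ppm, air +0.024 ppm.  The candidate cut of -28 ppm is the
#' midpoint between the gold and calcification bands; class bands are the
#' nominal values +/- 3 sigma with the boundary at the midpoint.
#'
#' @param search_margin_mm dilation of the prostate mask defining the
#'   search region (markers sit at the gland edge; missed markers in the
#'   clinical cohort were at the very edge of the prostate).
#' @param chi_threshold_ppm histogram cut: voxels at or below this
#'   susceptibility become candidates.
#' @param min_voxels minimum connected-region size (discrete-pixel
#'   removal).
#' @param min_slice_span minimum number of distinct slices a region must
#'   touch; a real marker's susceptibility void spans adjacent slices.
#' @param class_bands named list of `c(lo, hi)` chi intervals (ppm) for
#'   gold, calcification and air; must be disjoint.
#' @param max_markers expected marker count.
#' @param adaptive use the 5th-percentile fallback threshold when the
#'   fixed cut selects nothing.
#' @param centroid_weighting "chi" (|chi|-weighted, default; counters the
#'   asymmetric enlargement of dephasing voids) or "geometric".
#' @return Object of class `detection_params`.
#' @export
detection_params <- function(search_margin_mm = 3,
                             chi_threshold_ppm = -28,
                             min_voxels = 2L,
                             min_slice_span = 2L,
                             class_bands = list(
                               gold = c(-48, -24),
                               calcification = c(-24, -10),
                               air = c(0, Inf)),
                             max_markers = 3L,
                             adaptive = TRUE,
                             centroid_weighting = c("chi", "geometric")) {
  centroid_weighting <- match.arg(centroid_weighting)
  stopifnot(min_voxels >= 1L, min_slice_span >= 1L, max_markers >= 1L)
  bands <- do.call(rbind, class_bands)
  o <- order(bands[, 1])
  if (any(bands[o, 1][-1] < bands[o, 2][-nrow(bands)]))
    stop("class bands must be disjoint")
  structure(list(search_margin_mm = search_margin_mm,
                 chi_threshold_ppm = chi_threshold_ppm,
                 min_voxels = as.integer(min_voxels),
                 min_slice_span = as.integer(min_slice_span),
                 class_bands = class_bands,
                 max_markers = as.integer(max_markers),
                 adaptive = adaptive,
                 centroid_weighting = centroid_weighting),
            class = "detection_params")
}

#' Search region from the prostate mask
#'
#' Dilates the prostate mask by the margin, counted in whole voxels whose
#' centers stay within the margin along each axis
#' (`floor(margin_mm / voxel_size)` per axis), so a 1 mm margin does not
#' recruit neighbors across a 2 mm slice gap.
#'
#' @param prostate_mask logical volume, non-empty.
#' @param margin_mm dilation margin in mm.
#' @param grid a [grid_meta()].
#' @return Logical volume.
#' @export
make_search_mask <- function(prostate_mask, margin_mm, grid) {
  if (!any(prostate_mask)) stop("prostate mask is empty")
  r <- as.integer(floor(margin_mm / grid$voxel_size))
  dilate_box(array(prostate_mask > 0, dim = dim(prostate_mask)), r)
}

#' Candidate voxels by susceptibility threshold
#'
#' Histogram cut: selects voxels inside the search region with chi at or
#' below the threshold.  If the fixed cut selects no voxel and `adaptive`
#' is on, the threshold falls back to
#' `min(chi_threshold_ppm, 5th percentile of chi inside the search mask)`.
#'
#' @param chi a [qsm_chi_map()] or a susceptibility volume in ppm.
#' @param search_mask logical volume.
#' @param params a [detection_params()].
#' @return Logical volume with attribute `threshold_used`.
#' @export
threshold_candidates <- function(chi, search_mask, params = detection_params()) {
  if (inherits(chi, "qsm_chi_map")) chi <- chi$chi
  thr <- params$chi_threshold_ppm
  sel <- search_mask & (chi <= thr)
  mode <- "fixed"
  if (!any(sel) && params$adaptive) {
    thr <- min(params$chi_threshold_ppm,
               stats::quantile(chi[search_mask], 0.05, names = FALSE))
    sel <- search_mask & (chi <= thr)
    mode <- "adaptive"
  }
  structure(sel, threshold_used = thr, threshold_mode = mode)
}

# 26-connected component labeling restricted to TRUE voxels.  Works on the
# candidate voxel list, so cost scales with the number of candidates, not
# the grid.
label_components <- function(bin) {
  d <- dim(bin)
  ids <- which(bin)
  lbl <- array(0L, dim = d)
  if (length(ids) == 0L) return(lbl)
  coords <- arrayInd(ids, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  comp <- integer(length(ids))           # component id per candidate
  cur <- 0L
  for (seed in seq_along(ids)) {
    if (comp[seed] != 0L) next
    cur <- cur + 1L
    frontier <- seed
    comp[seed] <- cur
    while (length(frontier) > 0L) {
      fc <- coords[frontier, , drop = FALSE]
      cand <- fc[rep(seq_len(nrow(fc)), each = nrow(offs)), , drop = FALSE] +
        offs[rep(seq_len(nrow(offs)), nrow(fc)), , drop = FALSE]
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
        cand[, 2] >= 1 & cand[, 2] <= d[2] &
        cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      lin <- cand[, 1] + d[1] * (cand[, 2] - 1L) + d[1] * d[2] * (cand[, 3] - 1L)
      hit <- match(unique(lin), ids)
      hit <- hit[!is.na(hit)]
      hit <- hit[comp[hit] == 0L]
      comp[hit] <- cur
      frontier <- hit
    }
  }
  lbl[ids] <- comp
  lbl
}

#' Remove small connected components
#'
#' Discrete-pixel removal: drops 26-connected components with fewer than
#' `min_voxels` voxels.
#'
#' @param bin logical volume.
#' @param min_voxels minimum component size (1 = identity).
#' @return Logical volume.
#' @export
prune_isolated <- function(bin, min_voxels = 2L) {
  if (min_voxels <= 1L) return(bin & TRUE)
  lbl <- label_components(bin)
  keep <- which(tabulate(lbl[lbl > 0L]) >= min_voxels)
  array(lbl %in% keep, dim = dim(bin))
}

#' Slice-connected region labeling
#'
#' 26-connected 3D labeling; only regions whose extent along the slice
#' axis covers at least `min_slice_span` distinct slices are retained.
#'
#' @param bin logical volume.
#' @param params a [detection_params()].
#' @param slice_axis array axis indexing slices (default 3).
#' @return Integer label volume (labels renumbered 1..n).
#' @export
slice_connected_regions <- function(bin, params = detection_params(),
                                    slice_axis = 3L) {
  lbl <- label_components(bin)
  n <- max(lbl)
  if (n == 0L) return(lbl)
  ids <- which(lbl > 0L)
  sl <- arrayInd(ids, dim(bin))[, slice_axis]
  spans <- vapply(seq_len(n), function(k)
    length(unique(sl[lbl[ids] == k])), integer(1))
  keep <- which(spans >= params$min_slice_span)
  out <- array(0L, dim = dim(bin))
  for (j in seq_along(keep)) out[lbl == keep[j]] <- j
  out
}

#' Summarize and classify candidate regions
#'
#' For each labeled region: the centroid (|chi|-weighted mean of voxel
#' centers in world mm by default), size, slice span, mean and minimum
#' chi; a class label from the susceptibility bands; and a score
#' `|chi_mean - (-36)|` (distance to nominal gold, lower is better).
#' The `max_markers` best-scoring gold regions are the detections
#' (`detected = TRUE`); further gold-band regions keep the label but are
#' flagged `surplus`.
#'
#' @param regions integer label volume from [slice_connected_regions()].
#' @param chi a [qsm_chi_map()] or susceptibility volume (ppm).
#' @param params a [detection_params()].
#' @param grid a [grid_meta()].
#' @return data.frame of class `marker_candidates`, one row per region,
#'   sorted by score.
#' @export
summarize_and_classify <- function(regions, chi, params = detection_params(),
                                   grid) {
  if (inherits(chi, "qsm_chi_map")) chi <- chi$chi
  n <- max(regions)
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    ids <- which(regions == k)
    vox <- arrayInd(ids, dim(regions))
    w <- if (params$centroid_weighting == "chi") {
      ww <- abs(chi[ids]); if (sum(ww) <= 0) rep(1, length(ids)) else ww
    } else rep(1, length(ids))
    cen_vox <- colSums(vox * w) / sum(w)
    cen_mm <- drop(voxel_to_world(grid, matrix(cen_vox, 1)))
    chi_mean <- mean(chi[ids])
    bands <- params$class_bands
    lab <- "unknown"
    for (nm in names(bands)) {
      if (chi_mean >= bands[[nm]][1] && chi_mean <= bands[[nm]][2]) {
        lab <- nm
        break
      }
    }
    rows[[k]] <- data.frame(
      x_mm = cen_mm[1], y_mm = cen_mm[2], z_mm = cen_mm[3],
      vx = cen_vox[1], vy = cen_vox[2], vz = cen_vox[3],
      n_voxels = length(ids),
      slice_span = length(unique(vox[, 3])),
      chi_mean = chi_mean, chi_min = min(chi[ids]),
      label = lab, score = abs(chi_mean - (-36)), region_id = k)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(x_mm = numeric(0), y_mm = numeric(0), z_mm = numeric(0),
                      vx = numeric(0), vy = numeric(0), vz = numeric(0),
                      n_voxels = integer(0), slice_span = integer(0),
                      chi_mean = numeric(0), chi_min = numeric(0),
                      label = character(0), score = numeric(0),
                      region_id = integer(0))
  }
  out <- out[order(out$score), , drop = FALSE]
  rownames(out) <- NULL
  gold <- which(out$label == "gold")
  out$detected <- logical(nrow(out))
  out$surplus <- logical(nrow(out))
  if (length(gold) > 0) {
    det <- gold[seq_len(min(length(gold), params$max_markers))]
    out$detected[det] <- TRUE
    out$surplus[setdiff(gold, det)] <- TRUE
  }
  class(out) <- c("marker_candidates", class(out))
  out
}

#' Detect gold fiducial markers
#'
#' Runs the full chain on raw multi-echo data (field fit, Laplacian
#' unwrapping, background removal, dipole inversion, candidate extraction)
#' or the detection steps alone when given a susceptibility map.
#' Deterministic given its inputs.
#'
#' @param x a [multi_echo_gre()], a `qsm_phantom`, or a [qsm_chi_map()].
#' @param masks list with logical volumes `body` and `prostate` (taken
#'   from the phantom automatically for a `qsm_phantom` input).
#' @param params a [detection_params()].
#' @param inversion "medi0" (default) or "tkd".
#' @param marker_radius_mm nominal physical radius of the implanted
#'   marker (mm); sets the volume convention by which void dipole moments
#'   are expressed as susceptibilities (see [inpaint_void_fields()]).
#' @param grid required when `x` is a plain chi volume.
#' @param keep_volumes retain the intermediate volumes (field map, local
#'   field, chi map) in the result.
#' @param pdf_max_iter,medi_outer,medi_inner,solver_pad iteration caps
#'   and FFT padding used by the pipeline's solvers; the defaults trade a
#'   few percent of residual for a roughly threefold speedup relative to
#'   the solver-level defaults and leave phantom detection metrics
#'   unchanged.
#' @return Object of class `qsm_detection`: candidate table plus stage
#'   diagnostics.
#' @export
detect_markers <- function(x, masks = NULL, params = detection_params(),
                           inversion = c("medi0", "tkd"),
                           marker_radius_mm = 3.0, grid = NULL,
                           keep_volumes = FALSE,
                           pdf_max_iter = 30L, medi_outer = 10L,
                           medi_inner = 8L, solver_pad = 1.4) {
  inversion <- match.arg(inversion)
  diag <- list()
  if (inherits(x, "qsm_phantom")) {
    masks <- list(body = x$masks$body, prostate = x$masks$prostate)
    x <- x$gre
  }
  if (inherits(x, "multi_echo_gre")) {
    stopifnot(!is.null(masks$body), !is.null(masks$prostate))
    grid <- x$grid
    init <- temporal_field_init(x)
    fm <- fit_complex_field(x, init, mask = masks$body)
    f_hz <- unwrap_field(fm, grid)
    field0 <- f_hz / hz_per_ppm(grid)
    bg <- pdf_remove(field0, masks$body, fm$reliability, grid,
                     max_iter = pdf_max_iter, pad = solver_pad)
    # characterize every signal void by its equivalent point dipole,
    # fitted on the reliable shell around it; the hard core (no usable
    # first-echo signal) is inpainted with the equivalent-sphere field
    a1 <- Mod(x$signal[, , , 1])
    vp <- inpaint_void_fields(bg$local_field, a1, fm$reliability,
                              bg$mask_eroded, grid, void_frac = 0.15,
                              shell_mm = c(2, 8),
                              model_radius_mm = marker_radius_mm)
    # first-echo rescue of the dispersion-biased rim: the void dipole
    # model plus the estimated background provides the wrap-branch
    # reference for the (total-field) first-echo phase
    ref_total_hz <- (vp$model_field + bg$background_field) *
      hz_per_ppm(grid)
    rs <- rescue_dephased_field(x, fm, ref_total_hz, grid, masks$body)
    local_hz <- vp$field * hz_per_ppm(grid)
    fix <- rs$rescued & !vp$fill_mask & bg$mask_eroded
    local_hz[fix] <- rs$field_hz[fix] -
      bg$background_field[fix] * hz_per_ppm(grid)
    local_field <- local_hz / hz_per_ppm(grid)
    chi_map <- if (inversion == "medi0") {
      med_a <- stats::median(fm$amplitude[bg$mask_eroded &
                                            fm$amplitude > 0])
      w_fid <- pmin(fm$amplitude / med_a, 2) * fm$reliability
      w_fid[fix] <- pmax(w_fid[fix], rs$weights[fix])
      w_fid[vp$fill_mask] <- vp$weights[vp$fill_mask]
      invert_medi0(local_field, fm$amplitude, bg$mask_eroded,
                   reference_mask = NULL, grid,
                   exclude_mask = masks$prostate,
                   fidelity_weights = w_fid,
                   outer_iter = medi_outer, inner_iter = medi_inner,
                   pad = solver_pad)
    } else {
      invert_tkd(local_field, bg$mask_eroded, grid, pad = solver_pad)
    }
    diag <- list(fieldmap = if (keep_volumes) fm else NULL,
                 n_rescued = sum(fix),
                 pdf_iters = bg$n_iter, pdf_residual = bg$rel_residual,
                 voids = vp$voids,
                 inversion_converged = chi_map$converged)
    if (keep_volumes) diag$local_field <- local_field
  } else if (inherits(x, "qsm_chi_map")) {
    chi_map <- x
    stopifnot(!is.null(masks$prostate))
    if (is.null(grid)) grid <- attr(x, "grid")
    stopifnot(!is.null(grid))
  } else stop("x must be a multi_echo_gre, qsm_phantom or qsm_chi_map")

  search <- make_search_mask(masks$prostate, params$search_margin_mm, grid)
  regions <- array(0L, dim = dim(chi_map$chi))
  if (any(search)) {
    sel <- threshold_candidates(chi_map, search, params)
    diag$threshold_used <- attr(sel, "threshold_used")
    diag$threshold_mode <- attr(sel, "threshold_mode")
    sel <- prune_isolated(sel, params$min_voxels)
    regions <- slice_connected_regions(sel, params)
  }
  cands <- summarize_and_classify(regions, chi_map, params, grid)
  structure(list(candidates = cands, params = params, diagnostics = diag,
                 grid = grid, regions = regions,
                 chi_map = if (keep_volumes) chi_map else NULL),
            class = "qsm_detection")
}

#' @export
print.qsm_detection <- function(x, ...) {
  cc <- x$candidates
  cat(sprintf("qsm_detection: %d candidate region(s), %d gold detection(s)\n",
              nrow(cc), sum(cc$detected)))
  if (nrow(cc) > 0) {
    show <- cc[, c("x_mm", "y_mm", "z_mm", "n_voxels", "slice_span",
                   "chi_mean", "label", "detected")]
    show[, 1:3] <- round(show[, 1:3], 2)
    show$chi_mean <- round(show$chi_mean, 1)
    print.data.frame(show)
  }
  invisible(x)
}

#' @export
summary.qsm_detection <- function(object, ...) {
  cc <- object$candidates
  cat("Candidate regions by label:\n")
  print(table(cc$label))
  det <- cc[cc$detected, , drop = FALSE]
  if (nrow(det) > 0) {
    cat(sprintf("\nDetections: %d, chi_mean %.1f to %.1f ppm\n",
                nrow(det), min(det$chi_mean), max(det$chi_mean)))
  }
  if (!is.null(object$diagnostics$threshold_used))
    cat(sprintf("Threshold used: %.1f ppm (%s)\n",
                object$diagnostics$threshold_used,
                object$diagnostics$threshold_mode))
  invisible(object)
}
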