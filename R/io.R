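#' Write an acquisition sidecar
#'
#' JSON sidecar carrying the acquisition metadata that NIfTI headers do
#' not: echo times, field strength and the B0 axis.  Axis indices are
#' stored 0-based for interoperability.
#'
#' @param grid a [grid_meta()].
#' @param tes echo times in seconds.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sidecar <- function(grid, tes, path) {
  jsonlite::write_json(list(
    tes_s = tes, b0_T = grid$b0, b0_axis = grid$b0_axis - 1L,
    voxel_size_mm = grid$voxel_size, origin_mm = grid$origin,
    gamma_bar_MHz_T = grid$gamma_bar),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read an acquisition sidecar
#'
#' @param path sidecar JSON file.
#' @param shape grid shape (voxels) of the referenced volumes.
#' @return List with `grid` (a [grid_meta()]) and `tes`.
#' @export
read_sidecar <- function(path, shape) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- grid_meta(shape, s$voxel_size_mm, s$origin_mm,
                    b0_axis = s$b0_axis + 1L, b0 = s$b0_T,
                    gamma_bar = if (!is.null(s$gamma_bar_MHz_T))
                      s$gamma_bar_MHz_T else 42.577)
  list(grid = grid, tes = as.numeric(s$tes_s))
}

# NIfTI volume with the package's world convention:
# world = origin + 0-based index * voxel_size.
as_nifti_vol <- function(vol, grid) {
  aff <- diag(4)
  aff[1, 1] <- grid$voxel_size[1]
  aff[2, 2] <- grid$voxel_size[2]
  aff[3, 3] <- grid$voxel_size[3]
  aff[1:3, 4] <- grid$origin
  img <- RNifti::asNifti(vol + 0)
  img <- RNifti::`pixdim<-`(img, grid$voxel_size)
  RNifti::`sform<-`(img, structure(aff, code = 2L))
}

write_nifti_vol <- function(vol, grid, path) {
  RNifti::writeNifti(as_nifti_vol(vol, grid), path)
  invisible(path)
}

# Grid geometry from a NIfTI header (sform); b0/gamma come from the
# sidecar, not the header.
grid_from_nifti <- function(img) {
  aff <- RNifti::xform(img)
  vx <- sqrt(colSums(aff[1:3, 1:3]^2))
  grid_meta(dim(img), vx, aff[1:3, 4])
}

#' Write a simulated phantom acquisition to NIfTI + sidecars
#'
#' Writes per-echo magnitude (`mag_e{j}.nii.gz`) and phase
#' (`phs_e{j}.nii.gz`) volumes, body and prostate masks, the acquisition
#' sidecar `acq.json` and the ground truth `truth.json` (marker and
#' confounder positions in world mm; voxel indices 0-based).
#'
#' @param phantom a `qsm_phantom` from [simulate_phantom()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- phantom$gre$grid
  mag <- gre_magnitude(phantom$gre)
  phs <- gre_phase(phantom$gre)
  for (j in seq_along(phantom$gre$tes)) {
    write_nifti_vol(mag[, , , j], grid,
                    file.path(dir, sprintf("mag_e%d.nii.gz", j)))
    write_nifti_vol(phs[, , , j], grid,
                    file.path(dir, sprintf("phs_e%d.nii.gz", j)))
  }
  write_nifti_vol(phantom$masks$body * 1, grid, file.path(dir, "body.nii.gz"))
  write_nifti_vol(phantom$masks$prostate * 1, grid,
                  file.path(dir, "prostate.nii.gz"))
  write_sidecar(grid, phantom$gre$tes, file.path(dir, "acq.json"))
  tr <- phantom$truth
  jsonlite::write_json(list(
    marker_positions_mm = tr$marker_positions,
    marker_positions_voxel0 = world_to_voxel(grid, tr$marker_positions) - 1,
    confounders = lapply(tr$confounders, function(cf)
      list(label = cf$label, position_mm = cf$position))),
    file.path(dir, "truth.json"), auto_unbox = FALSE, digits = NA)
  invisible(dir)
}

#' Assemble multi-echo complex data from NIfTI volumes
#'
#' Reads paired per-echo magnitude and phase volumes plus the acquisition
#' sidecar and assembles the complex multi-echo container.  All volumes
#' must share one grid (voxel size within 1e-3 mm); the echo count must
#' match the sidecar.  Phase stored in the `(0, 2*pi]` convention is
#' normalized to `(-pi, pi]`; integer-scaled phase is handled by the NIfTI
#' scale slope, anything else out of range is an error.
#'
#' @param dir directory containing `mag_e*.nii.gz` / `phs_e*.nii.gz` and
#'   `acq.json`, or a list `list(magnitude = files, phase = files)`.
#' @param sidecar path to the sidecar (defaults to `acq.json` in `dir`).
#' @return A [multi_echo_gre()].
#' @export
read_multiecho <- function(dir, sidecar = NULL) {
  if (is.character(dir)) {
    mag_files <- sort(list.files(dir, "^mag_e[0-9]+\\.nii(\\.gz)?$",
                                 full.names = TRUE))
    phs_files <- sort(list.files(dir, "^phs_e[0-9]+\\.nii(\\.gz)?$",
                                 full.names = TRUE))
    if (is.null(sidecar)) sidecar <- file.path(dir, "acq.json")
  } else {
    mag_files <- dir$magnitude
    phs_files <- dir$phase
    if (is.null(sidecar)) stop("sidecar required with explicit file lists")
  }
  if (length(mag_files) == 0) stop("no magnitude volumes found")
  if (length(mag_files) != length(phs_files))
    stop(sprintf("echo count mismatch: %d magnitude vs %d phase volumes",
                 length(mag_files), length(phs_files)))
  imgs_m <- lapply(mag_files, RNifti::readNifti)
  imgs_p <- lapply(phs_files, RNifti::readNifti)
  ref_dim <- dim(imgs_m[[1]])
  ref_vx <- RNifti::pixdim(imgs_m[[1]])
  for (k in seq_along(imgs_m)) {
    for (img in list(imgs_m[[k]], imgs_p[[k]])) {
      if (!all(dim(img) == ref_dim))
        stop("grid mismatch in ",
             c(mag_files[k], phs_files[k])[which(!vapply(
               list(imgs_m[[k]], imgs_p[[k]]),
               function(i) all(dim(i) == ref_dim), TRUE))[1]])
      if (max(abs(RNifti::pixdim(img) - ref_vx)) > 1e-3)
        stop("voxel size mismatch across echoes")
    }
  }
  meta <- read_sidecar(sidecar, ref_dim)
  if (length(meta$tes) != length(mag_files))
    stop(sprintf("sidecar lists %d echoes but %d volumes found",
                 length(meta$tes), length(mag_files)))
  if (max(abs(meta$grid$voxel_size - ref_vx)) > 1e-3)
    stop("sidecar voxel size disagrees with NIfTI headers")
  shp <- meta$grid$shape
  sig <- array(0i, dim = c(shp, length(mag_files)))
  for (j in seq_along(mag_files)) {
    ph <- as.array(imgs_p[[j]])
    mx <- max(ph); mn <- min(ph)
    if (mx > pi + 1e-6) {
      if (mn >= -1e-6 && mx <= 2 * pi + 1e-6) {
        ph <- wrap_phase(ph)          # (0, 2*pi] convention
      } else {
        stop("phase volume ", phs_files[j], " is not in radians")
      }
    }
    sig[, , , j] <- as.array(imgs_m[[j]]) * exp(1i * ph)
  }
  multi_echo_gre(sig, meta$tes, meta$grid)
}

#' Write a marker report
#'
#' Writes the candidate table as CSV and JSON and, when the detection
#' carries its label volume, a labeled NIfTI mask (label `i` = candidate
#' row `i`).  Number formatting is fixed so identical inputs produce
#' byte-identical CSV files.
#'
#' @param detection a `qsm_detection` (or a `marker_candidates` table).
#' @param grid a [grid_meta()] (taken from the detection if omitted).
#' @param dir output directory.
#' @param prefix file name prefix (default "markers").
#' @return Named list of the files written, invisibly.
#' @export
write_markers <- function(detection, grid = NULL, dir = ".",
                          prefix = "markers") {
  if (inherits(detection, "qsm_detection")) {
    cands <- detection$candidates
    if (is.null(grid)) grid <- detection$grid
    regions <- detection$regions
  } else {
    cands <- detection
    regions <- NULL
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv_path <- file.path(dir, paste0(prefix, ".csv"))
  json_path <- file.path(dir, paste0(prefix, ".json"))
  fmt <- cands
  for (col in c("x_mm", "y_mm", "z_mm", "vx", "vy", "vz",
                "chi_mean", "chi_min", "score"))
    fmt[[col]] <- sprintf("%.6f", cands[[col]])
  utils::write.csv(fmt, csv_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(cands, json_path, dataframe = "rows", digits = NA)
  files <- list(csv = csv_path, json = json_path)
  if (!is.null(regions) && !is.null(grid) && nrow(cands) > 0) {
    lab <- array(0L, dim = dim(regions))
    for (i in seq_len(nrow(cands)))
      lab[regions == cands$region_id[i]] <- i
    nii_path <- file.path(dir, paste0(prefix, "_labels.nii.gz"))
    write_nifti_vol(lab, grid, nii_path)
    files$labels <- nii_path
  }
  invisible(files)
}

#' Read a mask volume
#'
#' @param path NIfTI file.
#' @return List with `mask` (logical volume) and `grid`.
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  list(mask = as.array(img) > 0.5, grid = grid_from_nifti(img))
}
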