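#' Plot a susceptibility map slice
#'
#' Grayscale axial slice of the susceptibility volume with a symmetric
#' intensity window.
#'
#' @param x a [qsm_chi_map()].
#' @param slice slice index along the third axis (default: middle).
#' @param zlim intensity window in ppm.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.qsm_chi_map <- function(x, slice = NULL,
                             zlim = c(-40, 10), ...) {
  d <- dim(x$chi)
  if (is.null(slice)) slice <- ceiling(d[3] / 2)
  sl <- x$chi[, , slice]
  sl[sl < zlim[1]] <- zlim[1]
  sl[sl > zlim[2]] <- zlim[2]
  graphics::image(seq_len(d[1]), seq_len(d[2]), sl, zlim = zlim,
                  col = grDevices::gray.colors(128), asp = 1,
                  xlab = "voxel x", ylab = "voxel y",
                  main = sprintf("chi (%s), slice %d", x$method, slice),
                  ...)
  invisible(x)
}

#' Plot detected marker candidates
#'
#' Axial scatter of candidate centroids (voxel coordinates), sized by
#' region volume, with gold detections filled and other labels hollow;
#' the slice index is annotated at each point.
#'
#' @param x a `qsm_detection`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.qsm_detection <- function(x, ...) {
  cc <- x$candidates
  if (nrow(cc) == 0) {
    graphics::plot(0, 0, type = "n", xlab = "x (mm)", ylab = "y (mm)",
                   main = "no candidate regions", ...)
    return(invisible(x))
  }
  pch <- ifelse(cc$detected, 19, ifelse(cc$label == "gold", 1, 4))
  cex <- 0.8 + 1.5 * sqrt(cc$n_voxels / max(cc$n_voxels))
  graphics::plot(cc$x_mm, cc$y_mm, pch = pch, cex = cex,
                 xlab = "x (mm)", ylab = "y (mm)",
                 main = sprintf("%d candidate(s), %d detection(s)",
                                nrow(cc), sum(cc$detected)), ...)
  graphics::text(cc$x_mm, cc$y_mm,
                 labels = sprintf("z=%.0f", cc$z_mm), pos = 3,
                 cex = 0.7)
  invisible(x)
}
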