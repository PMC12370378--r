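#' Score detected marker positions against reference positions
#'
#' One-to-one optimal assignment (Hungarian algorithm) minimizing total
#' Euclidean distance, restricted to pairs within the gate.  The detection
#' rate is the number of matches divided by the number of reference
#' markers, and displacement statistics are computed on matched pairs
#' only, mirroring the convention of scoring localization accuracy over
#' successfully detected markers.
#'
#' @param detected n-by-3 matrix of detected positions (mm); `NULL` or
#'   zero rows allowed.
#' @param truth m-by-3 matrix of reference positions (mm).
#' @param gate_mm maximum distance for a valid match (default 5 mm, about
#'   twice the clinically reported mean displacement).
#' @return Object of class `eval_report` with counts, `detection_rate`,
#'   per-pair `displacements_mm`, `mean_displacement_mm`, and the indices
#'   of false positives/negatives.
#' @export
match_markers <- function(detected, truth, gate_mm = 5) {
  stopifnot(gate_mm > 0)
  detected <- if (is.null(detected)) matrix(numeric(0), 0, 3) else
    matrix(as.numeric(detected), ncol = 3)
  truth <- if (is.null(truth)) matrix(numeric(0), 0, 3) else
    matrix(as.numeric(truth), ncol = 3)
  nd <- nrow(detected); nt <- nrow(truth)
  if (nd > 0 && nt > 0) {
    D <- outer(seq_len(nd), seq_len(nt), Vectorize(function(i, j)
      sqrt(sum((detected[i, ] - truth[j, ])^2))))
    # forbid out-of-gate pairs with a large finite cost, then drop them
    BIG <- max(D) + gate_mm + 1e6
    C <- ifelse(D <= gate_mm, D, BIG)
    asg <- solve_assignment(C)
    ok <- which(asg > 0 & C[cbind(seq_len(nd), pmax(asg, 1))] < BIG)
    pairs <- cbind(det = ok, truth = asg[ok])
  } else {
    pairs <- cbind(det = integer(0), truth = integer(0))
  }
  disp <- if (nrow(pairs) > 0)
    sqrt(rowSums((detected[pairs[, 1], , drop = FALSE] -
                    truth[pairs[, 2], , drop = FALSE])^2)) else numeric(0)
  structure(list(
    n_truth = nt, n_detected = nd, n_matched = nrow(pairs),
    detection_rate = if (nt > 0) nrow(pairs) / nt else NA_real_,
    displacements_mm = disp,
    mean_displacement_mm = if (length(disp) > 0) mean(disp) else NA_real_,
    matched_pairs = pairs,
    false_positives = setdiff(seq_len(nd), pairs[, 1]),
    false_negatives = setdiff(seq_len(nt), pairs[, 2])),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "eval_report: %d/%d matched (rate %.3f), mean displacement %s mm, %d FP, %d FN\n",
    x$n_matched, x$n_truth, x$detection_rate,
    if (is.na(x$mean_displacement_mm)) "NA" else
      sprintf("%.2f", x$mean_displacement_mm),
    length(x$false_positives), length(x$false_negatives)))
  invisible(x)
}

# Hungarian algorithm (Jonker-Volgenant style shortest augmenting paths)
# for the rectangular assignment problem; returns, for each row, the
# assigned column (0 = unassigned).  Cost matrix rows <= columns is not
# required; the matrix is transposed internally when needed.
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  transposed <- FALSE
  if (n > m) { cost <- t(cost); transposed <- TRUE; tmp <- n; n <- m; m <- tmp }
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1)        # p[j]: row assigned to column j (0 = none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[m + 1] <- i
    j0 <- m + 1L
    minv <- rep(INF, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(m + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == m + 1L) break
    }
  }
  row_of_col <- p[seq_len(m)]
  asg <- integer(n)
  for (j in seq_len(m)) if (row_of_col[j] > 0) asg[row_of_col[j]] <- j
  if (transposed) {
    out <- integer(ncol(cost))   # original rows = current columns
    for (i in seq_len(n)) if (asg[i] > 0) out[asg[i]] <- i
    out
  } else asg
}

#' Signed mean voxelwise difference
#'
#' Mean over the mask of `a - b`; positive and negative deviations cancel,
#' unlike the mean absolute error.
#'
#' @param img_a,img_b numeric volumes of identical dimension.
#' @param mask logical volume; defaults to everything.
#' @return List with `me` and `sd`.
#' @export
mean_error <- function(img_a, img_b, mask = NULL) {
  d <- img_a - img_b
  if (!is.null(mask)) d <- d[mask]
  list(me = mean(d), sd = stats::sd(d))
}

#' Mean absolute voxelwise difference
#'
#' @inheritParams mean_error
#' @return Scalar MAE.
#' @export
mean_absolute_error <- function(img_a, img_b, mask = NULL) {
  d <- abs(img_a - img_b)
  if (!is.null(mask)) d <- d[mask]
  mean(d)
}

#' Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)`; two empty masks count as perfectly
#' overlapping (1.0, with a message).
#'
#' @param mask_a,mask_b logical volumes of identical dimension.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  a <- sum(mask_a > 0); b <- sum(mask_b > 0)
  if (a + b == 0) {
    message("dice: both masks empty; returning 1")
    return(1.0)
  }
  2 * sum((mask_a > 0) & (mask_b > 0)) / (a + b)
}
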