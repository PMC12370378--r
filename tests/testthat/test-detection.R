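test_that("search mask dilation follows the per-axis voxel arithmetic", {
  g <- grid_meta(c(7, 7, 5), c(1, 1, 2))
  m <- array(FALSE, g$shape); m[4, 4, 3] <- TRUE
  # margin 0: identity
  expect_equal(make_search_mask(m, 0, g), m)
  # 1 mm margin with 1x1x2 mm voxels: 3x3x1 neighborhood
  d1 <- make_search_mask(m, 1, g)
  expect_equal(sum(d1), 9)
  expect_true(all(which(d1, arr.ind = TRUE)[, 3] == 3))
  # 3 mm margin: 7x7x3
  d3 <- make_search_mask(m, 3, g)
  expect_equal(sum(d3), 7 * 7 * 3)
  # dilation is monotone
  expect_true(all(d1[m]))
  expect_true(all(d3[d1]))
  expect_error(make_search_mask(array(FALSE, g$shape), 3, g), "empty")
})

test_that("threshold selects by the histogram cut", {
  g <- grid_meta(c(5, 5, 3), c(1, 1, 2))
  chi <- array(0, g$shape)
  chi[2, 2, 2] <- -36; chi[4, 4, 2] <- -21
  search <- array(TRUE, g$shape)
  sel <- threshold_candidates(chi, search, detection_params())
  expect_true(sel[2, 2, 2])     # gold-range voxel selected
  expect_false(sel[4, 4, 2])    # calcification-range voxel rejected
  expect_equal(attr(sel, "threshold_mode"), "fixed")
  # uniform zero map: nothing below the cut even with the fallback
  sel0 <- threshold_candidates(array(0, g$shape), search,
                               detection_params())
  expect_equal(sum(sel0), 0)
  # two-delta map at -30/-25: exactly the -30 voxel
  chi2 <- array(0, g$shape); chi2[1, 1, 1] <- -30; chi2[5, 5, 3] <- -25
  sel2 <- threshold_candidates(chi2, search, detection_params())
  expect_equal(which(sel2), which(chi2 == -30))
  # lowering the threshold never grows the selection
  p_lo <- detection_params(chi_threshold_ppm = -32, adaptive = FALSE)
  sel_lo <- threshold_candidates(chi, search, p_lo)
  expect_true(all(which(sel_lo) %in% which(sel)))
})

test_that("pruning removes discrete pixels but keeps pairs", {
  bin <- array(FALSE, c(6, 6, 4))
  bin[2, 2, 2] <- TRUE                       # isolated voxel
  bin[5, 5, 2] <- TRUE; bin[5, 6, 2] <- TRUE # adjacent pair
  out <- prune_isolated(bin, 2)
  expect_false(out[2, 2, 2])
  expect_true(out[5, 5, 2] && out[5, 6, 2])
  expect_equal(prune_isolated(bin, 1), bin)
})

test_that("slice-connected filtering uses 26-connectivity and slice span", {
  bin <- array(FALSE, c(6, 6, 6))
  bin[2, 2, 3] <- TRUE; bin[2, 3, 3] <- TRUE   # single-slice region
  reg <- slice_connected_regions(bin, detection_params())
  expect_equal(max(reg), 0)
  bin[2, 2, 4] <- TRUE                          # now spans slices 3-4
  reg2 <- slice_connected_regions(bin, detection_params())
  expect_equal(max(reg2), 1)
  # diagonal contact across slices merges under 26-connectivity
  bin2 <- array(FALSE, c(6, 6, 6))
  bin2[2, 2, 2] <- TRUE; bin2[3, 3, 3] <- TRUE
  expect_equal(max(qsmfid:::label_components(bin2)), 1)
})

test_that("classification follows the susceptibility bands", {
  g <- grid_meta(c(8, 8, 6), c(1, 1, 2))
  chi <- array(0, g$shape)
  reg <- array(0L, g$shape)
  chi[2, 2, 2:3] <- -36; reg[2, 2, 2:3] <- 1L
  chi[6, 6, 2:3] <- -21; reg[6, 6, 2:3] <- 2L
  cands <- summarize_and_classify(reg, chi, detection_params(), g)
  expect_equal(cands$label[order(cands$chi_mean)], c("gold", "calcification"))
  expect_equal(sum(cands$detected), 1)
  # equal-weight two-voxel region: centroid at the midpoint
  got <- cands[cands$label == "gold", ]
  mid <- colMeans(voxel_to_world(g, rbind(c(2, 2, 2), c(2, 2, 3))))
  expect_equal(unlist(got[c("x_mm", "y_mm", "z_mm")]), mid,
               ignore_attr = TRUE)
})

test_that("full pipeline finds the phantom markers without false positives", {
  ph <- simulate_phantom(default_phantom(compact = TRUE,
                                         noise_sigma = 0.01, seed = 42))
  det <- suppressWarnings(detect_markers(ph))
  cc <- det$candidates
  expect_equal(sum(cc$detected), 3)
  expect_true(all(cc$label[cc$detected] == "gold"))
  expect_equal(sum(cc$label == "gold" & !cc$detected), 0)
  rep <- match_markers(as.matrix(cc[cc$detected,
                                    c("x_mm", "y_mm", "z_mm")]),
                       ph$truth$marker_positions)
  expect_equal(rep$detection_rate, 1.0)
  expect_lt(rep$mean_displacement_mm, 1.5)
  # confounders never carry the gold label
  conf <- do.call(rbind, lapply(ph$truth$confounders, `[[`, "position"))
  gold_pts <- as.matrix(cc[cc$label == "gold", c("x_mm", "y_mm", "z_mm")])
  if (nrow(gold_pts) > 0) {
    dmin <- apply(conf, 1, function(p)
      min(sqrt(rowSums(sweep(gold_pts, 2, p)^2))))
    expect_true(all(dmin > 5))
  }
  # every centroid lies inside the dilated search mask
  search <- make_search_mask(ph$masks$prostate, 3, det$grid)
  vox <- round(world_to_voxel(det$grid,
                              as.matrix(cc[, c("x_mm", "y_mm", "z_mm")])))
  for (r in seq_len(nrow(vox)))
    expect_true(search[vox[r, 1], vox[r, 2], vox[r, 3]])
  # the noiseless phantom produces the same detections
  ph0 <- simulate_phantom(default_phantom(compact = TRUE, noise_sigma = 0,
                                          seed = 42))
  det0 <- suppressWarnings(detect_markers(ph0))
  rep0 <- match_markers(
    as.matrix(det0$candidates[det0$candidates$detected,
                              c("x_mm", "y_mm", "z_mm")]),
    ph$truth$marker_positions)
  expect_equal(rep0$n_matched, rep$n_matched)
})

test_that("detection from a chi map alone applies the extraction steps", {
  g <- grid_meta(c(24, 24, 10), c(1, 1, 2), -(c(24, 24, 10) - 1) / 2 *
                   c(1, 1, 2))
  chi <- array(0, g$shape)
  chi[12:13, 12, 5:6] <- -35
  pros <- array(FALSE, g$shape); pros[8:17, 8:17, 3:8] <- TRUE
  cm <- qsm_chi_map(chi, array(TRUE, g$shape), "tkd")
  det <- detect_markers(cm, masks = list(prostate = pros), grid = g)
  expect_equal(sum(det$candidates$detected), 1)
  expect_equal(det$candidates$label[1], "gold")
  # empty search region: empty candidate list
  pros0 <- array(FALSE, g$shape); pros0[2, 2, 2] <- TRUE
  det0 <- detect_markers(cm, masks = list(prostate = pros0), grid = g,
                         params = detection_params(search_margin_mm = 0))
  expect_equal(nrow(det0$candidates), 0)
})

test_that("candidate extraction ignores inclusion listing order", {
  spec_a <- default_phantom(compact = TRUE, noise_sigma = 0)
  spec_b <- spec_a
  spec_b$inclusions <- rev(spec_b$inclusions)
  ras_a <- rasterize_phantom(spec_a)
  ras_b <- rasterize_phantom(spec_b)
  expect_equal(ras_a$chi, ras_b$chi, tolerance = 1e-12)
  g <- spec_a$grid
  fld <- forward_field(ras_a$chi, g)
  cm <- qsm_chi_map(invert_tkd(fld, ras_a$truth$masks$body, g)$chi,
                    ras_a$truth$masks$body, "tkd")
  det_a <- detect_markers(cm, masks = list(prostate = ras_a$truth$masks$prostate),
                          grid = g)
  det_b <- detect_markers(cm, masks = list(prostate = ras_b$truth$masks$prostate),
                          grid = g)
  expect_equal(det_a$candidates, det_b$candidates)
})
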