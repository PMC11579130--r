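# Overlap metrics, surface distances, thickness, anchors, rank-sum test.

test_that("overlap metrics are exact on hand-counted cases", {
  # identity: every present class scores 1 everywhere
  ph <- generate_phantom(test_phantom_cfg(3))
  om <- overlap_metrics(ph$truth, ph$truth)
  expect_true(all(om$iou == 1 & om$dsc == 1 & om$recall == 1 &
                    om$precision == 1))

  # disjoint 10-pixel regions: IoU 0, smoothed DSC 1/21, recall 0, precision 0
  a <- matrix(0L, 6, 10); a[1, 1:10] <- 1L
  b <- matrix(0L, 6, 10); b[3, 1:10] <- 1L
  om2 <- overlap_metrics(layer_mask(a, 1), layer_mask(b, 1),
                         metrics_config(n_classes = 1L))
  expect_equal(om2$iou, 0)
  expect_equal(om2$dsc, 1 / 21)
  expect_equal(om2$recall, 0)
  expect_equal(om2$precision, 0)

  # prediction = truth plus 4 false positives on a 4-pixel true region
  y <- matrix(0L, 4, 4); y[1, 1:4] <- 2L
  p <- y; p[2, 1:4] <- 2L
  om3 <- overlap_metrics(layer_mask(y, 1), layer_mask(p, 1))
  r3 <- om3[om3$class == 2L, ]
  expect_equal(r3$iou, 0.5)
  expect_equal(r3$recall, 1.0)
  expect_equal(r3$precision, 0.5)
  expect_equal(r3$dsc, 9 / 13)

  # a class absent from both masks is flagged, not divided by zero
  expect_equal(om3$status[om3$class == 5L], "absent")
  expect_true(is.na(om3$iou[om3$class == 5L]))
  expect_equal(attr(om3, "means")$iou, 0.5)  # only class 2 is present in y
})

test_that("unsmoothed DSC equals 2*IoU/(1+IoU) exactly, and the smoothed gap vanishes", {
  set.seed(11)
  for (i in 1:5) {
    y <- layer_mask(matrix(sample(0:6, 30 * 30, TRUE), 30, 30), 1)
    p <- layer_mask(matrix(sample(0:6, 30 * 30, TRUE), 30, 30), 1)
    om <- overlap_metrics(y, p, metrics_config(smoothing = FALSE))
    ok <- om$status == "present"
    expect_equal(om$dsc[ok], 2 * om$iou[ok] / (1 + om$iou[ok]))
    oms <- overlap_metrics(y, p, metrics_config(smoothing = TRUE))
    gap <- abs(oms$dsc[ok] - om$dsc[ok])
    expect_true(all(gap < 1 / (om$n_truth[ok] + om$n_pred[ok] + 1)))
  }
})

test_that("boundary extraction matches neighbour enumeration", {
  # a single-pixel region is its own boundary
  m <- matrix(0L, 5, 5); m[3, 3] <- 1L
  bp <- boundary_points(layer_mask(m, 1), 1L)
  expect_equal(unname(bp$points), matrix(c(3L, 3L), 1))

  # a filled 3x3 square: the 8 perimeter pixels, centre excluded
  sq <- matrix(0L, 7, 7); sq[3:5, 3:5] <- 2L
  bp2 <- boundary_points(layer_mask(sq, 1), 2L)
  expect_equal(nrow(bp2$points), 8L)
  expect_false(any(bp2$points[, 1] == 4L & bp2$points[, 2] == 4L))

  # a full-canvas region: all edge pixels of the canvas
  full <- layer_mask(matrix(3L, 4, 6), 1)
  bp3 <- boundary_points(full, 3L)
  expect_equal(nrow(bp3$points), 2 * 4 + 2 * 6 - 4)

  expect_error(boundary_points(full, 5L), "absent")
})

test_that("surface distances are exact on enumerable cases and scale with spacing", {
  # identical sets: all four metrics 0
  A <- boundary_set(rbind(c(2, 3), c(5, 8)), 1)
  d0 <- distance_metrics(A, A)
  expect_true(all(unlist(d0[, c("hd_um", "ahd_um", "hd95_um", "assd_um")]) == 0))

  # 3-4-5 right triangle: every metric 5
  B <- boundary_set(rbind(c(1, 1)), 1)
  C <- boundary_set(rbind(c(4, 5)), 1)
  d1 <- distance_metrics(B, C)
  expect_equal(unlist(d1[, c("hd_um", "ahd_um", "hd95_um", "assd_um")]),
               c(hd_um = 5, ahd_um = 5, hd95_um = 5, assd_um = 5))

  # A = {(1,1),(1,11)}, B = {(1,1)}: directed A->B {0,10}, B->A {0}
  A2 <- boundary_set(rbind(c(1, 1), c(1, 11)), 1)
  B2 <- boundary_set(rbind(c(1, 1)), 1)
  d2 <- distance_metrics(A2, B2)
  expect_equal(d2$hd_um, 10)
  expect_equal(d2$ahd_um, (5 + 0) / 2)
  expect_equal(d2$assd_um, (0 + 10 + 0) / 3)
  expect_equal(d2$ahd_ab_um, 5)
  expect_equal(d2$ahd_ba_um, 0)

  # the same points at 9.2 um spacing scale every value by 9.2
  A9 <- boundary_set(A2$points, 9.2); B9 <- boundary_set(B2$points, 9.2)
  d9 <- distance_metrics(A9, B9)
  expect_equal(unlist(d9[, 1:4]), unlist(d2[, 1:4]) * 9.2,
               ignore_attr = TRUE)

  expect_error(distance_metrics(A9, B2), "spacing")
})

test_that("distance metrics agree with brute force to 1e-9 on random masks", {
  set.seed(101)
  for (trial in 1:50) {
    h <- sample(16:64, 1); w <- sample(16:64, 1)
    y <- matrix(0L, h, w)
    # random blobs of two layers
    for (k in 1:2) {
      n <- sample(3:8, 1)
      rs <- sample(h, n, TRUE); cs <- sample(w, n, TRUE)
      for (i in seq_len(n))
        y[max(1, rs[i] - 2):min(h, rs[i] + 2),
          max(1, cs[i] - 2):min(w, cs[i] + 2)] <- k
    }
    if (!any(y == 1L) || !any(y == 2L)) next
    m <- layer_mask(y, 1)
    A <- boundary_points(m, 1L); B <- boundary_points(m, 2L)
    fast <- distance_metrics(A, B)
    slow <- bf_distance_metrics(A, B)
    for (col in c("hd_um", "ahd_um", "hd95_um", "assd_um"))
      expect_equal(fast[[col]], slow[[col]], tolerance = 1e-9)
  }
})

test_that("distance metric invariants hold", {
  set.seed(7)
  y <- generate_phantom(test_phantom_cfg(4))$truth
  p <- perturb_mask(y, 2L, seed = 3)
  for (k in c(1L, 4L)) {
    A <- boundary_points(y, k); B <- boundary_points(p, k)
    d <- distance_metrics(A, B)
    # symmetry of ASSD
    expect_equal(d$assd_um, distance_metrics(B, A)$assd_um)
    # orderings
    expect_lte(d$hd95_um, d$hd_um)
    expect_lte(d$ahd_um, d$hd_um)
    # percentile 100 reduces HD95 to HD
    d100 <- distance_metrics(A, B, metrics_config(percentile = 100))
    expect_equal(d100$hd95_um, d100$hd_um)
    # translation invariance of both masks together
    sh <- function(m) layer_mask(rbind(matrix(0L, 3, ncol(m$labels)),
                                       m$labels), m$spacing_um)
    dt <- distance_metrics(boundary_points(sh(y), k),
                           boundary_points(sh(p), k))
    expect_equal(dt$hd_um, d$hd_um)
    expect_equal(dt$assd_um, d$assd_um)
  }
})

test_that("layer thickness recovers band heights", {
  # a horizontal band of height h at spacing s measures h * s
  for (h in c(1L, 4L, 9L)) {
    m <- make_band_mask(c(3, h, 3, 3, 3, 3), width = 30, spacing_um = 2)
    expect_equal(layer_thickness(m, 2L), h * 2, tolerance = 2)
    # within one pixel
    expect_lte(abs(layer_thickness(m, 2L) - h * 2), 2)
  }
  # minimal band: one pixel tall measures about one spacing
  m1 <- make_band_mask(c(3, 1, 3, 3, 3, 3), width = 30, spacing_um = 9.2)
  expect_equal(layer_thickness(m1, 2L), 9.2, tolerance = 1e-9)

  # phantom defaults at 9.2 um: configured thicknesses within one pixel
  cfg <- test_phantom_cfg(8)
  truth <- generate_phantom(cfg)$truth
  for (k in 1:6)
    expect_lte(abs(layer_thickness(truth, k) - band_heights_px(cfg)[k] * 9.2),
               9.2)

  # degenerate layer (no inner contour distinct from outer)
  deg <- matrix(0L, 6, 6); deg[3, ] <- 1L
  expect_error(layer_thickness(layer_mask(deg, 1), 1L), "degenerate")
})

test_that("evaluate produces a coherent report and honours regions", {
  ph <- generate_phantom(test_phantom_cfg(10))
  y <- ph$truth

  rep0 <- evaluate(y, y)
  expect_true(all(rep0$per_layer$iou == 1))
  expect_true(all(rep0$per_layer$hd_um == 0))
  expect_equal(rep0$means$mean_iou, 1)

  p <- perturb_mask(y, 2L, seed = 5)
  rep2 <- evaluate(y, p)
  expect_lte(rep2$means$mean_hd95_um, 2 * sqrt(2) * y$spacing_um)
  expect_true(all(rep2$per_layer$iou < 1))
  expect_s3_class(tidy(rep2), "tbl_df")
  expect_equal(nrow(glance(rep2)), 1L)

  # two-region overlay: region rows equal metrics of the cropped sub-problems
  ids <- matrix(0L, nrow(y$labels), ncol(y$labels))
  ids[, 1:200] <- 21L; ids[, 201:ncol(ids)] <- 22L
  tab <- tibble::tibble(region_id = c(21L, 22L),
                        abbreviation = c("AuA1", "AuR"),
                        definition = c("Primary area", "Rostral area"))
  ov <- region_overlay(ids, y$spacing_um)
  repr <- evaluate(y, p, regions = list(overlay = ov, table = tab))
  expect_equal(repr$per_region$region, c("AuA1", "AuR"))
  # crop-and-recompute oracle for the first region
  yl <- y$labels; yl[, 201:ncol(yl)] <- 0L
  pl <- p$labels; pl[, 201:ncol(pl)] <- 0L
  manual <- evaluate(layer_mask(yl, y$spacing_um),
                     layer_mask(pl, y$spacing_um))
  expect_equal(repr$per_region$mean_iou[1], manual$means$mean_iou)
  expect_equal(repr$per_region$mean_hd95_um[1], manual$means$mean_hd95_um)

  # a layer missing from the prediction is reported, not fatal
  p2 <- p$labels; p2[p2 == 2L] <- 3L
  repm <- evaluate(y, layer_mask(p2, y$spacing_um))
  expect_equal(repm$per_layer$status[2], "missed")
  expect_true(is.na(repm$per_layer$hd_um[2]))
  expect_equal(repm$per_layer$iou[2], 0)
})

test_that("anchor errors follow the two-sample formulas", {
  # ref = moved -> 0 +/- 0
  same <- tibble::tibble(ref_row = c(1, 5), ref_col = c(2, 7),
                         moved_row = c(1, 5), moved_col = c(2, 7))
  a0 <- anchor_error(same, 9.2)
  expect_equal(c(a0$mean_um, a0$sd_um), c(0, 0))

  # a single 3-4-5 pair: 5 +/- 0
  one <- tibble::tibble(ref_row = 0, ref_col = 0, moved_row = 3,
                        moved_col = 4)
  a1 <- anchor_error(one, 1)
  expect_equal(c(a1$mean_um, a1$sd_um, a1$n), c(5, 0, 1))

  # distances {3, 5}: mean 4, sd sqrt(2)
  two <- tibble::tibble(ref_row = c(0, 0), ref_col = c(0, 0),
                        moved_row = c(3, 0), moved_col = c(0, 5))
  a2 <- anchor_error(two, 1)
  expect_equal(a2$mean_um, 4)
  expect_equal(a2$sd_um, sqrt(2))

  expect_error(anchor_error(same[0, ]), "at least one")
})

test_that("acceptable_range is inclusive and matches the published reading", {
  expect_true(acceptable_range(0))
  expect_true(acceptable_range(1800.630, 1800.630))
  expect_false(acceptable_range(1800.631, 1800.630))
  # the published mapping error is within the published range
  expect_true(acceptable_range(1274.750, 1800.630))
  # under the alternative (half-of-threshold) reading it would not be
  expect_false(acceptable_range(1274.750, 1800.630 / 2))
})

test_that("compare_pipelines: exact rank-sum for small samples", {
  r <- compare_pipelines(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u, 0)
  expect_equal(r$p_value, 0.1)
  expect_equal(r$method, "exact")

  # identical lists: p = 1
  ri <- compare_pipelines(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ri$p_value, 1)

  # invariance under swapping the groups
  a <- c(0.1, 0.9, 0.4, 0.7); b <- c(0.2, 0.3, 0.8)
  expect_equal(compare_pipelines(a, b)$p_value,
               compare_pipelines(b, a)$p_value)

  # large samples switch to the normal approximation
  set.seed(1)
  big <- compare_pipelines(rnorm(15), rnorm(15))
  expect_equal(big$method, "normal approximation")

  expect_error(compare_pipelines(c(1, 2), c(3, 4, 5)), "at least 3")
})
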