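# Patch grid geometry and the three-rule training filter.

test_that("patch grid origins follow the stride-plus-flush-edge rule", {
  # canvas equal to the window -> a single origin
  g <- make_patch_grid(c(512, 512), patch_grid_spec(512L, 32L))
  expect_equal(nrow(g), 1L)
  expect_equal(c(g$row, g$col), c(0L, 0L))

  # 576 x 576, window 512, stride 32: floor((576-512)/32)+1 = 3 per axis
  g2 <- make_patch_grid(c(576, 576), patch_grid_spec(512L, 32L))
  expect_equal(nrow(g2), 9L)
  expect_setequal(unique(g2$row), c(0L, 32L, 64L))
  expect_setequal(unique(g2$col), c(0L, 32L, 64L))

  # 530 rows: origins {0, 18}; 18 is the flush origin 530 - 512
  g3 <- make_patch_grid(c(530, 512), patch_grid_spec(512L, 32L))
  expect_setequal(unique(g3$row), c(0L, 18L))
  expect_equal(unique(g3$col), 0L)

  # row-major ordering
  expect_true(!is.unsorted(g2$row))

  expect_error(make_patch_grid(c(100, 100), patch_grid_spec(512L, 32L)),
               "smaller than")
  expect_error(patch_grid_spec(64L, 0L), "stride")
  expect_error(patch_grid_spec(64L, 65L), "stride")
})

test_that("every canvas pixel is covered and counts match the analytic grid", {
  for (canvas in list(c(96L, 130L), c(101L, 97L))) {
    spec <- patch_grid_spec(64L, 24L)
    cov <- coverage_grid(canvas, spec)
    expect_true(all(cov >= 1L))
    # patch count per axis: floor((dim-window)/stride)+1 (+1 if flush added)
    per_axis <- function(dim) {
      n <- floor((dim - spec$window) / spec$stride) + 1
      if ((dim - spec$window) %% spec$stride != 0) n <- n + 1
      n
    }
    g <- make_patch_grid(canvas, spec)
    expect_equal(nrow(g), per_axis(canvas[1]) * per_axis(canvas[2]))
    expect_equal(sum(cov), nrow(g) * spec$window^2)
  }
})

test_that("passes_filter applies the three rules with the printed bounds", {
  mk <- function(labels, gray) {
    patch_pair(c(0L, 0L), raster_img(gray, 9.2), layer_mask(labels, 9.2))
  }
  full <- make_band_mask(rep(4, 6), width = 24, margin = 0)$labels
  bright <- matrix(128, 24, 24)

  ok <- passes_filter(mk(full, bright), filter_criteria())
  expect_true(as.logical(ok))
  expect_equal(attr(ok, "reason"), "ok")

  # missing layer 4
  no4 <- full; no4[no4 == 4L] <- 3L
  r <- passes_filter(mk(no4, bright), filter_criteria())
  expect_false(as.logical(r))
  expect_equal(attr(r, "reason"), "missing_layer")

  # a layer with exactly 5 pixels passes (bound is inclusive)
  five <- full; five[five == 2L] <- 1L; five[1, 1:5] <- 2L
  r5 <- passes_filter(mk(five, bright), filter_criteria())
  expect_true(as.logical(r5))
  # with exactly 4 pixels it fails rule (ii)
  four <- full; four[four == 2L] <- 1L; four[1, 1:4] <- 2L
  r4 <- passes_filter(mk(four, bright), filter_criteria())
  expect_false(as.logical(r4))
  expect_equal(attr(r4, "reason"), "too_few_pixels")

  # rule (iii) is strict: mean exactly 10 fails, all-black fails
  r0 <- passes_filter(mk(full, matrix(0, 24, 24)), filter_criteria())
  expect_false(as.logical(r0))
  expect_equal(attr(r0, "reason"), "low_intensity")
  r10 <- passes_filter(mk(full, matrix(10, 24, 24)), filter_criteria())
  expect_false(as.logical(r10))
  r10p <- passes_filter(mk(full, matrix(10.5, 24, 24)), filter_criteria())
  expect_true(as.logical(r10p))
})

test_that("extract_patches keeps exactly the brute-force-passing training patches", {
  for (seed in c(4, 9)) {
    ph <- generate_phantom(test_phantom_cfg(seed))
    spec <- patch_grid_spec(160L, 48L)
    kept <- extract_patches(ph$image, ph$truth, spec, filter_criteria())
    idx <- attr(kept, "index")
    gray <- ph$image$pixels
    manual <- mapply(function(r0, c0)
      bf_filter_ok(gray, ph$truth$labels, r0, c0, spec$window),
      idx$origin_row, idx$origin_col)
    expect_equal(idx$kept, unname(manual))
    # filtered set is a subset of the grid and every kept patch re-passes
    expect_true(all(vapply(kept, function(p)
      as.logical(passes_filter(p, filter_criteria())), logical(1))))
  }
})

test_that("inference mode returns the full unfiltered grid", {
  ph <- generate_phantom(test_phantom_cfg(5))
  spec <- patch_grid_spec(160L, 48L)
  all_p <- extract_patches(ph$image, ph$truth, spec, criteria = NULL)
  expect_equal(length(all_p),
               nrow(make_patch_grid(dim(ph$truth$labels), spec)))

  # an all-background mask keeps nothing under the filter
  blank <- layer_mask(matrix(0L, dim(ph$truth$labels)[1],
                             dim(ph$truth$labels)[2]), 9.2)
  none <- extract_patches(ph$image, blank, spec, filter_criteria())
  expect_equal(length(none), 0L)
})

test_that("small canvases are padded symmetrically and mismatched inputs error", {
  img <- raster_img(matrix(100, 40, 50), 9.2)
  msk <- layer_mask(matrix(1L, 40, 50), 9.2)
  ps <- extract_patches(img, msk, patch_grid_spec(64L, 64L), NULL)
  expect_equal(length(ps), 1L)
  expect_equal(dim(ps[[1]]$feature$pixels), c(64, 64))
  # padding is background for the mask, zero for the feature
  expect_equal(sum(ps[[1]]$mask$labels == 1L), 40 * 50)
  expect_equal(sum(ps[[1]]$feature$pixels == 100), 40 * 50)

  expect_error(extract_patches(img, layer_mask(matrix(1L, 10, 10), 9.2),
                               patch_grid_spec(64L, 64L)), "differ")
})
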