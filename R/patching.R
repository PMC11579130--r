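# Overlapping patch extraction and the three-rule training-patch filter.

#' Patch grid specification
#'
#' Sliding-window geometry for patch extraction: window size and stride in
#' pixels. The defaults (512 / 32) give heavily overlapping patches so that
#' the same region is captured many times.
#'
#' @param window Window side length in pixels.
#' @param stride Stride between window origins in pixels (1 <= stride <=
#'   window).
#' @return An object of class `patch_grid_spec`.
#' @export
patch_grid_spec <- function(window = 512L, stride = 32L) {
  window <- as.integer(window); stride <- as.integer(stride)
  if (stride < 1L || stride > window)
    stop("stride must satisfy 1 <= stride <= window", call. = FALSE)
  structure(list(window = window, stride = stride),
            class = "patch_grid_spec")
}

#' Training-patch filter criteria
#'
#' The three rules a training patch pair must satisfy: (i) the mask patch
#' contains all six layer labels, (ii) every layer label occupies at least
#' `min_pixels_per_layer` pixels (bound inclusive), and (iii) the grayscale
#' mean of the feature patch is strictly greater than `min_mean_intensity`.
#'
#' @param require_all_layers Must all six layers be present?
#' @param min_pixels_per_layer Minimum pixels per layer label (>= 1).
#' @param min_mean_intensity Strict lower bound on the feature patch's
#'   grayscale mean (0-255 scale).
#' @return An object of class `filter_criteria`.
#' @export
filter_criteria <- function(require_all_layers = TRUE,
                            min_pixels_per_layer = 5L,
                            min_mean_intensity = 10) {
  if (min_pixels_per_layer < 1L)
    stop("min_pixels_per_layer must be >= 1", call. = FALSE)
  if (min_mean_intensity < 0)
    stop("min_mean_intensity must be >= 0", call. = FALSE)
  structure(list(require_all_layers = isTRUE(require_all_layers),
                 min_pixels_per_layer = as.integer(min_pixels_per_layer),
                 min_mean_intensity = min_mean_intensity),
            class = "filter_criteria")
}

# Origins along one axis: multiples of stride with origin + window <= dim,
# plus a flush origin at dim - window when the stride does not tile the axis.
axis_origins <- function(dim, window, stride) {
  last <- dim - window
  if (last < 0L) stop("canvas smaller than window", call. = FALSE)
  org <- seq.int(0L, last, by = stride)
  if (org[length(org)] != last) org <- c(org, last)
  as.integer(org)
}

#' Compute the overlapping patch grid for a canvas
#'
#' Origins are 0-based `(row, col)` top-left corners, all multiples of the
#' stride, plus one flush origin per axis when `(dim - window)` is not a
#' multiple of the stride, so that every canvas pixel is covered by at least
#' one window. The list is sorted row-major.
#'
#' @param canvas `(height, width)` in pixels.
#' @param spec A [patch_grid_spec()].
#' @return A tibble with columns `row` and `col` (0-based origins).
#' @export
make_patch_grid <- function(canvas, spec = patch_grid_spec()) {
  stopifnot(inherits(spec, "patch_grid_spec"))
  if (any(canvas < spec$window))
    stop(sprintf("canvas %d x %d is smaller than the %d px window (pad first)",
                 canvas[1], canvas[2], spec$window), call. = FALSE)
  rows <- axis_origins(canvas[1], spec$window, spec$stride)
  cols <- axis_origins(canvas[2], spec$window, spec$stride)
  tibble::tibble(row = rep(rows, each = length(cols)),
                 col = rep(cols, times = length(rows)))
}

#' Analytic window-coverage count grid
#'
#' Number of grid windows covering each canvas pixel; used to cross-check
#' heatmap accumulation.
#'
#' @inheritParams make_patch_grid
#' @return An integer matrix of the canvas dimensions.
#' @export
coverage_grid <- function(canvas, spec = patch_grid_spec()) {
  grid <- make_patch_grid(canvas, spec)
  cov <- matrix(0L, canvas[1], canvas[2])
  for (i in seq_len(nrow(grid))) {
    r <- grid$row[i]; c <- grid$col[i]
    cov[(r + 1L):(r + spec$window), (c + 1L):(c + spec$window)] <-
      cov[(r + 1L):(r + spec$window), (c + 1L):(c + spec$window)] + 1L
  }
  cov
}

#' A feature/mask patch pair
#'
#' @param origin 0-based `(row, col)` of the window's top-left corner.
#' @param feature A [raster_img()] window.
#' @param mask A [layer_mask()] window of the same dimensions.
#' @return An object of class `patch_pair`.
#' @export
patch_pair <- function(origin, feature, mask) {
  stopifnot(inherits(feature, "raster_img"), inherits(mask, "layer_mask"))
  df <- dim(feature$pixels)[1:2]
  if (!all(df == dim(mask$labels)))
    stop("feature and mask windows must have equal dimensions", call. = FALSE)
  structure(list(origin = as.integer(origin), feature = feature, mask = mask),
            class = "patch_pair")
}

#' Apply the three-rule training filter to a patch pair
#'
#' Returns `TRUE` iff (i) labels 1-6 are all present in the mask patch,
#' (ii) each occupies at least `min_pixels_per_layer` pixels, and (iii) the
#' grayscale (luma) mean of the feature patch is strictly greater than
#' `min_mean_intensity`. The reason code names the first failed rule:
#' `"missing_layer"`, `"too_few_pixels"`, `"low_intensity"`, or `"ok"`.
#'
#' @param p A [patch_pair()].
#' @param criteria A [filter_criteria()].
#' @return Logical scalar with attribute `reason`.
#' @export
passes_filter <- function(p, criteria = filter_criteria()) {
  stopifnot(inherits(p, "patch_pair"), inherits(criteria, "filter_criteria"))
  counts <- tabulate(p$mask$labels[p$mask$labels > 0L], nbins = 6L)
  if (criteria$require_all_layers && any(counts == 0L))
    return(structure(FALSE, reason = "missing_layer"))
  if (any(counts > 0L & counts < criteria$min_pixels_per_layer) ||
      (criteria$require_all_layers &&
         any(counts < criteria$min_pixels_per_layer)))
    return(structure(FALSE, reason = "too_few_pixels"))
  if (!(mean(to_gray(p$feature$pixels)) > criteria$min_mean_intensity))
    return(structure(FALSE, reason = "low_intensity"))
  structure(TRUE, reason = "ok")
}

# Symmetric padding so a small canvas reaches window size: feature padded
# with zeros, mask padded with background. Returns padded objects plus the
# (top, left) pad offsets.
pad_to_window <- function(img, mask, window) {
  h <- nrow(mask$labels); w <- ncol(mask$labels)
  ph <- max(window - h, 0L); pw <- max(window - w, 0L)
  if (ph == 0L && pw == 0L)
    return(list(img = img, mask = mask, top = 0L, left = 0L))
  top <- ph %/% 2L; left <- pw %/% 2L
  nh <- h + ph; nw <- w + pw
  lab <- matrix(0L, nh, nw)
  lab[top + seq_len(h), left + seq_len(w)] <- mask$labels
  px <- img$pixels
  if (length(dim(px)) == 3L) {
    out <- array(0, dim = c(nh, nw, dim(px)[3]))
    out[top + seq_len(h), left + seq_len(w), ] <- px
  } else {
    out <- matrix(0, nh, nw)
    out[top + seq_len(h), left + seq_len(w)] <- px
  }
  list(img = raster_img(out, img$spacing_um, img$name),
       mask = layer_mask(lab, mask$spacing_um), top = top, left = left)
}

crop_window <- function(px, r0, c0, window) {
  if (length(dim(px)) == 3L)
    px[(r0 + 1L):(r0 + window), (c0 + 1L):(c0 + window), , drop = FALSE]
  else
    px[(r0 + 1L):(r0 + window), (c0 + 1L):(c0 + window), drop = FALSE]
}

#' Extract overlapping patch pairs from an image and its mask
#'
#' With `criteria` given (training mode), exactly the grid patches passing
#' [passes_filter()] are returned; with `criteria = NULL` (inference mode)
#' all grid patches are returned, because stitching requires full coverage.
#' Canvases smaller than the window are symmetrically zero-padded (feature)
#' and background-padded (mask).
#'
#' @param img A [raster_img()].
#' @param mask A [layer_mask()] of the same dimensions.
#' @param spec A [patch_grid_spec()].
#' @param criteria A [filter_criteria()], or `NULL` for no filtering.
#' @return A list of [patch_pair()] objects, with a tibble attribute
#'   `"index"` recording `origin_row`, `origin_col`, `kept`, `reason`.
#' @export
extract_patches <- function(img, mask, spec = patch_grid_spec(),
                            criteria = NULL) {
  stopifnot(inherits(img, "raster_img"), inherits(mask, "layer_mask"))
  if (!all(dim(img$pixels)[1:2] == dim(mask$labels)))
    stop("image and mask dimensions differ", call. = FALSE)
  padded <- pad_to_window(img, mask, spec$window)
  img <- padded$img; mask <- padded$mask
  canvas <- dim(mask$labels)
  grid <- make_patch_grid(canvas, spec)
  pairs <- vector("list", nrow(grid))
  kept <- logical(nrow(grid)); reason <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    r0 <- grid$row[i]; c0 <- grid$col[i]
    p <- patch_pair(
      c(r0, c0),
      raster_img(crop_window(img$pixels, r0, c0, spec$window),
                 img$spacing_um, img$name),
      layer_mask(crop_window(mask$labels, r0, c0, spec$window),
                 mask$spacing_um))
    if (is.null(criteria)) {
      kept[i] <- TRUE; reason[i] <- "unfiltered"
    } else {
      ok <- passes_filter(p, criteria)
      kept[i] <- as.logical(ok); reason[i] <- attr(ok, "reason")
    }
    pairs[[i]] <- p
  }
  out <- pairs[kept]
  attr(out, "index") <- tibble::tibble(
    origin_row = grid$row, origin_col = grid$col,
    kept = kept, reason = reason)
  attr(out, "pad") <- c(top = padded$top, left = padded$left)
  out
}
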