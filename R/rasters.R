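# Domain containers and image IO.
#
# All grids are row-major R matrices indexed [row, col], origin at the
# top-left, 0-based origins for patch windows, windows half-open.

#' Create a raster (intensity image with physical spacing)
#'
#' @param pixels Numeric matrix (gray) or h x w x 3 array (RGB) with values
#'   in 0-255.
#' @param spacing_um Physical size of one pixel side in micrometres.
#' @param name Identifier string.
#' @return An object of class `raster_img`.
#' @export
raster_img <- function(pixels, spacing_um, name = "raster") {
  if (is.null(dim(pixels)) || !length(dim(pixels)) %in% c(2L, 3L))
    stop("`pixels` must be a 2D matrix or an h x w x 3 array", call. = FALSE)
  if (length(dim(pixels)) == 3L && !dim(pixels)[3] %in% c(1L, 3L))
    stop("RGB rasters must have 1 or 3 channels", call. = FALSE)
  if (any(dim(pixels)[1:2] < 1L)) stop("raster must be at least 1 x 1", call. = FALSE)
  if (!is.numeric(spacing_um) || length(spacing_um) != 1L || spacing_um <= 0)
    stop("`spacing_um` must be a single positive number", call. = FALSE)
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 255)
    stop("raster values must lie within 0-255", call. = FALSE)
  structure(list(pixels = pixels, spacing_um = spacing_um, name = name),
            class = "raster_img")
}

#' @export
print.raster_img <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<raster_img '%s': %d x %d px, %s channel(s), %.3g um/px>\n",
              x$name, d[1], d[2], if (length(d) == 3L) d[3] else 1L,
              x$spacing_um))
  invisible(x)
}

#' Create a cortical layer mask
#'
#' Per-pixel labels: 0 = background / outside cortex, 1-6 = cortical
#' Layers I-VI.
#'
#' @param labels Integer matrix with values in 0-6.
#' @param spacing_um Micrometres per pixel.
#' @return An object of class `layer_mask`.
#' @export
layer_mask <- function(labels, spacing_um) {
  if (is.null(dim(labels)) || length(dim(labels)) != 2L)
    stop("`labels` must be a 2D matrix", call. = FALSE)
  bad <- !(labels %in% 0:6)
  if (any(bad)) {
    vals <- sort(unique(labels[bad]))
    stop(sprintf(
      "invalid layer labels: value(s) %s outside {0..6} at %d pixel(s)",
      paste(vals, collapse = ", "), sum(bad)), call. = FALSE)
  }
  if (!is.numeric(spacing_um) || length(spacing_um) != 1L || spacing_um <= 0)
    stop("`spacing_um` must be a single positive number", call. = FALSE)
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing_um = spacing_um),
            class = "layer_mask")
}

#' @export
print.layer_mask <- function(x, ...) {
  cat(sprintf("<layer_mask: %d x %d px, %.3g um/px, layers present: %s>\n",
              nrow(x$labels), ncol(x$labels), x$spacing_um,
              paste(sort(setdiff(unique(as.vector(x$labels)), 0L)),
                    collapse = ",")))
  invisible(x)
}

#' Create a brain-region overlay
#'
#' @param ids Integer matrix of non-negative brain-region IDs; 0 = unlabeled.
#' @param spacing_um Micrometres per pixel.
#' @return An object of class `region_overlay`.
#' @export
region_overlay <- function(ids, spacing_um) {
  if (is.null(dim(ids)) || length(dim(ids)) != 2L)
    stop("`ids` must be a 2D matrix", call. = FALSE)
  if (any(ids < 0) || any(ids != round(ids)))
    stop("region IDs must be non-negative integers", call. = FALSE)
  storage.mode(ids) <- "integer"
  structure(list(ids = ids, spacing_um = spacing_um),
            class = "region_overlay")
}

# ---- file IO --------------------------------------------------------------

read_image_values <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (ext %in% c("png")) {
    img <- png::readPNG(path)
    depth <- 255
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path)
    depth <- 255
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  # readers return values in [0,1]; rescale to 0-255 (16-bit handled by caller)
  list(values = img, depth = depth)
}

#' Read a raster image (PNG or TIFF, 8-bit gray or RGB)
#'
#' @param path File path.
#' @param spacing_um Micrometres per pixel of the stored image.
#' @param name Optional identifier; defaults to the file name.
#' @return A [raster_img()].
#' @export
read_raster <- function(path, spacing_um, name = basename(path)) {
  img <- read_image_values(path)$values
  if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3]  # drop alpha
  raster_img(round(img * 255), spacing_um, name)
}

#' Write a raster image
#'
#' @param x A [raster_img()].
#' @param path Destination path; format chosen by extension (.png or .tif).
#' @export
write_raster <- function(x, path) {
  stopifnot(inherits(x, "raster_img"))
  v <- x$pixels / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(v, path)
  else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(v, path, bits.per.sample = 8L)
  else stop("unsupported image format: .", ext, call. = FALSE)
  invisible(path)
}

#' Read a layer mask from an 8-bit single-channel image
#'
#' Values must lie in 0-6; anything else is a format error (the mask is never
#' silently clamped).
#'
#' @param path File path (8-bit single-channel PNG).
#' @param spacing_um Micrometres per pixel.
#' @return A [layer_mask()].
#' @export
read_mask <- function(path, spacing_um) {
  img <- read_image_values(path)$values
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] != 1L)
      stop("layer masks must be single-channel; got ", dim(img)[3],
           " channels", call. = FALSE)
    img <- img[, , 1L]
  }
  vals <- round(img * 255)
  layer_mask(vals, spacing_um)
}

#' Write a layer mask as an 8-bit single-channel PNG
#'
#' Round-trips bit-exactly through [read_mask()].
#'
#' @param x A [layer_mask()].
#' @param path Destination .png path.
#' @export
write_mask <- function(x, path) {
  stopifnot(inherits(x, "layer_mask"))
  png::writePNG(x$labels / 255, path)
  invisible(path)
}

#' Read a brain-region overlay (8- or 16-bit single-channel PNG or TIFF)
#'
#' The stored bit depth is read from the file header, so 8-bit and 16-bit
#' overlays both round-trip to integer region IDs.
#'
#' @param path File path.
#' @param spacing_um Micrometres per pixel.
#' @return A [region_overlay()].
#' @export
read_region_overlay <- function(path, spacing_um) {
  ext <- tolower(tools::file_ext(path))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    depth <- attr(img, "info")$bit.depth %||% 8L
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    depth <- attr(img, "bits.per.sample") %||% 16L
  } else stop("unsupported image format: .", ext, call. = FALSE)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  ids <- matrix(round(as.vector(img) * (2^depth - 1)), nrow(img), ncol(img))
  region_overlay(ids, spacing_um)
}

#' Write a brain-region overlay
#'
#' TIFF output is 16-bit; PNG output is 8-bit and therefore requires all
#' region IDs to be at most 255.
#'
#' @param x A [region_overlay()].
#' @param path Destination path (.png or .tif).
#' @export
write_region_overlay <- function(x, path) {
  stopifnot(inherits(x, "region_overlay"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (max(x$ids) > 255L)
      stop("PNG overlays are 8-bit; use TIFF for region IDs above 255",
           call. = FALSE)
    png::writePNG(x$ids / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(x$ids / 65535, path, bits.per.sample = 16L)
  } else stop("unsupported image format: .", ext, call. = FALSE)
  invisible(path)
}

#' Read a brain-region lookup table
#'
#' CSV with header `region_id,abbreviation,definition`; region IDs and
#' abbreviations must be unique.
#'
#' @param path CSV file path.
#' @return A tibble with columns `region_id`, `abbreviation`, `definition`.
#' @export
read_region_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("region_id", "abbreviation", "definition")
  if (!all(req %in% names(df)))
    stop("region table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  region_table(tibble::as_tibble(df[req]))
}

#' Validate a brain-region lookup table
#'
#' @param df Data frame with columns `region_id`, `abbreviation`,
#'   `definition`.
#' @return The validated tibble.
#' @export
region_table <- function(df) {
  df <- tibble::as_tibble(df)
  if (anyDuplicated(df$region_id))
    stop("region_id values must be unique", call. = FALSE)
  if (anyDuplicated(df$abbreviation))
    stop("abbreviations must be unique", call. = FALSE)
  df
}

# ---- level A -> level B preprocessing ------------------------------------

#' Down-sample and contrast-enhance a raster
#'
#' Emulates the preparation of working-resolution imagery from
#' ultra-high-resolution scans: block-mean (area) reduction by an integer
#' factor followed by linear contrast enhancement about the grayscale mean,
#' `out = clamp(mean + contrast * (in - mean))`. A factor of 10 takes
#' 0.92 um/pixel imagery to 9.2 um/pixel, where individual cells vanish and
#' layer transitions read as texture changes.
#'
#' @param img A [raster_img()].
#' @param factor Integer down-sampling factor (>= 1).
#' @param contrast Contrast enhancement factor (>= 0); 1 leaves the image
#'   unchanged, 2 doubles the deviation of every pixel from the mean.
#' @return A [raster_img()] with dimensions `floor(dim / factor)` and
#'   spacing multiplied by `factor`.
#' @export
downsample_enhance <- function(img, factor = 10L, contrast = 2.0) {
  stopifnot(inherits(img, "raster_img"))
  if (factor < 1 || factor != round(factor))
    stop("`factor` must be a positive integer", call. = FALSE)
  if (contrast < 0) stop("`contrast` must be >= 0", call. = FALSE)
  d <- dim(img$pixels)
  if (factor > d[1] || factor > d[2])
    stop(sprintf("factor %d exceeds image dimensions %d x %d",
                 factor, d[1], d[2]), call. = FALSE)
  down_one <- function(m) {
    h2 <- nrow(m) %/% factor; w2 <- ncol(m) %/% factor
    m <- m[seq_len(h2 * factor), seq_len(w2 * factor), drop = FALSE]
    # block mean: average rows within blocks, then columns
    m <- matrix(colMeans(matrix(m, nrow = factor)), nrow = h2)
    t(matrix(colMeans(matrix(t(m), nrow = factor)), nrow = w2))
  }
  px <- img$pixels
  if (length(dim(px)) == 3L) {
    out <- array(0, dim = c(dim(px)[1] %/% factor, dim(px)[2] %/% factor,
                            dim(px)[3]))
    for (ch in seq_len(dim(px)[3])) out[, , ch] <- down_one(px[, , ch])
  } else {
    out <- down_one(px)
  }
  mu <- mean(to_gray(out))
  out <- clamp255(mu + contrast * (out - mu))
  raster_img(out, img$spacing_um * factor, img$name)
}

# ---- region-based cortex extraction --------------------------------------

#' Extract a binary cortex mask for selected brain regions
#'
#' Uses the region-ID lookup table to select all pixels whose overlay ID maps
#' to one of the wanted region abbreviations (e.g. the twelve auditory-cortex
#' subregions).
#'
#' @param overlay A [region_overlay()].
#' @param table A region lookup table (see [read_region_table()]).
#' @param wanted Character vector of region abbreviations.
#' @return An integer 0/1 matrix of the overlay's dimensions.
#' @export
extract_region_mask <- function(overlay, table, wanted) {
  stopifnot(inherits(overlay, "region_overlay"))
  table <- region_table(table)
  unknown <- setdiff(wanted, table$abbreviation)
  if (length(unknown))
    stop(sprintf("unknown region abbreviation(s): %s; valid names are: %s",
                 paste(unknown, collapse = ", "),
                 paste(table$abbreviation, collapse = ", ")), call. = FALSE)
  ids <- table$region_id[table$abbreviation %in% wanted]
  mask <- matrix(0L, nrow(overlay$ids), ncol(overlay$ids))
  mask[overlay$ids %in% ids] <- 1L
  mask
}

#' Apply a binary cortex mask to a raster
#'
#' Pixels outside the mask are set to 0; pixels inside are unchanged.
#'
#' @param img A [raster_img()].
#' @param mask Integer/logical matrix of the raster's dimensions.
#' @return A masked [raster_img()].
#' @export
apply_cortex_mask <- function(img, mask) {
  stopifnot(inherits(img, "raster_img"))
  d <- dim(img$pixels)
  if (!all(dim(mask) == d[1:2]))
    stop(sprintf("mask dimensions %d x %d do not match raster %d x %d",
                 nrow(mask), ncol(mask), d[1], d[2]), call. = FALSE)
  px <- img$pixels
  if (length(d) == 3L) {
    for (ch in seq_len(d[3])) {
      slice <- px[, , ch]; slice[mask == 0] <- 0; px[, , ch] <- slice
    }
  } else {
    px[mask == 0] <- 0
  }
  raster_img(px, img$spacing_um, img$name)
}
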