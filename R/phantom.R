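# Seeded six-layer cortex phantom generator.
#
# The phantom emulates working-resolution (~9.2 um/pixel) Nissl imagery: a
# curved six-layer ribbon whose layers differ texturally, not at the level of
# individual resolvable cells. Texture is a homogeneous Poisson dot process
# per layer; dot darkening is additive over overlapping dots, so the local
# mean intensity is linear in the layer's dot mass (density x dot area) and
# the six layers form a monotone darkness ladder along the cortical depth.
# Unstained blood vessels appear as white (255) disks.

#' Configuration for a six-layer cortex phantom
#'
#' Defaults generate a horizontal ribbon with gentle sinusoidal curvature at
#' 9.2 um/pixel whose per-layer thicknesses follow reported marmoset
#' auditory-cortex values. Per-layer dot densities keep a >= 2x contrast
#' between adjacent layers except the II/III pair (1.3x), which is
#' deliberately the hardest transition.
#'
#' @param canvas `(height, width)` of the phantom in pixels.
#' @param spacing_um Micrometres per pixel.
#' @param layer_thickness_um Thickness of Layers I-VI in micrometres.
#' @param dot_density Dots per 100 x 100 pixel area, per layer.
#' @param dot_radius_px Integer dot radius per layer (0 = single pixel).
#' @param ribbon_curvature Amplitude in pixels of the sinusoidal vertical
#'   displacement of the ribbon (0 = straight horizontal band).
#' @param vessel_count Number of white vessel holes.
#' @param vessel_radius_px Integer range `c(min, max)` of vessel radii.
#' @param base_gray Intensity of undotted ribbon tissue (0-255).
#' @param dot_contrast Darkening per overlapping dot, in gray levels.
#' @param background_gray Intensity outside the ribbon.
#' @param seed Integer seed; the phantom is a pure function of its config.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(canvas = c(224L, 448L),
                           spacing_um = 9.2,
                           layer_thickness_um = c(92.200, 80.620, 247.390,
                                                  186.820, 338.380, 177.200),
                           dot_density = c(4000, 41600, 32000, 64000,
                                           128000, 256000),
                           dot_radius_px = c(0L, 0L, 1L, 1L, 1L, 1L),
                           ribbon_curvature = 4,
                           vessel_count = 3L,
                           vessel_radius_px = c(2L, 3L),
                           base_gray = 200,
                           dot_contrast = 0.55,
                           background_gray = 235,
                           seed = 1L) {
  cfg <- list(canvas = as.integer(canvas), spacing_um = spacing_um,
              layer_thickness_um = layer_thickness_um,
              dot_density = dot_density,
              dot_radius_px = as.integer(dot_radius_px),
              ribbon_curvature = ribbon_curvature,
              vessel_count = as.integer(vessel_count),
              vessel_radius_px = as.integer(vessel_radius_px),
              base_gray = base_gray, dot_contrast = dot_contrast,
              background_gray = background_gray, seed = as.integer(seed))
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  if (length(cfg$canvas) != 2L || any(cfg$canvas < 1L))
    stop("canvas must be two positive integers", call. = FALSE)
  if (length(cfg$layer_thickness_um) != 6L || any(cfg$layer_thickness_um <= 0))
    stop("layer_thickness_um must be six positive numbers", call. = FALSE)
  if (length(cfg$dot_density) != 6L || any(cfg$dot_density < 0))
    stop("dot_density must be six non-negative rates", call. = FALSE)
  if (length(cfg$dot_radius_px) != 6L || any(cfg$dot_radius_px < 0))
    stop("dot_radius_px must be six non-negative integers", call. = FALSE)
  if (cfg$ribbon_curvature < 0)
    stop("ribbon_curvature must be >= 0", call. = FALSE)
  if (cfg$vessel_count < 0) stop("vessel_count must be >= 0", call. = FALSE)
  band_px <- sum(round(cfg$layer_thickness_um / cfg$spacing_um))
  if (band_px + 2 * ceiling(cfg$ribbon_curvature) > cfg$canvas[1])
    stop(sprintf(
      "layer thicknesses (%d px) plus curvature do not fit canvas height %d",
      band_px, cfg$canvas[1]), call. = FALSE)
  invisible(cfg)
}

#' Band heights in pixels implied by a phantom configuration
#'
#' `round(layer_thickness_um / spacing_um)` per layer; at the 9.2 um default
#' spacing the default thicknesses give bands of 10, 9, 27, 20, 37 and 19
#' pixels.
#'
#' @param cfg A [phantom_config()].
#' @return Integer vector of six band heights.
#' @export
band_heights_px <- function(cfg) {
  as.integer(round(cfg$layer_thickness_um / cfg$spacing_um))
}

#' Generate a six-layer cortex phantom
#'
#' Deterministic given the config (including its seed). Returns the textured
#' image, the ground-truth layer mask (labels 1-6 in contiguous bands ordered
#' pia to white matter, 0 above Layer I and below Layer VI), the vessel
#' centres, and the number of texture dots drawn per layer.
#'
#' @param cfg A [phantom_config()].
#' @return An object of class `phantom`: list with `image` ([raster_img()]),
#'   `truth` ([layer_mask()]), `vessels` (tibble `row`, `col`, `radius_px`)
#'   and `dot_counts` (integer vector of length 6).
#' @export
generate_phantom <- function(cfg) {
  if (!inherits(cfg, "phantom_config")) cfg <- do.call(phantom_config, cfg)
  validate_phantom_config(cfg)
  h <- cfg$canvas[1]; w <- cfg$canvas[2]
  th_px <- band_heights_px(cfg)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(cfg$seed)

  # ribbon geometry: per-column vertical displacement of the whole band
  top <- (h - sum(th_px)) %/% 2L
  phase <- stats::runif(1, 0, 2 * pi)
  disp <- round(cfg$ribbon_curvature *
                  sin(2 * pi * (seq_len(w) - 1L) / w + phase))
  labels <- matrix(0L, h, w)
  bstart <- top + c(0L, cumsum(th_px))[1:6]
  for (k in 1:6) {
    for (col in seq_len(w)) {
      rows <- (bstart[k] + disp[col] + 1L):(bstart[k] + disp[col] + th_px[k])
      rows <- rows[rows >= 1L & rows <= h]
      labels[rows, col] <- k
    }
  }

  # Poisson dot texture, additive darkening over overlaps
  overlap <- matrix(0L, h, w)
  dot_counts <- integer(6)
  for (k in 1:6) {
    idx <- which(labels == k)
    n <- stats::rpois(1, cfg$dot_density[k] * length(idx) / 1e4)
    dot_counts[k] <- n
    if (n == 0L) next
    pick <- sample(idx, n, replace = TRUE)
    overlap <- overlap + stamp_disks(h, w, (pick - 1L) %% h + 1L,
                                     (pick - 1L) %/% h + 1L,
                                     cfg$dot_radius_px[k])
  }
  overlap[labels == 0L] <- 0L
  img <- matrix(cfg$background_gray, h, w)
  inband <- labels > 0L
  img[inband] <- pmax(cfg$base_gray - cfg$dot_contrast * overlap[inband], 10)

  # white vessel holes
  vrows <- integer(0); vcols <- integer(0); vrad <- integer(0)
  if (cfg$vessel_count > 0L) {
    inrib <- which(inband)
    for (v in seq_len(cfg$vessel_count)) {
      ctr <- sample(inrib, 1L)
      r0 <- sample(cfg$vessel_radius_px[1]:cfg$vessel_radius_px[2], 1L)
      cr <- (ctr - 1L) %% h + 1L; cc <- (ctr - 1L) %/% h + 1L
      rr <- max(1L, cr - r0):min(h, cr + r0)
      ccv <- max(1L, cc - r0):min(w, cc + r0)
      d2 <- outer((rr - cr)^2, (ccv - cc)^2, "+")
      sub <- img[rr, ccv]
      sub[d2 <= r0^2 & labels[rr, ccv] > 0L] <- 255
      img[rr, ccv] <- sub
      vrows <- c(vrows, cr); vcols <- c(vcols, cc); vrad <- c(vrad, r0)
    }
  }

  structure(list(
    image = raster_img(img, cfg$spacing_um,
                       sprintf("phantom-seed%d", cfg$seed)),
    truth = layer_mask(labels, cfg$spacing_um),
    vessels = tibble::tibble(row = vrows, col = vcols, radius_px = vrad),
    dot_counts = dot_counts,
    config = cfg
  ), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom: %d x %d px at %.3g um/px, %d vessel(s), seed %d>\n",
              nrow(x$truth$labels), ncol(x$truth$labels),
              x$truth$spacing_um, nrow(x$vessels), x$config$seed))
  invisible(x)
}

#' Perturb a layer mask by smoothly displacing its boundaries
#'
#' Produces an imperfect "prediction" from a ground-truth mask: each of the
#' five inter-layer boundaries is displaced vertically by a smooth, seeded
#' sinusoidal offset whose magnitude never exceeds `shift_px`, so surface
#' distances between truth and perturbation are bounded by
#' `shift_px * sqrt(2) * spacing_um`. The label set is preserved;
#' `shift_px` should not exceed half the thinnest band.
#'
#' @param truth A [layer_mask()] whose labelled region is column-wise
#'   contiguous (as produced by [generate_phantom()]).
#' @param shift_px Maximum boundary displacement in pixels (>= 0).
#' @param seed Integer seed.
#' @return A perturbed [layer_mask()].
#' @export
perturb_mask <- function(truth, shift_px, seed = 1L) {
  stopifnot(inherits(truth, "layer_mask"))
  if (shift_px < 0) stop("`shift_px` must be >= 0", call. = FALSE)
  if (shift_px == 0) return(truth)
  lab <- truth$labels
  h <- nrow(lab); w <- ncol(lab)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)

  # one smooth offset curve per inter-layer boundary
  wavelen <- stats::runif(5, w / 8, w / 2)
  phase <- stats::runif(5, 0, 2 * pi)
  amp <- stats::runif(5, 0.5, 1) * shift_px
  cols <- seq_len(w)
  out <- matrix(0L, h, w)
  for (col in cols) {
    colv <- lab[, col]
    present <- which(colv > 0L)
    if (!length(present)) next
    # first row of each layer in this column (layers are contiguous bands)
    first <- vapply(1:6, function(k) {
      i <- which(colv == k)
      if (length(i)) min(i) else NA_integer_
    }, integer(1))
    lastv <- max(present)
    b <- first  # boundary k = first row of layer k (k >= 2 are displaceable)
    for (k in 2:6) {
      if (is.na(b[k])) next
      off <- round(amp[k - 1] * sin(2 * pi * col / wavelen[k - 1] +
                                      phase[k - 1]))
      b[k] <- b[k] + off
    }
    # enforce ordering with at least one pixel per layer
    for (k in 2:6) if (!is.na(b[k]) && !is.na(b[k - 1]))
      b[k] <- max(b[k], b[k - 1] + 1L)
    b <- pmin(pmax(b, min(present)), lastv)
    ends <- c(b[-1] - 1L, lastv)
    for (k in 1:6) {
      if (is.na(b[k])) next
      rows <- b[k]:max(ends[k], b[k])
      out[rows, col] <- k
    }
  }
  layer_mask(out, truth$spacing_um)
}
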