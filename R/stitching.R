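# Heatmap accumulation, locally adaptive thresholding, and merging of
# overlapping patch predictions into one layer mask.

#' A per-patch layer prediction
#'
#' @param origin 0-based `(row, col)` top-left corner of the window.
#' @param probs `window x window x 6` array of per-layer probabilities in
#'   `[0, 1]`; per-pixel sums over layers must not exceed 1 (the residual is
#'   background). One-hot values are allowed for hard backends.
#' @return An object of class `patch_prediction`.
#' @export
patch_prediction <- function(origin, probs) {
  d <- dim(probs)
  if (length(d) != 3L || d[1] != d[2] || d[3] != 6L)
    stop("`probs` must be a window x window x 6 array", call. = FALSE)
  if (min(probs) < 0 || max(probs) > 1)
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  structure(list(origin = as.integer(origin), probs = probs),
            class = "patch_prediction")
}

#' Accumulate overlapping patch predictions into per-layer heatmaps
#'
#' Every pixel of the final canvas is interpolated from all windows covering
#' it: each layer's heatmap holds the mean over covering windows of that
#' layer's probability, and `coverage` counts the contributing windows.
#' Pixels covered by no window stay 0. The result does not depend on the
#' order of the patch list.
#'
#' @param preds List of [patch_prediction()] objects.
#' @param canvas `(height, width)` of the output canvas.
#' @return An object of class `heatmap_stack`: list with `maps`
#'   (`h x w x 6` array) and `coverage` (integer matrix).
#' @export
accumulate <- function(preds, canvas) {
  h <- canvas[1]; w <- canvas[2]
  sums <- array(0, dim = c(h, w, 6L))
  cov <- matrix(0L, h, w)
  for (p in preds) {
    stopifnot(inherits(p, "patch_prediction"))
    win <- dim(p$probs)[1]
    r0 <- p$origin[1]; c0 <- p$origin[2]
    if (r0 < 0L || c0 < 0L || r0 + win > h || c0 + win > w)
      stop(sprintf("window at (%d, %d) size %d lies outside canvas %d x %d",
                   r0, c0, win, h, w), call. = FALSE)
    ri <- (r0 + 1L):(r0 + win); ci <- (c0 + 1L):(c0 + win)
    sums[ri, ci, ] <- sums[ri, ci, , drop = FALSE] + p$probs
    cov[ri, ci] <- cov[ri, ci] + 1L
  }
  denom <- pmax(cov, 1L)
  maps <- sums / array(denom, dim = c(h, w, 6L))
  structure(list(maps = maps, coverage = cov), class = "heatmap_stack")
}

# Otsu split of values in [0, 1] over `levels` histogram bins.
# Returns the threshold (a bin edge; zero values strictly below it) and the
# ratio of the maximal between-class variance to the total variance, which
# diagnoses effectively unimodal histograms.
otsu_split <- function(x, levels = 256L) {
  tot_var <- stats::var(x)
  if (!is.finite(tot_var) || tot_var == 0)
    return(list(threshold = 0, var_ratio = 0))
  bins <- pmin(pmax(floor(x * levels) + 1L, 1L), levels)
  cnt <- tabulate(bins, nbins = levels)
  n <- length(x)
  p <- cnt / n
  mids <- (seq_len(levels) - 0.5) / levels
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[levels]
  # between-class variance for a cut after each bin
  sb <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  best <- max(sb)
  # middle of the argmax plateau, the standard tie-break
  ks <- which(sb >= best - 1e-12)
  k <- ks[ceiling(length(ks) / 2)]
  list(threshold = k / levels, var_ratio = best / tot_var)
}

#' Adaptively threshold a heatmap stack
#'
#' Heatmaps of stitched patch predictions are bimodal: high where a layer is
#' consistently predicted, near zero elsewhere. Per layer and per square
#' tile, a threshold is chosen by bimodal histogram splitting (the Otsu
#' criterion) and all values below it are set to zero. Tiles whose histogram
#' is effectively unimodal (maximal between-class variance below `1e-6` of
#' the total variance) fall back to the layer's global Otsu threshold.
#' Surviving values are retained, not binarized, so the merge step can still
#' rank layers.
#'
#' @param h A [accumulate()] heatmap stack with normalized maps.
#' @param method `"adaptive"` (tiled) or `"global"` (one threshold per
#'   layer).
#' @param tile Tile side length in pixels (>= 16).
#' @return The thresholded `heatmap_stack`, with chosen global thresholds in
#'   attribute `"global_thresholds"`.
#' @export
threshold_stack <- function(h, method = c("adaptive", "global"),
                            tile = 256L) {
  stopifnot(inherits(h, "heatmap_stack"))
  method <- match.arg(method)
  if (tile < 16L) stop("tile must be at least 16 px", call. = FALSE)
  maps <- h$maps
  nr <- dim(maps)[1]; nc <- dim(maps)[2]
  glob <- numeric(6)
  for (k in 1:6) {
    m <- maps[, , k]
    gs <- otsu_split(as.vector(m))
    glob[k] <- if (gs$var_ratio >= 1e-6) gs$threshold else 0
    if (method == "global") {
      m[m < glob[k]] <- 0
    } else {
      rstarts <- seq.int(1L, nr, by = tile)
      cstarts <- seq.int(1L, nc, by = tile)
      for (r0 in rstarts) for (c0 in cstarts) {
        ri <- r0:min(r0 + tile - 1L, nr)
        ci <- c0:min(c0 + tile - 1L, nc)
        sub <- m[ri, ci]
        ts <- otsu_split(as.vector(sub))
        thr <- if (ts$var_ratio >= 1e-6) ts$threshold else glob[k]
        sub[sub < thr] <- 0
        m[ri, ci] <- sub
      }
    }
    maps[, , k] <- m
  }
  out <- structure(list(maps = maps, coverage = h$coverage),
                   class = "heatmap_stack")
  attr(out, "global_thresholds") <- glob
  out
}

#' Merge thresholded heatmaps into a single layer mask
#'
#' Each pixel is labelled with the layer of the largest surviving heatmap
#' value; ties break toward the smaller layer index, and pixels where all
#' layers are zero are labelled background (0).
#'
#' @param h A thresholded [threshold_stack()] heatmap stack.
#' @param spacing_um Micrometres per pixel for the output mask.
#' @return A [layer_mask()].
#' @export
merge_layers <- function(h, spacing_um = 1) {
  stopifnot(inherits(h, "heatmap_stack"))
  d <- dim(h$maps)
  flat <- matrix(h$maps, nrow = d[1] * d[2], ncol = 6L)
  lab <- max.col(flat, ties.method = "first")
  lab[flat[cbind(seq_len(nrow(flat)), lab)] <= 0] <- 0L
  layer_mask(matrix(as.integer(lab), d[1], d[2]), spacing_um)
}
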