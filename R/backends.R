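# Pluggable per-patch segmentation backends.
#
# A backend is a list with a `predict(feature)` function mapping a
# raster window to a window x window x 6 array of per-layer probabilities
# in [0, 1] (one-hot allowed). The deep segmentation network sits behind
# this same seam in a production deployment; the package ships an oracle
# backend (testing) and a desk-scale texture backend.

new_backend <- function(predict, name, params = list()) {
  structure(list(predict = predict, name = name, params = params),
            class = "seg_backend")
}

#' @export
print.seg_backend <- function(x, ...) {
  cat(sprintf("<seg_backend '%s'>\n", x$name))
  invisible(x)
}

one_hot <- function(labels) {
  d <- dim(labels)
  probs <- array(0, dim = c(d[1], d[2], 6L))
  for (k in 1:6) probs[, , k][labels == k] <- 1
  probs
}

#' Oracle segmentation backend
#'
#' Returns the one-hot ground truth restricted to each requested window;
#' used to verify the stitching fixed point (with perfect per-patch
#' predictions the stitched result must equal the truth on every covered
#' pixel).
#'
#' @param truth A [layer_mask()] covering the full canvas.
#' @return A `seg_backend`.
#' @export
oracle_backend <- function(truth) {
  stopifnot(inherits(truth, "layer_mask"))
  canvas <- dim(truth$labels)
  predict <- function(feature, origin) {
    win <- dim(feature$pixels)[1]
    r0 <- origin[1]; c0 <- origin[2]
    if (r0 < 0L || c0 < 0L || r0 + win > canvas[1] || c0 + win > canvas[2])
      stop("window lies outside the truth mask", call. = FALSE)
    one_hot(truth$labels[(r0 + 1L):(r0 + win), (c0 + 1L):(c0 + win),
                         drop = FALSE])
  }
  new_backend(predict, "oracle")
}

# ---- texture features ----------------------------------------------------

# Per-pixel texture features over a (2r+1)^2 neighbourhood, masked to
# tissue: pixels that are background (0) or bright vessel lumen (>=
# bright_thresh) are excluded from the window statistics, so features near
# the cortex edge and around white holes are computed from surrounding
# tissue only.
texture_features <- function(gray, r = 7L, dark_thresh = 199,
                             bright_thresh = 220) {
  tissue <- gray > 0 & gray < bright_thresh
  cnt <- box_mean(tissue * 1, r)
  masked_mean <- function(m) {
    out <- box_mean(m * tissue, r) / pmax(cnt, 1e-9)
    out[cnt == 0] <- 0
    out
  }
  f1 <- masked_mean(gray)
  dark <- (gray < dark_thresh & gray > 0) * 1
  cc <- EBImage::bwlabel(dark)
  centers <- matrix(0, nrow(gray), ncol(gray))
  if (max(cc) > 0) {
    cm <- EBImage::computeFeatures.moment(cc)
    rc <- cbind(pmin(pmax(round(cm[, "m.cx"]), 1), nrow(gray)),
                pmin(pmax(round(cm[, "m.cy"]), 1), ncol(gray)))
    centers[rc] <- 1
  }
  list(intensity = f1, blob_density = masked_mean(centers), tissue = tissue)
}

#' Nearest-centroid texture segmentation backend
#'
#' A desk-scale stand-in for a trained segmentation network that exercises
#' every pipeline stage. Per-pixel features are the local mean intensity
#' and the local dark-blob density over a 15 x 15 neighbourhood (masked to
#' tissue). Class centroids are fitted from training patch pairs: with
#' `k = 1` (default) the pure per-layer feature means are recovered by
#' least-squares unmixing against the window class fractions (exact for
#' layers thinner than the feature window, whose pixels are never pure);
#' with `k > 1`, k-means subcentroids per class are fitted instead.
#' Prediction assigns each pixel the class of the nearest centroid under
#' feature weights that default to the intensity channel only, and emits
#' one-hot probabilities.
#'
#' @param training Non-empty list of [patch_pair()] objects containing all
#'   six layers.
#' @param k Centroids per class (>= 1).
#' @param feature_weights Length-2 weights for (intensity, blob density) in
#'   the nearest-centroid distance. The default disables the blob channel,
#'   whose window statistics are not linear in class mixtures.
#' @param dark_quantile The dark-blob threshold is this fraction of the
#'   brightest tissue intensity seen in training.
#' @return A `seg_backend` with the fitted centroids in `$params`.
#' @export
texture_backend <- function(training, k = 1L,
                            feature_weights = c(1, 0),
                            dark_quantile = 0.995) {
  if (!length(training)) stop("training set is empty", call. = FALSE)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  labs <- unlist(lapply(training, function(p) unique(as.vector(p$mask$labels))))
  missing <- setdiff(1:6, labs)
  if (length(missing))
    stop("training patches lack layer(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  grays <- lapply(training, function(p) to_gray(p$feature$pixels))
  tissue_max <- max(vapply(grays, function(g) {
    v <- g[g > 0 & g < 220]
    if (length(v)) max(v) else 0
  }, numeric(1)))
  dark_thresh <- dark_quantile * tissue_max

  f1 <- c(); f2 <- c(); W <- NULL
  for (i in seq_along(training)) {
    p <- training[[i]]
    ft <- texture_features(grays[[i]], dark_thresh = dark_thresh)
    lab <- p$mask$labels
    tissue <- ft$tissue & lab > 0L
    cnt <- box_mean((lab > 0L) * 1, 7L)
    wk <- vapply(1:6, function(kk) {
      as.vector(box_mean((lab == kk) * 1, 7L) / pmax(cnt, 1e-9))[tissue]
    }, numeric(sum(tissue)))
    f1 <- c(f1, ft$intensity[tissue])
    f2 <- c(f2, ft$blob_density[tissue])
    W <- rbind(W, wk)
  }

  if (k == 1L) {
    fit1 <- stats::lm.fit(W, f1)
    fit2 <- stats::lm.fit(W, f2)
    centroids <- cbind(fit1$coefficients, fit2$coefficients)
    classes <- 1:6
    scale <- c(stats::sd(fit1$residuals), stats::sd(fit2$residuals))
  } else {
    dom <- max.col(W, ties.method = "first")
    scale <- c(stats::sd(f1), stats::sd(f2))
    centroids <- NULL; classes <- integer(0)
    for (kk in 1:6) {
      X <- cbind(f1[dom == kk], f2[dom == kk])
      km <- suppressWarnings(stats::kmeans(X, centers = min(k, nrow(unique(X))),
                                           nstart = 3L, iter.max = 100L))
      centroids <- rbind(centroids, km$centers)
      classes <- c(classes, rep(kk, nrow(km$centers)))
    }
  }
  scale[scale <= 0 | !is.finite(scale)] <- 1

  predict <- function(feature, origin = c(0L, 0L)) {
    g <- to_gray(feature$pixels)
    ft <- texture_features(g, dark_thresh = dark_thresh)
    z1 <- as.vector(ft$intensity); z2 <- as.vector(ft$blob_density)
    D <- outer(z1, centroids[, 1], "-")^2 * (feature_weights[1] / scale[1]^2) +
      outer(z2, centroids[, 2], "-")^2 * (feature_weights[2] / scale[2]^2)
    lab <- classes[max.col(-D, ties.method = "first")]
    # vessel lumina keep the label implied by surrounding tissue (their
    # features are masked means); only true background is left unlabelled
    lab[as.vector(g) == 0] <- 0L
    one_hot(matrix(lab, nrow(g), ncol(g)))
  }
  new_backend(predict, "texture-nearest-centroid",
              params = list(centroids = centroids, classes = classes,
                            scale = scale, dark_thresh = dark_thresh,
                            feature_weights = feature_weights, k = k))
}
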