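# Internal numeric helpers shared across modules.

# Clamp to the 8-bit intensity range.
clamp255 <- function(x) pmin(pmax(x, 0), 255)

# Rec. 601 luma weights; the single grayscale convention used everywhere.
LUMA <- c(0.299, 0.587, 0.114)

# Convert an h x w (already gray) matrix or h x w x 3 array to a gray matrix.
to_gray <- function(px) {
  if (length(dim(px)) == 2L) return(px)
  stopifnot(length(dim(px)) == 3L, dim(px)[3] %in% c(1L, 3L))
  if (dim(px)[3] == 1L) return(px[, , 1L])
  LUMA[1] * px[, , 1L] + LUMA[2] * px[, , 2L] + LUMA[3] * px[, , 3L]
}

# Box (moving-average) filter of half-width r via an integral image,
# with edge clipping: each output is the mean over the in-canvas part
# of the (2r+1) x (2r+1) window.
box_mean <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  ii <- matrix(0, h + 1L, w + 1L)
  ii[-1L, -1L] <- t(apply(apply(m, 2L, cumsum), 1L, cumsum))
  rows <- as.vector(row(m)); cols <- as.vector(col(m))
  r1 <- pmax(rows - r, 1L); r2 <- pmin(rows + r, h)
  c1 <- pmax(cols - r, 1L); c2 <- pmin(cols + r, w)
  s <- ii[cbind(r2 + 1L, c2 + 1L)] - ii[cbind(r1, c2 + 1L)] -
    ii[cbind(r2 + 1L, c1)] + ii[cbind(r1, c1)]
  matrix(s / ((r2 - r1 + 1L) * (c2 - c1 + 1L)), h, w)
}

# Pixel offsets of a filled disk of integer radius r (r = 0 is one pixel).
disk_offsets <- function(r) {
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
}

# Stamp unit mass at (rows, cols) + disk offsets, accumulating overlaps.
stamp_disks <- function(h, w, rows, cols, radius) {
  off <- disk_offsets(radius)
  rr <- rep(rows, each = nrow(off)) + off$dr
  cc <- rep(cols, each = nrow(off)) + off$dc
  ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
  matrix(tabulate((cc[ok] - 1L) * h + rr[ok], nbins = h * w), h, w)
}

# 4-neighbour label shifts with NA outside the canvas.
shift_up <- function(m) rbind(NA, m[-nrow(m), , drop = FALSE])
shift_down <- function(m) rbind(m[-1L, , drop = FALSE], NA)
shift_left <- function(m) cbind(NA, m[, -ncol(m), drop = FALSE])
shift_right <- function(m) cbind(m[, -1L, drop = FALSE], NA)

# Exact Euclidean distance (per pixel) to the nearest TRUE pixel of `mask`.
distance_to <- function(mask) {
  storage.mode(mask) <- "integer"
  as.matrix(EBImage::distmap(1L - mask, metric = "euclidean"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
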