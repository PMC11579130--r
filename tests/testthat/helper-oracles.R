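# Shared fixtures and independent brute-force oracles.

# A flat horizontal six-band mask (no curvature, no texture), bands of the
# given pixel heights, with `margin` background rows above and below.
make_band_mask <- function(heights = c(4, 4, 4, 4, 4, 4), width = 40,
                           margin = 3, spacing_um = 1) {
  h <- sum(heights) + 2 * margin
  lab <- matrix(0L, h, width)
  r <- margin
  for (k in seq_along(heights)) {
    lab[(r + 1):(r + heights[k]), ] <- k
    r <- r + heights[k]
  }
  layer_mask(lab, spacing_um)
}

# Brute-force O(|A| * |B|) surface distances; the implementation under test
# uses a distance transform instead.
bf_distance_metrics <- function(A, B, percentile = 95) {
  s <- A$spacing_um
  pd <- function(P, Q) {
    apply(P, 1, function(p)
      sqrt(min((p[1] - Q[, 1])^2 + (p[2] - Q[, 2])^2)))
  }
  dab <- pd(A$points, B$points)
  dba <- pd(B$points, A$points)
  list(
    hd_um = max(max(dab), max(dba)) * s,
    ahd_um = mean(c(mean(dab), mean(dba))) * s,
    hd95_um = max(stats::quantile(dab, percentile / 100, names = FALSE),
                  stats::quantile(dba, percentile / 100, names = FALSE)) * s,
    assd_um = (sum(dab) + sum(dba)) / (length(dab) + length(dba)) * s)
}

# Brute-force re-application of the three printed filter rules at one grid
# origin, written independently of passes_filter().
bf_filter_ok <- function(img_px, mask_lab, r0, c0, window,
                         min_px = 5, min_mean = 10) {
  ri <- (r0 + 1):(r0 + window); ci <- (c0 + 1):(c0 + window)
  sub_lab <- mask_lab[ri, ci]
  for (k in 1:6) if (sum(sub_lab == k) < min_px) return(FALSE)
  gray <- img_px[ri, ci]
  mean(gray) > min_mean
}

# A small deterministic phantom configuration for fast tests.
test_phantom_cfg <- function(seed) phantom_config(seed = seed)
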