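# laminaseg

Patch-based segmentation and evaluation of the six Brodmann cortical
layers in down-sampled Nissl-stained histology images.

## The problem

Tracing and connectivity studies need to know not just *which* cortical
region a signal sits in but *which lamina* (Layers I-VI, pia to white
matter). Laminae are invisible in fluorescent tracer images, so they are
delineated on adjacent Nissl-stained sections - a task far too slow to do
by hand across hundreds of slides of ~26000 x 21000 pixels. At a 10x
down-sampled working resolution (~9.2 um/pixel) individual cells vanish
but each layer keeps a distinctive texture, which makes automated
segmentation feasible.

`laminaseg` is for image-analysis and neuroinformatics researchers
building or evaluating such segmentation pipelines. It implements
everything *around* the segmentation network - the part that is usually
re-written ad hoc - as tested, reusable components:

* **Patch extraction**: overlapping sliding-window grid (default 512 px
  window, 32 px stride) with the three-rule training filter: a mask patch
  must contain all six layers, every layer with >= 5 pixels, and the
  feature patch's grayscale mean must exceed 10.
* **Heatmap stitching**: per-layer probability heatmaps averaged over all
  covering windows, tiled Otsu thresholding with a global fallback for
  unimodal tiles, argmax merge with deterministic tie-breaks.
* **Region handling**: brain-region ID overlays + CSV lookup tables select
  the cortex of interest (e.g. the twelve auditory subregions AuA1 ... AuRT).
* **The full metric suite**: IoU, Dice (with the published +1 smoothing),
  recall, precision, Hausdorff (HD), average Hausdorff (AHD),
  95th-percentile Hausdorff (95HD), average symmetric surface distance
  (ASSD), per-layer thickness, anchor-based registration error, and exact
  Mann-Whitney pipeline comparison. For boundary sets A, B:

  ```
  HD(A,B)   = max( max_a min_b ||a-b||, max_b min_a ||a-b|| )
  95HD(A,B) = max of the two directed 95th percentiles
  ASSD(A,B) = ( sum_a min_b ||a-b|| + sum_b min_a ||a-b|| ) / (|A| + |B|)
  ```

  computed exactly via Euclidean distance transforms.
* **A seeded cortex phantom generator**: six-band ribbons with
  layer-specific Poisson dot textures, curvature, and white vessel holes,
  with analytic ground truth - so every stage is testable without brain
  data.
* **Pluggable backends**: the segmentation model is an interface
  (`predict(window) -> window x window x 6 probabilities`). An oracle
  backend verifies the stitching fixed point; a nearest-centroid texture
  backend (least-squares-unmixed class centroids over 15 x 15 windowed
  features) exercises the whole pipeline at desk scale.

## Worked example

Train the texture backend on one phantom, segment a held-out phantom with
a different seed, and score the result:

```r
library(laminaseg)

train_ph <- generate_phantom(phantom_config(seed = 1))
test_ph  <- generate_phantom(phantom_config(seed = 2))

cfg <- pipeline_config(grid = patch_grid_spec(160L, 48L),
                       stitch = list(method = "adaptive", tile = 64L))
patches <- extract_patches(train_ph$image, train_ph$truth,
                           cfg$grid, cfg$filter)
backend <- texture_backend(patches)

cortex <- (test_ph$truth$labels > 0L) * 1L
pred <- run_pipeline(test_ph$image, cortex, cfg, backend)

report <- evaluate(test_ph$truth, pred)
tidy(report)[, c("class", "iou", "dsc", "hd95_um", "assd_um", "thickness_um")]
glance(report)[, 1:4]
```

```
# A tibble: 6 x 6
  class   iou   dsc hd95_um assd_um thickness_um
  <int> <dbl> <dbl>   <dbl>   <dbl>        <dbl>
1     1 0.974 0.987     9.2    1.17         89.6
2     2 0.935 0.967     9.2    2.73         83.4
3     3 0.971 0.985     9.2    3.43        244.
4     4 0.961 0.980     9.2    3.47        181.
5     5 0.984 0.992     9.2    2.54        336.
6     6 0.987 0.993     9.2    1.13        175.

# A tibble: 1 x 4
  mean_iou mean_dsc mean_recall mean_precision
     <dbl>    <dbl>       <dbl>          <dbl>
1    0.969    0.984       0.985          0.983
```

Reading the numbers: every layer overlaps its ground truth at IoU >= 0.94;
the worst boundary deviation that survives the robust 95th percentile is a
single pixel (9.2 um); and the recovered layer thicknesses sit within one
pixel of the configured values (e.g. Layer II: 83.4 vs 80.6 um). Layer II
is the thinnest band and the II/III texture contrast is deliberately the
weakest, so it is - as expected - the hardest layer.

`autoplot(test_ph)` renders the phantom, `plot_layer_mask(pred)` the
segmentation, and `autoplot(report)` the per-layer score bars.

A thin command-line wrapper over the same functions lives at
`inst/cli/laminaseg.R` with subcommands `synth`, `patch`, `stitch`, `run`,
`evaluate`, and `cv-plan`.

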