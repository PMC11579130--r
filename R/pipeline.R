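# End-to-end orchestration: mask -> patches -> backend -> stitch -> mask,
# plus the nested cross-validation plan.

#' Pipeline configuration
#'
#' @param grid A [patch_grid_spec()].
#' @param filter A [filter_criteria()] applied to training extraction only;
#'   inference extraction is never filtered.
#' @param stitch List with `method` ("adaptive" or "global") and `tile`.
#' @param spacing_um Micrometres per pixel of the imagery.
#' @param seed Integer seed for any stochastic backend.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(grid = patch_grid_spec(),
                            filter = filter_criteria(),
                            stitch = list(method = "adaptive", tile = 256L),
                            spacing_um = 9.2,
                            seed = 1L) {
  stopifnot(inherits(grid, "patch_grid_spec"),
            inherits(filter, "filter_criteria"))
  if (!stitch$method %in% c("adaptive", "global"))
    stop("stitch method must be 'adaptive' or 'global'", call. = FALSE)
  structure(list(grid = grid, filter = filter, stitch = stitch,
                 spacing_um = spacing_um, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full segmentation pipeline on one image
#'
#' Applies the cortex mask, extracts the unfiltered overlapping patch grid,
#' obtains a per-layer probability array from the backend for every patch,
#' accumulates the overlapping predictions into per-layer heatmaps,
#' thresholds them adaptively, merges them into one layer mask, and forces
#' pixels outside the cortex mask to background. Deterministic given the
#' config seed and backend.
#'
#' @param img A [raster_img()].
#' @param cortex_mask Binary matrix of the image's dimensions (1 = cortex).
#' @param cfg A [pipeline_config()].
#' @param backend A `seg_backend` (see [oracle_backend()],
#'   [texture_backend()]).
#' @param verbose Emit per-stage log lines with counts?
#' @return A [layer_mask()].
#' @export
run_pipeline <- function(img, cortex_mask, cfg, backend, verbose = FALSE) {
  stopifnot(inherits(img, "raster_img"), inherits(cfg, "pipeline_config"),
            inherits(backend, "seg_backend"))
  say <- function(...) if (verbose) message(sprintf(...))
  h0 <- dim(img$pixels)[1]; w0 <- dim(img$pixels)[2]
  if (!all(dim(cortex_mask) == c(h0, w0)))
    stop("[mask] cortex mask dimensions do not match the image",
         call. = FALSE)
  set.seed(cfg$seed)

  masked <- apply_cortex_mask(img, cortex_mask)
  say("[mask] %d of %d pixels inside cortex", sum(cortex_mask == 1L), h0 * w0)

  dummy <- layer_mask(matrix(0L, h0, w0), cfg$spacing_um)
  patches <- extract_patches(masked, dummy, cfg$grid, criteria = NULL)
  pad <- attr(patches, "pad")
  say("[patch] %d inference patches (window %d, stride %d)",
      length(patches), cfg$grid$window, cfg$grid$stride)

  preds <- lapply(patches, function(p) {
    probs <- tryCatch(backend$predict(p$feature, p$origin),
                      error = function(e)
                        stop("[predict] backend failed at origin (",
                             p$origin[1], ", ", p$origin[2], "): ",
                             conditionMessage(e), call. = FALSE))
    patch_prediction(p$origin, probs)
  })

  canvas <- c(max(h0, cfg$grid$window), max(w0, cfg$grid$window))
  stack <- accumulate(preds, canvas)
  say("[stitch] coverage %d-%d windows/pixel", min(stack$coverage),
      max(stack$coverage))
  stack <- threshold_stack(stack, method = cfg$stitch$method,
                           tile = cfg$stitch$tile)
  say("[stitch] global thresholds: %s",
      paste(sprintf("%.3f", attr(stack, "global_thresholds")),
            collapse = ", "))
  merged <- merge_layers(stack, cfg$spacing_um)

  lab <- merged$labels[pad["top"] + seq_len(h0), pad["left"] + seq_len(w0),
                       drop = FALSE]
  lab[cortex_mask == 0L] <- 0L
  layer_mask(lab, cfg$spacing_um)
}

#' Nested cross-validation plan over brains
#'
#' Builds the rotation plan for nested cross-validation with one brain per
#' role: each brain appears exactly once as the test set (outer folds rotate
#' the test brain, starting from the last), and within each outer fold every
#' remaining brain serves once as the validation set while the others train;
#' the best-validation model is then evaluated on the test brain. Execution
#' is delegated to the configured backend trainer; this function only emits
#' the manifest.
#'
#' @param brains Character vector of at least 3 dataset names.
#' @return A tibble with columns `outer_fold`, `inner_fold`, `train`
#'   (comma-joined), `validation`, `test`.
#' @export
nested_cv_plan <- function(brains) {
  brains <- as.character(brains)
  n <- length(brains)
  if (n < 3L) stop("need at least 3 dataset names", call. = FALSE)
  rows <- list()
  for (fold in seq_len(n)) {
    test <- brains[n - fold + 1L]
    rest <- setdiff(brains, test)
    for (j in seq_along(rest)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        outer_fold = fold, inner_fold = j,
        train = paste(setdiff(rest, rest[j]), collapse = ","),
        validation = rest[j], test = test)
    }
  }
  dplyr::bind_rows(rows)
}
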