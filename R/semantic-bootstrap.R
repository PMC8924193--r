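# Recursive weak-label bootstrapping: classical segmentation + human edits
# seed the first pool, a trainable three-class model is then alternately
# trained on the pool and used to label the next set, with edits applied
# between rounds.

#' Pool bookkeeping for the three-round bootstrap
#'
#' Round 1 labels set 1 by the classical pipeline (+ edits); round 2 trains
#' on the pool and labels set 2 (+ edits); round 3 retrains on the grown
#' pool and labels set 3 with no further edits, so the pool does not grow.
#' For set sizes (26, 16, 168) the pool sizes are (26, 42, 42) with 168
#' prediction-only outputs.
#'
#' @param n1,n2,n3 sizes of the three weak sets.
#' @return data.frame with `round`, `pool_size`, `predictions`.
#' @export
bootstrap_schedule <- function(n1, n2, n3) {
  data.frame(round = 1:3,
             pool_size = c(n1, n1 + n2, n1 + n2),
             predictions = c(0L, 0L, n3))
}

#' Run the recursive weak-label bootstrap
#'
#' @param set1,set2,set3 lists of nuclear-channel rasters (disjoint sets).
#' @param edit_provider function `(raster, predicted NuclearSegResult) ->
#'   EditOverlay`; use an oracle provider on synthetic data, or a provider
#'   returning empty overlays for a fully automatic run.
#' @param model_factory zero-argument function returning a fresh untrained
#'   [semantic_model()].
#' @param config list; honoured fields: `epochs` (per training round,
#'   default 200), `seed` (default 1), `min_distance` (marker suppression
#'   for the classical stage, default 5).
#' @return list with `model` (final trained model), `labels` (per-set lists
#'   of [nuclear_seg_result()]), and `state` (a `BootstrapState`: the
#'   labelled pool with provenance tags, round index, pool-size trace).
#' @export
run_bootstrap <- function(set1, set2, set3, edit_provider, model_factory,
                          config = list()) {
  if (!length(set1)) stop("empty set1: cannot bootstrap")
  cfg <- modifyList(list(epochs = 200L, seed = 1L, min_distance = 5), config)
  pool <- list()
  add_item <- function(raster, result, provenance) {
    pool[[length(pool) + 1L]] <<- list(raster = raster,
                                       three_class = result$three_class,
                                       provenance = provenance)
  }
  apply_edits <- function(raster, result) {
    ov <- edit_provider(raster, result)
    if (length(ov$split_lines) || length(ov$removal_contours))
      suppressWarnings(apply_edit_overlay(result, ov))
    else result
  }

  # round 1: classical segmentation + edits on set1
  labels1 <- lapply(set1, function(r) {
    res <- segment_nuclei_classic(r, min_distance = cfg$min_distance)
    apply_edits(r, res)
  })
  for (i in seq_along(set1)) add_item(set1[[i]], labels1[[i]],
                                      "classic+edits")
  pool_trace <- length(pool)

  train_pool <- function(seed) {
    model <- model_factory()
    pairs <- lapply(pool, function(it)
      list(raster = it$raster, map = it$three_class))
    train_three_class(model, pairs, epochs = cfg$epochs, seed = seed)
  }
  predict_result <- function(model, raster) {
    map <- predict_three_class(model, raster)$map
    inst <- three_class_to_instances(map)
    nuclear_seg_result(inst, instances_to_three_class(inst))
  }

  # round 2: train on pool, label set2, apply edits, grow pool
  model <- train_pool(cfg$seed)
  labels2 <- lapply(set2, function(r) apply_edits(r, predict_result(model, r)))
  for (i in seq_along(set2)) add_item(set2[[i]], labels2[[i]], "model+edits")
  pool_trace <- c(pool_trace, length(pool))

  # round 3: retrain on grown pool, label set3 (no edits, pool frozen)
  model <- train_pool(cfg$seed + 1L)
  labels3 <- lapply(set3, function(r) predict_result(model, r))
  pool_trace <- c(pool_trace, length(pool))

  state <- structure(list(labeled_pool = pool, round_index = 3L,
                          pool_sizes = pool_trace,
                          n_predictions = length(set3),
                          schedule = bootstrap_schedule(length(set1),
                                                        length(set2),
                                                        length(set3))),
                     class = "BootstrapState")
  list(model = model,
       labels = list(set1 = labels1, set2 = labels2, set3 = labels3),
       state = state)
}

#' @export
print.BootstrapState <- function(x, ...) {
  cat(sprintf("<BootstrapState: round %d, pool sizes %s, %d prediction(s)>\n",
              x$round_index, paste(x$pool_sizes, collapse = "/"),
              x$n_predictions))
  invisible(x)
}

#' Write a bootstrap manifest (pool provenance) to JSON
#' @param state a `BootstrapState`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bootstrap_manifest <- function(state, path) {
  obj <- list(round_index = state$round_index,
              pool_sizes = state$pool_sizes,
              n_predictions = state$n_predictions,
              items = lapply(seq_along(state$labeled_pool), function(i)
                list(index = i,
                     provenance = state$labeled_pool[[i]]$provenance)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}
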