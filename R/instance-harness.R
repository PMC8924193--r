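# Two-stage domain-adaptation training harness for pluggable instance
# segmentation backends, with a CPU reference backend (three-class pixel
# model + connected components) for desk-scale experiments.

#' Training configuration
#'
#' Defaults are the published training schedule of the original system:
#' SGD, batch size 6, learning rate 1e-4, weight decay 1e-4, momentum 0.9,
#' gradients clipped to 5.0, heads trained for 20 epochs then all layers
#' for 40, ResNet-101 backbone. These parameters bind the heavy-backend
#' contract; the bundled reference backend honours `heads_epochs`,
#' `all_layers_epochs`, `gradient_clip` and `seed`, and documents its own
#' optimizer mapping (full-batch Adam).
#'
#' @param batch_size images per gradient step (heavy backend).
#' @param learning_rate,weight_decay,momentum SGD parameters.
#' @param gradient_clip global gradient-norm clip.
#' @param heads_epochs epochs of heads-only fine-tuning per stage.
#' @param all_layers_epochs epochs of all-layers fine-tuning per stage.
#' @param backbone_id backbone identifier for the heavy backend.
#' @param optimizer optimizer identifier.
#' @param seed integer seed.
#' @return a `TrainingConfig` list.
#' @export
training_config <- function(batch_size = 6L, learning_rate = 1e-4,
                            weight_decay = 1e-4, momentum = 0.9,
                            gradient_clip = 5.0, heads_epochs = 20L,
                            all_layers_epochs = 40L,
                            backbone_id = "resnet101",
                            optimizer = "sgd", seed = 1L) {
  stopifnot(batch_size > 0, learning_rate > 0, weight_decay >= 0,
            momentum >= 0, gradient_clip > 0,
            heads_epochs >= 0, all_layers_epochs >= 0)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 momentum = momentum, gradient_clip = gradient_clip,
                 heads_epochs = as.integer(heads_epochs),
                 all_layers_epochs = as.integer(all_layers_epochs),
                 backbone_id = backbone_id, optimizer = optimizer,
                 seed = as.integer(seed)),
            class = "TrainingConfig")
}

#' Domain adaptation plan
#'
#' @param init pretrained-weights identifier (natural-image corpus for the
#'   heavy backend; `"random"` for the reference backend, seeded from the
#'   training config).
#' @param stage1 optional weak-label training dataset (from
#'   [build_training_dataset()]); omit (`NULL`) for the single-stage
#'   comparison arm.
#' @param stage2 manual-label training dataset (required).
#' @return a `DomainAdaptationPlan`.
#' @export
domain_adaptation_plan <- function(init = "random", stage1 = NULL, stage2) {
  if (missing(stage2) || is.null(stage2))
    stop("stage2 (manual-label dataset) is required")
  structure(list(init = init, stage1 = stage1, stage2 = stage2),
            class = "DomainAdaptationPlan")
}

#' Build a training dataset from ROIs with instance labels
#'
#' Per item: 16-to-8-bit conversion, DAPI-MEM-DAPI stacking, 2x
#' nearest-neighbour upscaling, per-channel normalization, and mask-stack
#' extraction scaled identically. Items with empty label maps are excluded
#' and recorded in the exclusion log. Augmentation is applied at sampling
#' time via [sample_training_batch()].
#'
#' The harness z-scores each channel (not just zero-centering): weak-label
#' and manual datasets can differ strongly in staining intensity, and
#' without variance scaling that domain gap destabilizes two-stage transfer
#' (verified empirically; see the methods vignette).
#'
#' @param rois list of `list(dapi =, mem =, labels =)`: 16- or 8-bit
#'   rasters plus an aligned instance label map.
#' @param policy an [augmentation_policy()].
#' @param normalize_mode per-channel normalization for the network input;
#'   `"zscore"` (default) or `"mean"`.
#' @return a `TrainingDataset`: `items` (each with `channels` normalized
#'   r/g/b, `instances` upscaled label map, `masks` upscaled mask stack),
#'   `policy`, `excluded` (indices of dropped items).
#' @export
build_training_dataset <- function(rois, policy = augmentation_policy(),
                                   normalize_mode = c("zscore", "mean")) {
  normalize_mode <- match.arg(normalize_mode)
  items <- list(); excluded <- integer(0)
  for (i in seq_along(rois)) {
    roi <- rois[[i]]
    lab <- roi$labels
    storage.mode(lab) <- "integer"
    d <- roi$dapi; m <- roi$mem
    px_dim <- if (is_raster(d)) c(d$height, d$width) else dim(d)
    if (!all(dim(lab) == px_dim))
      stop(sprintf("ROI %d: label map does not align with rasters", i))
    if (!any(lab > 0L)) {
      excluded <- c(excluded, i)
      next
    }
    if (is_raster(d) && d$bit_depth == 16L) d <- convert_16_to_8(d)
    if (is_raster(m) && m$bit_depth == 16L) m <- convert_16_to_8(m)
    sci <- stack_dapi_mem(d, m)
    sci_up <- upscale_2x_nearest(sci)
    chans <- normalize_channels(sci_up, normalize_mode)
    lab_up <- upscale_2x_nearest(lab)
    items[[length(items) + 1L]] <- list(
      channels = chans, instances = lab_up,
      masks = instances_to_mask_stack(lab_up), sci = sci_up, roi_index = i)
  }
  structure(list(items = items, policy = policy, excluded = excluded,
                 normalize_mode = normalize_mode),
            class = "TrainingDataset")
}

#' @export
print.TrainingDataset <- function(x, ...) {
  cat(sprintf("<TrainingDataset: %d item(s), %d excluded>\n",
              length(x$items), length(x$excluded)))
  invisible(x)
}

#' Sample an augmented batch from a training dataset
#'
#' Applies the dataset's augmentation policy to the selected items;
#' byte-identical for a fixed seed.
#'
#' @param dataset a [build_training_dataset()] result.
#' @param indices item indices.
#' @param seed integer seed.
#' @return list of augmented items (`image` = stacked color image, `masks`).
#' @export
sample_training_batch <- function(dataset, indices, seed = 1L) {
  lapply(seq_along(indices), function(k) {
    it <- dataset$items[[indices[k]]]
    augment(it$sci, it$masks, dataset$policy,
            seed = seed + 7919L * (indices[k] - 1L))
  })
}

# ---- backend contract ------------------------------------------------------

#' Initialize an instance segmentation backend
#' @param backend backend object.
#' @param weights_source pretrained-weights identifier.
#' @param config a [training_config()].
#' @return the initialized backend.
#' @export
backend_initialize <- function(backend, weights_source, config)
  UseMethod("backend_initialize")

#' Fine-tune an instance segmentation backend
#' @param backend backend object.
#' @param dataset a `TrainingDataset`.
#' @param config a [training_config()].
#' @param stage `"heads_only"` or `"all_layers"`.
#' @return the fine-tuned backend (with `training_log` grown).
#' @export
backend_fine_tune <- function(backend, dataset, config,
                              stage = c("heads_only", "all_layers"))
  UseMethod("backend_fine_tune")

#' Predict instance masks with a backend
#' @param backend trained backend.
#' @param sci a `StackedColorImage`.
#' @return list of `list(mask = logical matrix, score = confidence in
#'   \[0, 1\])`.
#' @export
backend_predict <- function(backend, sci) UseMethod("backend_predict")

# ---- reference backend -----------------------------------------------------

#' CPU reference instance segmentation backend
#'
#' Proposal-free stand-in for the heavy region-proposal backend: a
#' three-class pixel model (cell interior / boundary / background) over the
#' stacked color image, decoded to instances by connected components. Its
#' "heads" are the output layer of the pixel model; "all layers" trains the
#' full model. Confidence of a predicted mask is the mean probability of
#' non-background over the mask.
#'
#' @param hidden hidden width of the pixel model.
#' @param lr internal Adam learning rate (the published SGD rate applies to
#'   the heavy backend; see the methods vignette for the mapping).
#' @return a `ReferenceBackend`.
#' @export
reference_backend <- function(hidden = 16L, lr = 0.01) {
  structure(list(hidden = as.integer(hidden), lr = lr,
                 model = NULL, init_seed = NULL, training_log = list()),
            class = c("ReferenceBackend", "InstanceSegBackend"))
}

#' @export
print.ReferenceBackend <- function(x, ...) {
  cat(sprintf("<ReferenceBackend: hidden %d, %s, %d log entr%s>\n",
              x$hidden,
              if (is.null(x$model)) "uninitialized"
              else if (isTRUE(attr(x$model, "fitted"))) "trained" else "initialized",
              length(x$training_log),
              if (length(x$training_log) == 1L) "y" else "ies"))
  invisible(x)
}

#' @export
backend_initialize.ReferenceBackend <- function(backend, weights_source,
                                                config) {
  seed <- if (is.numeric(weights_source)) as.integer(weights_source)
          else config$seed
  backend$init_seed <- seed
  backend$model <- NULL       # weights materialize at first fine-tune
  backend$training_log <- list()
  backend
}

ref_backend_xy <- function(dataset) {
  Xs <- list(); ys <- list()
  for (it in dataset$items) {
    Xs[[length(Xs) + 1L]] <- pixel_features(list(it$channels$r,
                                                 it$channels$g))
    ys[[length(ys) + 1L]] <-
      as.integer(as.vector(instances_to_three_class(it$instances)))
  }
  list(X = do.call(rbind, Xs), y = unlist(ys))
}

#' @export
backend_fine_tune.ReferenceBackend <- function(backend, dataset, config,
                                               stage = c("heads_only",
                                                         "all_layers")) {
  stage <- match.arg(stage)
  epochs <- if (stage == "heads_only") config$heads_epochs
            else config$all_layers_epochs
  if (epochs == 0L) return(backend)   # identity schedule
  if (!length(dataset$items)) stop("empty training dataset")
  xy <- ref_backend_xy(dataset)
  st <- backend$model
  if (is.null(st)) {
    feat_mean <- colMeans(xy$X)
    feat_sd <- pmax(sqrt(colMeans(sweep(xy$X, 2L, feat_mean)^2)), 1e-8)
    params <- mlp_init(ncol(xy$X), backend$hidden,
                       if (is.null(backend$init_seed)) config$seed
                       else backend$init_seed)
    st <- list(params = params, feat_mean = feat_mean, feat_sd = feat_sd)
  }
  X <- sweep(sweep(xy$X, 2L, st$feat_mean), 2L, st$feat_sd, "/")
  freq <- tabulate(xy$y + 1L, nbins = 3L)
  w <- ifelse(freq > 0, sum(freq) / (3 * pmax(freq, 1)), 0)
  fit <- mlp_train(st$params, X, xy$y, epochs, lr = backend$lr,
                   class_weights = w, grad_clip = config$gradient_clip,
                   heads_only = (stage == "heads_only"))
  st$params <- fit$params
  attr(st, "fitted") <- TRUE
  backend$model <- st
  backend$training_log[[length(backend$training_log) + 1L]] <-
    list(stage = stage, epochs = epochs, loss = fit$loss_log)
  backend
}

#' @export
backend_predict.ReferenceBackend <- function(backend, sci) {
  if (is.null(backend$model) || !isTRUE(attr(backend$model, "fitted")))
    stop("backend is not trained")
  chans <- if (is_sci(sci)) normalize_channels(sci, "zscore") else sci
  st <- backend$model
  X <- pixel_features(list(chans$r, chans$g))
  X <- sweep(sweep(X, 2L, st$feat_mean), 2L, st$feat_sd, "/")
  H <- pmax(sweep(X %*% st$params$W1, 2L, st$params$b1, "+"), 0)
  P <- softmax_rows(sweep(H %*% st$params$W2, 2L, st$params$b2, "+"))
  nr <- nrow(chans$r); nc <- ncol(chans$r)
  map <- matrix(max.col(P, ties.method = "first") - 1L, nr, nc)
  inst <- three_class_to_instances(map)
  p_fg <- matrix(1 - P[, 1], nr, nc)
  labs <- setdiff(unique(as.vector(inst)), 0L)
  lapply(labs, function(l) {
    m <- inst == l
    list(mask = m, score = min(1, max(0, mean(p_fg[m]))))
  })
}

#' Serialize a reference backend to a JSON checkpoint
#' @param backend a trained `ReferenceBackend`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference_backend <- function(backend, path) {
  st <- backend$model
  obj <- list(hidden = backend$hidden, lr = backend$lr,
              init_seed = backend$init_seed,
              fitted = isTRUE(attr(st, "fitted")),
              feat_mean = st$feat_mean, feat_sd = st$feat_sd,
              params = lapply(st$params, function(p)
                if (is.matrix(p)) list(dim = dim(p), data = as.vector(p))
                else list(dim = NULL, data = p)),
              training_log = backend$training_log)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a reference backend from a JSON checkpoint
#' @param path checkpoint path.
#' @return a `ReferenceBackend`.
#' @export
read_reference_backend <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  backend <- reference_backend(obj$hidden, obj$lr)
  backend$init_seed <- obj$init_seed
  st <- list(params = lapply(obj$params, function(p) {
    if (!is.null(p$dim) && length(p$dim)) matrix(p$data, p$dim[1], p$dim[2])
    else as.numeric(p$data)
  }), feat_mean = obj$feat_mean, feat_sd = obj$feat_sd)
  if (isTRUE(obj$fitted)) attr(st, "fitted") <- TRUE
  backend$model <- st
  backend
}

# ---- harness ---------------------------------------------------------------

#' Run two-stage domain adaptation
#'
#' For each stage present in the plan (weak stage first, manual stage
#' second): heads-only fine-tuning for `heads_epochs`, then all-layers
#' fine-tuning for `all_layers_epochs`, with gradient clipping throughout.
#' Omitting `stage1` gives the single-stage comparison arm (natural-image
#' pretraining followed directly by manual fine-tuning).
#'
#' @param backend backend object (see [reference_backend()]).
#' @param plan a [domain_adaptation_plan()].
#' @param config a [training_config()].
#' @return the trained backend; its `training_log` holds the per-stage
#'   per-epoch loss trace.
#' @export
run_two_stage_adaptation <- function(backend, plan, config = training_config()) {
  if (is.null(plan$stage2)) stop("plan lacks the stage2 (manual) dataset")
  backend <- backend_initialize(backend, plan$init, config)
  stages <- if (is.null(plan$stage1)) list(plan$stage2)
            else list(plan$stage1, plan$stage2)
  for (ds in stages) {
    backend <- backend_fine_tune(backend, ds, config, "heads_only")
    backend <- backend_fine_tune(backend, ds, config, "all_layers")
  }
  backend
}

#' Desk-scale two-stage vs single-stage adaptation comparison
#'
#' Replays, at desk scale on synthetic data, the small-sample comparison
#' between the two training arms: weak-label pre-training followed by
#' manual fine-tuning on a single ROI, versus manual fine-tuning alone.
#' The weak domain is a clean packed sheet labelled by the classical
#' weak-label pipeline; the target domain is small, noisy and dimly
#' stained, so a single manual ROI is genuinely data-limited. Held-out
#' object-Dice is averaged over the given seeds per arm.
#'
#' @param seeds integer vector of experiment seeds (one independent data
#'   draw + model initialization per seed).
#' @param n_weak number of weak-label ROIs for stage 1.
#' @param n_test held-out target ROIs per seed.
#' @param config a [training_config()] (the seed field is overridden per
#'   run).
#' @return data.frame with one row per seed and columns `seed`,
#'   `od_two_stage`, `od_single_stage`.
#' @export
run_adaptation_comparison <- function(seeds = 1:5, n_weak = 4L, n_test = 3L,
                                      config = training_config()) {
  target_roi <- function(s)
    generate_roi(synth_config(frame = c(64L, 64L), n_cells = 4L, seed = s,
                              noise_sd = 2500,
                              membrane_intensity_range = c(6000, 12000),
                              nucleus_intensity_range = c(12000, 20000),
                              membrane_break_probability = 0.1))
  run_arm <- function(seed, use_weak) {
    weak_rois <- lapply(seed * 1000L + seq_len(n_weak), function(s) {
      roi <- generate_roi(synth_config(frame = c(96L, 96L), n_cells = 9L,
                                       seed = s,
                                       membrane_break_probability = 0.2))
      nuc <- segment_nuclei_classic(roi$dapi)
      weak <- generate_weak_labels(roi$dapi, roi$mem, nuc)
      list(dapi = roi$dapi, mem = roi$mem, labels = weak$instances)
    })
    manual <- {
      roi <- target_roi(seed * 1000L + 50L)
      list(dapi = roi$dapi, mem = roi$mem, labels = roi$gt_cells)
    }
    tests <- lapply(seed * 1000L + 59L + seq_len(n_test), target_roi)
    plan <- domain_adaptation_plan(
      init = seed,
      stage1 = if (use_weak) build_training_dataset(weak_rois),
      stage2 = build_training_dataset(list(manual)))
    cfg <- config
    cfg$seed <- as.integer(seed)
    be <- run_two_stage_adaptation(reference_backend(), plan, cfg)
    mean(vapply(tests, function(roi)
      object_dice(predict_instances(be, roi$dapi, roi$mem), roi$gt_cells),
      numeric(1)))
  }
  data.frame(seed = seeds,
             od_two_stage = vapply(seeds, run_arm, numeric(1),
                                   use_weak = TRUE),
             od_single_stage = vapply(seeds, run_arm, numeric(1),
                                      use_weak = FALSE))
}

#' Predict an instance label map for a two-channel ROI
#'
#' Builds the stacked color image exactly as in training (bit conversion,
#' DAPI-MEM-DAPI stacking, 2x upscaling), runs the backend, keeps masks
#' with confidence at or above `score_threshold`, resolves overlapping
#' pixels towards the higher-confidence mask, and downscales back to the
#' original resolution.
#'
#' @param backend trained backend.
#' @param dapi,mem input rasters (16- or 8-bit).
#' @param score_threshold confidence cut-off (default 0.5).
#' @return integer instance label map at the input resolution.
#' @export
predict_instances <- function(backend, dapi, mem, score_threshold = 0.5) {
  if (is_raster(dapi) && dapi$bit_depth == 16L) dapi <- convert_16_to_8(dapi)
  if (is_raster(mem) && mem$bit_depth == 16L) mem <- convert_16_to_8(mem)
  sci <- upscale_2x_nearest(stack_dapi_mem(dapi, mem))
  preds <- backend_predict(backend, sci)
  keep <- Filter(function(p) p$score >= score_threshold, preds)
  out_up <- matrix(0L, nrow(sci$r), ncol(sci$r))
  if (length(keep)) {
    conf <- matrix(-Inf, nrow(sci$r), ncol(sci$r))
    ord <- order(vapply(keep, function(p) p$score, numeric(1)))
    for (i in ord) {           # ascending: higher scores overwrite
      m <- keep[[i]]$mask
      win <- m & keep[[i]]$score > conf
      out_up[win] <- i
      conf[win] <- keep[[i]]$score
    }
    # renumber consecutively
    labs <- setdiff(unique(as.vector(out_up)), 0L)
    re <- integer(max(c(labs, 1L)))
    re[labs] <- seq_along(labs)
    out_up[out_up > 0L] <- re[out_up[out_up > 0L]]
  }
  downscale_2x(out_up)
}
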