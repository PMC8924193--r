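roi_as_item <- function(roi, labels = roi$gt_cells)
  list(dapi = roi$dapi, mem = roi$mem, labels = labels)

test_that("build_training_dataset applies the full input pipeline", {
  roi <- fx_small_roi(seed = 3, frame = c(48L, 48L), n_cells = 4L)
  ds <- build_training_dataset(list(roi_as_item(roi)))
  expect_length(ds$items, 1L)
  it <- ds$items[[1]]
  # dimensions doubled, one mask per cell
  expect_equal(dim(it$channels$r), c(96L, 96L))
  expect_length(it$masks, roi$generated_cells)
  # channels are z-scored per image
  expect_equal(mean(it$channels$g), 0, tolerance = 1e-9)
  expect_equal(stats::sd(as.vector(it$channels$g)), 1, tolerance = 1e-9)
  # upscaled label map downscales back to the 8-bit original partition
  expect_identical(downscale_2x(it$instances), roi$gt_cells)
  # empty label map is excluded and logged
  ds2 <- build_training_dataset(list(
    roi_as_item(roi), roi_as_item(roi, matrix(0L, 48L, 48L))))
  expect_length(ds2$items, 1L)
  expect_equal(ds2$excluded, 2L)
  # misaligned labels are fatal
  expect_error(build_training_dataset(list(
    roi_as_item(roi, matrix(1L, 10L, 10L)))), "align")
})

test_that("sampled augmented batches are reproducible", {
  roi <- fx_small_roi(seed = 4, frame = c(32L, 32L), n_cells = 3L)
  ds <- build_training_dataset(list(roi_as_item(roi)))
  b1 <- sample_training_batch(ds, 1L, seed = 5L)
  b2 <- sample_training_batch(ds, 1L, seed = 5L)
  expect_identical(b1, b2)
})

test_that("zero-epoch schedules leave the backend untouched", {
  roi <- fx_small_roi(seed = 5, frame = c(32L, 32L), n_cells = 3L)
  ds <- build_training_dataset(list(roi_as_item(roi)))
  cfg <- training_config(heads_epochs = 0L, all_layers_epochs = 0L)
  be <- backend_initialize(reference_backend(), "random", cfg)
  be2 <- run_two_stage_adaptation(reference_backend(),
                                  domain_adaptation_plan(stage2 = ds), cfg)
  expect_null(be2$model)
  expect_identical(be$training_log, be2$training_log)
})

test_that("the plan without stage1 runs exactly one fine-tuning stage", {
  roi <- fx_small_roi(seed = 6, frame = c(32L, 32L), n_cells = 3L)
  ds <- build_training_dataset(list(roi_as_item(roi)))
  cfg <- training_config(heads_epochs = 2L, all_layers_epochs = 3L)
  be <- run_two_stage_adaptation(reference_backend(),
                                 domain_adaptation_plan(stage2 = ds), cfg)
  stages <- vapply(be$training_log, `[[`, character(1), "stage")
  expect_equal(stages, c("heads_only", "all_layers"))
  # with stage1 present there are two stage blocks
  be2 <- run_two_stage_adaptation(
    reference_backend(),
    domain_adaptation_plan(stage1 = ds, stage2 = ds), cfg)
  expect_equal(vapply(be2$training_log, `[[`, character(1), "stage"),
               rep(c("heads_only", "all_layers"), 2))
  expect_error(domain_adaptation_plan(stage1 = ds, stage2 = NULL),
               "stage2")
})

test_that("training losses stay finite under the clip rule", {
  roi <- fx_small_roi(seed = 7, frame = c(32L, 32L), n_cells = 3L)
  ds <- build_training_dataset(list(roi_as_item(roi)))
  cfg <- training_config(heads_epochs = 5L, all_layers_epochs = 10L)
  be <- run_two_stage_adaptation(reference_backend(),
                                 domain_adaptation_plan(stage2 = ds), cfg)
  for (entry in be$training_log)
    expect_true(all(is.finite(entry$loss)))
})

test_that("heads-only fine-tuning freezes the trunk", {
  roi <- fx_small_roi(seed = 8, frame = c(32L, 32L), n_cells = 3L)
  ds <- build_training_dataset(list(roi_as_item(roi)))
  cfg <- training_config(heads_epochs = 5L, all_layers_epochs = 0L)
  be <- backend_initialize(reference_backend(), 1L, cfg)
  be <- backend_fine_tune(be, ds, cfg, "heads_only")
  init <- mxifseg:::mlp_init(ncol(mxifseg:::ref_backend_xy(ds)$X), 16L, 1L)
  expect_identical(be$model$params$W1, init$W1)
  expect_false(identical(be$model$params$W2, init$W2))
})

test_that("predict_instances yields a valid partition with overlap rules", {
  roi <- fx_small_roi(seed = 9, frame = c(48L, 48L), n_cells = 4L)
  ds <- build_training_dataset(list(roi_as_item(roi)))
  cfg <- training_config(heads_epochs = 10L, all_layers_epochs = 30L)
  be <- run_two_stage_adaptation(reference_backend(),
                                 domain_adaptation_plan(stage2 = ds), cfg)
  pred <- predict_instances(be, roi$dapi, roi$mem)
  expect_equal(dim(pred), c(48L, 48L))
  expect_true(all(pred >= 0L))
  # trained on the same ROI: should align well with ground truth
  expect_gt(object_dice(pred, roi$gt_cells), 0.7)
  # threshold above 1 removes every mask
  empty <- predict_instances(be, roi$dapi, roi$mem, score_threshold = 1.01)
  expect_true(all(empty == 0L))
  # full run is reproducible
  be2 <- run_two_stage_adaptation(reference_backend(),
                                  domain_adaptation_plan(stage2 = ds), cfg)
  expect_identical(pred, predict_instances(be2, roi$dapi, roi$mem))
})

test_that("overlapping masks resolve towards the higher confidence", {
  # exercise the overlap rule directly through a stub backend
  stub <- structure(list(), class = c("StubBackend", "InstanceSegBackend"))
  m1 <- matrix(FALSE, 8, 8); m1[1:6, 1:6] <- TRUE
  m2 <- matrix(FALSE, 8, 8); m2[4:8, 4:8] <- TRUE
  stub_fun <- function(backend, sci)
    list(list(mask = upscale_2x_nearest(m1), score = 0.9),
         list(mask = upscale_2x_nearest(m2), score = 0.6))
  registerS3method("backend_predict", "StubBackend", stub_fun,
                   envir = asNamespace("mxifseg"))
  d <- fx_raster(matrix(0L, 8, 8))
  pred <- predict_instances(stub, d, d)
  # shared pixels belong to the 0.9 mask
  expect_true(all(pred[4:6, 4:6] == pred[1, 1]))
  expect_equal(length(setdiff(unique(as.vector(pred)), 0L)), 2L)
})

test_that("reference backend checkpoints round-trip", {
  roi <- fx_small_roi(seed = 10, frame = c(32L, 32L), n_cells = 3L)
  ds <- build_training_dataset(list(roi_as_item(roi)))
  cfg <- training_config(heads_epochs = 3L, all_layers_epochs = 5L)
  be <- run_two_stage_adaptation(reference_backend(),
                                 domain_adaptation_plan(stage2 = ds), cfg)
  p <- withr::local_tempfile(fileext = ".json")
  write_reference_backend(be, p)
  back <- read_reference_backend(p)
  expect_identical(predict_instances(back, roi$dapi, roi$mem),
                   predict_instances(be, roi$dapi, roi$mem))
})
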