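test_that("the semantic model memorizes a single ROI", {
  roi <- fx_small_roi(seed = 5, frame = c(64L, 64L), n_cells = 4L,
                      noise_sd = 300)
  tc <- instances_to_three_class(roi$gt_nuclei)
  m <- train_three_class(semantic_model(),
                         list(list(raster = roi$dapi, map = tc)),
                         epochs = 200L, seed = 1L)
  pred <- predict_three_class(m, roi$dapi)
  expect_gte(mean(pred$map == tc), 0.95)
  # loss trend is non-increasing overall (first quarter vs last quarter)
  n <- length(m$loss_log)
  expect_lt(mean(m$loss_log[(3 * n %/% 4):n]),
            mean(m$loss_log[1:(n %/% 4)]))
  # prediction is deterministic for a fixed trained state
  expect_identical(pred$map, predict_three_class(m, roi$dapi)$map)
  expect_equal(dim(pred$scores), c(64L, 64L, 3L))
  expect_equal(max(abs(apply(pred$scores, c(1, 2), sum) - 1)), 0,
               tolerance = 1e-8)
})

test_that("training on all-background labels predicts all background", {
  r <- fx_raster(matrix(sample.int(200, 32 * 32, TRUE), 32, 32))
  m <- train_three_class(semantic_model(),
                         list(list(raster = r,
                                   map = matrix(0L, 32, 32))),
                         epochs = 50L, seed = 2L)
  pred <- predict_three_class(m, r)
  expect_true(all(pred$map == 0L))
})

test_that("duplicated pairs equal a single pair under full-batch training", {
  roi <- fx_small_roi(seed = 7, frame = c(32L, 32L), n_cells = 3L)
  tc <- instances_to_three_class(roi$gt_nuclei)
  one <- train_three_class(semantic_model(),
                           list(list(raster = roi$dapi, map = tc)),
                           epochs = 30L, seed = 3L)
  two <- train_three_class(semantic_model(),
                           list(list(raster = roi$dapi, map = tc),
                                list(raster = roi$dapi, map = tc)),
                           epochs = 30L, seed = 3L)
  expect_equal(one$params, two$params, tolerance = 1e-10)
  expect_equal(one$loss_log, two$loss_log, tolerance = 1e-10)
})

test_that("train_three_class validates inputs", {
  roi <- fx_small_roi(seed = 8, frame = c(32L, 32L), n_cells = 3L)
  expect_error(train_three_class(semantic_model(), list()), "empty")
  expect_error(train_three_class(
    semantic_model(),
    list(list(raster = roi$dapi, map = matrix(0L, 16, 16)))),
    "dimensions")
  expect_error(predict_three_class(semantic_model(), roi$dapi),
               "not trained")
})

test_that("semantic model checkpoints round-trip through JSON", {
  roi <- fx_small_roi(seed = 9, frame = c(32L, 32L), n_cells = 3L)
  tc <- instances_to_three_class(roi$gt_nuclei)
  m <- train_three_class(semantic_model(hidden = 8L),
                         list(list(raster = roi$dapi, map = tc)),
                         epochs = 20L, seed = 4L)
  p <- withr::local_tempfile(fileext = ".json")
  write_semantic_model(m, p)
  back <- read_semantic_model(p)
  expect_identical(predict_three_class(back, roi$dapi)$map,
                   predict_three_class(m, roi$dapi)$map)
})

test_that("bootstrap_schedule reproduces the weak-set bookkeeping", {
  sch <- bootstrap_schedule(26L, 16L, 168L)
  expect_equal(sch$pool_size, c(26L, 42L, 42L))
  expect_equal(sch$predictions, c(0L, 0L, 168L))
})

test_that("run_bootstrap grows the pool and reports provenance", {
  rois <- lapply(1:4, function(s)
    fx_small_roi(seed = 20 + s, frame = c(48L, 48L), n_cells = 4L,
                 noise_sd = 300))
  rasters <- lapply(rois, `[[`, "dapi")
  res <- run_bootstrap(rasters[1:2], rasters[3], rasters[4],
                       edit_provider = function(raster, result)
                         edit_overlay(),
                       model_factory = function() semantic_model(hidden = 8L),
                       config = list(epochs = 40L, seed = 1L))
  expect_equal(res$state$pool_sizes, c(2L, 3L, 3L))
  expect_equal(res$state$n_predictions, 1L)
  prov <- vapply(res$state$labeled_pool, `[[`, character(1), "provenance")
  expect_equal(prov, c("classic+edits", "classic+edits", "model+edits"))
  expect_length(res$labels$set3, 1L)
  expect_s3_class(res$labels$set3[[1]], "NuclearSegResult")
  expect_error(run_bootstrap(list(), rasters[3], rasters[4],
                             function(...) edit_overlay(),
                             function() semantic_model()),
               "empty set1")
  # manifest written with one entry per pool item
  p <- withr::local_tempfile(fileext = ".json")
  write_bootstrap_manifest(res$state, p)
  man <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(nrow(man$items), 3L)
})

test_that("bootstrap is reproducible from (config, seed)", {
  rois <- lapply(1:3, function(s)
    fx_small_roi(seed = 30 + s, frame = c(48L, 48L), n_cells = 4L,
                 noise_sd = 300))
  rasters <- lapply(rois, `[[`, "dapi")
  run <- function() run_bootstrap(
    rasters[1], rasters[2], rasters[3],
    edit_provider = function(raster, result) edit_overlay(),
    model_factory = function() semantic_model(hidden = 8L),
    config = list(epochs = 30L, seed = 7L))
  a <- run(); b <- run()
  expect_identical(a$labels$set3[[1]]$instances,
                   b$labels$set3[[1]]$instances)
  expect_equal(a$model$params, b$model$params, tolerance = 0)
})

test_that("oracle edits never increase foreground disagreement", {
  for (s in 1:3) {
    roi <- fx_small_roi(seed = 40 + s, frame = c(64L, 64L), n_cells = 4L)
    res <- segment_nuclei_classic(roi$dapi)
    ov <- oracle_edit_provider(res, roi$gt_nuclei)
    fixed <- suppressWarnings(apply_edit_overlay(res, ov))
    dis <- function(x) mean((x$instances > 0L) != (roi$gt_nuclei > 0L))
    expect_lte(dis(fixed), dis(res))
  }
})
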