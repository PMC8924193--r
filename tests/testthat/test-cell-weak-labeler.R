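test_that("erode_markers shrinks objects and keeps tiny ones", {
  # 3x3 square erodes to its centre pixel (cross element)
  inst <- fx_rects(7, 7, list(c(3, 5, 3, 5)))
  er <- erode_markers(inst)
  expect_equal(which(er == 1L, arr.ind = TRUE)[1, ], c(row = 4L, col = 4L))
  expect_equal(sum(er > 0L), 1L)
  # 5x5 square erodes to a 3x3 centre block
  inst2 <- fx_rects(9, 9, list(c(3, 7, 3, 7)))
  er2 <- erode_markers(inst2)
  expect_equal(sum(er2 == 1L), 9L)
  expect_true(all(er2[4:6, 4:6] == 1L))
  # 1-pixel object is retained at its centroid
  inst3 <- matrix(0L, 5, 5); inst3[2, 4] <- 1L
  er3 <- erode_markers(inst3)
  expect_equal(er3[2, 4], 1L)
  expect_equal(sum(er3 > 0L), 1L)
})

test_that("cell_watershed floods the whole frame from markers", {
  # one marker, flat membrane -> whole frame one region
  mk <- matrix(0L, 8, 8); mk[4, 4] <- 1L
  expect_true(all(cell_watershed(matrix(0, 8, 8), mk) == 1L))
  # two markers separated by a bright ridge -> border on the ridge crest
  mem <- matrix(0, 9, 11); mem[, 6] <- 100
  mk2 <- matrix(0L, 9, 11); mk2[5, 3] <- 1L; mk2[5, 9] <- 2L
  ws <- cell_watershed(mem, mk2)
  expect_true(all(ws[, 1:5] == 1L))
  expect_true(all(ws[, 7:11] == 2L))
  expect_true(all(ws %in% 1:2))  # ridge itself assigned, frame covered
})

test_that("cell_watershed equals the shared watershed oracle", {
  set.seed(51)
  for (i in 1:6) {
    elev <- matrix(sample.int(6, 12 * 12, replace = TRUE), 12, 12)
    mk <- matrix(0L, 12, 12)
    pos <- sample.int(144, 3)
    mk[pos] <- 1:3
    expect_identical(cell_watershed(elev, mk), oracle_watershed(elev, mk))
  }
})

test_that("size_filter_background applies the inclusive 1400 px rule", {
  # 1400-px region (35 x 40) removed; 1399-px region retained
  big <- fx_rects(60, 60, list(c(1, 35, 1, 40)))
  expect_true(all(size_filter_background(big) == 0L))
  small <- matrix(0L, 60, 60)
  small[1:35, 1:40] <- 1L
  small[35, 40] <- 0L  # 1399 px
  expect_equal(sum(size_filter_background(small) == 1L), 1399L)
  # empty map passes through; filter only deletes
  expect_true(all(size_filter_background(matrix(0L, 4, 4)) == 0L))
  mixed <- fx_rects(60, 60, list(c(1, 35, 1, 40), c(40, 45, 40, 45)))
  out <- size_filter_background(mixed)
  expect_true(all(out[mixed == 1L] == 0L))
  expect_true(all(out[mixed == 2L] == 2L))
})

test_that("make_cell_map matches the three-class derivation", {
  inst <- fx_rects(5, 5, list(c(2, 4, 2, 4)))
  cm <- make_cell_map(inst)
  expect_equal(sum(cm == 2L), 8L)   # black boundary
  expect_equal(sum(cm == 1L), 1L)   # white interior
  expect_equal(sum(cm == 0L), 16L)  # grey background
  expect_equal(attr(cm, "semantics"), "cell")
  expect_true(all(make_cell_map(matrix(0L, 3, 3)) == 0L))
})

test_that("mask stacks are disjoint, complete and invertible", {
  inst <- fx_random_instances(20, 20, 5, seed = 8, fg_prob = 0.8)
  stack <- instances_to_mask_stack(inst)
  expect_equal(length(stack), length(setdiff(unique(as.vector(inst)), 0L)))
  acc <- Reduce(`+`, lapply(stack, function(m) m * 1L))
  expect_true(all(acc <= 1L))                      # pairwise disjoint
  expect_identical(acc == 1L, inst > 0L)           # union = object pixels
  labs <- as.integer(names(stack))
  expect_identical(mask_stack_to_instances(stack, labs), inst)
  expect_length(instances_to_mask_stack(matrix(0L, 3, 3)), 0L)
})

test_that("generate_weak_labels yields one cell per nucleus on clean data", {
  roi <- fx_small_roi(seed = 9, noise_sd = 0, membrane_break_probability = 0)
  nuc <- segment_nuclei_classic(roi$dapi)
  weak <- generate_weak_labels(roi$dapi, roi$mem, nuc)
  expect_equal(length(weak$mask_stack), roi$generated_cells)
  # every surviving cell contains its eroded nuclear marker
  markers <- erode_markers(nuc$instances)
  for (l in setdiff(unique(as.vector(weak$instances)), 0L)) {
    mk_px <- which(markers == l)
    expect_true(all(weak$instances[mk_px] == l))
  }
  # cell count never exceeds nuclear count
  expect_lte(max(weak$instances), max(nuc$instances))
  # no nuclei -> empty output
  empty <- generate_weak_labels(roi$dapi, roi$mem,
                                nuclear_seg_result(matrix(0L, 96, 96)))
  expect_length(empty$mask_stack, 0L)
})

test_that("a blank membrane with one nucleus is removed by the size filter", {
  dapi <- matrix(0L, 64, 64)
  dapi[fx_disk(64, 64, 32, 32, 5)] <- 200L
  mem <- fx_raster(matrix(0L, 64, 64))
  nuc <- segment_nuclei_classic(fx_raster(dapi))
  expect_equal(max(nuc$instances), 1L)
  weak <- generate_weak_labels(fx_raster(dapi), mem, nuc)
  # the single watershed region spans the 4096-px frame -> filtered out
  expect_length(weak$mask_stack, 0L)
  # with a large enough threshold it survives as a single frame-wide cell
  weak2 <- generate_weak_labels(fx_raster(dapi), mem, nuc, max_area = 5000L)
  expect_length(weak2$mask_stack, 1L)
})

test_that("membrane breaks degrade weak-label fidelity monotonically", {
  od <- vapply(c(0, 0.5), function(p) {
    roi <- fx_small_roi(seed = 12, noise_sd = 0,
                        membrane_break_probability = p)
    nuc <- segment_nuclei_classic(roi$dapi)
    weak <- generate_weak_labels(roi$dapi, roi$mem, nuc)
    object_dice(weak$instances, roi$gt_cells)
  }, numeric(1))
  expect_gt(od[1], od[2])
})
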