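test_that("otsu_threshold separates a bimodal image and matches brute force", {
  r <- fx_raster(matrix(c(rep(10L, 50), rep(200L, 50)), 10, 10))
  thr <- otsu_threshold(r)
  expect_true(thr >= 10 && thr < 200)
  expect_equal(as.numeric(thr), oracle_otsu(r$pixels))
})

test_that("otsu_threshold equals the exhaustive oracle on random images", {
  set.seed(21)
  for (i in 1:25) {
    m <- matrix(sample.int(256, 12 * 12, replace = TRUE) - 1L, 12, 12)
    expect_equal(as.numeric(otsu_threshold(fx_raster(m))),
                 oracle_otsu(m), info = paste("case", i))
  }
})

test_that("otsu_threshold flags constant images as degenerate", {
  expect_warning(thr <- otsu_threshold(fx_raster(matrix(42L, 5, 5))),
                 "degenerate")
  expect_equal(as.numeric(thr), 42)
  expect_true(attr(thr, "degenerate"))
})

test_that("distance_seeds marks disk centres and respects suppression", {
  disk <- fx_disk(21, 21, 11, 11, 7)
  mk <- distance_seeds(disk)
  expect_equal(sum(mk > 0L), 1L)
  expect_equal(which(mk == 1L, arr.ind = TRUE)[1, ], c(row = 11, col = 11))
  # two disjoint disks -> two markers
  two <- fx_disk(21, 41, 11, 10, 6) | fx_disk(21, 41, 11, 31, 6)
  mk2 <- distance_seeds(two)
  expect_equal(max(mk2), 2L)
  # empty mask -> empty markers
  expect_true(all(distance_seeds(matrix(FALSE, 5, 5)) == 0L))
  # every marker lies inside the foreground
  expect_true(all(two[mk2 > 0L]))
})

test_that("seeded_watershed handles trivial and symmetric cases", {
  # one marker, flat elevation, full mask -> one region everywhere
  elev <- matrix(0, 6, 6)
  mk <- matrix(0L, 6, 6); mk[3, 3] <- 1L
  expect_true(all(seeded_watershed(elev, mk) == 1L))
  # no markers -> all background
  expect_true(all(seeded_watershed(elev, matrix(0L, 6, 6)) == 0L))
  # two markers on a flat ridge split at the equidistant column
  elev2 <- matrix(0, 5, 7)
  mk2 <- matrix(0L, 5, 7); mk2[3, 1] <- 1L; mk2[3, 7] <- 2L
  ws <- seeded_watershed(elev2, mk2)
  expect_true(all(ws[, 1:3] == 1L))
  expect_true(all(ws[, 5:7] == 2L))
  expect_identical(ws, oracle_watershed(elev2, mk2))
  # markers outside the mask are rejected
  msk <- matrix(TRUE, 6, 6); msk[3, 3] <- FALSE
  expect_error(seeded_watershed(elev, mk, msk), "mask")
})

test_that("seeded_watershed equals the priority-flood oracle on random maps", {
  set.seed(31)
  for (i in 1:12) {
    elev <- matrix(sample.int(8, 16 * 16, replace = TRUE), 16, 16)
    k <- sample(2:4, 1)
    mk <- matrix(0L, 16, 16)
    pos <- sample.int(256, k)
    mk[pos] <- seq_len(k)
    mask <- if (i %% 3 == 0) matrix(runif(256) < 0.9, 16, 16) else NULL
    if (!is.null(mask)) mask[pos] <- TRUE
    got <- seeded_watershed(elev, mk, mask)
    expect_identical(got, oracle_watershed(elev, mk, mask),
                     info = paste("case", i))
    # labels are a subset of marker labels and cover reachable pixels
    expect_true(all(got %in% c(0L, seq_len(k))))
  }
})

test_that("instances_to_three_class labels boundaries and interiors", {
  # empty map -> all background
  expect_true(all(instances_to_three_class(matrix(0L, 4, 4)) == 0L))
  # single 3x3 square: 8 boundary + 1 interior
  inst <- fx_rects(5, 5, list(c(2, 4, 2, 4)))
  tc <- instances_to_three_class(inst)
  expect_equal(sum(tc == 2L), 8L)
  expect_equal(sum(tc == 1L), 1L)
  expect_equal(tc[3, 3], 1L)
  # two touching squares: the shared seam is boundary on both sides
  inst2 <- fx_rects(7, 9, list(c(2, 6, 2, 4), c(2, 6, 5, 7)))
  tc2 <- instances_to_three_class(inst2)
  expect_true(all(tc2[2:6, 4] == 2L))
  expect_true(all(tc2[2:6, 5] == 2L))
  expect_true(all(tc2[3:5, 3] == 1L))
})

test_that("three-class round trip recovers partitions with interiors", {
  set.seed(41)
  for (i in 1:8) {
    inst <- fx_rects(20, 20, list(c(2, 6, 2, 7), c(9, 14, 4, 9),
                                  c(16, 19, 12, 18)))
    tc <- instances_to_three_class(inst)
    back <- three_class_to_instances(tc)
    # same partition up to label names
    expect_equal(attr(back, "dropped"), 0L)
    expect_true(all((back > 0L) == (inst > 0L)))
    key <- table(inst[inst > 0L], back[inst > 0L])
    expect_true(all(rowSums(key > 0) == 1L), info = paste("case", i))
  }
  # all-background map -> empty instance map
  empty <- three_class_to_instances(matrix(0L, 5, 5))
  expect_true(all(empty == 0L))
  # lone boundary ring with no interior is dropped and reported
  ring <- matrix(0L, 5, 5)
  ring[2:4, 2:4] <- 2L; ring[3, 3] <- 2L
  out <- three_class_to_instances(ring)
  expect_true(all(out == 0L))
  expect_equal(attr(out, "dropped"), 9L)
})

test_that("apply_edit_overlay splits and removes objects", {
  # one object bisected by a straight vertical split line -> two objects
  inst <- fx_rects(9, 9, list(c(2, 8, 2, 8)))
  res <- nuclear_seg_result(inst)
  ov <- edit_overlay(split_lines = list(rbind(c(1L, 5L), c(9L, 5L))))
  split <- apply_edit_overlay(res, ov)
  expect_equal(max(split$instances), 2L)
  expect_true(all((split$instances > 0L) == (inst > 0L)))  # no pixel lost
  # removal contour around one of two objects leaves one object
  inst2 <- fx_rects(12, 12, list(c(2, 4, 2, 4), c(8, 11, 8, 11)))
  res2 <- nuclear_seg_result(inst2)
  ov2 <- edit_overlay(removal_contours = list(
    rbind(c(1L, 1L), c(1L, 6L), c(6L, 6L), c(6L, 1L))))
  rem <- apply_edit_overlay(res2, ov2)
  expect_equal(max(rem$instances), 1L)
  expect_true(all(rem$instances[8:11, 8:11] == 1L))
  # empty overlay is the identity
  same <- apply_edit_overlay(res2, edit_overlay())
  expect_true(all((same$instances > 0L) == (inst2 > 0L)))
  # overlay touching nothing warns and is a no-op
  ov3 <- edit_overlay(removal_contours = list(
    rbind(c(5L, 1L), c(5L, 6L), c(7L, 6L), c(7L, 1L))))
  expect_warning(noop <- apply_edit_overlay(res2, ov3), "no object")
  expect_equal(max(noop$instances), 2L)
  # out-of-bounds coordinates are rejected
  expect_error(apply_edit_overlay(res2, edit_overlay(
    split_lines = list(rbind(c(0L, 1L), c(3L, 3L))))), "bounds")
})

test_that("edits do not disturb pixels away from the edit bounding boxes", {
  inst <- fx_rects(15, 15, list(c(2, 6, 2, 6), c(9, 14, 9, 14)))
  res <- nuclear_seg_result(inst)
  ov <- edit_overlay(split_lines = list(rbind(c(2L, 4L), c(6L, 4L))))
  out <- apply_edit_overlay(res, ov)
  # the second object is untouched geometrically (relabelling aside)
  expect_true(all((out$instances[9:14, 9:14] > 0L)))
  far <- out$instances[9:14, 9:14]
  expect_equal(length(unique(as.vector(far))), 1L)
  # the first object is split into two
  expect_equal(length(setdiff(unique(as.vector(out$instances[2:6, 2:6])), 0L)),
               2L)
})

test_that("segment_nuclei_classic finds well-separated blobs", {
  # blank image -> empty result
  blank <- segment_nuclei_classic(fx_raster(matrix(0L, 16, 16)))
  expect_true(all(blank$instances == 0L))
  # synthetic nuclei: one instance per ground-truth nucleus
  roi <- fx_small_roi(seed = 6, frame = c(96L, 96L), n_cells = 9L,
                      noise_sd = 200)
  res <- segment_nuclei_classic(roi$dapi)
  expect_equal(max(res$instances), roi$generated_cells)
  # two overlapping blobs with distinct distance maxima -> 2 instances
  m <- matrix(0L, 25, 25)
  m[fx_disk(25, 25, 13, 8, 6)] <- 180L
  m[fx_disk(25, 25, 13, 18, 6)] <- 180L
  res2 <- segment_nuclei_classic(fx_raster(m))
  expect_equal(max(res2$instances), 2L)
})
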