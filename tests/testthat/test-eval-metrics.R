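test_that("dice handles identity, disjoint and partial overlap", {
  a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
  expect_equal(dice(a, a), 1)
  b <- matrix(FALSE, 4, 4); b[3:4, 3:4] <- TRUE
  expect_equal(dice(a, b), 0)
  # 2x2 squares overlapping in 2 px -> 0.5
  c2 <- matrix(FALSE, 4, 4); c2[2:3, 1:2] <- TRUE
  expect_equal(dice(a, c2), 0.5)
  expect_equal(dice(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 1)
})

test_that("hausdorff matches hand values and the brute-force oracle", {
  expect_equal(hausdorff(rbind(c(1, 1)), rbind(c(1, 1))), 0)
  expect_equal(hausdorff(rbind(c(0, 0)), rbind(c(3, 4))), 5)
  expect_error(hausdorff(matrix(numeric(0), 0, 2), rbind(c(1, 1))), "empty")
  set.seed(61)
  for (i in 1:20) {
    a <- cbind(sample.int(12, 6, TRUE), sample.int(12, 6, TRUE))
    b <- cbind(sample.int(12, 5, TRUE), sample.int(12, 5, TRUE))
    expect_equal(hausdorff(a, b), oracle_hausdorff(a, b))
  }
})

test_that("match_objects follows maximal overlap with low-label ties", {
  S <- fx_rects(10, 10, list(c(1, 5, 1, 10)))
  G <- fx_rects(10, 10, list(c(1, 5, 1, 6), c(1, 5, 7, 10)))
  m <- match_objects(S, G)
  expect_equal(m$s_match, 1L)      # 60 % overlap beats 40 %
  expect_equal(m$g_match, c(1L, 1L))
  # identity matching on identical maps
  mid <- match_objects(G, G)
  expect_equal(mid$s_match, mid$s_labels)
  # zero-overlap object picks the nearest boundary for OH
  S2 <- matrix(0L, 12, 12); S2[1:2, 1:2] <- 1L
  G2 <- matrix(0L, 12, 12); G2[4:5, 4:5] <- 1L; G2[10:11, 10:11] <- 2L
  m2 <- match_objects(S2, G2)
  expect_equal(m2$s_match, 0L)
  expect_equal(m2$s_match_oh, 1L)
  # one empty side is flagged
  expect_true(match_objects(matrix(0L, 12, 12), G2)$flagged)
  expect_error(match_objects(matrix(0L, 3, 3), G2), "dimensions")
})

test_that("object_dice identities and split example", {
  G <- fx_rects(10, 10, list(c(2, 8, 2, 5), c(2, 8, 6, 9)))
  expect_equal(object_dice(G, G), 1)
  # one object vs the same object split in half: equals the oracle
  S <- matrix(0L, 10, 10); S[G > 0L] <- 1L
  expect_equal(object_dice(S, G), oracle_object_dice(S, G))
  # S empty, G non-empty -> 0
  expect_equal(object_dice(matrix(0L, 10, 10), G), 0)
  expect_equal(object_dice(matrix(0L, 4, 4), matrix(0L, 4, 4)), 1)
})

test_that("object metrics equal the per-definition oracles on random maps", {
  set.seed(71)
  for (i in 1:30) {
    S <- fx_random_instances(16, 16, sample(2:4, 1), seed = 100 + i,
                             fg_prob = 0.85)
    G <- fx_random_instances(16, 16, sample(2:4, 1), seed = 200 + i,
                             fg_prob = 0.85)
    if (!any(S > 0L) || !any(G > 0L)) next
    m <- match_objects(S, G)
    expect_equal(object_dice(S, G, m), oracle_object_dice(S, G),
                 info = paste("OD case", i))
    expect_equal(object_hausdorff(S, G, m), oracle_object_hausdorff(S, G),
                 info = paste("OH case", i))
    od <- object_dice(S, G, m)
    expect_true(od >= 0 && od <= 1)
    # symmetry of the bidirectional forms
    expect_equal(od, object_dice(G, S))
    expect_equal(object_hausdorff(S, G), object_hausdorff(G, S))
  }
})

test_that("object_hausdorff identities and flags", {
  S <- fx_rects(8, 8, list(c(2, 4, 2, 4), c(6, 8, 5, 8)))
  expect_equal(object_hausdorff(S, S), 0)
  # single pair of objects: equals the plain boundary Hausdorff
  A <- fx_rects(10, 10, list(c(2, 5, 2, 5)))
  B <- fx_rects(10, 10, list(c(3, 7, 3, 7)))
  expect_equal(object_hausdorff(A, B),
               hausdorff(oracle_boundary_points(A, 1L),
                         oracle_boundary_points(B, 1L)))
  flagged <- object_hausdorff(matrix(0L, 10, 10), A)
  expect_true(is.na(flagged))
  expect_true(attr(flagged, "flagged"))
})

test_that("merging two touching cells strictly lowers object-Dice", {
  G <- fx_rects(10, 12, list(c(2, 9, 2, 6), c(2, 9, 7, 11)))
  S_merged <- matrix(0L, 10, 12); S_merged[G > 0L] <- 1L
  expect_lt(object_dice(S_merged, G), object_dice(G, G))
  # whole-region pixel Dice is nevertheless perfect: the object level is
  # what detects the failure to split
  expect_equal(dice(S_merged > 0L, G > 0L), 1)
})

test_that("object_metric_report aggregates mean and SD over ROIs", {
  G1 <- fx_rects(8, 8, list(c(2, 4, 2, 4)))
  G2 <- fx_rects(8, 8, list(c(3, 6, 3, 6)))
  rep <- object_metric_report(list(G1, G2), list(G1, G2))
  expect_equal(rep$od_mean, 1)
  expect_equal(rep$oh_mean, 0)
  expect_equal(nrow(rep$per_roi), 2L)
  p <- withr::local_tempfile(fileext = ".csv")
  write_metric_report_csv(rep, p)
  back <- utils::read.csv(p)
  expect_equal(nrow(back), 3L)
  expect_equal(back$od[3], 1)
})

test_that("pairwise_agreement averages over observer pairs", {
  G <- fx_rects(10, 10, list(c(2, 5, 2, 5), c(7, 10, 6, 10)))
  # three identical observers -> OD 1, OH 0, 3 pairs
  rep3 <- pairwise_agreement(list(list(G), list(G), list(G)))
  expect_equal(rep3$n_pairs, 3L)
  expect_equal(rep3$od_mean, 1)
  expect_equal(rep3$oh_mean, 0)
  # two observers -> averages equal the single pairwise value
  H <- degrade_labels(G, boundary_jitter_px = 1L, seed = 5L)
  rep2 <- pairwise_agreement(list(a = list(G), b = list(H)))
  expect_equal(rep2$n_pairs, 1L)
  expect_equal(rep2$od_mean, object_dice(G, H))
  # perturbed three-observer case equals the hand-computed mean
  K <- degrade_labels(G, boundary_jitter_px = 1L, seed = 9L)
  rep <- pairwise_agreement(list(list(G), list(H), list(K)))
  manual <- mean(c(object_dice(G, H), object_dice(G, K), object_dice(H, K)))
  expect_equal(rep$od_mean, manual)
  expect_error(pairwise_agreement(list(list(G))), "2 observers")
})
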