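test_that("threshold_mask equals the brute-force predicate loop everywhere", {
  set.seed(41)
  for (trial in 1:6) {
    d <- sample(8:16, 3, replace = TRUE)
    vol <- image_volume(array(sample(1:9, prod(d), TRUE), d))
    b <- sort(sample(2:8, 2))
    lo <- sapply(d, function(n) sample(0:(n - 2), 1))
    hi <- pmin(lo + sapply(d, function(n) sample(1:(n - 1), 1)), d - 1)
    box <- rbind(lo, hi)
    idx <- as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1), 0:(d[3] - 1)))
    inbox <- array(idx[, 1] >= lo[1] & idx[, 1] <= hi[1] &
                   idx[, 2] >= lo[2] & idx[, 2] <= hi[2] &
                   idx[, 3] >= lo[3] & idx[, 3] <= hi[3], d)
    for (mode in c("min_to_value", "value_to_max", "between")) {
      spec <- threshold_spec(mode, if (mode == "between") b else b[1])
      pred <- switch(mode,
                     min_to_value = vol$voxels <= b[1],
                     value_to_max = vol$voxels >= b[1],
                     between = vol$voxels >= b[1] & vol$voxels <= b[2])
      expect_equal(threshold_mask(vol, spec)$mask, pred)
      expect_equal(threshold_mask(vol, spec, constraint_region(box, "inside"))$mask,
                   pred & inbox)
      expect_equal(threshold_mask(vol, spec, constraint_region(box, "outside"))$mask,
                   pred & !inbox)
    }
  }
})

test_that("thresholds are inclusive, empty results legal, percent mode relative", {
  vol <- image_volume(array(c(3, 5, 7), c(3, 1, 1)))
  m <- threshold_mask(vol, threshold_spec("between", c(4, 6)))
  expect_equal(as.vector(m$mask), c(FALSE, TRUE, FALSE))
  u5 <- image_volume(array(5, c(4, 4, 4)))
  expect_true(all(threshold_mask(u5, threshold_spec("between", c(4, 6)))$mask))
  expect_equal(sum(threshold_mask(u5, threshold_spec("value_to_max", 9))$mask), 0)
  # value_to_max includes the maximum (inclusive bound)
  expect_true(any(threshold_mask(vol, threshold_spec("value_to_max", 7))$mask))
  # percent_of_max is relative to the max inside the allowed region
  v2 <- image_volume(array(c(10, rep(2, 26)), c(3, 3, 3)))
  cons <- constraint_region(rbind(c(1, 0, 0), c(2, 2, 2)), "inside")
  m2 <- threshold_mask(v2, threshold_spec("value_to_max", 0.9,
                                          "percent_of_max"), cons)
  # max inside the box is 2 (the 10 sits outside), so 0.9 * 2 = 1.8 passes
  # every allowed voxel: 2 x 3 x 3 = 18
  expect_equal(sum(m2$mask), 18)
  expect_error(threshold_spec("between", c(6, 4)), "lower")
})

test_that("replace_voxels touches exactly the masked voxels", {
  vol <- random_volume(c(8, 8, 8), seed = 43)
  set.seed(44)
  m <- voi_mask(array(runif(512) > 0.7, c(8, 8, 8)), vol$geometry)
  out <- replace_voxels(vol, m, -7)
  expect_true(all(out$voxels[m$mask] == -7))
  expect_identical(out$voxels[!m$mask], vol$voxels[!m$mask])
  # accounting identity for the sum
  expect_equal(sum(out$voxels) - sum(vol$voxels),
               sum(-7 - vol$voxels[m$mask]))
  # empty and full masks
  e <- voi_mask(array(FALSE, c(8, 8, 8)), vol$geometry)
  expect_identical(replace_voxels(vol, e, 0)$voxels, vol$voxels)
  f <- voi_mask(array(TRUE, c(8, 8, 8)), vol$geometry)
  expect_true(all(replace_voxels(vol, f, 0)$voxels == 0))
})

test_that("edge detectors find steps and contours, and reject unknown names", {
  cv <- image_volume(array(5, c(12, 12, 3)))
  expect_equal(sum(edge_detect(cv, "sobel")$mask), 0)
  expect_equal(sum(edge_detect(cv, "canny")$mask), 0)

  sv <- array(0, c(20, 20, 3)); sv[11:20, , ] <- 10
  for (meth in c("sobel", "prewitt")) {
    e <- edge_detect(image_volume(sv), meth)
    rows <- which(apply(e$mask[, , 2], 1, any))
    expect_true(all(rows %in% c(10, 11)))  # the two planes flanking the step
    expect_gt(length(rows), 0)
  }

  rv <- array(0, c(30, 30, 1)); rv[8:22, 10:20, 1] <- 50
  ec <- edge_detect(image_volume(rv), "canny")
  # one closed ring: a single 26-connected component surrounding the rectangle
  objs <- label_objects(ec)
  expect_equal(length(objs), 1)
  w <- which(ec$mask[, , 1], arr.ind = TRUE)
  expect_true(all(w[, 1] >= 6 & w[, 1] <= 24 & w[, 2] >= 8 & w[, 2] <= 22))
  # approx-canny (no hysteresis) marks a subset of stronger edges
  ea <- edge_detect(image_volume(rv), "approx_canny")
  expect_gt(sum(ea$mask), 0)
  expect_lte(sum(ea$mask), sum(ec$mask))

  expect_error(edge_detect(cv, "roberts"), "sobel, prewitt, canny")
})

test_that("label_objects matches brute-force flood fill across connectivities", {
  m <- array(FALSE, c(10, 10, 10))
  m[2:3, 2:3, 2:3] <- TRUE; m[7:8, 7:8, 7:8] <- TRUE
  expect_equal(length(label_objects(voi_mask(m))), 2)

  # diagonal touch: one object at 26-connectivity, two at 6
  m2 <- array(FALSE, c(4, 4, 4)); m2[1, 1, 1] <- TRUE; m2[2, 2, 2] <- TRUE
  expect_equal(length(label_objects(voi_mask(m2), connectivity = 26)), 1)
  expect_equal(length(label_objects(voi_mask(m2), connectivity = 6)), 2)

  set.seed(45)
  for (trial in 1:4) {
    r <- array(runif(12^3) > 0.72, c(12, 12, 12))
    for (conn in c(6L, 26L))
      expect_equal(length(label_objects(voi_mask(r), connectivity = conn)),
                   brute_force_components(r, conn))
  }

  # peak bookkeeping
  vol <- random_volume(c(10, 10, 10), seed = 46)
  objs <- label_objects(voi_mask(m), vol)
  for (o in objs) {
    expect_equal(o$peak_value, max(vol$voxels[o$voxels]))
    pidx <- o$peak_index + 1L
    expect_equal(vol$voxels[pidx[1], pidx[2], pidx[3]], o$peak_value)
  }
})

test_that("aggregate_vois unions masks with inclusion-exclusion volumes", {
  g <- grid_geometry(c(10, 10, 10))
  a <- array(FALSE, c(10, 10, 10)); a[1:4, , ] <- TRUE
  b <- array(FALSE, c(10, 10, 10)); b[7:9, , ] <- TRUE
  u <- aggregate_vois(list(voi_mask(a, g), voi_mask(b, g)))
  expect_equal(sum(u$mask), sum(a) + sum(b))   # disjoint: additive
  c1 <- array(FALSE, c(10, 10, 10)); c1[3:8, , ] <- TRUE
  u2 <- aggregate_vois(list(voi_mask(a, g), voi_mask(c1, g)))
  expect_equal(sum(u2$mask), sum(a) + sum(c1) - sum(a & c1))
  expect_equal(aggregate_vois(list(voi_mask(a, g)))$mask, a)
})

test_that("segment_lungs recovers both lungs with correct laterality", {
  ct <- make_thorax_ct()
  gt <- attr(ct, "ground_truth")
  lungs <- segment_lungs(ct)
  vml <- voxel_volume_ml(ct$geometry)
  expect_lt(abs(sum(lungs$left$mask) * vml - gt$left$analytic_volume_ml) /
            gt$left$analytic_volume_ml, 0.05)
  expect_lt(abs(sum(lungs$right$mask) * vml - gt$right$analytic_volume_ml) /
            gt$right$analytic_volume_ml, 0.05)
  # disjoint, single components
  expect_equal(sum(lungs$left$mask & lungs$right$mask), 0)
  expect_equal(length(label_objects(lungs$left)), 1)
  expect_equal(length(label_objects(lungs$right)), 1)
  # laterality: patient left is +x in LPS
  cl <- colMeans(voxel_to_world(ct$geometry,
                                which(lungs$left$mask, arr.ind = TRUE) - 1L,
                                check = FALSE))
  cr <- colMeans(voxel_to_world(ct$geometry,
                                which(lungs$right$mask, arr.ind = TRUE) - 1L,
                                check = FALSE))
  expect_gt(cl[1], cr[1])
  # never includes soft tissue
  expect_lt(max(ct$voxels[lungs$left$mask | lungs$right$mask]), -300)
  # errors on a lung-less volume
  flat <- image_volume(array(40, c(16, 16, 8)), value_kind = "HU")
  expect_error(segment_lungs(flat), "threshold")
})
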