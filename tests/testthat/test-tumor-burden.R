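test_that("burden_config validates its parameter relationships", {
  cfg <- burden_config()
  expect_equal(cfg$grow_percent, 0.10)
  expect_equal(cfg$local_percent, 0.42)
  expect_equal(cfg$secondary_peak_percent, 0.20)
  expect_equal(cfg$min_volume_ml, 0.3)
  expect_error(burden_config(grow_percent = 0.5, local_percent = 0.42))
  expect_error(burden_config(min_volume_ml = -1))
  expect_error(burden_config(mode = "absolute_suv"), "absolute_suv")
})

test_that("candidate detection grows at 10% of the global max with exclusions", {
  pet <- make_multipeak_pet(peaks = c(10, 8), separation_mm = 60, sigma_mm = 5)
  objs <- detect_candidates(pet)
  expect_equal(length(objs), 2)
  # voxel sets equal brute-force threshold + flood fill
  thr <- 0.10 * max(pet$voxels)
  fg <- pet$voxels >= thr
  expect_equal(brute_force_components(fg, 26L), 2)
  expect_equal(sort(unlist(lapply(objs, `[[`, "voxels"))), which(fg))

  # an exclusion box over the second lesion removes it
  ex <- constraint_region(rbind(c(40, 0, 0), c(63, 63, 63)), "inside")
  objs2 <- detect_candidates(pet, burden_config(exclusions = list(ex)))
  expect_equal(length(objs2), 1)

  # all-zero image: empty candidate list
  zero <- image_volume(array(0, c(8, 8, 8)), value_kind = "SUV")
  expect_equal(length(detect_candidates(zero)), 0)
})

test_that("a merged object splits by the 42% / 20% secondary-peak rules", {
  # peaks 10 and 5 (50% of primary, above the 20% rule): one candidate, two VOIs
  pet <- make_multipeak_pet(peaks = c(10, 5), separation_mm = 20, sigma_mm = 6)
  objs <- detect_candidates(pet)
  expect_equal(length(objs), 1)
  vois <- segment_object(pet, objs[[1]])
  expect_equal(length(vois), 2)
  # the secondary region is thresholded at 42% of its own local max
  v2 <- pet$voxels[vois[[2]]$mask]
  expect_gte(min(v2), 0.42 * max(v2))
  # the secondary region's own maximum is the 5-ish local peak, not the
  # object's global 10 peak, and it clears the 20% rule
  expect_lt(max(v2), 0.6 * objs[[1]]$peak_value)
  expect_gte(max(v2), 0.20 * objs[[1]]$peak_value)
  # stage-2 VOIs are disjoint subsets of the stage-1 object
  expect_equal(sum(vois[[1]]$mask & vois[[2]]$mask), 0)
  ob <- array(FALSE, dim(pet$voxels)); ob[objs[[1]]$voxels] <- TRUE
  expect_true(all(ob[vois[[1]]$mask]) && all(ob[vois[[2]]$mask]))

  # peaks 10 and 1.5 (below 20% of 10): still one candidate, but one VOI
  pet2 <- make_multipeak_pet(peaks = c(10, 1.5), separation_mm = 20,
                             sigma_mm = 6)
  objs2 <- detect_candidates(pet2)
  expect_equal(length(objs2), 1)
  expect_equal(length(segment_object(pet2, objs2[[1]])), 1)
})

test_that("percent-mode output is invariant under global intensity rescaling", {
  pet <- make_multipeak_pet(peaks = c(10, 5), separation_mm = 20, sigma_mm = 6)
  res1 <- total_tumor_burden(pet)
  res7 <- total_tumor_burden(vol_like(pet, pet$voxels * 7))
  expect_equal(length(res1$vois), length(res7$vois))
  for (i in seq_along(res1$vois))
    expect_identical(res1$vois[[i]]$mask, res7$vois[[i]]$mask)
})

test_that("raising the local threshold never grows a VOI", {
  pet <- make_multipeak_pet(peaks = c(10, 5), separation_mm = 20, sigma_mm = 6)
  obj <- detect_candidates(pet)[[1]]
  v42 <- segment_object(pet, obj, burden_config(local_percent = 0.42))
  v60 <- segment_object(pet, obj, burden_config(local_percent = 0.60))
  expect_lte(sum(v60[[1]]$mask), sum(v42[[1]]$mask))
  expect_true(all(v42[[1]]$mask[v60[[1]]$mask]))
})

test_that("the 0.3 ml filter keeps a 1.0 ml lesion and drops a 0.1 ml one", {
  # uniform spheres segment whole at 42%: radii chosen for 0.1 and 1.0 ml
  pet <- make_phantom(phantom_spec(c(48, 48, 24), c(1, 1, 2), shapes = list(
    list(type = "sphere", center = c(-12, 0, 0), radius = 2.879, value = 10),
    list(type = "sphere", center = c(12, 0, 0), radius = 6.2, value = 10)),
    modality = "PT", value_kind = "SUV"))
  res <- total_tumor_burden(pet)
  expect_equal(length(res$vois), 1)
  expect_gt(res$statistics[[1]]$volume_ml, 0.9)
  # boundary semantics: exactly min_volume_ml is removed (strict "exceed")
  g <- grid_geometry(c(10, 10, 10))
  exact <- voi_mask(array(c(rep(TRUE, 300), rep(FALSE, 700)), c(10, 10, 10)), g)
  expect_equal(length(filter_small(list(exact), burden_config())), 0)
  just_over <- voi_mask(array(c(rep(TRUE, 301), rep(FALSE, 699)),
                              c(10, 10, 10)), g)
  expect_equal(length(filter_small(list(just_over), burden_config())), 1)
  # min_volume_ml = 0 keeps any nonempty VOI
  tiny <- voi_mask(array(c(TRUE, rep(FALSE, 999)), c(10, 10, 10)), g)
  expect_equal(length(filter_small(list(tiny),
                                   burden_config(min_volume_ml = 0))), 1)
})

test_that("42% VOI volume matches the analytic Gaussian lesion volume", {
  pet <- make_phantom(phantom_spec(c(45, 45, 45), c(1, 1, 1), shapes = list(
    list(type = "gaussian_blob", center = c(0, 0, 0), sigma = 6, peak = 10)),
    modality = "PT", value_kind = "SUV"))
  res <- total_tumor_burden(pet)
  expect_equal(length(res$vois), 1)
  r42 <- 6 * sqrt(2 * log(1 / 0.42))
  analytic_ml <- 4 / 3 * pi * r42^3 / 1000
  expect_lt(abs(res$statistics[[1]]$volume_ml - analytic_ml) / analytic_ml,
            0.05)
})

test_that("review ordering is superior-to-inferior and deletion is strict", {
  pet <- make_phantom(phantom_spec(c(24, 24, 48), c(2, 2, 2), shapes = list(
    list(type = "sphere", center = c(0, 0, -30), radius = 6.5, value = 10),
    list(type = "sphere", center = c(0, 0, 30), radius = 6.5, value = 9)),
    modality = "PT", value_kind = "SUV"))
  res <- total_tumor_burden(pet)
  expect_equal(length(res$vois), 2)
  s1 <- mean(voxel_to_world(res$vois[[1]]$geometry,
                            which(res$vois[[1]]$mask, arr.ind = TRUE) - 1L,
                            check = FALSE)[, 3])
  s2 <- mean(voxel_to_world(res$vois[[2]]$geometry,
                            which(res$vois[[2]]$mask, arr.ind = TRUE) - 1L,
                            check = FALSE)[, 3])
  expect_gt(s1, s2)  # first VOI is the superior one

  n_before <- sum(global_mask(res)$mask)
  v1 <- sum(res$vois[[1]]$mask)
  res2 <- delete_voi(res, "VOI_01")
  expect_equal(sum(global_mask(res2)$mask), n_before - v1)
  expect_equal(res2$deleted_ids, "VOI_01")
  expect_error(delete_voi(res2, "VOI_01"), "unknown")
  res3 <- delete_voi(res2, "VOI_02")
  expect_equal(sum(global_mask(res3)$mask), 0)
})

test_that("burden report totals volumes and TLG across disjoint VOIs", {
  # one uniform-SUV-5 lesion of exactly 2 ml: TLG = 10
  g <- grid_geometry(c(20, 20, 20))
  v <- array(0, c(20, 20, 20)); v[1:10, 1:10, 1:20] <- 5
  pet <- image_volume(v, g, "PT", "SUV")
  m <- voi_mask(v == 5, g, "VOI_01")
  res <- structure(list(vois = list(m),
                        statistics = list(compute_statistics(pet, m)),
                        candidate_objects = list(), deleted_ids = character(0),
                        pet_geometry = g), class = "burden_result")
  rep <- burden_report(res, pet)
  expect_equal(rep$tlg[rep$name == "VOI_01"], 10)
  expect_equal(rep$volume_ml[rep$name == "TOTAL"],
               sum(rep$volume_ml[rep$name != "TOTAL"]))
  # empty result: a zero TOTAL row
  empty <- structure(list(vois = list(), statistics = list(),
                          candidate_objects = list(),
                          deleted_ids = character(0), pet_geometry = g),
                     class = "burden_result")
  rep0 <- burden_report(empty, pet)
  expect_equal(nrow(rep0), 1)
  expect_equal(rep0$volume_ml, 0)
})

test_that("absolute-SUV mode thresholds each object at the fixed value", {
  pet <- make_multipeak_pet(peaks = c(10, 5), separation_mm = 20, sigma_mm = 6)
  obj <- detect_candidates(pet)[[1]]
  vois <- segment_object(pet, obj,
                         burden_config(mode = "absolute_suv",
                                       absolute_suv = 3))
  expect_equal(length(vois), 1)
  expect_gte(min(pet$voxels[vois[[1]]$mask]), 3)
  ob <- array(FALSE, dim(pet$voxels)); ob[obj$voxels] <- TRUE
  expect_equal(sum(vois[[1]]$mask), sum(ob & pet$voxels >= 3))
})

test_that("burden config files round-trip", {
  cfg <- burden_config(grow_percent = 0.15, local_percent = 0.5,
                       secondary_peak_percent = 0.25, min_volume_ml = 0.4)
  p <- tempfile(fileext = ".cfg")
  write_burden_config(cfg, p)
  back <- read_burden_config(p)
  expect_equal(back$grow_percent, 0.15)
  expect_equal(back$local_percent, 0.5)
  expect_equal(back$secondary_peak_percent, 0.25)
  expect_equal(back$min_volume_ml, 0.4)
})
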