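test_that("assign_tissue matches a brute-force range lookup with overrides", {
  g <- grid_geometry(c(10, 10, 10), c(4, 4, 4))
  set.seed(51)
  hu <- array(runif(1000, -1040, 2000), c(10, 10, 10))
  ct <- image_volume(hu, g, "CT", "HU")
  map <- tissue_map()
  lab <- assign_tissue(ct, map)
  bf <- ifelse(hu < -120, "lung", ifelse(hu < 120, "soft_tissue", "bone"))
  expect_equal(as.vector(lab), as.vector(bf))

  # uniform 0 HU body with a soft-tissue range
  u <- image_volume(array(0, c(5, 5, 5)), value_kind = "HU")
  expect_true(all(assign_tissue(u, map) == "soft_tissue"))

  # an override VOI wins over its HU range
  ov <- voi_mask(array(c(rep(TRUE, 100), rep(FALSE, 900)), c(10, 10, 10)), g,
                 "tumor")
  map2 <- tissue_map(overrides = list(list(voi = ov, tissue = "tumor")))
  lab2 <- assign_tissue(ct, map2)
  expect_true(all(lab2[1:100] == "tumor"))
  expect_equal(as.vector(lab2[101:1000]), as.vector(bf)[101:1000])

  # out-of-range voxels fall back to the default with a warning count
  hot <- image_volume(array(c(5000, rep(0, 124)), c(5, 5, 5)),
                      value_kind = "HU")
  expect_warning(lab3 <- assign_tissue(hot, map), "outside")
  expect_equal(attr(lab3, "unassigned"), 1)
  expect_equal(lab3[1], "soft_tissue")
})

test_that("dose_rate: delta kernel scales, point kernel reproduces its profile", {
  g <- grid_geometry(c(12, 12, 12), c(4, 4, 4))
  set.seed(52)
  act <- image_volume(array(runif(12^3, 0, 1000), c(12, 12, 12)), g, "PT",
                      "activity_conc")
  c0 <- 3e-6
  dr <- dose_rate(act, list(all = delta_kernel(c(4, 4, 4), value = c0)), "all")
  expect_lt(max(abs(dr$voxels - c0 * act$voxels)), 1e-12)
  expect_equal(dr$value_kind, "dose_rate")

  # point source: the dose-rate image reproduces the kernel profile
  pt <- array(0, c(12, 12, 12)); pt[6, 6, 6] <- 1
  src <- image_volume(pt, g, "PT", "activity_conc")
  kv <- array(0, c(5, 5, 5))
  kidx <- as.matrix(expand.grid(-2:2, -2:2, -2:2))
  kv[] <- exp(-rowSums(kidx^2) / 2)
  k <- kernel3d(kv, c(4, 4, 4))
  drp <- dose_rate(src, list(all = k), "all")
  expect_lt(max(abs(drp$voxels[4:8, 4:8, 4:8] - kv)), 1e-9)

  # missing kernel for a present label errors by name
  lab <- array("bone", c(12, 12, 12))
  expect_error(dose_rate(act, list(all = k), lab), "bone")
})

test_that("region-wise convolution equals brute-force per-region sums; linear in activity", {
  g <- grid_geometry(c(10, 10, 10), c(4, 4, 4))
  set.seed(53)
  act <- image_volume(array(runif(1000, 0, 100), c(10, 10, 10)), g, "PT",
                      "activity_conc")
  lab <- array(ifelse(runif(1000) < 0.4, "lung", "soft_tissue"),
               c(10, 10, 10))
  kl <- kernel3d(array(runif(27), c(3, 3, 3)), c(4, 4, 4))
  ks <- kernel3d(array(runif(27), c(3, 3, 3)), c(4, 4, 4))
  kernels <- list(lung = kl, soft_tissue = ks)
  dr <- dose_rate(act, kernels, lab)
  bf <- brute_force_convolve(act$voxels * (lab == "lung"), kl$values) +
        brute_force_convolve(act$voxels * (lab == "soft_tissue"), ks$values)
  expect_lt(max(abs(dr$voxels - bf)), 1e-6)

  # linearity in activity
  act2 <- vol_like(act, act$voxels * 3)
  expect_lt(max(abs(dose_rate(act2, kernels, lab)$voxels - 3 * dr$voxels)),
            1e-6)

  # with one tissue, region-wise equals plain convolution
  one <- dose_rate(act, list(soft_tissue = ks), "soft_tissue")
  plain <- convolve_volume(act, ks)
  expect_lt(max(abs(one$voxels - plain$voxels)), 1e-9)

  # density correction divides by local density
  map <- tissue_map()
  drd <- dose_rate(act, kernels, lab, map, density_correction = TRUE)
  rho <- ifelse(lab == "lung", 0.26, 1.00)
  expect_lt(max(abs(drd$voxels - dr$voxels / rho)), 1e-9)
})

test_that("energy bookkeeping: sum-normalized kernel conserves interior totals", {
  g <- grid_geometry(c(20, 20, 20), c(4, 4, 4))
  a <- array(0, c(20, 20, 20)); a[8:13, 8:13, 8:13] <- 500
  act <- image_volume(a, g, "PT", "activity_conc")
  kv <- array(runif(125), c(5, 5, 5)); kv <- kv / sum(kv)
  dr <- dose_rate(act, list(all = kernel3d(kv, c(4, 4, 4))), "all")
  expect_lt(abs(sum(dr$voxels) - sum(a)) / sum(a), 0.01)
})

test_that("DVH is an exact step for uniform dose and non-increasing in general", {
  g <- grid_geometry(c(12, 12, 12), c(4, 4, 4))
  voi <- voi_mask(array(TRUE, c(12, 12, 12)), g)
  u <- image_volume(array(5, c(12, 12, 12)), g, "PT", "dose_rate")
  dvh <- compute_dvh(u, voi, 10)
  expect_true(all(dvh$volume_fraction == 1))   # every edge <= max dose
  expect_equal(dvh$max, 5)

  # two-level dose: fraction 0.5 strictly between the two levels
  v <- array(2, c(12, 12, 12)); v[1:6, , ] <- 8
  two <- image_volume(v, g, "PT", "dose_rate")
  d2 <- compute_dvh(two, voi, 100)
  mid <- d2$dose_edges > 2 & d2$dose_edges < 8
  expect_true(all(abs(d2$volume_fraction[mid] - 0.5) < 1e-12))
  expect_equal(d2$volume_fraction[1], 1)

  # random maps: curve equals brute-force counting, never increases,
  # and the trapezoid mean matches the voxel mean within binning error
  set.seed(54)
  for (trial in 1:5) {
    dm <- image_volume(array(runif(1728, 0, 40), c(12, 12, 12)), g, "PT",
                       "dose_rate")
    dd <- compute_dvh(dm, voi, 200)
    vals <- dm$voxels[voi$mask]
    bf <- vapply(dd$dose_edges, function(e) mean(vals >= e), numeric(1))
    bf[1] <- 1
    expect_equal(dd$volume_fraction, bf)
    expect_true(all(diff(dd$volume_fraction) <= 1e-12))
    expect_true(all(dd$volume_fraction >= 0 & dd$volume_fraction <= 1))
    expect_lt(abs(dvh_mean(dd) - mean(vals)) / mean(vals),
              2 / 200)  # one bin width of slack
  }
  expect_error(compute_dvh(u, voi_mask(array(FALSE, c(12, 12, 12)), g,
                                       "void")), "void")
})

test_that("DVH and tissue-map files export and reload", {
  g <- grid_geometry(c(8, 8, 8), c(2, 2, 2))
  dm <- image_volume(array(runif(512, 0, 10), c(8, 8, 8)), g, "PT",
                     "dose_rate")
  voi <- voi_mask(array(TRUE, c(8, 8, 8)), g, "target")
  dvh <- compute_dvh(dm, voi, 50)
  p <- tempfile(fileext = ".csv")
  write_dvh_csv(list(dvh), p)
  df <- utils::read.csv(p)
  expect_equal(df$name, "target")
  expect_equal(df$mean, dvh$mean)
  expect_equal(df$volume_ml, dvh$volume_ml)
  write_dvh_csv(list(dvh), p, curves = TRUE)
  dfc <- utils::read.csv(p)
  expect_equal(nrow(dfc), 51)
  expect_equal(dfc$volume_fraction, dvh$volume_fraction)

  map <- tissue_map()
  pm <- tempfile(fileext = ".txt")
  write_tissue_map(map, pm)
  back <- read_tissue_map(pm)
  expect_equal(back$entries$tissue, map$entries$tissue)
  expect_equal(back$entries$density_g_ml, map$entries$density_g_ml)
})
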