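test_that("DICOM series round-trips geometry and voxels to one quantum", {
  ct <- make_thorax_ct(dims = c(24, 20, 8), spacing = c(4, 4, 5))
  td <- file.path(tempdir(), "dcm_rt"); unlink(td, recursive = TRUE)
  out <- write_dicom_series(ct, td, series_header(modality = "CT"))
  expect_equal(length(attr(out, "files")), 8)
  lr <- load_dicom_series(td)
  expect_true(same_geometry(lr$volume$geometry, ct$geometry))
  quantum <- (max(ct$voxels) - min(ct$voxels)) / 65535
  expect_lte(max(abs(lr$volume$voxels - ct$voxels)), quantum)
  expect_equal(lr$volume$value_kind, "HU")
  expect_equal(lr$header$modality, "CT")
})

test_that("a single-slice volume writes exactly one file", {
  v <- image_volume(array(runif(64), c(8, 8, 1)))
  td <- file.path(tempdir(), "dcm_one"); unlink(td, recursive = TRUE)
  out <- write_dicom_series(v, td)
  expect_equal(length(list.files(td, pattern = "\\.dcm$")), 1)
})

test_that("shuffled slice files load identically to sorted ones", {
  ct <- make_thorax_ct(dims = c(16, 16, 10), spacing = c(5, 5, 4))
  d1 <- file.path(tempdir(), "dcm_sorted"); unlink(d1, recursive = TRUE)
  write_dicom_series(ct, d1)
  d2 <- file.path(tempdir(), "dcm_shuffled"); unlink(d2, recursive = TRUE)
  dir.create(d2)
  fs <- list.files(d1, full.names = TRUE, pattern = "\\.dcm$")
  set.seed(71)
  perm <- sample(length(fs))
  for (i in seq_along(fs))
    file.copy(fs[perm[i]], file.path(d2, sprintf("zz_%02d.dcm", i)))
  a <- load_dicom_series(d1); b <- load_dicom_series(d2)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_true(same_geometry(a$volume$geometry, b$volume$geometry))
})

test_that("mixing two series in one directory is rejected, listing the UIDs", {
  v <- image_volume(array(0, c(4, 4, 2)))
  td <- file.path(tempdir(), "dcm_mixed"); unlink(td, recursive = TRUE)
  write_dicom_series(v, td)
  t2 <- file.path(tempdir(), "dcm_mixed2"); unlink(t2, recursive = TRUE)
  write_dicom_series(v, t2)
  file.copy(list.files(t2, full.names = TRUE)[1],
            file.path(td, "intruder.dcm"))
  expect_error(load_dicom_series(td), "multiple series")
})

test_that("rescale slope is applied on load", {
  # a written series whose values span [0, 200] gets slope (200/65535); a
  # stored value v reloads as v*slope + intercept — verify against the tags
  v <- image_volume(array(seq(0, 200, length.out = 128), c(8, 8, 2)),
                    grid_geometry(c(8, 8, 2), c(4, 4, 4)), "PT",
                    "activity_conc")
  td <- file.path(tempdir(), "dcm_slope"); unlink(td, recursive = TRUE)
  write_dicom_series(v, td, series_header(modality = "PT", units = "BQML"))
  f <- list.files(td, full.names = TRUE)[1]
  ds <- voxquant:::read_dicom_file(f)
  pix <- readBin(ds$PixelData, "integer", n = 64, size = 2,
                 endian = "little", signed = FALSE)
  lr <- load_dicom_series(td)
  expect_equal(as.vector(lr$volume$voxels[, , 1]),
               pix * ds$RescaleSlope + ds$RescaleIntercept)
})

test_that("SUV conversion follows the body-weight definition with decay", {
  pv <- image_volume(array(5285.7, c(8, 8, 4)),
                     grid_geometry(c(8, 8, 4), c(4, 4, 4)), "PT",
                     "activity_conc")
  hdr <- series_header(modality = "PT", patient_weight_kg = 70,
                       injected_dose_bq = 3.7e8, units = "BQML")
  suv <- to_suv(pv, hdr)
  expect_lt(abs(suv$voxels[1, 1, 1] - 1.0), 1e-3)
  expect_equal(suv$value_kind, "SUV")

  # doubling the weight doubles every SUV
  hdr2 <- hdr; hdr2$patient_weight_kg <- 140
  expect_equal(to_suv(pv, hdr2)$voxels, 2 * suv$voxels)

  # one half-life between injection and scan halves the dose -> doubles SUV
  hdr3 <- hdr
  hdr3$injection_time_s <- 0; hdr3$series_time_s <- 6586.2
  hdr3$half_life_s <- 6586.2
  expect_lt(max(abs(to_suv(pv, hdr3)$voxels - 2 * suv$voxels)), 1e-9)

  # missing tags are named in errors
  expect_error(to_suv(pv, series_header(injected_dose_bq = 1)), "PatientWeight")
  expect_error(to_suv(pv, series_header(patient_weight_kg = 70)),
               "RadionuclideTotalDose")
  expect_error(to_suv(image_volume(array(1, c(2, 2, 2))), hdr),
               "activity")
})

test_that("radiopharmaceutical tags survive a DICOM round trip", {
  pv <- image_volume(array(100, c(6, 6, 2)),
                     grid_geometry(c(6, 6, 2), c(4, 4, 4)), "PT",
                     "activity_conc")
  hdr <- series_header(modality = "PT", patient_position = "FFS",
                       patient_weight_kg = 70, injected_dose_bq = 3.7e8,
                       injection_time_s = 3600, series_time_s = 7200,
                       half_life_s = 6586.2, units = "BQML")
  td <- file.path(tempdir(), "dcm_rph"); unlink(td, recursive = TRUE)
  write_dicom_series(pv, td, hdr)
  lr <- load_dicom_series(td)
  expect_equal(lr$header$patient_weight_kg, 70)
  expect_equal(lr$header$injected_dose_bq, 3.7e8)
  expect_equal(lr$header$injection_time_s, 3600)
  expect_equal(lr$header$series_time_s, 7200)
  expect_equal(lr$header$half_life_s, 6586.2)
  expect_equal(lr$header$patient_position, "FFS")
  expect_equal(lr$volume$value_kind, "activity_conc")
})

test_that("reoriented volumes written to DICOM reload with corrected geometry", {
  vol <- make_phantom(phantom_spec(c(10, 10, 6), c(2, 2, 4)))
  vol$voxels[2, 3, 2] <- 50
  fixed <- reorient(vol, "HFS", "FFS")
  td <- file.path(tempdir(), "dcm_reo"); unlink(td, recursive = TRUE)
  write_dicom_series(fixed, td, series_header(patient_position = "HFS"))
  lr <- load_dicom_series(td)
  expect_true(same_geometry(lr$volume$geometry, fixed$geometry))
  expect_equal(lr$header$patient_position, "HFS")
  w <- which(lr$volume$voxels == max(lr$volume$voxels), arr.ind = TRUE)
  expect_equal(as.vector(w), c(10 - 2 + 1, 3, 6 - 2 + 1))
})

test_that("RT-struct round trip preserves volume, names and colors", {
  ph <- make_phantom(phantom_spec(c(50, 50, 50), c(1, 1, 1), shapes = list(
    list(type = "sphere", center = c(0, 0, 0), radius = 20, value = 1))))
  voi <- voi_mask(ph$voxels > 0.5, ph$geometry, "sphere", c(10L, 200L, 30L))
  cube <- array(FALSE, c(50, 50, 50)); cube[5:10, 5:10, 5:10] <- TRUE
  voi2 <- voi_mask(cube, ph$geometry, "cube", c(1L, 2L, 3L))
  p <- tempfile(fileext = ".dcm")
  write_rtstruct(list(voi, voi2), ph$geometry, p)
  back <- read_rtstruct(p, ph$geometry)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$name, "sphere")
  expect_equal(back[[2]]$name, "cube")
  expect_equal(back[[1]]$color, c(10L, 200L, 30L))
  expect_equal(back[[2]]$color, c(1L, 2L, 3L))
  v0 <- sum(voi$mask); v1 <- sum(back[[1]]$mask)
  expect_lt(abs(v1 - v0) / v0, 0.02)
  expect_equal(sum(back[[2]]$mask), sum(cube))

  # empty list -> valid structure set with zero ROIs
  p2 <- tempfile(fileext = ".dcm")
  write_rtstruct(list(), ph$geometry, p2)
  expect_equal(length(read_rtstruct(p2, ph$geometry)), 0)

  # zero-voxel VOIs are skipped with a warning
  ev <- voi_mask(array(FALSE, c(50, 50, 50)), ph$geometry, "ghost")
  expect_warning(write_rtstruct(list(voi, ev), ph$geometry, p2), "ghost")
  expect_equal(length(read_rtstruct(p2, ph$geometry)), 1)
})

test_that("RT-struct preserves masks with holes via even-odd rings", {
  g <- grid_geometry(c(30, 30, 6), c(1.5, 1.5, 3))
  m <- array(FALSE, c(30, 30, 6))
  m[5:25, 5:25, 2:4] <- TRUE
  m[12:18, 12:18, 2:4] <- FALSE  # a hole
  voi <- voi_mask(m, g, "annulus")
  p <- tempfile(fileext = ".dcm")
  write_rtstruct(list(voi), g, p)
  back <- read_rtstruct(p, g)[[1]]
  expect_equal(back$mask, m)
})

test_that("STL export writes valid facets and bitmap stacks slice the interior", {
  ph <- make_phantom(phantom_spec(c(25, 25, 25), c(1, 1, 1), shapes = list(
    list(type = "sphere", center = c(0, 0, 0), radius = 10, value = 1))))
  mesh <- isosurface(ph, 0.5)
  p <- tempfile(fileext = ".stl")
  write_stl(mesh, p)
  back <- read_stl(p)
  expect_equal(nrow(back$faces), nrow(mesh$faces))
  lens <- sqrt(rowSums(back$normals^2))
  expect_lt(max(abs(lens - 1)), 1e-5)

  # unit tetrahedron: 4 facets
  tet <- structure(list(
    vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    faces = rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))),
    class = "mesh_surface")
  write_stl(tet, p)
  expect_equal(nrow(read_stl(p)$faces), 4)

  # degenerate mesh with unreferenced vertices is rejected
  bad <- tet; bad$vertices <- rbind(bad$vertices, c(9, 9, 9))
  expect_error(write_stl(bad, p), "unreferenced")

  # sphere mesh at 1 mm slices: about 2r + 1 nonempty bitmaps
  td <- file.path(tempdir(), "bmp_stack"); unlink(td, recursive = TRUE)
  out <- write_bitmap_stack(mesh, 1, td)
  fs <- attr(out, "files")
  nonempty <- sum(vapply(fs, function(f) {
    b <- readBin(f, "raw", file.info(f)$size)
    any(b[-(1:1078)] != as.raw(0))   # beyond BMP header + palette
  }, logical(1)))
  expect_gte(nonempty, 19); expect_lte(nonempty, 22)
  expect_error(write_bitmap_stack(mesh, 0, td), "slice_thickness")

  # mask input slices at the grid's own resolution
  td2 <- file.path(tempdir(), "bmp_mask"); unlink(td2, recursive = TRUE)
  out2 <- write_bitmap_stack(voi_mask(ph$voxels > 0.5, ph$geometry), 1, td2)
  expect_equal(length(attr(out2, "files")), 25)
})

test_that("RGB fusion output exports as a 24-bit bitmap stack", {
  g <- grid_geometry(c(8, 8, 3))
  ct <- fusion_layer(image_volume(array(0.5, c(8, 8, 3)), g), "gray",
                     window_level(1, 0.5), alpha = 1)
  ov <- fusion_layer(image_volume(array(1, c(8, 8, 3)), g), "red",
                     window_level(1, 0.5), alpha = 1)
  rgb <- blend_layers(ct, list(ov))
  td <- file.path(tempdir(), "rgb_stack"); unlink(td, recursive = TRUE)
  out <- write_rgb_stack(rgb, td)
  fs <- attr(out, "files")
  expect_equal(length(fs), 3)
  b <- readBin(fs[1], "raw", file.info(fs[1])$size)
  expect_equal(rawToChar(b[1:2]), "BM")
  # 24 bpp, first pixel fully red: bytes (B, G, R) = (0, 127ish, 255)
  bpp <- readBin(b[29:30], "integer", size = 2, endian = "little")
  expect_equal(bpp, 24)
  px <- as.integer(b[55:57])
  expect_equal(px[3], 255)  # R saturated
  expect_lt(px[1], 255)     # B below saturation
})

test_that("statistics CSV writes one row per VOI and reparses to 1e-9", {
  vol <- random_volume(c(8, 8, 8), seed = 72, value_kind = "SUV")
  m1 <- voi_mask(array(c(rep(TRUE, 100), rep(FALSE, 412)), c(8, 8, 8)),
                 vol$geometry, "a")
  m2 <- voi_mask(array(c(rep(FALSE, 212), rep(TRUE, 300)), c(8, 8, 8)),
                 vol$geometry, "b")
  stats <- list(compute_statistics(vol, m1), compute_statistics(vol, m2))
  p <- tempfile(fileext = ".csv")
  write_statistics_csv(stats, p)
  lines <- readLines(p)
  expect_equal(length(lines), 3)  # header + 2 rows
  expect_equal(strsplit(lines[1], ",")[[1]],
               c("name", "volume_ml", "total", "mean", "min", "max", "peak",
                 "sd", "tlg"))
  df <- utils::read.csv(p)
  expect_lt(abs(df$mean[1] - stats[[1]]$mean), 1e-9)
  expect_lt(abs(df$tlg[2] - stats[[2]]$tlg), 1e-9)
  expect_error(write_statistics_csv(list(), p), "no rows")
})
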