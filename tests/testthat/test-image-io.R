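test_that("DICOM slice round-trips integer HU exactly, with metadata", {
  set.seed(71)
  px <- matrix(round(rnorm(24 * 24, 40, 12)), 24, 24)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_dicom_slice(px, f, pixel_spacing_mm = 0.625,
                    image_position_mm = c(-50, -60, 12.5),
                    slice_thickness_mm = 2.5, kvp = 120, ctdi_vol_mgy = 7.5,
                    scanner_model = "synthetic-ct")
  r <- read_dicom_slice(f)
  expect_identical(r$pixels, px + 0)
  expect_identical(r$pixel_spacing_mm, c(0.625, 0.625))
  expect_identical(r$image_position_mm, c(-50, -60, 12.5))
  expect_identical(r$meta$ctdi_vol_mgy, 7.5)
  expect_identical(r$meta$kvp, 120)
  expect_identical(r$meta$slice_thickness_mm, 2.5)
  expect_identical(r$meta$scanner_model, "synthetic-ct")
})

test_that("HU rescale equation is applied on read", {
  # writer stores HU + 1024 with slope 1, intercept -1024:
  # stored 1024 -> 0 HU, stored 100 -> -924 HU
  f <- withr::local_tempfile(fileext = ".dcm")
  write_dicom_slice(matrix(c(0, -924, 100, 500), 2, 2), f, 0.7)
  r <- read_dicom_slice(f)
  expect_identical(sort(as.numeric(r$pixels)), c(-924, 0, 100, 500))
})

test_that("a synthetic dataset exported to DICOM reloads identically", {
  cfg <- tiny_config()
  rois <- generate_dataset(cfg)
  # integer HU so the 16-bit quantisation is lossless
  rois <- lapply(rois, function(r) { r$pixels <- round(r$pixels); r })
  d <- withr::local_tempdir()
  export_dicom_dataset(rois, d)
  vol <- load_series(d)
  expect_identical(dim(vol$voxels), c(30L, 16L, 16L))
  # slices come back sorted by z = write order here
  for (i in c(1L, 15L, 30L))
    expect_identical(vol$voxels[i, , ], rois[[i]]$pixels)
  expect_equal(vol$pixel_spacing_mm, rep(cfg$pixel_spacing_mm, 2),
               tolerance = 1e-12)
})

test_that("load_series sorts by z and rejects inconsistent series", {
  d <- withr::local_tempdir()
  uid <- choiq:::dcm_uid()
  z_order <- c(30, 10, 20)
  for (i in 1:3)
    write_dicom_slice(matrix(i, 8, 8), file.path(d, sprintf("s%d.dcm", i)),
                      0.5, image_position_mm = c(0, 0, z_order[i]),
                      series_uid = uid, instance_number = i)
  vol <- load_series(d)
  expect_identical(vol$slice_positions_mm, c(10, 20, 30))
  expect_identical(vol$voxels[1, 1, 1], 2)   # slice written with z=10
  # a stray non-DICOM file is ignored, not fatal
  writeLines("not dicom", file.path(d, "notes.txt"))
  expect_identical(dim(load_series(d)$voxels)[1], 3L)
  # mismatched matrix size is a format error naming a file
  write_dicom_slice(matrix(0, 12, 12), file.path(d, "bad.dcm"), 0.5,
                    image_position_mm = c(0, 0, 40))
  expect_error(load_series(d), "matrix size")
})

test_that("extract_rois takes the window around each configured centre", {
  # one 40x40 slice with a known bright voxel
  px <- matrix(0, 40, 40)
  px[21, 25] <- 200     # 0-based (20, 24)
  d <- withr::local_tempdir()
  write_dicom_slice(px, file.path(d, "s1.dcm"), 1,
                    image_position_mm = c(0, 0, 0))
  vol <- load_series(d)
  lay <- lesion_layout("M", matrix(c(24, 20, 0), 1), 5,
                       matrix(c(10, 10, 0), 1))
  rois <- extract_rois(vol, lay, roi_size_px = 8)
  expect_length(rois, 2L)
  # centre pixel of the ROI (0-based index floor(8/2)=4 -> 1-based 5)
  expect_identical(rois[[1]]$pixels[5, 5], 200)
  expect_identical(rois[[1]]$label, "signal_present")
  expect_identical(rois[[1]]$lesion_diameter_mm, 5)
  expect_identical(rois[[2]]$label, "signal_absent")
  # translation consistency: shifting the centre by 2 px shifts the window
  lay2 <- lesion_layout("M", matrix(c(26, 22, 0), 1), 5,
                        matrix(c(10, 10, 0), 1))
  r2 <- extract_rois(vol, lay2, roi_size_px = 8)
  expect_identical(r2[[1]]$pixels[3, 3], 200)
  # a centre too close to the border fails loudly
  lay3 <- lesion_layout("M", matrix(c(2, 2, 0), 1), 5,
                        matrix(numeric(0), 0, 3))
  expect_error(extract_rois(vol, lay3, roi_size_px = 8), "border")
})

test_that("ten scans of a 4-lesion / 9-background layout give the 40/90 design", {
  lesions <- cbind(x = c(12, 24, 12, 24), y = c(12, 12, 24, 24), z = 0)
  bg <- cbind(x = rep(c(40, 52, 64), 3), y = rep(c(40, 52, 64), each = 3), z = 0)
  lay <- lesion_layout("M", lesions, rep(5, 4), bg)
  rois <- list()
  for (scan in 1:10) {
    d <- withr::local_tempdir()
    set.seed(scan)
    write_dicom_slice(matrix(round(rnorm(80 * 80, 0, 10)), 80, 80),
                      file.path(d, "s.dcm"), 1)
    vol <- load_series(d)
    rois <- c(rois, extract_rois(vol, lay, roi_size_px = 8,
                                 source_id = sprintf("scan%02d", scan)))
  }
  labels <- vapply(rois, `[[`, "", "label")
  expect_identical(sum(labels == "signal_present"), 40L)
  expect_identical(sum(labels == "signal_absent"), 90L)
})

test_that("lesion layouts load from JSON (and YAML when available)", {
  cfg <- list(phantom_size = "S",
              lesion_centres_mm = list(c(1, 2, 3), c(4, 5, 6)),
              lesion_diameters_mm = c(5, 8),
              background_centres_mm = list(c(10, 10, 3)))
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, f, auto_unbox = TRUE)
  lay <- read_lesion_layout(f)
  expect_identical(lay$phantom_size, "S")
  expect_identical(dim(lay$lesion_centres_mm), c(2L, 3L))
  expect_identical(lay$lesion_diameters_mm, c(5, 8))
  if (requireNamespace("yaml", quietly = TRUE)) {
    fy <- withr::local_tempfile(fileext = ".yaml")
    yaml::write_yaml(cfg, fy)
    lay_y <- read_lesion_layout(fy)
    expect_equal(lay_y$lesion_centres_mm, lay$lesion_centres_mm)
  }
  expect_error(lesion_layout("S", matrix(1, 1, 3), numeric(0),
                             matrix(numeric(0), 0, 3)), "diameter")
})

test_that("ROI datasets round-trip through the CSV container", {
  rois <- generate_dataset(tiny_config(seed = 9))
  d <- withr::local_tempdir()
  write_roi_dataset(rois, d)
  back <- read_roi_dataset(d)
  expect_length(back, length(rois))
  for (i in c(1L, 21L, 30L)) {
    expect_equal(back[[i]]$pixels, rois[[i]]$pixels, tolerance = 1e-12)
    expect_identical(back[[i]]$label, rois[[i]]$label)
  }
  expect_identical(back[[25]]$lesion_diameter_mm, 5)
  expect_error(read_roi_dataset(withr::local_tempdir()), "manifest")
})
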