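test_that("stack metadata passes through TIFF round trips untouched", {
  set.seed(1)
  vox <- array(sample(0:255, 6 * 40 * 32, replace = TRUE), dim = c(6, 40, 32))
  st <- image_stack(vox, bit_depth = 8)
  expect_equal(dim(st), c(6L, 40L, 32L))
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(st, path)
  rt <- read_stack(path)
  expect_identical(rt$voxels, st$voxels)    # bitwise voxel identity
  expect_identical(rt$bit_depth, 8L)

  vox16 <- array(sample(0:65535, 3 * 16 * 16, replace = TRUE), dim = c(3, 16, 16))
  st16 <- image_stack(vox16, bit_depth = 16)
  path16 <- withr::local_tempfile(fileext = ".tif")
  write_stack(st16, path16)
  rt16 <- read_stack(path16)
  expect_identical(rt16$voxels, st16$voxels)
  expect_identical(rt16$bit_depth, 16L)
})

test_that("a single-page TIFF yields a valid one-slice stack", {
  m <- matrix(sample(0:255, 20 * 20, replace = TRUE), 20, 20)
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(m / 255, path, bits.per.sample = 8L)
  st <- read_stack(path)
  expect_equal(dim(st)[1], 1L)
  # downstream operations remain valid; doublet removal is a no-op
  parts <- dedup_particles(tibble::tibble(
    brain_id = "b", slice = 0L, iteration = 1L, centroid_y = 5, centroid_x = 5,
    area_px = 10L, area_um2 = NA_real_, perimeter_px = 10, circularity = 1,
    mean_intensity = 1, max_intensity = 1, kept_after_dedup = TRUE))
  expect_true(all(parts$kept_after_dedup))
})

test_that("multichannel input is rejected unless a channel is chosen", {
  arr <- array(runif(10 * 10 * 3), dim = c(10, 10, 3))
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(arr, path, bits.per.sample = 8L)
  expect_error(read_stack(path), "channel")
  st <- read_stack(path, channel = 2)
  expect_equal(dim(st)[2:3], c(10L, 10L))
})

test_that("mask reading broadcasts, validates shape, and thresholds nonzero", {
  st <- image_stack(array(0L, dim = c(3, 12, 16)))
  full <- matrix(255, 12, 16)
  p1 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(full / 255, p1, bits.per.sample = 8L)
  m1 <- read_mask(p1, st)
  expect_identical(m1$origin, "file")
  expect_equal(dim(m1$mask), c(3L, 12L, 16L))
  expect_equal(sum(m1$mask), 3 * 12 * 16)

  half <- matrix(0, 12, 16)
  half[, 1:8] <- 255
  p2 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(half / 255, p2, bits.per.sample = 8L)
  m2 <- read_mask(p2, st)
  expect_equal(sum(m2$mask), 3 * 12 * 8)

  wrong <- matrix(255, 5, 5)
  p3 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(wrong / 255, p3, bits.per.sample = 8L)
  expect_error(read_mask(p3, st), "dimensions")
})

test_that("particle tables round-trip through CSV", {
  parts <- tibble::tibble(
    brain_id = "b1", slice = c(2L, 0L, 1L), iteration = c(1L, 2L, 1L),
    centroid_y = c(5.5, 1.25, 9), centroid_x = c(3, 7.75, 2),
    area_px = c(10L, 20L, 30L), area_um2 = c(2.5, 5, 7.5),
    perimeter_px = c(10, 14, 18), circularity = c(1, 0.9, 0.8),
    mean_intensity = c(100.5, 60, 40), max_intensity = c(120, 80, 50),
    kept_after_dedup = c(TRUE, TRUE, FALSE)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_particles(parts, path)
  rt <- read_particles(path)
  expect_equal(nrow(rt), 3)
  # rows come back ordered by slice, centroid_y, centroid_x
  expect_equal(rt$slice, c(0L, 1L, 2L))
  ord <- order(parts$slice, parts$centroid_y, parts$centroid_x)
  for (col in names(rt)) {
    expect_equal(rt[[col]], parts[[col]][ord], info = col)
  }
})

test_that("empty particle sets write a header-only CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_particles(dropletquant:::empty_particles(), path)
  lines <- readLines(path)
  expect_length(lines, 1)
  expect_match(lines, "^\"brain_id\",\"slice\"")
  expect_equal(nrow(read_particles(path)), 0)
})

test_that("area_um2 is left empty when no pixel size is known", {
  parts <- tibble::tibble(
    brain_id = "b", slice = 0L, iteration = 1L, centroid_y = 1, centroid_x = 1,
    area_px = 10L, area_um2 = NA_real_, perimeter_px = 10, circularity = 1,
    mean_intensity = 1, max_intensity = 1, kept_after_dedup = TRUE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_particles(parts, path)
  row <- strsplit(readLines(path)[2], ",")[[1]]
  expect_identical(row[7], "")   # area_um2 column
})

test_that("malformed stacks are rejected at construction", {
  expect_error(image_stack(array(-1, dim = c(1, 2, 2))), "non-negative")
  expect_error(image_stack(array(0.5, dim = c(1, 2, 2))), "integer")
  expect_error(image_stack(array(300L, dim = c(1, 2, 2)), bit_depth = 8),
               "bit depth")
})
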