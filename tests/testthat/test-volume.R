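test_that("NIfTI volumes round-trip with spacing and origin", {
  v <- make_test_volume(c(4, 5, 6), seed = 2, spacing = c(0.5, 0.6, 0.7))
  v$origin <- c(10, -20, 5.5)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  v2 <- read_volume(path)
  expect_equal(v2$data, v$data, tolerance = 1e-7)
  expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)
  expect_equal(v2$origin, v$origin, tolerance = 1e-5)
})

test_that("MetaImage volumes round-trip in both .mhd and .mha forms", {
  v <- make_test_volume(c(5, 4, 3), seed = 3, spacing = c(0.33, 0.33, 0.33))
  for (ext in c(".mhd", ".mha")) {
    dir <- withr::local_tempdir()
    path <- file.path(dir, paste0("vol", ext))
    write_volume(v, path)
    v2 <- read_volume(path)
    expect_identical(v2$data, v$data)
    expect_equal(v2$spacing, c(0.33, 0.33, 0.33))
  }
})

test_that("MetaImage integer element types quantize but keep geometry", {
  v <- volume(array(round(runif(60) * 100), c(5, 4, 3)), spacing = c(1, 2, 3))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "vol.mhd")
  write_volume(v, path, element_type = "MET_SHORT")
  v2 <- read_volume(path)
  expect_identical(v2$data, v$data)  # values were integral
  expect_equal(v2$spacing, v$spacing)
})

test_that("truncated MetaImage payloads and missing spacing are I/O errors", {
  v <- make_test_volume(c(6, 6, 6), seed = 4)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "vol.mhd")
  write_volume(v, path)
  raw_path <- file.path(dir, "vol.raw")
  payload <- readBin(raw_path, "raw", n = file.size(raw_path))
  writeBin(payload[seq_len(length(payload) - 64)], raw_path)
  expect_error(read_volume(path), "truncated")

  # header without ElementSpacing: spacing must never default silently
  hdr <- readLines(path)
  writeLines(hdr[!grepl("ElementSpacing", hdr)], path)
  write_volume(v, file.path(dir, "restore.mhd"))  # regenerate payload file name
  file.copy(file.path(dir, "restore.raw"), raw_path, overwrite = TRUE)
  expect_error(read_volume(path), "ElementSpacing")
})

test_that("unknown formats and missing files are rejected", {
  expect_error(read_volume("nope.xyz"), "not found")
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines("x", f)
  expect_error(read_volume(f), "format")
  expect_error(volume(array(1, c(2, 2, 2)), spacing = c(1, 0, 1)), "positive")
})

test_that("voxel/world conversion is invertible and matches origin + p * spacing", {
  v <- make_test_volume(c(8, 8, 8), spacing = c(0.33, 0.5, 2))
  v$origin <- c(-4, 7, 0.5)
  p <- c(3, 0, 7)
  w <- voxel_to_world(v, p)
  expect_equal(w, v$origin + p * v$spacing)
  expect_equal(world_to_voxel(v, w), p)
})

test_that("landmarks round-trip through JSON and validate against volumes", {
  v <- make_test_volume(c(10, 10, 10), spacing = c(0.33, 0.33, 0.33))
  lm <- landmark("LCA_ostium", c(3, 4, 5), volume = v)
  expect_equal(lm$world_mm, c(3, 4, 5) * 0.33)
  path <- withr::local_tempfile(fileext = ".json")
  write_landmarks(list(lm), path)
  back <- read_landmarks(path, volume = v)
  expect_length(back, 1)
  expect_equal(back[[1]]$name, lm$name)
  expect_equal(back[[1]]$voxel, lm$voxel)
  expect_equal(back[[1]]$world_mm, lm$world_mm)
})

test_that("malformed landmark files raise parse/validation errors", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(list(name = "a")), path, auto_unbox = TRUE)
  expect_error(read_landmarks(path), "voxel")
  writeLines("{not json", path)
  expect_error(read_landmarks(path), "parse")
  v <- make_test_volume(c(5, 5, 5))
  write_landmarks(list(landmark("far", c(40, 2, 2))), path)
  expect_error(read_landmarks(path, volume = v), "outside")
})
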