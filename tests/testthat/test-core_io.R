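# core_io: ImageStack / MissingMask containers and TIFF/MRC round-trips

test_that("image_stack validates input and promotes 2D matrices", {
  a <- array(runif(2 * 3 * 4), dim = c(2, 3, 4))
  st <- image_stack(a, voxel_size = c(8, 5, 5))
  expect_s3_class(st, "ImageStack")
  expect_identical(dim(st), c(2L, 3L, 4L))
  expect_identical(n_slices(st), 2L)
  expect_equal(st$voxel_size, c(8, 5, 5))

  m <- matrix(1:12, 3, 4)
  st2 <- image_stack(m)
  expect_identical(dim(st2), c(1L, 3L, 4L))
  expect_equal(get_slice(st2, 0), matrix(as.double(1:12), 3, 4))

  expect_error(image_stack(1:10), "3D array")
  expect_error(image_stack(array(1, dim = c(2, 2, 2, 2))), "3D array")
  bad <- a; bad[1, 1, 1] <- NA
  expect_error(image_stack(bad), "finite")
  expect_error(image_stack(a, voxel_size = c(1, 2)), "voxel_size")
  expect_error(image_stack(a, voxel_size = c(1, -2, 3)), "voxel_size")
  expect_error(image_stack(a, dtype_origin = 12), "8 or 16")
})

test_that("get_slice/set_slice use 0-based z and bound-check", {
  a <- array(seq_len(3 * 4 * 5), dim = c(3, 4, 5))
  st <- image_stack(a)
  expect_equal(get_slice(st, 0), matrix(a[1, , ], 4, 5))
  expect_equal(get_slice(st, 2), matrix(a[3, , ], 4, 5))
  expect_error(get_slice(st, -1), "out of range")
  expect_error(get_slice(st, 3), "out of range")

  repl <- matrix(-1, 4, 5)
  st2 <- set_slice(st, 1, repl)
  expect_equal(get_slice(st2, 1), repl)
  expect_equal(get_slice(st2, 0), get_slice(st, 0))  # other slices untouched
  expect_error(set_slice(st, 1, matrix(0, 5, 4)), "shape mismatch")
  expect_error(set_slice(st, 5, repl), "out of range")
})

test_that("missing_mask and mask_from_slices", {
  m <- mask_from_slices(c(400, 4, 4), c(295, 293, 294))
  expect_s3_class(m, "MissingMask")
  expect_equal(sum(m$mask), 3 * 4 * 4)
  expect_identical(masked_slices(m), c(293L, 294L, 295L))

  expect_identical(masked_slices(mask_from_slices(c(10, 4, 4), integer(0))),
                   integer(0))
  expect_error(mask_from_slices(c(10, 4, 4), 10), "\\[0, 10\\)")
  expect_error(mask_from_slices(c(10, 4, 4), -1), "\\[0, 10\\)")
  expect_error(missing_mask(matrix(TRUE, 2, 2)), "3D")
  na_mask <- array(TRUE, dim = c(2, 2, 2)); na_mask[1] <- NA
  expect_error(missing_mask(na_mask), "NA")

  # partial-plane masks are not reported as whole masked slices
  pm <- array(FALSE, dim = c(5, 4, 4)); pm[2, 1, 1] <- TRUE
  expect_identical(masked_slices(missing_mask(pm)), integer(0))
})

test_that("integer TIFF round-trips exactly and keeps bit depth", {
  dir <- withr::local_tempdir()
  set.seed(11)
  a8 <- array(sample(0:255, 2 * 9 * 7, replace = TRUE), dim = c(2, 9, 7))
  p8 <- file.path(dir, "a8.tif")
  write_stack(image_stack(a8, dtype_origin = 8), p8)
  r8 <- read_stack(p8)
  expect_identical(r8$dtype_origin, 8L)
  expect_equal(r8$data, a8 * 1.0)

  a16 <- array(sample(0:65535, 3 * 6 * 8, replace = TRUE), dim = c(3, 6, 8))
  p16 <- file.path(dir, "a16.tif")
  write_stack(image_stack(a16, dtype_origin = 16), p16)
  r16 <- read_stack(p16)
  expect_identical(r16$dtype_origin, 16L)
  expect_equal(r16$data, a16 * 1.0)
})

test_that("float TIFF round-trips within float32 precision", {
  dir <- withr::local_tempdir()
  set.seed(12)
  a <- array(runif(4 * 8 * 6), dim = c(4, 8, 6))
  p <- file.path(dir, "f.tif")
  write_stack(image_stack(a), p)
  r <- read_stack(p)
  expect_null(r$dtype_origin)
  expect_lt(max(abs(r$data - a)), 1e-6)

  # out-of-range float data are rescaled with a warning, not corrupted
  b <- a * 4 - 1
  pb <- file.path(dir, "g.tif")
  expect_warning(write_stack(image_stack(b), pb), "rescaling")
  rb <- read_stack(pb)
  expect_lt(max(abs(rb$data - (b - min(b)) / diff(range(b)))), 1e-6)
})

test_that("MRC round-trips arbitrary-range floats with voxel size", {
  dir <- withr::local_tempdir()
  set.seed(13)
  a <- array(rnorm(2 * 3 * 4, sd = 100), dim = c(2, 3, 4))
  p <- file.path(dir, "v.mrc")
  write_stack(image_stack(a, voxel_size = c(8, 5, 5)), p)
  r <- read_stack(p)
  expect_lt(max(abs(r$data - a)) / max(abs(a)), 1e-6)
  expect_equal(r$voxel_size, c(8, 5, 5), tolerance = 1e-6)
  # asymmetric shape proves (z, y, x) axis order survives the round-trip
  expect_identical(dim(r), c(2L, 3L, 4L))
})

test_that("format guessing and error paths", {
  dir <- withr::local_tempdir()
  expect_error(read_stack(file.path(dir, "nope.tif")), "not found")
  expect_error(write_stack(image_stack(array(0.5, dim = c(1, 4, 4))),
                           file.path(dir, "missing_dir", "x.tif")),
               "directory")

  # truncated MRC header
  pt <- file.path(dir, "trunc.mrc")
  writeBin(raw(100), pt)
  expect_error(read_stack(pt), "truncated")

  # a TIFF written under an .mrc name still reads when forced
  a <- array(runif(1 * 8 * 8), dim = c(1, 8, 8))
  px <- file.path(dir, "x.mrc")
  write_stack(image_stack(a), px, format = "tiff")
  expect_error(read_stack(px), "MRC")     # auto-guesses MRC from extension
  r <- read_stack(px, format = "tiff")
  expect_lt(max(abs(r$data - a)), 1e-6)
})

test_that("mask TIFF round-trip", {
  dir <- withr::local_tempdir()
  m <- mask_from_slices(c(6, 5, 7), c(1, 4))
  p <- file.path(dir, "mask.tif")
  write_mask(m, p)
  r <- read_mask(p)
  expect_identical(r$mask, m$mask)
  expect_identical(masked_slices(r), c(1L, 4L))
})
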