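# quality: LoG sharpness, FRC, artifactual-slice detection, FRC validation

# Independent dense-convolution oracle for the sharpness metric: mirror-pad
# explicitly, convolve with an O(n^2 k^2) double loop, take the population
# standard deviation.
sharpness_oracle <- function(img, log_sigma = 2) {
  k <- semrestore:::log_kernel(log_sigma)
  hw <- (nrow(k) - 1L) %/% 2L
  img <- img - mean(img)
  ny <- nrow(img); nx <- ncol(img)
  mi <- function(i, n) {
    i <- abs(i - 1L) + 1L
    i <- ifelse(i > n, 2L * n - i, i)
    i
  }
  pad <- matrix(0, ny + 2 * hw, nx + 2 * hw)
  for (i in seq_len(ny + 2 * hw)) {
    for (j in seq_len(nx + 2 * hw)) {
      pad[i, j] <- img[mi(i - hw, ny), mi(j - hw, nx)]
    }
  }
  out <- matrix(0, ny, nx)
  for (i in seq_len(ny)) {
    for (j in seq_len(nx)) {
      out[i, j] <- sum(pad[i:(i + 2 * hw), j:(j + 2 * hw)] * k)
    }
  }
  sqrt(mean((out - mean(out))^2))
}

test_that("sharpness basic contracts", {
  expect_identical(sharpness(matrix(0.37, 16, 16)), 0)
  set.seed(21)
  img <- matrix(runif(16 * 20), 16, 20)
  s <- sharpness(img)
  expect_gt(s, 0)
  # exact additive-offset invariance
  expect_identical(s, sharpness(img + 5))
  # linear intensity scaling scales the metric linearly
  expect_equal(sharpness(3 * img), 3 * s, tolerance = 1e-12)
  # blur strictly reduces sharpness
  expect_lt(sharpness(semrestore:::gaussian_blur(img, 2)), s)

  expect_error(sharpness(matrix(0, 2, 2)), "3x3")
  expect_error(sharpness(matrix(c(1, NA, 1, 1), 2, 2)), "3x3|non-finite")
  expect_error(sharpness(img, log_sigma = 0), "log_sigma")
  bad <- img; bad[3, 3] <- Inf
  expect_error(sharpness(bad), "non-finite")
})

test_that("sharpness matches a dense mirror-padded convolution oracle", {
  set.seed(22)
  for (dm in list(c(12, 12), c(9, 14))) {
    img <- matrix(rnorm(prod(dm)), dm[1], dm[2])
    expect_equal(sharpness(img, log_sigma = 1.2),
                 sharpness_oracle(img, log_sigma = 1.2), tolerance = 1e-10)
  }
})

test_that("sharpness is approximately invariant to circular shifts", {
  # mirror boundary handling makes this approximate, not exact: tolerate a
  # few percent relative deviation
  set.seed(23)
  img <- matrix(rnorm(48 * 48), 48, 48)
  s0 <- sharpness(img)
  s1 <- sharpness(img[c(9:48, 1:8), c(20:48, 1:19)])
  expect_lt(abs(s1 - s0) / s0, 0.05)
})

test_that("FRC self-correlation is exactly 1 and anti-correlation -1", {
  set.seed(24)
  img <- matrix(rnorm(32 * 32), 32, 32)
  f <- frc(img, img)
  expect_s3_class(f, "FRCCurve")
  expect_lt(max(abs(f$values - 1)), 1e-12)
  expect_equal(f$global_score, 1, tolerance = 1e-12)
  g <- frc(img, -img)
  expect_lt(max(abs(g$values + 1)), 1e-12)
})

test_that("FRC is symmetric, scale-invariant, offset-invariant, bounded", {
  set.seed(25)
  a <- matrix(rnorm(24 * 40), 24, 40)
  b <- a + 0.5 * matrix(rnorm(24 * 40), 24, 40)
  f1 <- frc(a, b); f2 <- frc(b, a)
  expect_equal(f1$values, f2$values, tolerance = 1e-12)
  expect_equal(frc(a, 3 * b)$values, f1$values, tolerance = 1e-12)
  expect_equal(frc(a + 10, b - 2)$values, f1$values, tolerance = 1e-12)
  expect_true(all(abs(f1$values) <= 1 + 1e-12))
  # non-square image: rings span up to Nyquist 0.5 on the normalized axis
  expect_lte(max(f1$ring_radii), 0.5 + f1$ring_width)
})

test_that("FRC of independent noise is near zero", {
  scores <- vapply(1:20, function(s) {
    set.seed(100 + s)
    frc(matrix(rnorm(64 * 64), 64), matrix(rnorm(64 * 64), 64))$global_score
  }, numeric(1))
  expect_lt(mean(abs(scores)), 0.05)
  expect_lt(max(abs(scores)), 0.15)
})

test_that("FRC input validation and options", {
  a <- matrix(rnorm(16 * 16), 16)
  expect_error(frc(a, matrix(0, 8, 8)), "same shape")
  expect_error(frc(a[1:4, ], a[1:4, ]), "8x8")
  expect_error(frc(1:5, 1:5), "matrices")
  expect_error(frc(a, a, ring_width = 0), "ring_width")
  fw <- frc(a, a, weight_by_counts = TRUE)
  expect_equal(fw$global_score, 1, tolerance = 1e-12)
  expect_identical(sum(fw$ring_counts), sum(frc(a, a)$ring_counts))
})

test_that("detection flags planted blur and nothing else", {
  ph <- make_phantom(shape = c(50, 48, 48), independent_slices = TRUE, seed = 31)
  deg <- degrade(ph, degradation_spec(
    blur_slices = c("12" = 4, "30" = 4, "31" = 4), seed = 31))
  rep <- detect_artifactual_slices(deg$degraded)
  expect_identical(rep$flagged, c(12L, 30L, 31L))
  expect_length(rep$sharpness, 50)
  expect_identical(rep$threshold_rule$rule, "robust_z")
})

test_that("detection edge cases and rules", {
  ph <- tiny_phantom(shape = c(8, 32, 32), seed = 32)
  # a zero-filled (dropped) slice is always flagged by the robust rule
  dropped <- set_slice(ph, 3, matrix(0, 32, 32))
  expect_true(3L %in% detect_artifactual_slices(dropped)$flagged)

  # identical slices: MAD collapses but the floor prevents false positives
  one <- get_slice(ph, 0)
  same <- image_stack(array(rep(one, each = 1), dim = c(6, 32, 32)))
  for (z in 0:5) same <- set_slice(same, z, one)
  expect_length(detect_artifactual_slices(same)$flagged, 0)

  expect_error(detect_artifactual_slices(image_stack(ph$data[1:4, , ])),
               "at least 5 slices")
  const <- image_stack(array(1, dim = c(6, 32, 32)))
  expect_error(detect_artifactual_slices(const), "nonzero sharpness")
  expect_error(detect_artifactual_slices(ph, rule = "absolute"), "cutoff")

  s <- vapply(0:7, function(z) sharpness(get_slice(ph, z)), numeric(1))
  cut <- sort(s)[3] * 1.0000001
  abs_rep <- detect_artifactual_slices(ph, rule = "absolute", cutoff = cut)
  expect_identical(sort(abs_rep$flagged), sort(which(s < cut) - 1L))
  expect_identical(abs_rep$threshold_rule$cutoff, cut)
})

test_that("frc_validation scores replaced slices against distant references", {
  ph <- tiny_phantom(shape = c(12, 48, 48), seed = 33)
  # blur + noise mimics a defocused acquisition: blur alone nearly cancels in
  # the FRC per-ring normalization, noise decorrelates the crushed band
  set.seed(33)
  bad <- semrestore:::gaussian_blur(get_slice(ph, 5), 4) +
    matrix(rnorm(48 * 48, 0, 0.02), 48, 48)
  blurred <- set_slice(ph, 5, bad)
  v <- frc_validation(blurred, ph, target_slices = 5, plane_range = 3)
  expect_identical(nrow(v), 1L)
  expect_identical(v$slice, 5L)
  expect_gte(abs(v$reference - 5L), 3L)
  expect_false(v$reference %in% 5L)
  expect_gt(v$frc_after, v$frc_before)
  expect_true(v$accepted)

  # flagged slices are never used as references
  v2 <- frc_validation(blurred, ph, target_slices = 5, plane_range = 3,
                       flagged = c(5L, 8L))
  expect_false(v2$reference %in% c(5L, 8L))

  # no in-range reference -> warning and empty result
  expect_warning(v3 <- frc_validation(blurred, ph, target_slices = 5,
                                      plane_range = 50),
                 "no valid reference")
  expect_identical(nrow(v3), 0L)

  expect_error(frc_validation(blurred, image_stack(ph$data[1:4, , ]), 1),
               "shape mismatch")
  expect_error(frc_validation(blurred, ph, 1, plane_range = 0), "plane_range")
})
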