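# corrections: PSF estimation and Richardson-Lucy deconvolution

test_that("gaussian_psf builds a normalized symmetric kernel", {
  psf <- gaussian_psf(1.5)
  expect_s3_class(psf, "PSFModel")
  expect_equal(sum(psf$kernel), 1, tolerance = 1e-12)
  expect_equal(psf$kernel, t(psf$kernel), tolerance = 1e-15)
  expect_equal(psf$kernel, psf$kernel[rev(seq_len(nrow(psf$kernel))), ],
               tolerance = 1e-15)
  expect_error(gaussian_psf(0), "sigma")
})

test_that("estimate_psf recovers planted blur within tolerance", {
  img <- get_slice(make_phantom(shape = c(8, 128, 128), seed = 61), 4)
  est <- estimate_psf(semrestore:::gaussian_blur(img, 2))
  expect_gt(est$sigma, 1.5)
  expect_lt(est$sigma, 2.5)
})

test_that("estimate_psf is strictly monotone in the true blur", {
  img <- get_slice(make_phantom(shape = c(8, 128, 128), seed = 62), 4)
  sig <- vapply(c(1, 2, 3), function(s) {
    estimate_psf(semrestore:::gaussian_blur(img, s))$sigma
  }, numeric(1))
  expect_true(all(diff(sig) > 0))
})

test_that("estimate_psf degenerate inputs warn and fall back", {
  # a constant image has no usable spectrum at all
  img <- matrix(0.5, 64, 64)
  expect_warning(est <- estimate_psf(img, sigma_grid = c(1, 2, 3)),
                 "degenerate")
  expect_identical(est$sigma, 1)
  expect_error(estimate_psf(matrix(0, 16, 16)), "32x32")
  expect_error(estimate_psf(matrix(0, 64, 64), sigma_grid = numeric(0)),
               "sigma_grid")
})

test_that("richardson_lucy with an identity PSF is a fixed point", {
  set.seed(63)
  img <- matrix(runif(32 * 32, 0.1, 1), 32, 32)
  delta <- structure(list(kind = "delta", sigma = 0, kernel = matrix(1, 1, 1),
                          support = 0), class = "PSFModel")
  out <- richardson_lucy(img, delta, deconvolution_params(n_iter = 10))
  expect_lt(max(abs(out - img)), 1e-6)
})

test_that("richardson_lucy conserves flux and sharpens blurred content", {
  img <- get_slice(make_phantom(shape = c(8, 64, 64), seed = 64), 3)
  blurred <- semrestore:::gaussian_blur(img, 2)
  out <- richardson_lucy(blurred, gaussian_psf(2), deconvolution_params(n_iter = 50))
  expect_lt(abs(sum(out) - sum(blurred)) / sum(blurred), 1e-3)
  expect_gt(sharpness(out), sharpness(blurred))
  expect_true(all(out >= 0))
  expect_error(richardson_lucy(1:3, gaussian_psf(1)), "matrix")
  bad <- gaussian_psf(1); bad$kernel <- bad$kernel * 2
  expect_error(richardson_lucy(img, bad), "sum to 1")
})

test_that("richardson_lucy decreases the Poisson objective on noiseless data", {
  # KL divergence between the observation and the reblurred estimate must
  # fall monotonically with iteration count on clean data
  img <- get_slice(make_phantom(shape = c(8, 48, 48), seed = 65), 2)
  psf <- gaussian_psf(1.5)
  y <- semrestore:::conv2_circular(img, psf$kernel)
  kl <- vapply(c(1, 5, 20, 50), function(n) {
    u <- richardson_lucy(y, psf, deconvolution_params(n_iter = n,
                                                      clip_negative = FALSE))
    est <- semrestore:::conv2_circular(u, psf$kernel)
    est <- pmax(est, 1e-12)
    sum(est - y * log(est))
  }, numeric(1))
  expect_true(all(diff(kl) < 1e-9))
})

test_that("TV-regularized RL stays close to the plain result on clean data", {
  img <- get_slice(make_phantom(shape = c(8, 48, 48), seed = 66), 2)
  blurred <- semrestore:::gaussian_blur(img, 2)
  plain <- richardson_lucy(blurred, gaussian_psf(2), deconvolution_params(n_iter = 20))
  tv <- richardson_lucy(blurred, gaussian_psf(2),
                        deconvolution_params(n_iter = 20, tv_weight = 0.002))
  expect_gt(sharpness(tv), sharpness(blurred))
  expect_lt(rmse_(tv, plain), 0.1 * diff(range(blurred)))
})

test_that("deconvolve_stack applies per-slice PSFs and reports sigmas", {
  ph <- make_phantom(shape = c(8, 64, 64), seed = 67)
  st <- ph
  for (z in 0:7) {
    st <- set_slice(st, z, semrestore:::gaussian_blur(get_slice(ph, z), 2))
  }
  res <- deconvolve_stack(st, deconvolution_params(n_iter = 20), sigma = 2)
  expect_length(res$sigmas, 8)
  expect_true(all(res$sigmas == 2))
  for (z in 0:7) {
    expect_gt(sharpness(get_slice(res$stack, z)), sharpness(get_slice(st, z)))
  }
})

test_that("deconvolution_params validation", {
  expect_error(deconvolution_params(n_iter = 0), "n_iter")
  expect_error(deconvolution_params(tv_weight = -1), "tv_weight")
})
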