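# inpainting: multiscale, DCT (Garcia), harmonic, TV -- all natively 3D

test_that("inpaint contracts: empty mask, known voxels, full mask, dispatch", {
  ph <- tiny_phantom(shape = c(8, 32, 32), seed = 81)
  empty <- missing_mask(array(FALSE, dim = dim(ph)))
  expect_identical(inpaint(ph, empty), ph)

  m <- mask_from_slices(dim(ph), 4)
  for (fun in list(inpaint_harmonic, inpaint_dct, inpaint_tv, inpaint_multiscale)) {
    out <- fun(ph, m)
    # known voxels are bit-identical, the masked slice actually changed
    expect_identical(out$data[-5, , ], ph$data[-5, , ])
    expect_gt(max(abs(out$data[5, , ] - ph$data[5, , ])), 0)
  }

  full <- missing_mask(array(TRUE, dim = dim(ph)))
  expect_error(inpaint(ph, full), "fully masked")
  expect_error(inpaint(ph, mask_from_slices(c(9, 32, 32), 1)), "does not match")
})

test_that("a masked run longer than max_slice_run warns", {
  ph <- tiny_phantom(shape = c(12, 32, 32), seed = 82)
  m <- mask_from_slices(dim(ph), 3:8)    # run of 6 > default 5
  expect_warning(inpaint_harmonic(ph, m), "consecutive slices")
  expect_silent(suppressMessages(
    inpaint(ph, m, inpaint_params("harmonic", max_slice_run = 6L))))
})

test_that("harmonic inpainting reproduces a discrete-harmonic function", {
  vol <- harmonic_volume(c(8, 8, 8))
  m <- array(FALSE, dim = c(8, 8, 8))
  m[3:6, 3:6, 3:6] <- TRUE
  out <- inpaint(vol, missing_mask(m), inpaint_params("harmonic", tol = 1e-9))
  expect_lt(max(abs(out$data - vol$data)), 1e-6)
})

test_that("harmonic inpainting matches the direct sparse solve", {
  set.seed(84)
  for (dm in list(c(6, 7, 8), c(16, 16, 16))) {
    base <- array(rnorm(prod(dm)), dim = dm)
    sm <- semrestore:::tv_denoise(base, weight = 0.3, n_iter = 5)
    vol <- image_stack(sm)
    m <- array(runif(prod(dm)) < 0.2, dim = dm)
    m[1, 1, 1] <- FALSE                     # keep at least one known voxel
    out <- inpaint(vol, missing_mask(m), inpaint_params("harmonic", tol = 1e-9))
    oracle <- harmonic_oracle(vol$data, m)
    expect_lt(max(abs(out$data[which(m)] - oracle)), 1e-6)
  }
})

test_that("harmonic inpainting in 2D (single slice) and the maximum principle", {
  f <- outer(1:16, 1:16, function(y, x) 2 * x - 3 * y)
  vol <- image_stack(f)
  m <- array(FALSE, dim = c(1, 16, 16)); m[1, 5:12, 6:11] <- TRUE
  out <- inpaint_harmonic(vol, missing_mask(m),
                          inpaint_params("harmonic", tol = 1e-9))
  expect_lt(max(abs(out$data - vol$data)), 1e-6)

  set.seed(85)
  r <- image_stack(array(runif(16 * 16), dim = c(1, 16, 16)))
  ro <- inpaint_harmonic(r, missing_mask(m))
  filled <- ro$data[m]
  expect_gte(min(filled), min(r$data[!m]) - 1e-9)
  expect_lte(max(filled), max(r$data[!m]) + 1e-9)
})

test_that("DCT inpainting matches the dense penalized least-squares solve", {
  set.seed(86)
  dm <- c(8, 8, 8)
  base <- array(rnorm(prod(dm)), dim = dm)
  y <- semrestore:::tv_denoise(base, weight = 0.5, n_iter = 10)
  m <- array(runif(prod(dm)) < 0.2, dim = dm)
  m[1, 1, 1] <- FALSE
  params <- inpaint_params("dct", max_iter = 2000, tol = 1e-9)
  out <- inpaint(image_stack(y), missing_mask(m), params)
  s_final <- min(params$dct_smoothing_schedule)
  oracle <- dct_oracle(y, m, s_final)
  rel <- rmse_(out$data[m], oracle[m]) / max(sd(y), 1e-12)
  expect_lt(rel, 1e-3)
})

test_that("DCT slice replacement restores high FRC against the truth", {
  ph <- make_phantom(shape = c(16, 64, 64), bead_fraction = 0, seed = 87)
  m <- mask_from_slices(dim(ph), 8)
  out <- inpaint_dct(ph, m)
  score <- frc(get_slice(out, 8), get_slice(ph, 8))$global_score
  expect_gt(score, 0.9)
})

test_that("TV inpainting keeps a step edge sharp", {
  # vertical step; a band of missing columns crossing it
  dm <- c(4, 32, 32)
  truth <- array(rep(rep(c(0, 1), each = 16), each = dm[1] * dm[2] / 2), dim = dm)
  truth <- array(0, dim = dm); truth[, , 17:32] <- 1
  m <- array(FALSE, dim = dm); m[, 9:24, 13:20] <- TRUE
  vol <- image_stack(truth)
  tv <- inpaint_tv(vol, missing_mask(m), inpaint_params("tv", max_iter = 200))
  harm <- inpaint_harmonic(vol, missing_mask(m))
  err_tv <- rmse_(tv$data[m], truth[m])
  err_h <- rmse_(harm$data[m], truth[m])
  expect_lt(err_tv, err_h)           # TV preserves the edge better
  # the reconstructed transition stays within one voxel of the true edge
  mid <- tv$data[2, 16, ]
  expect_true(all(mid[1:15] < 0.5))
  expect_true(all(mid[18:32] > 0.5))
})

test_that("multiscale inpainting is bounded and beats slice copying under drift", {
  ph <- make_phantom(shape = c(16, 64, 64), seed = 88, drift_amplitude = 8)
  m <- mask_from_slices(dim(ph), 7)
  out <- inpaint_multiscale(ph, m)
  filled <- out$data[8, , ]
  expect_gte(min(filled), min(ph$data[-8, , ]) - 1e-9)
  expect_lte(max(filled), max(ph$data[-8, , ]) + 1e-9)
  # with in-plane structure drifting >= 1 px/slice, blending both neighbours
  # beats copying either one
  err_ms <- rmse_(filled, ph$data[8, , ])
  err_copy <- min(rmse_(ph$data[7, , ], ph$data[8, , ]),
                  rmse_(ph$data[9, , ], ph$data[8, , ]))
  expect_lt(err_ms, err_copy)
})

test_that("inpaint_params validates method and parameters", {
  expect_error(inpaint_params("nope"), "arg")
  expect_error(inpaint_params("dct", max_iter = 0), "max_iter")
  expect_error(inpaint_params("tv", tv_weight = -1), "tv_weight")
  p <- inpaint_params("harmonic")
  expect_identical(p$max_iter, 10000L)
  expect_equal(p$tol, 1e-6)
})
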