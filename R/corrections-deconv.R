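#' Gaussian PSF model
#'
#' Defocus in FIB-SEM acquisitions is modelled as an isotropic Gaussian
#' point spread function, the dominant focus artifact; its single parameter
#' can be estimated per slice from the image spectrum ([estimate_psf()]).
#'
#' @param sigma Blur scale in pixels (> 0).
#' @param support Kernel half-width in pixels (default `ceiling(4 * sigma)`).
#' @return A `PSFModel`: `kind`, `sigma`, normalized `kernel` (sums to 1),
#'   `support`.
#' @export
gaussian_psf <- function(sigma, support = ceiling(4 * sigma)) {
  if (sigma <= 0) stop("`sigma` must be > 0")
  k <- gaussian_kernel(sigma, half_width = support)
  structure(list(kind = "gaussian", sigma = sigma, kernel = k, support = support),
            class = "PSFModel")
}

#' @export
print.PSFModel <- function(x, ...) {
  cat(sprintf("PSFModel: %s, sigma = %.3f px, support = %d px\n",
              x$kind, x$sigma, x$support))
  invisible(x)
}

#' Estimate the defocus PSF of a slice from its power spectrum
#'
#' Fits a Gaussian modulation transfer function to the radially averaged log
#' power spectrum: for each candidate sigma the model
#' `log P(f) = a - 4 pi^2 sigma^2 f^2` is fitted by least squares over the
#' usable frequency band, and the candidate with the smallest residual is
#' refined sub-grid by a parabolic fit over its neighbours. The usable band
#' excludes rings at the noise floor (estimated from the highest
#' frequencies) and rings more than ~50 dB below the strongest used ring,
#' where spectral leakage rather than the attenuated signal dominates.
#'
#' The estimate reflects the total Gaussian spectral width, i.e. defocus
#' blur combined with the intrinsic correlation scale of the specimen
#' texture; for visibly defocused slices the blur term dominates.
#'
#' @param image 2D matrix, at least 32x32.
#' @param sigma_grid Candidate sigmas in pixels (positive, non-empty).
#' @param band Frequency band (cycles/pixel) used for the fit.
#' @return A [gaussian_psf()] at the best-fit sigma. A degenerate (flat)
#'   spectrum returns the smallest candidate with a warning.
#' @export
estimate_psf <- function(image, sigma_grid = seq(0.5, 6, by = 0.25),
                         band = c(0.05, 0.45)) {
  if (!is.matrix(image) || any(dim(image) < 32L)) stop("`image` must be at least 32x32")
  if (!length(sigma_grid) || any(sigma_grid <= 0)) {
    stop("`sigma_grid` must be non-empty and positive")
  }
  sigma_grid <- sort(sigma_grid)
  rp <- radial_power_profile(image)
  sel <- rp$f >= band[1] & rp$f <= band[2]
  # exclude rings at/below the noise floor (median power beyond 0.4 c/px)
  floor_est <- stats::median(rp$power[rp$f > 0.4])
  if (is.finite(floor_est) && floor_est > 0) sel <- sel & rp$power > 16 * floor_est
  # and rings dominated by residual spectral leakage
  if (any(sel)) sel <- sel & rp$power > max(rp$power[sel]) * exp(-12)
  f <- rp$f[sel]; y <- log(pmax(rp$power[sel], .Machine$double.xmin))
  if (length(f) < 4L || stats::sd(y) < 1e-8) {
    warning("degenerate spectrum; returning smallest candidate sigma")
    return(gaussian_psf(sigma_grid[1]))
  }
  rss <- vapply(sigma_grid, function(s) {
    yy <- y + 4 * pi^2 * s^2 * f^2
    sum((yy - mean(yy))^2)
  }, numeric(1))
  i <- which.min(rss)
  sigma <- sigma_grid[i]
  if (i > 1L && i < length(sigma_grid)) {
    # parabolic refinement on the residual curve
    s0 <- sigma_grid[i - 1]; s1 <- sigma_grid[i]; s2 <- sigma_grid[i + 1]
    r0 <- rss[i - 1]; r1 <- rss[i]; r2 <- rss[i + 1]
    denom <- r0 - 2 * r1 + r2
    if (denom > 0) {
      delta <- 0.5 * (r0 - r2) / denom
      sigma <- s1 + delta * (s2 - s0) / 2
      sigma <- min(max(sigma, s0), s2)
    }
  }
  gaussian_psf(sigma)
}

# Radially averaged power spectrum in 1-Fourier-pixel rings (DC excluded).
# A Hann window suppresses the spectral leakage of the non-periodic image,
# which would otherwise flood the attenuated high frequencies.
radial_power_profile <- function(image) {
  ny <- nrow(image); nx <- ncol(image)
  w <- outer(hann_window(ny), hann_window(nx))
  P <- Mod(fft2((image - mean(image)) * w))^2
  r <- fft_radius(ny, nx)
  width <- 1 / min(ny, nx)
  sel <- r > 0 & r <= 0.5 + 1e-12
  bin <- as.integer(ceiling(r[sel] / width))
  pw <- as.vector(rowsum(P[sel], bin)) / as.vector(rowsum(rep(1, sum(sel)), bin))
  bins <- sort(unique(bin))
  list(f = (bins - 0.5) * width, power = pw)
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))

#' Deconvolution parameters
#'
#' @param n_iter Richardson-Lucy iteration count (default 50).
#' @param tv_weight Total-variation regularization weight; 0 (the default)
#'   is plain Richardson-Lucy, preferred for speed.
#' @param clip_negative Clamp negative values in the result to 0.
#' @return A `DeconvolutionParams` list.
#' @export
deconvolution_params <- function(n_iter = 50, tv_weight = 0, clip_negative = TRUE) {
  if (n_iter < 1) stop("`n_iter` must be >= 1")
  if (tv_weight < 0) stop("`tv_weight` must be >= 0")
  structure(list(n_iter = as.integer(n_iter), tv_weight = tv_weight,
                 clip_negative = clip_negative),
            class = "DeconvolutionParams")
}

#' Richardson-Lucy deconvolution of a slice
#'
#' Iterative maximum-likelihood deconvolution for Poisson noise with the
#' standard multiplicative update
#' `u <- u * corr(y / conv(u, h), h)`; with `tv_weight > 0` each update is
#' additionally divided by the total-variation regularization factor
#' `1 - tv_weight * div(grad u / |grad u|)`. Convolution is periodic via
#' FFT, so total flux is conserved exactly for a normalized PSF. Negative
#' inputs are shifted to nonnegative before iterating and the shift undone
#' afterwards.
#'
#' @param image 2D matrix.
#' @param psf A [gaussian_psf()] (or any `PSFModel` with a normalized kernel).
#' @param params A [deconvolution_params()].
#' @return Deconvolved matrix of the same shape.
#' @export
richardson_lucy <- function(image, psf, params = deconvolution_params()) {
  if (!is.matrix(image)) stop("`image` must be a matrix")
  kern <- psf$kernel
  if (abs(sum(kern) - 1) > 1e-9) stop("PSF kernel must sum to 1")
  shift <- 0
  if (min(image) < 0) {
    shift <- -min(image)
    image <- image + shift
  }
  ny <- nrow(image); nx <- ncol(image)
  H <- fft2(embed_kernel(kern, ny, nx))
  Hc <- Conj(H)
  eps <- .Machine$double.eps * max(image, 1)
  u <- image
  u[u <= 0] <- eps
  for (it in seq_len(params$n_iter)) {
    est <- Re(ifft2(fft2(u) * H))
    ratio <- image / pmax(est, eps)
    corr <- Re(ifft2(fft2(ratio) * Hc))
    u <- u * corr
    if (params$tv_weight > 0) {
      u <- u / pmax(1 - params$tv_weight * curvature(u), 0.1)
    }
    u[u < 0] <- 0
  }
  u <- u - shift
  if (params$clip_negative) u[u < 0] <- 0
  u
}

# div(grad u / |grad u|): mean-curvature term of the TV-regularized RL update.
curvature <- function(u) {
  gy <- fdiff(u, 1L); gx <- fdiff(u, 2L)
  gn <- sqrt(gy^2 + gx^2)
  gn[gn < 1e-8] <- 1e-8
  bdiff(gy / gn, 1L) + bdiff(gx / gn, 2L)
}

#' Deconvolve every slice of a stack
#'
#' Per-slice focus correction: estimates a Gaussian PSF for each slice (or
#' uses one fixed sigma) and applies Richardson-Lucy deconvolution.
#'
#' @param stack An [image_stack()].
#' @param params A [deconvolution_params()].
#' @param sigma `"auto"` for per-slice spectral estimation (the default,
#'   since focus drifts between acquisitions) or a fixed numeric sigma.
#' @param sigma_grid Candidate grid for the per-slice estimate.
#' @param n_workers Parallel workers for the slice loop.
#' @return List with `stack` (deconvolved) and `sigmas` (per-slice values).
#' @export
deconvolve_stack <- function(stack, params = deconvolution_params(),
                             sigma = "auto", sigma_grid = seq(0.5, 6, by = 0.25),
                             n_workers = 1L) {
  nz <- n_slices(stack)
  op <- function(img) {
    psf <- if (identical(sigma, "auto")) estimate_psf(img, sigma_grid) else gaussian_psf(sigma)
    list(img = richardson_lucy(img, psf, params), sigma = psf$sigma)
  }
  res <- run_slicewise(stack, function(img) op(img), n_workers)
  out <- stack
  for (z in seq_len(nz)) out$data[z, , ] <- res[[z]]$img
  list(stack = out, sigmas = vapply(res, function(r) r$sigma, numeric(1)))
}
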