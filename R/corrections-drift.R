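#' Estimate the drift between two slices by multi-scale cross-correlation
#'
#' Coarse-to-fine registration: image pyramids are built by factor-2 block
#' averaging; at the coarsest level the full cross-correlation peak is
#' located, and each finer level searches a small window around the doubled
#' coarse estimate. The finest level refines the integer peak to subpixel
#' precision by local Fourier-domain upsampling of the correlation surface.
#'
#' @param reference,moving 2D matrices of the same shape.
#' @param levels Pyramid depth (>= 1); the smallest dimension at the
#'   coarsest level must be >= 8.
#' @param search Half-width in pixels of the per-level refinement window.
#' @return Numeric `(dy, dx)` such that `moving` is `reference` translated
#'   by `(dy, dx)`.
#' @export
estimate_drift <- function(reference, moving, levels = 3L, search = 3L) {
  if (!is.matrix(reference) || !is.matrix(moving)) stop("inputs must be matrices")
  if (!all(dim(reference) == dim(moving))) stop("images must have the same shape")
  if (levels < 1) stop("`levels` must be >= 1")
  if (min(dim(reference)) / 2^(levels - 1) < 8) {
    stop("pyramid too deep: coarsest level smaller than 8 pixels")
  }
  if (stats::sd(reference) == 0 || stats::sd(moving) == 0) {
    stop("cannot register a flat (zero-variance) image")
  }
  pyr_ref <- build_pyramid(reference, levels)
  pyr_mov <- build_pyramid(moving, levels)
  est <- c(0, 0)
  for (lev in seq.int(levels, 1L)) {
    a <- pyr_ref[[lev]]; b <- pyr_mov[[lev]]
    cc <- cross_correlation(a, b)
    if (lev == levels) {
      pk <- cc_peak(cc)                       # full search at the coarsest level
    } else {
      est <- est * 2
      pk <- cc_peak(cc, center = round(est), window = search)
    }
    est <- pk
  }
  # subpixel refinement at the finest level
  refine_subpixel(pyr_ref[[1L]], pyr_mov[[1L]], round(est))
}

build_pyramid <- function(x, levels) {
  pyr <- vector("list", levels)
  pyr[[1L]] <- x
  for (l in seq_len(levels - 1L)) pyr[[l + 1L]] <- downsample2(pyr[[l]])
  pyr
}

# Normalized cross-power spectrum (phase correlation): whitening sharpens
# the correlation peak to near-delta, removing the bias a broad plain
# cross-correlation peak has on smooth images. A radial Gaussian low-pass
# (cutoff in cycles/pixel) suppresses the high frequencies where genuine
# slice-to-slice content change decorrelates the phases.
cross_spectrum <- function(reference, moving, lowpass = 0.25) {
  a <- reference - mean(reference)
  b <- moving - mean(moving)
  CP <- fft2(b) * Conj(fft2(a))
  CP <- CP / (Mod(CP) + 1e-9 * max(Mod(CP)))
  if (is.finite(lowpass) && lowpass > 0) {
    r <- fft_radius(nrow(CP), ncol(CP))
    CP <- CP * exp(-(r / lowpass)^2)
  }
  CP
}

# Circular correlation surface; the peak at wrapped index (dy, dx) means
# moving ~ translate(reference, dy, dx).
cross_correlation <- function(reference, moving) {
  Re(ifft2(cross_spectrum(reference, moving))) * length(reference)
}

wrap_index <- function(i, n) ((i %% n) + n) %% n

# Integer peak of the correlation surface as a signed (dy, dx) shift,
# optionally restricted to a window around a prior estimate.
cc_peak <- function(cc, center = NULL, window = NULL) {
  ny <- nrow(cc); nx <- ncol(cc)
  if (is.null(center)) {
    i <- which.max(cc)
    iy <- (i - 1L) %% ny
    ix <- (i - 1L) %/% ny
  } else {
    oy <- wrap_index(center[1] + (-window:window), ny)
    ox <- wrap_index(center[2] + (-window:window), nx)
    sub <- cc[oy + 1L, ox + 1L, drop = FALSE]
    i <- which.max(sub)
    iy <- oy[((i - 1L) %% nrow(sub)) + 1L]
    ix <- ox[((i - 1L) %/% nrow(sub)) + 1L]
  }
  c(signed_shift(iy, ny), signed_shift(ix, nx))
}

signed_shift <- function(i, n) if (i > n / 2) i - n else i

# Subpixel refinement by local DFT upsampling of the correlation surface
# around the integer peak: the correlation is evaluated on a fine grid
# (step 1/upsample px, +-1.5 px window) directly from the cross spectrum by
# matrix DFTs, and the fine-grid maximum taken.
refine_subpixel <- function(reference, moving, peak, upsample = 16L) {
  CP <- cross_spectrum(reference, moving)
  ny <- nrow(CP); nx <- ncol(CP)
  fy <- fft_freq(ny); fx <- fft_freq(nx)
  grid <- seq(-1.5, 1.5, by = 1 / upsample)
  uy <- peak[1] + grid
  ux <- peak[2] + grid
  Ey <- exp(2i * pi * outer(uy, fy))
  Ex <- exp(2i * pi * outer(ux, fx))
  R <- Re(Ey %*% CP %*% t(Ex))
  i <- which.max(R)
  c(uy[((i - 1L) %% nrow(R)) + 1L], ux[((i - 1L) %/% nrow(R)) + 1L])
}

#' Align a stack by multi-scale cross-correlation
#'
#' Pairwise drift is estimated with [estimate_drift()] for slice pairs at
#' several z-lags (1 and 2 by default) and the absolute trajectory
#' relative to slice 0 is solved by least squares over all pair estimates.
#' The longer lags pin down the long-range accumulation that a purely
#' sequential chain of noisy lag-1 estimates would drift away on. Each slice
#' is then resampled by its negated shift (separable cubic splines, edge
#' values extended). A consecutive pair whose registration fails inherits
#' the previous pair's relative shift with a warning.
#'
#' @param stack An [image_stack()] with at least 2 slices.
#' @param levels Pyramid depth for [estimate_drift()].
#' @param lags z-lags of the registered slice pairs (lag 1 is always
#'   included).
#' @return List with `aligned` (an [image_stack()]) and `trajectory`, a
#'   `DriftTrajectory` (`shifts`: n_z x 2 matrix of (dy, dx) relative to
#'   slice 0, first row (0, 0); `levels`).
#' @export
align_stack <- function(stack, levels = 3L, lags = c(1L, 2L)) {
  nz <- n_slices(stack)
  if (nz < 2L) stop("alignment needs at least 2 slices")
  lags <- sort(unique(c(1L, as.integer(lags))))
  lags <- lags[lags >= 1L & lags < nz]
  obs_i <- integer(0); obs_j <- integer(0); obs <- matrix(0, 0, 2)
  prev_rel <- c(0, 0)
  for (L in lags) {
    for (i in 0:(nz - 1L - L)) {
      est <- tryCatch(
        estimate_drift(get_slice(stack, i), get_slice(stack, i + L), levels),
        error = function(e) {
          if (L == 1L) {
            warning("drift estimate failed for slice pair (", i, ", ", i + 1L,
                    "): ", conditionMessage(e), "; reusing previous shift")
            prev_rel
          } else NULL
        })
      if (is.null(est)) next
      if (L == 1L) prev_rel <- est
      obs_i <- c(obs_i, i); obs_j <- c(obs_j, i + L)
      obs <- rbind(obs, est)
    }
  }
  abs_shift <- solve_trajectory(nz, obs_i, obs_j, obs)
  aligned <- stack
  for (z in seq_len(nz)) {
    if (any(abs_shift[z, ] != 0)) {
      aligned$data[z, , ] <- translate_image(get_slice(stack, z - 1L),
                                             -abs_shift[z, 1], -abs_shift[z, 2])
    }
  }
  trajectory <- structure(list(shifts = abs_shift, levels = as.integer(levels)),
                          class = "DriftTrajectory")
  list(aligned = aligned, trajectory = trajectory)
}

# Least-squares trajectory from pairwise shift observations
# s_k ~ a[j_k] - a[i_k] with a[0] fixed at (0, 0); solved per axis via the
# normal equations (a graph Laplacian system, dense solve at stack scale).
solve_trajectory <- function(nz, obs_i, obs_j, obs) {
  n <- nz - 1L                       # unknowns: a_1 .. a_{nz-1}
  AtA <- matrix(0, n, n)
  Atb <- matrix(0, n, 2)
  for (k in seq_along(obs_i)) {
    i <- obs_i[k]; j <- obs_j[k]
    if (j > 0) { AtA[j, j] <- AtA[j, j] + 1; Atb[j, ] <- Atb[j, ] + obs[k, ] }
    if (i > 0) { AtA[i, i] <- AtA[i, i] + 1; Atb[i, ] <- Atb[i, ] - obs[k, ] }
    if (i > 0 && j > 0) { AtA[i, j] <- AtA[i, j] - 1; AtA[j, i] <- AtA[j, i] - 1 }
  }
  a <- solve(AtA + diag(1e-9, n), Atb)
  rbind(c(0, 0), a)
}

#' @export
print.DriftTrajectory <- function(x, ...) {
  mag <- sqrt(rowSums(x$shifts^2))
  cat(sprintf("DriftTrajectory: %d slices, max |shift| %.2f px (pyramid depth %d)\n",
              nrow(x$shifts), max(mag), x$levels))
  invisible(x)
}
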