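#' Synthetic FIB-SEM-like phantom
#'
#' Generates a smooth test volume emulating a resin-embedded sample imaged
#' by FIB-SEM: a low-intensity background, a "matrix" of smooth 3D Gaussian
#' blobs whose in-plane centroids drift smoothly along z (so adjacent slices
#' are correlated but not identical, as in a real milling series), and small
#' bright spheres of 2-4 px radius mimicking colloidal gold beads.
#' Intensities lie in the unit interval.
#'
#' Blob z-profiles wrap around the stack so slice statistics are stationary
#' along z (no fading towards the first/last slices), which keeps the
#' sharpness profile of a clean phantom flat.
#'
#' @param shape `(n_z, n_y, n_x)`, at least `(8, 32, 32)`.
#' @param n_blobs Number of Gaussian matrix blobs.
#' @param bead_fraction Number of beads as a fraction of `n_blobs`.
#' @param drift_amplitude Peak-to-peak in-plane wander of blob centroids
#'   across the stack, in pixels.
#' @param independent_slices If `TRUE`, every slice is an independent 2D
#'   draw of the same texture statistics (no correlation between slices) --
#'   the fixture for slice-quality statistics; the default `FALSE` gives a
#'   smooth correlated volume.
#' @param texture_amplitude Standard deviation of the fine-grain matrix
#'   texture (band-limited noise) overlaid on the blobs; 0 disables it.
#' @param texture_sigma Gaussian correlation scales `(z, y, x)` of the
#'   texture in voxels; a larger z scale yields stronger slice-to-slice
#'   continuity.
#' @param seed RNG seed; the same seed yields an identical stack.
#' @return An [image_stack()].
#' @export
make_phantom <- function(shape = c(40, 64, 64), n_blobs = 30,
                         bead_fraction = 0.3, drift_amplitude = 6,
                         independent_slices = FALSE,
                         texture_amplitude = 0.06,
                         texture_sigma = c(3, 0.9, 0.9), seed = 1) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || shape[1] < 8L || shape[2] < 32L || shape[3] < 32L) {
    stop("`shape` must be at least (8, 32, 32)")
  }
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  set.seed(seed)
  vol <- array(0.1, dim = shape)   # background
  ys <- seq_len(ny); xs <- seq_len(nx)
  if (independent_slices) {
    for (z in seq_len(nz)) {
      sl <- phantom_slice(ny, nx, n_blobs, bead_fraction)
      if (texture_amplitude > 0) {
        tex <- gaussian_blur(matrix(stats::rnorm(ny * nx), ny, nx), 0.9)
        sl <- sl + texture_amplitude * tex / stats::sd(tex)
      }
      vol[z, , ] <- sl
    }
    vol[vol > 1] <- 1
    vol[vol < 0] <- 0
    return(image_stack(vol))
  }
  if (n_blobs > 0) {
    cy0 <- stats::runif(n_blobs, 1, ny)
    cx0 <- stats::runif(n_blobs, 1, nx)
    cz <- stats::runif(n_blobs, 1, nz)
    sy <- stats::runif(n_blobs, 4, 9)
    sx <- stats::runif(n_blobs, 4, 9)
    sz <- stats::runif(n_blobs, nz / 8, nz / 4)
    amp <- stats::runif(n_blobs, 0.15, 0.45)
    phy <- stats::runif(n_blobs, 0, 2 * pi)
    phx <- stats::runif(n_blobs, 0, 2 * pi)
    frq <- stats::runif(n_blobs, 0.5, 1.5)
    for (z in seq_len(nz)) {
      t <- (z - 1) / max(nz - 1, 1)
      cy <- cy0 + drift_amplitude / 2 * sin(2 * pi * frq * t + phy)
      cx <- cx0 + drift_amplitude / 2 * sin(2 * pi * frq * t + phx)
      dz <- pmin(abs(z - cz), nz - abs(z - cz))   # periodic z distance
      sl <- matrix(0, ny, nx)
      for (b in seq_len(n_blobs)) {
        az <- exp(-dz[b]^2 / (2 * sz[b]^2))
        if (az < 1e-4) next
        sl <- sl + amp[b] * az * outer(exp(-(ys - cy[b])^2 / (2 * sy[b]^2)),
                                       exp(-(xs - cx[b])^2 / (2 * sx[b]^2)))
      }
      vol[z, , ] <- vol[z, , ] + sl
    }
  }
  n_beads <- max(0L, round(bead_fraction * n_blobs))
  if (n_beads > 0) {
    bz <- stats::runif(n_beads, 1, nz)
    by <- stats::runif(n_beads, 4, ny - 3)
    bx <- stats::runif(n_beads, 4, nx - 3)
    br <- stats::runif(n_beads, 2, 4)
    for (b in seq_len(n_beads)) {
      zr <- max(1, floor(bz[b] - br[b])):min(nz, ceiling(bz[b] + br[b]))
      yr <- max(1, floor(by[b] - br[b])):min(ny, ceiling(by[b] + br[b]))
      xr <- max(1, floor(bx[b] - br[b])):min(nx, ceiling(bx[b] + br[b]))
      d2 <- outer(outer((zr - bz[b])^2, (yr - by[b])^2, `+`), (xr - bx[b])^2, `+`)
      # soft-edged sphere: full intensity inside, half-pixel rolloff
      hit <- pmax(pmin(br[b] + 0.5 - sqrt(d2), 1), 0)
      vol[zr, yr, xr] <- pmax(vol[zr, yr, xr], 0.1 + 0.8 * hit)
    }
  }
  if (texture_amplitude > 0) {
    # fine-grain matrix texture: 3D band-limited noise, correlated along z
    # so adjacent slices share their high-frequency content
    tex <- array(stats::rnorm(nz * ny * nx), dim = shape)
    tex <- smooth3d(tex, texture_sigma)
    vol <- vol + texture_amplitude * tex / stats::sd(tex)
  }
  vol[vol > 1] <- 1
  vol[vol < 0] <- 0
  image_stack(vol)
}

# Separable Gaussian smoothing of a 3D array (circular boundaries).
smooth3d <- function(a, sigmas) {
  for (ax in 1:3) {
    n <- dim(a)[ax]
    if (n <= 1L || sigmas[ax] <= 0) next
    d <- outer(seq_len(n), seq_len(n), function(i, j) {
      dd <- abs(i - j); pmin(dd, n - dd)
    })
    M <- exp(-d^2 / (2 * sigmas[ax]^2))
    M <- M / rowSums(M)
    a <- apply_along(a, M, ax)
  }
  a
}

# One independent 2D texture draw: blobs + bead discs over background 0.1.
phantom_slice <- function(ny, nx, n_blobs, bead_fraction) {
  sl <- matrix(0.1, ny, nx)
  ys <- seq_len(ny); xs <- seq_len(nx)
  if (n_blobs > 0) {
    cy <- stats::runif(n_blobs, 1, ny); cx <- stats::runif(n_blobs, 1, nx)
    sy <- stats::runif(n_blobs, 4, 9); sx <- stats::runif(n_blobs, 4, 9)
    amp <- stats::runif(n_blobs, 0.15, 0.45)
    for (b in seq_len(n_blobs)) {
      sl <- sl + amp[b] * outer(exp(-(ys - cy[b])^2 / (2 * sy[b]^2)),
                                exp(-(xs - cx[b])^2 / (2 * sx[b]^2)))
    }
  }
  n_beads <- max(0L, round(bead_fraction * n_blobs))
  if (n_beads > 0) {
    by <- stats::runif(n_beads, 4, ny - 3); bx <- stats::runif(n_beads, 4, nx - 3)
    br <- stats::runif(n_beads, 2, 4)
    for (b in seq_len(n_beads)) {
      yr <- max(1, floor(by[b] - br[b])):min(ny, ceiling(by[b] + br[b]))
      xr <- max(1, floor(bx[b] - br[b])):min(nx, ceiling(bx[b] + br[b]))
      d2 <- outer((yr - by[b])^2, (xr - bx[b])^2, `+`)
      hit <- pmax(pmin(br[b] + 0.5 - sqrt(d2), 1), 0)
      sl[yr, xr] <- pmax(sl[yr, xr], 0.1 + 0.8 * hit)
    }
  }
  sl
}

#' Degradation specification for synthetic stacks
#'
#' Parameterizes the FIB-SEM artifact taxonomy injected by [degrade()]:
#' per-slice defocus blur, vertical stripes (curtaining), smooth charge
#' gradients, per-slice translation drift, mixed Poisson-Gaussian noise,
#' and dropped (unrecoverable) slices.
#'
#' @param blur_slices Named numeric vector: names are 0-based z indices,
#'   values the Gaussian blur sigma in pixels.
#' @param stripe_amplitude Stripe amplitude as a fraction of the dynamic
#'   range (0 disables).
#' @param stripe_period Stripe period in pixels.
#' @param stripe_orientation `"vertical"` or `"horizontal"`.
#' @param drift_step_std Per-slice random-walk drift step (pixels; 0
#'   disables).
#' @param charge_gradient_amplitude Smooth additive gradient amplitude as a
#'   fraction of the dynamic range.
#' @param noise `(gaussian_std, poisson_scale)`; `poisson_scale` is the
#'   expected count at intensity 1 (0 disables shot noise).
#' @param dropped_slices 0-based z indices zero-filled to mimic lost frames.
#' @param seed RNG seed; the same seed yields an identical degraded stack.
#' @return A `DegradationSpec` list.
#' @export
degradation_spec <- function(blur_slices = NULL, stripe_amplitude = 0,
                             stripe_period = 8,
                             stripe_orientation = c("vertical", "horizontal"),
                             drift_step_std = 0,
                             charge_gradient_amplitude = 0,
                             noise = c(0, 0), dropped_slices = integer(0),
                             seed = 1) {
  stripe_orientation <- match.arg(stripe_orientation)
  if (stripe_amplitude < 0 || drift_step_std < 0 || charge_gradient_amplitude < 0) {
    stop("amplitudes must be >= 0")
  }
  if (length(noise) != 2L || any(noise < 0)) stop("`noise` must be (gaussian_std, poisson_scale) >= 0")
  if (!is.null(blur_slices)) {
    if (is.null(names(blur_slices)) || any(as.numeric(blur_slices) <= 0)) {
      stop("`blur_slices` must be a named vector of positive sigmas, names = z indices")
    }
  }
  structure(list(blur_slices = blur_slices, stripe_amplitude = stripe_amplitude,
                 stripe_period = stripe_period, stripe_orientation = stripe_orientation,
                 drift_step_std = drift_step_std,
                 charge_gradient_amplitude = charge_gradient_amplitude,
                 noise = as.numeric(noise), dropped_slices = as.integer(dropped_slices),
                 seed = seed),
            class = "DegradationSpec")
}

#' Degrade a phantom with parameterized FIB-SEM artifacts
#'
#' Applies, in order: per-slice translation drift (random walk), charge
#' gradient (smooth planar + quadratic additive field), stripes (oriented
#' sinusoid plus random per-line offsets), per-slice Gaussian blur on the
#' listed slices, mixed Poisson-Gaussian noise, and finally slice drops
#' (zero-filled so shape and indexing stay stable). Each degradation can be
#' applied alone; an empty spec is a no-op.
#'
#' @param stack An [image_stack()].
#' @param spec A [degradation_spec()].
#' @return List with `degraded` (an [image_stack()]) and `truth`: the clean
#'   stack plus the planted parameters (`drift` as an n_z x 2 matrix of
#'   cumulative (dy, dx), `blur_slices`, `dropped_slices`, the spec echo).
#' @export
degrade <- function(stack, spec = degradation_spec()) {
  nz <- n_slices(stack); ny <- dim(stack$data)[2]; nx <- dim(stack$data)[3]
  if (length(spec$dropped_slices) &&
      (any(spec$dropped_slices < 0L) || any(spec$dropped_slices >= nz))) {
    stop("`dropped_slices` out of range")
  }
  set.seed(spec$seed)
  d <- stack$data
  rng <- diff(range(d))
  if (rng == 0) rng <- 1
  drift <- matrix(0, nz, 2)
  if (spec$drift_step_std > 0 && nz > 1) {
    steps <- matrix(stats::rnorm(2 * (nz - 1), 0, spec$drift_step_std), nz - 1, 2)
    drift[2:nz, ] <- apply(steps, 2L, cumsum)
    for (z in 2:nz) {
      d[z, , ] <- translate_image(d[z, , ], drift[z, 1], drift[z, 2])
    }
  }
  if (spec$charge_gradient_amplitude > 0) {
    yh <- (seq_len(ny) - 1) / max(ny - 1, 1)
    xh <- (seq_len(nx) - 1) / max(nx - 1, 1)
    co <- stats::runif(5, -1, 1)
    g <- co[1] * outer(yh, rep(1, nx)) + co[2] * outer(rep(1, ny), xh) +
      co[3] * outer(yh^2, rep(1, nx)) + co[4] * outer(rep(1, ny), xh^2) +
      co[5] * outer(yh, xh)
    g <- g - min(g)
    if (max(g) > 0) g <- g / max(g)
    g <- g * spec$charge_gradient_amplitude * rng
    for (z in seq_len(nz)) d[z, , ] <- d[z, , ] + g
  }
  if (spec$stripe_amplitude > 0) {
    amp <- spec$stripe_amplitude * rng
    for (z in seq_len(nz)) {
      n_lines <- if (spec$stripe_orientation == "vertical") nx else ny
      prof <- amp * sin(2 * pi * seq_len(n_lines) / spec$stripe_period +
                          stats::runif(1, 0, 2 * pi)) +
        stats::rnorm(n_lines, 0, amp / 3)
      if (spec$stripe_orientation == "vertical") {
        d[z, , ] <- d[z, , ] + matrix(prof, ny, nx, byrow = TRUE)
      } else {
        d[z, , ] <- d[z, , ] + matrix(prof, ny, nx)
      }
    }
  }
  if (!is.null(spec$blur_slices)) {
    zi <- as.integer(names(spec$blur_slices))
    if (any(zi < 0L) || any(zi >= nz)) stop("`blur_slices` index out of range")
    for (i in seq_along(zi)) {
      d[zi[i] + 1L, , ] <- gaussian_blur(d[zi[i] + 1L, , ], as.numeric(spec$blur_slices[[i]]))
    }
  }
  if (spec$noise[2] > 0) {
    lam <- pmax(d, 0) * spec$noise[2]
    d <- array(stats::rpois(length(d), lam) / spec$noise[2], dim = dim(d))
  }
  if (spec$noise[1] > 0) {
    d <- d + array(stats::rnorm(length(d), 0, spec$noise[1]), dim = dim(d))
  }
  if (length(spec$dropped_slices)) d[spec$dropped_slices + 1L, , ] <- 0
  list(
    degraded = image_stack(d, voxel_size = stack$voxel_size),
    truth = list(clean = stack, drift = drift, blur_slices = spec$blur_slices,
                 dropped_slices = spec$dropped_slices, spec = spec)
  )
}
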