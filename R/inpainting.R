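#' Inpainting parameters
#'
#' Shared knob block for the four structural inpainting methods. `NULL`
#' iteration/tolerance values resolve to per-method defaults: harmonic
#' (10000 sweeps, tol 1e-6), dct (100 inner iterations per smoothing step,
#' tol 1e-5), tv (60 outer iterations, tol 1e-5); multiscale is direct
#' (non-iterative).
#'
#' @param method One of `"multiscale"`, `"dct"`, `"harmonic"`, `"tv"`.
#' @param max_iter Iteration cap (per smoothing step for `"dct"`).
#' @param tol Relative-change convergence threshold on masked voxels.
#' @param dct_smoothing_schedule Strictly decreasing positive smoothing
#'   parameters for the DCT method (default 10 log-spaced values from 1e3
#'   down to 1e-3, an annealing schedule from heavy to light smoothing).
#' @param tv_weight TV step weight for the `"tv"` method; the default 0.1
#'   keeps inpainted edges sharp, while heavier weights diffuse them toward
#'   the harmonic solution.
#' @param max_slice_run Longest run of fully masked consecutive z-slices
#'   accepted without warning; structural inpainting cannot restore large
#'   areas, so longer runs trigger a warning.
#' @return An `InpaintParams` list.
#' @export
inpaint_params <- function(method = c("dct", "harmonic", "tv", "multiscale"),
                           max_iter = NULL, tol = NULL,
                           dct_smoothing_schedule = 10^seq(3, -3, length.out = 10),
                           tv_weight = 0.1, max_slice_run = 5L) {
  method <- match.arg(method)
  if (is.null(max_iter)) {
    max_iter <- switch(method, harmonic = 10000L, dct = 100L, tv = 60L, multiscale = 1L)
  }
  if (is.null(tol)) tol <- switch(method, harmonic = 1e-6, 1e-5)
  if (max_iter < 1) stop("`max_iter` must be >= 1")
  if (tol <= 0) stop("`tol` must be > 0")
  s <- dct_smoothing_schedule
  if (!length(s) || any(s <= 0) || any(diff(s) >= 0)) {
    stop("`dct_smoothing_schedule` must be strictly decreasing and positive")
  }
  if (tv_weight < 0) stop("`tv_weight` must be >= 0")
  structure(list(method = method, max_iter = as.integer(max_iter), tol = tol,
                 dct_smoothing_schedule = s, tv_weight = tv_weight,
                 max_slice_run = as.integer(max_slice_run)),
            class = "InpaintParams")
}

#' Structural inpainting of masked voxels
#'
#' Replaces the voxels marked by `mask` using one of four structural
#' methods, all operating natively in 3D so a missing slice is constrained
#' by both of its z-neighbours:
#' \describe{
#'   \item{multiscale}{Known-voxel average pyramid; unknowns filled from the
#'     first fully known level by trilinear upsampling (close to linear
#'     interpolation).}
#'   \item{dct}{Penalized least squares in the 3D DCT basis with an annealed
#'     smoothing schedule (Garcia-style); solves `(W + s L^2) u = W y` at
#'     the final smoothing parameter.}
#'   \item{harmonic}{Laplace equation on the masked region with Dirichlet
#'     data from known voxels (red-black Gauss-Seidel); diffuses information
#'     homogeneously in all directions.}
#'   \item{tv}{Total-variation minimization alternated with exact
#'     re-injection of known voxels; preserves edges the harmonic method
#'     would smear.}
#' }
#' Unmasked voxels are returned bit-identical to the input for every method.
#'
#' @param volume An [image_stack()].
#' @param mask A [missing_mask()] of the same shape with at least one known
#'   voxel.
#' @param params An [inpaint_params()].
#' @return The restored [image_stack()].
#' @export
inpaint <- function(volume, mask, params = inpaint_params()) {
  check_stack_mask(volume, mask)
  m <- mask$mask
  if (all(m)) stop("fully masked volume cannot be inpainted")
  if (!any(m)) return(volume)
  run <- longest_masked_run(mask)
  if (run > params$max_slice_run) {
    warning("masked run of ", run, " consecutive slices exceeds ",
            params$max_slice_run, "; structural inpainting cannot restore ",
            "large missing areas reliably")
  }
  y <- volume$data
  filled <- switch(params$method,
    multiscale = inpaint_multiscale_core(y, m),
    dct        = inpaint_dct_core(y, m, params),
    harmonic   = inpaint_harmonic_core(y, m, params),
    tv         = inpaint_tv_core(y, m, params)
  )
  out <- y
  out[m] <- filled[m]      # known voxels stay bit-identical
  if (!all(is.finite(out))) stop("inpainting produced non-finite values")
  volume$data <- out
  volume
}

#' @rdname inpaint
#' @export
inpaint_multiscale <- function(volume, mask, params = inpaint_params("multiscale")) {
  params$method <- "multiscale"; inpaint(volume, mask, params)
}

#' @rdname inpaint
#' @export
inpaint_dct <- function(volume, mask, params = inpaint_params("dct")) {
  params$method <- "dct"; inpaint(volume, mask, params)
}

#' @rdname inpaint
#' @export
inpaint_harmonic <- function(volume, mask, params = inpaint_params("harmonic")) {
  params$method <- "harmonic"; inpaint(volume, mask, params)
}

#' @rdname inpaint
#' @export
inpaint_tv <- function(volume, mask, params = inpaint_params("tv")) {
  params$method <- "tv"; inpaint(volume, mask, params)
}

longest_masked_run <- function(mask) {
  full <- apply(mask$mask, 1L, all)
  if (!any(full)) return(0L)
  r <- rle(full)
  max(r$lengths[r$values])
}

# Initial guess: per-(y, x) column linear interpolation along z across
# masked voxels (exact for whole-slice masks between known planes),
# remaining unknowns set to the known-voxel mean.
init_fill <- function(y, m) {
  u <- y
  fallback <- mean(y[!m])
  nz <- dim(y)[1]
  if (nz > 1) {
    full <- apply(m, 1L, all)
    if (any(full)) {
      kn <- which(!full)
      for (z in which(full)) {
        lo <- suppressWarnings(max(kn[kn < z])); hi <- suppressWarnings(min(kn[kn > z]))
        if (is.finite(lo) && is.finite(hi)) {
          w <- (hi - z) / (hi - lo)
          u[z, , ] <- w * y[lo, , ] + (1 - w) * y[hi, , ]
        } else if (is.finite(lo)) {
          u[z, , ] <- y[lo, , ]
        } else if (is.finite(hi)) {
          u[z, , ] <- y[hi, , ]
        }
      }
      m2 <- m
      m2[full, , ] <- FALSE
      u[m2] <- fallback
      return(u)
    }
  }
  u[m] <- fallback
  u
}

# --- harmonic -----------------------------------------------------------

# Red-black Gauss-Seidel solve of the Laplace equation on the masked set
# with Dirichlet data from known voxels; out-of-domain neighbours are
# dropped (Neumann at the volume faces). Satisfies the discrete maximum
# principle by construction.
inpaint_harmonic_core <- function(y, m, params) {
  dm <- dim(y)
  idx <- which(m)
  u <- init_fill(y, m)
  coords <- arrayInd(idx, dm)
  nb <- neighbor_index_matrix(coords, dm)
  counts <- rowSums(!is.na(nb))
  nb_flat <- nb
  nb_flat[is.na(nb_flat)] <- 1L   # dummy; contributions zeroed by weight
  wgt <- !is.na(nb)
  color <- (rowSums(coords) %% 2L) == 0L
  scale <- max(abs(y[!m]), 1e-12)
  for (it in seq_len(params$max_iter)) {
    old <- u[idx]
    for (col in c(TRUE, FALSE)) {
      sel <- color == col
      vals <- matrix(u[nb_flat[sel, , drop = FALSE]], ncol = 6L)
      vals[!wgt[sel, , drop = FALSE]] <- 0
      u[idx[sel]] <- rowSums(vals) / counts[sel]
    }
    if (max(abs(u[idx] - old)) <= params$tol * scale) break
  }
  u
}

# 6-neighbour linear indices for voxel coordinates; NA outside the volume.
neighbor_index_matrix <- function(coords, dm) {
  n <- nrow(coords)
  nb <- matrix(NA_integer_, n, 6L)
  k <- 0L
  for (ax in 1:3) {
    if (dm[ax] == 1L) { k <- k + 2L; next }
    for (d in c(-1L, 1L)) {
      k <- k + 1L
      cc <- coords
      cc[, ax] <- cc[, ax] + d
      ok <- cc[, ax] >= 1L & cc[, ax] <= dm[ax]
      nb[ok, k] <- cc[ok, 1L] + dm[1L] * (cc[ok, 2L] - 1L) +
        dm[1L] * dm[2L] * (cc[ok, 3L] - 1L)
    }
  }
  nb
}

# --- dct ----------------------------------------------------------------

# Garcia-style penalized least squares: fixed point of
# u = IDCT(Gamma_s * DCT(W (y - u) + u)), Gamma_s = 1 / (1 + s Lambda^2),
# whose limit solves (W + s L^2) u = W y. The smoothing parameter s is
# annealed down the schedule; a relaxation factor of 2 accelerates the
# fixed-point iteration.
inpaint_dct_core <- function(y, m, params) {
  dm <- dim(y)
  w <- array(1, dm); w[m] <- 0
  lam2 <- laplace_eigen3(dm)^2
  u <- init_fill(y, m)
  idx <- which(m)
  scale <- max(abs(y[!m]), 1e-12)
  relax <- 2
  for (s in params$dct_smoothing_schedule) {
    gamma <- 1 / (1 + s * lam2)
    for (it in seq_len(params$max_iter)) {
      old <- u[idx]
      v <- idct3(gamma * dct3(w * (y - u) + u))
      u <- relax * v + (1 - relax) * u
      if (max(abs(u[idx] - old)) <= params$tol * scale) break
    }
  }
  u
}

# --- tv -----------------------------------------------------------------

inpaint_tv_core <- function(y, m, params) {
  u <- init_fill(y, m)
  idx <- which(m)
  scale <- max(abs(y[!m]), 1e-12)
  for (it in seq_len(params$max_iter)) {
    old <- u[idx]
    u <- tv_denoise(u, weight = params$tv_weight, n_iter = 10)
    u[!m] <- y[!m]            # re-inject original values where defined
    if (max(abs(u[idx] - old)) <= params$tol * scale) break
  }
  u
}

# --- multiscale ---------------------------------------------------------

# Pyramid of known-voxel averages: scale down by 2 until no cell is missing
# (a cell is known when at least one contributing voxel is known), then
# propagate values back up, filling unknowns by trilinear upsampling of the
# coarser, fully known level. Known voxels are kept at every level.
inpaint_multiscale_core <- function(y, m, params = NULL) {
  vols <- list(y * !m)
  kns <- list(array(as.numeric(!m), dim = dim(y)))
  while (any(kns[[length(kns)]] == 0) && any(dim(vols[[length(vols)]]) > 1L)) {
    v <- downsample2_3d(vols[[length(vols)]])
    k <- downsample2_3d(kns[[length(kns)]])
    vols[[length(vols) + 1L]] <- v
    kns[[length(kns) + 1L]] <- k
  }
  L <- length(vols)
  top <- vols[[L]]
  kc <- kns[[L]]
  val <- array(0, dim = dim(top))
  val[kc > 0] <- top[kc > 0] / kc[kc > 0]
  if (any(kc == 0)) val[kc == 0] <- mean(val[kc > 0])  # isolated degenerate case
  for (l in seq.int(L - 1L, 1L, length.out = max(L - 1L, 0L))) {
    up <- trilinear_upsample(val, dim(vols[[l]]))
    k <- kns[[l]]
    cur <- array(0, dim = dim(k))
    cur[k > 0] <- vols[[l]][k > 0] / k[k > 0]
    cur[k == 0] <- up[k == 0]
    val <- cur
  }
  val
}

# Factor-2 block sum along every axis of length > 1 (sums, so known-count
# arrays combine consistently with value sums).
downsample2_3d <- function(a) {
  for (ax in 1:3) {
    n <- dim(a)[ax]
    if (n <= 1L) next
    grp <- (seq_len(n) + 1L) %/% 2L
    M <- matrix(0, max(grp), n)
    M[cbind(grp, seq_len(n))] <- 1
    a <- apply_along(a, M, ax)
  }
  a
}

# Trilinear upsampling to `target` dims, consistent with block-mean cell
# centres (fine index i maps to coarse coordinate (i - 0.5) / 2).
trilinear_upsample <- function(a, target) {
  for (ax in 1:3) {
    nf <- target[ax]; nc <- dim(a)[ax]
    if (nf == nc) next
    # fine cell centre i - 0.5 sits at coarse index coordinate
    # (i - 0.5) / 2 - 0.5 (0-based), so paired fine cells straddle their
    # coarse cell centre symmetrically
    pos <- pmin(pmax((seq_len(nf) - 1.5) / 2, 0), nc - 1)
    lo <- pmin(floor(pos), nc - 1)
    hi <- pmin(lo + 1, nc - 1)
    whi <- pos - lo
    M <- matrix(0, nf, nc)
    M[cbind(seq_len(nf), lo + 1)] <- M[cbind(seq_len(nf), lo + 1)] + (1 - whi)
    M[cbind(seq_len(nf), hi + 1)] <- M[cbind(seq_len(nf), hi + 1)] + whi
    a <- apply_along(a, M, ax)
  }
  a
}
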