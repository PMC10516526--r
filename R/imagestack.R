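#' ImageStack: a 3D grayscale volume
#'
#' The central container all restoration stages transform. Data are stored as
#' a 3D double array indexed `[z, y, x]`, where `z` is the slice (milling)
#' axis in acquisition order. Intensities are held in double precision
#' internally; any integer origin bit depth is recorded so writers can
#' restore it.
#'
#' @param data A 3D numeric array indexed `(z, y, x)`, or a 2D matrix which
#'   is promoted to a single-slice stack.
#' @param voxel_size Optional numeric length-3 vector `(dz, dy, dx)` in
#'   nanometers. Metadata only; no algorithmic effect.
#' @param dtype_origin Optional integer bit depth (8 or 16) of the source
#'   file, used to restore the depth on writing. `NULL` means float origin.
#' @return An object of class `ImageStack`.
#' @export
image_stack <- function(data, voxel_size = NULL, dtype_origin = NULL) {
  if (is.matrix(data)) {
    data <- array(data, dim = c(1L, nrow(data), ncol(data)))
  }
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array indexed (z, y, x) or a 2D matrix")
  }
  if (any(dim(data) < 1L)) stop("all stack dimensions must be >= 1")
  if (!all(is.finite(data))) stop("stack intensities must be finite (no NA/NaN/Inf)")
  storage.mode(data) <- "double"
  if (!is.null(voxel_size)) {
    voxel_size <- as.numeric(voxel_size)
    if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
      stop("`voxel_size` must be 3 positive finite numbers (dz, dy, dx)")
    }
  }
  if (!is.null(dtype_origin)) {
    dtype_origin <- as.integer(dtype_origin)
    if (!dtype_origin %in% c(8L, 16L)) stop("`dtype_origin` must be 8 or 16")
  }
  structure(
    list(data = data, voxel_size = voxel_size, dtype_origin = dtype_origin),
    class = "ImageStack"
  )
}

#' @export
dim.ImageStack <- function(x) dim(x$data)

#' Number of slices along the milling axis
#' @param stack An [image_stack()].
#' @return Integer slice count.
#' @export
n_slices <- function(stack) dim(stack$data)[1L]

#' Extract one z-slice as a 2D matrix indexed (y, x)
#' @param stack An [image_stack()].
#' @param z 0-based slice index.
#' @return A `n_y x n_x` matrix.
#' @export
get_slice <- function(stack, z) {
  nz <- n_slices(stack)
  if (z < 0L || z >= nz) stop("slice index ", z, " out of range [0, ", nz, ")")
  m <- stack$data[z + 1L, , , drop = TRUE]
  dim(m) <- dim(stack$data)[2:3]
  m
}

#' Replace one z-slice
#' @inheritParams get_slice
#' @param value A matrix of the stack's in-plane shape.
#' @return The modified stack.
#' @export
set_slice <- function(stack, z, value) {
  nz <- n_slices(stack)
  if (z < 0L || z >= nz) stop("slice index ", z, " out of range [0, ", nz, ")")
  if (!all(dim(value) == dim(stack$data)[2:3])) stop("slice shape mismatch")
  stack$data[z + 1L, , ] <- value
  stack
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ImageStack: %d slices of %d x %d (z, y, x)\n", d[1], d[2], d[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  if (!is.null(x$voxel_size)) {
    cat(sprintf("  voxel size (dz, dy, dx) = (%g, %g, %g) nm\n",
                x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  }
  if (!is.null(x$dtype_origin)) cat(sprintf("  origin bit depth: %d\n", x$dtype_origin))
  invisible(x)
}

#' MissingMask: voxels to be restored
#'
#' A boolean volume the same shape as its companion stack; `TRUE` marks
#' voxels whose value is unknown (to be inpainted).
#'
#' @param mask A 3D logical array indexed `(z, y, x)`.
#' @return An object of class `MissingMask`.
#' @export
missing_mask <- function(mask) {
  if (!is.array(mask) || length(dim(mask)) != 3L) stop("`mask` must be a 3D array")
  if (anyNA(mask)) stop("mask must not contain NA")
  storage.mode(mask) <- "logical"
  structure(list(mask = mask), class = "MissingMask")
}

#' @export
dim.MissingMask <- function(x) dim(x$mask)

#' Build a mask marking whole z-slices as missing
#'
#' Removed (artifactual) planes are typically whole slices; this constructor
#' marks the listed 0-based z-planes as unknown.
#'
#' @param shape Integer length-3 vector `(n_z, n_y, n_x)`.
#' @param slices Integer vector of 0-based z indices (may be empty).
#' @return A [missing_mask()] with exactly `n_y * n_x * length(unique(slices))`
#'   `TRUE` voxels.
#' @export
mask_from_slices <- function(shape, slices) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop("`shape` must be 3 positive integers")
  slices <- as.integer(unique(slices))
  if (length(slices) && (any(slices < 0L) || any(slices >= shape[1L]))) {
    stop("slice indices must lie in [0, ", shape[1L], ")")
  }
  m <- array(FALSE, dim = shape)
  if (length(slices)) m[slices + 1L, , ] <- TRUE
  missing_mask(m)
}

#' z-indices of fully masked slices
#' @param mask A [missing_mask()].
#' @return Sorted 0-based indices of planes that are entirely `TRUE`.
#' @export
masked_slices <- function(mask) {
  full <- apply(mask$mask, 1L, all)
  which(full) - 1L
}

check_stack_mask <- function(stack, mask) {
  if (!all(dim(stack$data) == dim(mask$mask))) {
    stop("mask shape ", paste(dim(mask$mask), collapse = "x"),
         " does not match stack shape ", paste(dim(stack$data), collapse = "x"))
  }
  invisible(TRUE)
}
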