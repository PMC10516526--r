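#' Rolling-ball charge-gradient correction
#'
#' Charge effects show up as smooth intensity gradients or ghosting. The
#' background is estimated by rolling a ball of the given radius under the
#' intensity surface -- equivalently, the grayscale morphological opening of
#' the image by a ball (ellipsoid-cap) structuring element -- and
#' subtracted. Structures narrower than the ball are preserved; broad
#' gradients go into the background. Image borders use replicate padding.
#'
#' The ball's lateral radius is in pixels while the surface it rolls under
#' is in intensity units, so the vertical semi-axis must be expressed on the
#' intensity scale: by default it equals the image's intensity range, making
#' the cap sag appreciably only over lateral distances comparable to
#' `radius`. A vertical radius much larger than the intensity range degrades
#' toward a flat disc opening that also removes wide genuine structures.
#'
#' @param image 2D matrix (y, x).
#' @param radius Ball radius in pixels (>= 1, smaller than the image).
#' @param intensity_radius Vertical semi-axis of the ball in intensity
#'   units; default `NULL` uses the image's intensity range (1 for a
#'   constant image).
#' @return List with `corrected` (`image - background`, nonnegative) and
#'   `background` (the opening, pointwise `<= image`).
#' @export
rolling_ball <- function(image, radius = 25, intensity_radius = NULL) {
  if (!is.matrix(image)) stop("`image` must be a matrix")
  if (radius < 1) stop("`radius` must be >= 1")
  if (radius > min(dim(image))) {
    stop("`radius` (", radius, ") exceeds the smallest image dimension")
  }
  if (is.null(intensity_radius)) {
    intensity_radius <- diff(range(image))
    if (intensity_radius == 0) intensity_radius <- 1
  }
  if (intensity_radius <= 0) stop("`intensity_radius` must be > 0")
  se <- ball_element(radius, intensity_radius)
  bg <- gray_dilate(gray_erode(image, se), se)
  corrected <- image - bg
  corrected[corrected < 0] <- 0  # guard against rounding
  list(corrected = corrected, background = bg)
}

# Ball (ellipsoid-cap) structuring element: height
# v * sqrt(1 - (d/r)^2) over the disc of radius r, as offsets
# (dy, dx, height). The constant -v offset is immaterial to the opening.
ball_element <- function(radius, intensity_radius = radius) {
  r <- floor(radius)
  off <- expand.grid(dy = -r:r, dx = -r:r)
  d2 <- off$dy^2 + off$dx^2
  keep <- d2 <= radius^2
  list(dy = off$dy[keep], dx = off$dx[keep],
       h = intensity_radius * sqrt(1 - d2[keep] / radius^2))
}

# Integer shift with replicate (clamped) borders.
shift_replicate <- function(x, dy, dx) {
  ny <- nrow(x); nx <- ncol(x)
  x[pmin(pmax(seq_len(ny) + dy, 1L), ny),
    pmin(pmax(seq_len(nx) + dx, 1L), nx), drop = FALSE]
}

# Grayscale erosion/dilation with a non-flat structuring element.
gray_erode <- function(x, se) {
  out <- matrix(Inf, nrow(x), ncol(x))
  for (i in seq_along(se$h)) {
    out <- pmin(out, shift_replicate(x, se$dy[i], se$dx[i]) - se$h[i])
  }
  out
}

gray_dilate <- function(x, se) {
  out <- matrix(-Inf, nrow(x), ncol(x))
  for (i in seq_along(se$h)) {
    out <- pmax(out, shift_replicate(x, -se$dy[i], -se$dx[i]) + se$h[i])
  }
  out
}
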