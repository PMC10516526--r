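# Shared low-level image numerics: FFT frequency grids, convolution with
# mirror boundaries, circular convolution via an origin-centred PSF, Gaussian
# kernels, subpixel translation, and factor-2 pyramid resampling. All 2D
# images are matrices indexed (y, x).

# Discrete Fourier sample frequencies in cycles/pixel for length n:
# 0, 1/n, ..., then negative frequencies (matches the unshifted fft layout).
fft_freq <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= (n - 1) %/% 2, k, k - n) / n
}

# Radial frequency magnitude (cycles/pixel, per-axis normalized) for each
# element of an n_y x n_x unshifted FFT array.
fft_radius <- function(ny, nx) {
  fy <- fft_freq(ny)
  fx <- fft_freq(nx)
  sqrt(outer(fy^2, fx^2, `+`))
}

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Mirror-pad a matrix by (py, px) on each side (reflection without repeating
# the edge sample, as in symmetric boundary conditions).
mirror_pad <- function(x, py, px) {
  ny <- nrow(x); nx <- ncol(x)
  if (py >= ny || px >= nx) stop("mirror padding exceeds image size")
  iy <- c(rev(seq_len(py) + 1L), seq_len(ny), ny - seq_len(py))
  ix <- c(rev(seq_len(px) + 1L), seq_len(nx), nx - seq_len(px))
  x[iy, ix, drop = FALSE]
}

# Dense 2D convolution with an odd-sized kernel and mirror boundary handling.
conv2_mirror <- function(x, kernel) {
  ky <- nrow(kernel); kx <- ncol(kernel)
  stopifnot(ky %% 2 == 1, kx %% 2 == 1)
  py <- (ky - 1L) %/% 2L; px <- (kx - 1L) %/% 2L
  xp <- mirror_pad(x, py, px)
  conv2_circular(xp, kernel)[py + seq_len(nrow(x)), px + seq_len(ncol(x)), drop = FALSE]
}

# Circular (periodic) convolution of an image with an odd-sized kernel whose
# centre pixel is the origin. Exact flux preservation for normalized kernels.
conv2_circular <- function(x, kernel) {
  ny <- nrow(x); nx <- ncol(x)
  K <- embed_kernel(kernel, ny, nx)
  Re(ifft2(fft2(x) * fft2(K)))
}

# Place an odd-sized kernel into an ny x nx array with its centre at [1, 1]
# (FFT origin), wrapping negative offsets.
embed_kernel <- function(kernel, ny, nx) {
  ky <- nrow(kernel); kx <- ncol(kernel)
  if (ky > ny || kx > nx) stop("kernel larger than image")
  cy <- (ky + 1L) %/% 2L; cx <- (kx + 1L) %/% 2L
  K <- matrix(0, ny, nx)
  oy <- ((seq_len(ky) - cy) %% ny) + 1L
  ox <- ((seq_len(kx) - cx) %% nx) + 1L
  K[oy, ox] <- kernel
  K
}

# Normalized 2D Gaussian kernel; half-width defaults to ceil(4 sigma).
gaussian_kernel <- function(sigma, half_width = ceiling(4 * sigma)) {
  stopifnot(sigma > 0)
  r <- -half_width:half_width
  g <- exp(-r^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# Laplacian-of-Gaussian kernel (sum-normalized to zero so constants map to 0).
log_kernel <- function(sigma, half_width = ceiling(4 * sigma)) {
  stopifnot(sigma > 0)
  r <- -half_width:half_width
  xs <- outer(rep(1, length(r)), r)
  ys <- outer(r, rep(1, length(r)))
  r2 <- xs^2 + ys^2
  k <- (r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2))
  k - mean(k)
}

gaussian_blur <- function(x, sigma) conv2_mirror(x, gaussian_kernel(sigma))

# Subpixel translation by (dy, dx) using separable cubic splines with edge
# value extension (not periodic wrap: milled stacks are not periodic).
translate_image <- function(x, dy, dx) {
  ny <- nrow(x); nx <- ncol(x)
  if (dy != 0) {
    ys <- pmin(pmax(seq_len(ny) - dy, 1), ny)
    x <- apply(x, 2L, function(col) stats::spline(seq_len(ny), col, xout = ys,
                                                  method = "natural")$y)
    dim(x) <- c(ny, nx)
  }
  if (dx != 0) {
    xs <- pmin(pmax(seq_len(nx) - dx, 1), nx)
    x <- t(apply(x, 1L, function(row) stats::spline(seq_len(nx), row, xout = xs,
                                                    method = "natural")$y))
    dim(x) <- c(ny, nx)
  }
  x
}

# Factor-2 block mean downsampling of a matrix (trailing odd row/col averaged
# over the available samples).
downsample2 <- function(x) {
  ny <- nrow(x); nx <- ncol(x)
  iy <- (seq_len(ny) + 1L) %/% 2L
  ix <- (seq_len(nx) + 1L) %/% 2L
  sums <- rowsum(x, iy)
  sums <- t(rowsum(t(sums), ix))
  cnt <- outer(tabulate(iy), tabulate(ix))
  sums / cnt
}

rmse <- function(a, b) sqrt(mean((a - b)^2))

psnr <- function(x, ref, peak = max(abs(ref))) {
  err <- rmse(x, ref)
  if (err == 0) Inf else 20 * log10(peak / err)
}
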