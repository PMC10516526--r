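# Orthonormal type-II DCT along array axes, realized as dense transform
# matrices (volumes here are modest, so matrix products beat FFT tricks for
# clarity and exactness). The DCT-II basis diagonalizes the Neumann
# (reflective-boundary) discrete Laplacian, which is what makes the
# penalized-least-squares inpainting solvable per frequency.

dct_matrix_cache <- new.env(parent = emptyenv())

dct_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(dct_matrix_cache[[key]])) return(dct_matrix_cache[[key]])
  k <- 0:(n - 1)
  i <- 0:(n - 1)
  M <- sqrt(2 / n) * cos(pi * outer(k, 2 * i + 1) / (2 * n))
  M[1, ] <- M[1, ] / sqrt(2)
  dct_matrix_cache[[key]] <- M
  M
}

# Apply matrix M (m x n) along axis `ax` of a 3D array with dim[ax] == n.
apply_along <- function(a, M, ax) {
  dm <- dim(a)
  perm <- c(ax, setdiff(1:3, ax))
  b <- aperm(a, perm)
  dim(b) <- c(dm[ax], prod(dm[-ax]))
  b <- M %*% b
  dim(b) <- c(nrow(M), dm[perm[2]], dm[perm[3]])
  aperm(b, order(perm))
}

dct3 <- function(a) {
  for (ax in 1:3) if (dim(a)[ax] > 1) a <- apply_along(a, dct_matrix(dim(a)[ax]), ax)
  a
}

idct3 <- function(a) {
  for (ax in 1:3) if (dim(a)[ax] > 1) a <- apply_along(a, t(dct_matrix(dim(a)[ax])), ax)
  a
}

# Eigenvalues of the 1D Neumann Laplacian in the DCT-II basis.
laplace_eigen <- function(n) 2 * cos(pi * (0:(n - 1)) / n) - 2

# 3D Laplacian eigenvalue array (outer sum over axes; singleton axes
# contribute 0).
laplace_eigen3 <- function(dm) {
  lz <- if (dm[1] > 1) laplace_eigen(dm[1]) else 0
  ly <- if (dm[2] > 1) laplace_eigen(dm[2]) else 0
  lx <- if (dm[3] > 1) laplace_eigen(dm[3]) else 0
  outer(outer(lz, ly, `+`), lx, `+`)
}
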