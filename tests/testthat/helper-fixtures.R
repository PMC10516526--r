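# Shared test helpers. All fixtures are generated in code by the synthetic
# module; no binary test data ships with the package.

rmse_ <- function(a, b) sqrt(mean((a - b)^2))

# Small deterministic phantom reused across files.
tiny_phantom <- function(shape = c(12, 32, 32), seed = 1, ...) {
  make_phantom(shape = shape, seed = seed, ...)
}

# A volume sampling the discrete-harmonic function 2x - 3y + z.
harmonic_volume <- function(dm) {
  co <- expand.grid(z = seq_len(dm[1]), y = seq_len(dm[2]), x = seq_len(dm[3]))
  image_stack(array(2 * co$x - 3 * co$y + co$z, dim = dm))
}

# Direct sparse solve of the Laplace system on the masked set (oracle for
# harmonic inpainting). Returns the filled values at `which(m)` in order.
harmonic_oracle <- function(vol, m) {
  dm <- dim(vol)
  idx <- which(m)
  nb <- semrestore:::neighbor_index_matrix(arrayInd(idx, dm), dm)
  n <- length(idx)
  pos <- match(seq_len(prod(dm)), idx)
  ti <- integer(0); tj <- integer(0); tv <- numeric(0)
  b <- rep(0, n)
  deg <- rowSums(!is.na(nb))
  for (k in seq_len(ncol(nb))) {
    nbk <- nb[, k]
    ok <- !is.na(nbk)
    inm <- ok & !is.na(pos[nbk])
    out <- ok & is.na(pos[nbk])
    ti <- c(ti, which(inm)); tj <- c(tj, pos[nbk[inm]])
    tv <- c(tv, rep(-1, sum(inm)))
    b[which(out)] <- b[which(out)] + vol[nbk[out]]
  }
  A <- Matrix::sparseMatrix(i = c(ti, seq_len(n)), j = c(tj, seq_len(n)),
                            x = c(tv, deg), dims = c(n, n))
  as.vector(Matrix::solve(A, b))
}

# Dense oracle for DCT inpainting: solve (W + s L^2) u = W y at smoothing s.
dct_oracle <- function(y, m, s) {
  dm <- dim(y)
  Ls <- lapply(dm, function(n) {
    D <- semrestore:::dct_matrix(n)
    t(D) %*% diag(semrestore:::laplace_eigen(n)) %*% D
  })
  I1 <- diag(dm[1]); I2 <- diag(dm[2]); I3 <- diag(dm[3])
  L3 <- kronecker(I3, kronecker(I2, Ls[[1]])) +
    kronecker(I3, kronecker(Ls[[2]], I1)) +
    kronecker(Ls[[3]], kronecker(I2, I1))
  W <- diag(as.numeric(!as.vector(m)))
  array(solve(W + s * (L3 %*% L3), W %*% as.vector(y)), dim = dm)
}
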