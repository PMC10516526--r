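# Minimal MRC2014 volume I/O (little-endian; modes 0, 1, 2, 6 read; mode 2
# written). Header layout follows the MRC2014 standard: 1024-byte fixed
# header, data stored x-fastest then y then z.

MRC_HEADER_BYTES <- 1024L

read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = MRC_HEADER_BYTES)
  if (length(hdr_raw) < MRC_HEADER_BYTES) stop("failed to read MRC '", path, "': truncated header")
  int_at <- function(w) readBin(hdr_raw[(4 * (w - 1) + 1):(4 * w)], "integer", size = 4,
                                endian = "little")
  dbl_at <- function(w) readBin(hdr_raw[(4 * (w - 1) + 1):(4 * w)], "double", size = 4,
                                endian = "little")
  nx <- int_at(1); ny <- int_at(2); nz <- int_at(3)
  mode <- int_at(4)
  mx <- int_at(8); my <- int_at(9); mz <- int_at(10)
  cella <- c(dbl_at(11), dbl_at(12), dbl_at(13))  # x, y, z cell lengths in Angstrom
  nsymbt <- int_at(24)
  if (any(c(nx, ny, nz) < 1L)) stop("failed to read MRC '", path, "': bad dimensions")
  if (nsymbt > 0) invisible(readBin(con, "raw", n = nsymbt))
  n <- as.double(nx) * ny * nz
  vals <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = n, size = 1, signed = TRUE, endian = "little"),
    "1" = readBin(con, "integer", n = n, size = 2, signed = TRUE, endian = "little"),
    "2" = readBin(con, "double",  n = n, size = 4, endian = "little"),
    "6" = readBin(con, "integer", n = n, size = 2, signed = FALSE, endian = "little"),
    stop("unsupported MRC mode ", mode, " in '", path, "'")
  )
  if (length(vals) < n) stop("failed to read MRC '", path, "': truncated data")
  # file order: x fastest, then y, then z -> array (x, y, z), then permute to (z, y, x)
  a <- array(as.double(vals), dim = c(nx, ny, nz))
  data <- aperm(a, c(3L, 2L, 1L))
  voxel_size <- NULL
  if (all(c(mx, my, mz) > 0L) && all(is.finite(cella)) && all(cella > 0)) {
    # Angstrom per voxel -> nanometers; (dz, dy, dx)
    voxel_size <- c(cella[3] / mz, cella[2] / my, cella[1] / mx) / 10
  }
  dtype_origin <- if (mode %in% c(0L)) 8L else if (mode %in% c(1L, 6L)) 16L else NULL
  image_stack(data, voxel_size = voxel_size, dtype_origin = dtype_origin)
}

write_mrc <- function(stack, path) {
  d <- stack$data
  nz <- dim(d)[1]; ny <- dim(d)[2]; nx <- dim(d)[3]
  vx <- stack$voxel_size  # (dz, dy, dx) nm or NULL
  cella <- if (is.null(vx)) c(nx, ny, nz) * 1.0 else c(nx * vx[3], ny * vx[2], nz * vx[1]) * 10
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  wi(c(nx, ny, nz))          # words 1-3
  wi(2L)                     # mode 2 = float32
  wi(c(0L, 0L, 0L))          # nxstart/nystart/nzstart
  wi(c(nx, ny, nz))          # mx/my/mz
  wf(cella)                  # cella (Angstrom)
  wf(c(90, 90, 90))          # cellb
  wi(c(1L, 2L, 3L))          # mapc/mapr/maps
  wf(c(min(d), max(d), mean(d)))  # dmin/dmax/dmean
  wi(1L)                     # ispg (volume)
  wi(0L)                     # nsymbt
  writeBin(raw(4 * 25), con) # extra (words 25-49)
  wf(c(0, 0, 0))             # origin (words 50-52)
  writeBin(charToRaw("MAP "), con)                    # word 53
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)    # machst, little-endian
  wf(stats::sd(d))           # rms
  wi(0L)                     # nlabl
  writeBin(raw(800), con)    # labels
  v <- aperm(d, c(3L, 2L, 1L))  # back to x-fastest order
  writeBin(as.double(v), con, size = 4, endian = "little")
  invisible(path)
}
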