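#' Read a volume from disk
#'
#' Reads a multipage grayscale TIFF (8/16-bit integer or 32-bit float) or an
#' MRC2014 volume into an [image_stack()]. Slices are returned in file order
#' along `z` (acquisition/milling order); a single 2D image is accepted as a
#' one-slice stack.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"tiff"` or `"mrc"`.
#' @return An [image_stack()]. Integer TIFF data keep their raw integer
#'   values with `dtype_origin` recording the bit depth; float data are read
#'   as-is. MRC voxel size (when present in the header) is preserved.
#' @export
read_stack <- function(path, format = c("auto", "tiff", "mrc")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- guess_format(path)
  switch(format,
    tiff = read_stack_tiff(path),
    mrc  = read_mrc(path)
  )
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("mrc", "rec", "st", "map")) "mrc" else "tiff"
}

read_stack_tiff <- function(path) {
  # read normalized (integer depths come back as value / (2^bits - 1),
  # floats as-is); raw integer values are restored from the metadata, which
  # is exact because n / (2^b - 1) * (2^b - 1) rounds back to n
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, info = TRUE),
    error = function(e) stop("failed to read TIFF '", path, "': ", conditionMessage(e))
  )
  if (is.array(pages)) pages <- list(pages)
  if (!length(pages)) stop("failed to read TIFF '", path, "': no pages")
  if (!is.null(dim(pages[[1]])) && length(dim(pages[[1]])) == 3L) {
    stop("only single-channel grayscale TIFFs are supported: ", path)
  }
  shp <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), shp), logical(1)))) {
    stop("TIFF pages have inconsistent shapes: ", path)
  }
  bits <- attr(pages[[1]], "bits.per.sample")
  fmt <- attr(pages[[1]], "sample.format")
  is_int <- is.null(fmt) || identical(fmt, "uint") || identical(fmt, "int")
  data <- array(0, dim = c(length(pages), shp[1], shp[2]))
  for (i in seq_along(pages)) data[i, , ] <- pages[[i]]
  if (!all(is.finite(data))) stop("TIFF '", path, "' contains non-finite values")
  dtype_origin <- NULL
  if (is_int && !is.null(bits) && bits %in% c(8L, 16L)) {
    dtype_origin <- as.integer(bits)
    data <- round(data * (2^dtype_origin - 1))
  }
  image_stack(data, dtype_origin = dtype_origin)
}

#' Write a volume to disk
#'
#' Writes an [image_stack()] as a multipage TIFF or an MRC2014 volume so that
#' [read_stack()] round-trips within quantization error.
#'
#' With `format = "tiff"`: if `dtype_origin` is recorded (8 or 16), values
#' are rounded and written at that integer depth; otherwise data are written
#' as 32-bit float, which requires intensities in `[0, 1]` (the TIFF writer's
#' float range) -- out-of-range float data are affinely rescaled with a
#' warning. MRC output is 32-bit float with no range restriction and carries
#' the voxel size in the header.
#'
#' @param stack An [image_stack()].
#' @param path Output path; the parent directory must exist.
#' @param format `"tiff"` or `"mrc"` (default: by extension of `path`).
#' @return Invisibly, `path`.
#' @export
write_stack <- function(stack, path, format = c("auto", "tiff", "mrc")) {
  format <- match.arg(format)
  if (!dir.exists(dirname(path))) stop("parent directory does not exist: ", dirname(path))
  if (format == "auto") format <- guess_format(path)
  switch(format,
    tiff = write_stack_tiff(stack, path),
    mrc  = write_mrc(stack, path)
  )
  invisible(path)
}

write_stack_tiff <- function(stack, path) {
  d <- stack$data
  nz <- dim(d)[1L]
  if (!is.null(stack$dtype_origin)) {
    b <- stack$dtype_origin
    top <- 2^b - 1
    v <- pmin(pmax(round(d), 0), top)
    pages <- lapply(seq_len(nz), function(i) {
      m <- v[i, , , drop = TRUE]; dim(m) <- dim(d)[2:3]; m / top
    })
    ok <- tryCatch({tiff::writeTIFF(pages, path, bits.per.sample = b); TRUE},
                   error = function(e) stop("failed to write TIFF '", path, "': ",
                                            conditionMessage(e)))
  } else {
    lo <- min(d); hi <- max(d)
    if (lo < 0 || hi > 1) {
      warning("float TIFF requires intensities in [0, 1]; rescaling range [",
              signif(lo, 6), ", ", signif(hi, 6), "] (scale metadata not persisted)")
      rng <- hi - lo
      d <- if (rng > 0) (d - lo) / rng else d * 0
    }
    pages <- lapply(seq_len(nz), function(i) {
      m <- d[i, , , drop = TRUE]; dim(m) <- dim(d)[2:3]; m
    })
    ok <- tryCatch({tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE); TRUE},
                   error = function(e) stop("failed to write TIFF '", path, "': ",
                                            conditionMessage(e)))
  }
  invisible(path)
}

#' Read a mask volume from an 8-bit TIFF (0 = known, nonzero = missing)
#' @param path Path to the mask TIFF.
#' @return A [missing_mask()].
#' @export
read_mask <- function(path) {
  st <- read_stack(path, format = "tiff")
  missing_mask(array(st$data != 0, dim = dim(st$data)))
}

#' Write a mask volume as an 8-bit TIFF (0/255)
#' @param mask A [missing_mask()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  st <- image_stack(array(ifelse(mask$mask, 255, 0), dim = dim(mask$mask)),
                    dtype_origin = 8L)
  write_stack(st, path, format = "tiff")
}
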