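#' Laplacian-of-Gaussian sharpness of a slice
#'
#' Focus metric used to rank slices: the standard deviation over all pixels
#' of the slice filtered with a Laplacian of Gaussian. Defocused slices score
#' low because blur suppresses the band the LoG responds to. The metric is
#' exactly 0 for a constant slice and invariant to additive intensity
#' offsets. Boundaries are mirror-padded so edge response does not dominate.
#'
#' @param image 2D matrix (y, x), at least 3x3, finite values.
#' @param log_sigma Gaussian scale of the LoG filter in pixels (> 0).
#' @return Nonnegative scalar sharpness.
#' @export
sharpness <- function(image, log_sigma = 2) {
  if (!is.matrix(image) || nrow(image) < 3 || ncol(image) < 3) {
    stop("`image` must be a matrix of at least 3x3")
  }
  if (!all(is.finite(image))) stop("`image` contains non-finite pixels")
  if (log_sigma <= 0) stop("`log_sigma` must be > 0")
  k <- log_kernel(log_sigma)
  hw <- (nrow(k) - 1L) %/% 2L
  # cap kernel support so mirror padding stays valid on small images
  max_hw <- min(nrow(image), ncol(image)) - 1L
  if (hw > max_hw) {
    k <- log_kernel(log_sigma, half_width = max_hw)
  }
  # centring makes offset invariance exact and constants score exactly 0
  image <- image - mean(image)
  if (all(image == 0)) return(0)
  filtered <- conv2_mirror(image, k)
  sqrt(mean((filtered - mean(filtered))^2))
}

#' Fourier ring correlation between two slices
#'
#' Measures the signal coherence of two images' Fourier transforms over
#' rings of spatial frequency. For each ring `r` the value is
#' `Re(sum(F1 * Conj(F2))) / sqrt(sum(|F1|^2) * sum(|F2|^2))` over the
#' Fourier samples in the ring; by Cauchy-Schwarz it lies in `[-1, 1]`. The
#' global score is the unweighted mean over rings, the single-number
#' acceptance criterion for a restored slice.
#'
#' The DC sample is excluded (it encodes only mean intensity, and excluding
#' it makes the metric offset-invariant). Frequencies are normalized per
#' axis to cycles/pixel, so Nyquist is 0.5 for both axes of non-square
#' images; rings beyond 0.5 (FFT corners) are not scored.
#'
#' @param image_a,image_b 2D matrices of the same shape, at least 8x8.
#' @param ring_width Ring width in cycles/pixel; default one Fourier pixel,
#'   `1 / min(dim(image_a))`.
#' @param weight_by_counts If `TRUE`, the global score weights rings by
#'   their Fourier sample counts instead of the default unweighted mean.
#' @return An object of class `FRCCurve` with fields `ring_radii` (ring
#'   centre frequencies), `values`, `ring_counts` and `global_score`.
#' @export
frc <- function(image_a, image_b, ring_width = NULL, weight_by_counts = FALSE) {
  if (!is.matrix(image_a) || !is.matrix(image_b)) stop("inputs must be matrices")
  if (!all(dim(image_a) == dim(image_b))) stop("images must have the same shape")
  if (any(dim(image_a) < 8L)) stop("images must be at least 8x8")
  ny <- nrow(image_a); nx <- ncol(image_a)
  if (is.null(ring_width)) ring_width <- 1 / min(ny, nx)
  if (ring_width <= 0) stop("`ring_width` must be > 0")

  F1 <- fft2(image_a)
  F2 <- fft2(image_b)
  r <- fft_radius(ny, nx)
  sel <- r > 0 & r <= 0.5 + 1e-12       # DC excluded, Nyquist circle kept
  bin <- as.integer(ceiling(r[sel] / ring_width))

  cross <- Re(F1[sel] * Conj(F2[sel]))
  p1 <- Mod(F1[sel])^2
  p2 <- Mod(F2[sel])^2

  num <- rowsum(cross, bin)
  d1 <- rowsum(p1, bin)
  d2 <- rowsum(p2, bin)
  counts <- as.vector(rowsum(rep(1L, length(bin)), bin))
  denom <- sqrt(as.vector(d1) * as.vector(d2))
  vals <- ifelse(denom > 0, as.vector(num) / denom, 0)
  if (any(denom == 0)) {
    message("frc: ", sum(denom == 0), " ring(s) with zero power set to 0")
  }
  bins <- as.integer(rownames(num))
  radii <- (bins - 0.5) * ring_width
  global <- if (weight_by_counts) sum(vals * counts) / sum(counts) else mean(vals)
  structure(
    list(ring_radii = radii, values = vals, ring_counts = counts,
         global_score = global, ring_width = ring_width),
    class = "FRCCurve"
  )
}

#' @export
print.FRCCurve <- function(x, ...) {
  cat(sprintf("FRCCurve: %d rings (width %.4g cycles/pixel), global score %.4f\n",
              length(x$values), x$ring_width, x$global_score))
  invisible(x)
}

#' Detect artifactual slices from the sharpness profile
#'
#' Scores every slice with the LoG sharpness metric and flags slices whose
#' sharpness falls below a threshold. The default `"robust_z"` rule works on
#' the log of the sharpness -- sharpness is a positive scale variable whose
#' legitimate slice-to-slice variation is multiplicative -- and flags slices
#' below `median - k * MAD` of the log values (zero-sharpness slices are
#' `-Inf` on the log scale and always flagged). The linear-scale equivalent
#' of the threshold is reported. Alternatively `rule = "absolute"` applies a
#' user-supplied cutoff on the raw sharpness.
#'
#' @param stack An [image_stack()].
#' @param log_sigma LoG scale in pixels passed to [sharpness()].
#' @param rule `"robust_z"` or `"absolute"`.
#' @param k Threshold multiplier for the robust rule (default 3).
#' @param cutoff Absolute sharpness cutoff (required for `rule = "absolute"`).
#' @return An object of class `SliceQualityReport`: per-slice `sharpness`,
#'   0-based `flagged` indices in ascending order, and the `threshold_rule`
#'   record.
#' @export
detect_artifactual_slices <- function(stack, log_sigma = 2,
                                      rule = c("robust_z", "absolute"),
                                      k = 3, cutoff = NULL) {
  rule <- match.arg(rule)
  nz <- n_slices(stack)
  if (rule == "robust_z" && nz < 5L) {
    stop("robust_z rule needs at least 5 slices (have ", nz,
         "); use rule = \"absolute\" with an explicit cutoff")
  }
  s <- vapply(seq_len(nz) - 1L, function(z) sharpness(get_slice(stack, z), log_sigma),
              numeric(1))
  if (rule == "robust_z") {
    ls <- suppressWarnings(log(s))     # sharpness 0 -> -Inf, always flagged
    fin <- is.finite(ls)
    if (sum(fin) < 3L) {
      stop("robust_z rule needs at least 3 slices with nonzero sharpness")
    }
    # floor the spread: in very uniform stacks the MAD collapses and slices
    # within normal acquisition variation (tens of percent) would be
    # flagged, while true defocus cuts the LoG response severalfold
    spread <- max(stats::mad(ls[fin]), 0.1)
    thr_log <- stats::median(ls[fin]) - k * spread
    thr <- exp(thr_log)
    rule_rec <- list(rule = "robust_z", k = k, log_sigma = log_sigma, threshold = thr)
    flagged <- which(ls < thr_log) - 1L
  } else {
    if (is.null(cutoff)) stop("rule = \"absolute\" requires `cutoff`")
    thr <- cutoff
    rule_rec <- list(rule = "absolute", cutoff = cutoff, log_sigma = log_sigma,
                     threshold = thr)
    flagged <- which(s < thr) - 1L
  }
  structure(
    list(sharpness = s, flagged = flagged, threshold_rule = rule_rec),
    class = "SliceQualityReport"
  )
}

#' @export
print.SliceQualityReport <- function(x, ...) {
  cat(sprintf("SliceQualityReport: %d slices, %d flagged (%s threshold %.4g)\n",
              length(x$sharpness), length(x$flagged), x$threshold_rule$rule,
              x$threshold_rule$threshold))
  if (length(x$flagged)) cat("  flagged z:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' FRC validation of restored slices against out-of-range references
#'
#' For each target (replaced) slice, computes the global FRC score against
#' the nearest non-flagged reference slice at z-distance `plane_range`,
#' before and after restoration. The reference distance keeps the comparison
#' clear of any artifactual run (default 3 planes, sized for runs of up to
#' 3 consecutive bad slices); a restoration is accepted when the score does
#' not decrease.
#'
#' @param stack_before,stack_after Stacks of identical shape.
#' @param target_slices 0-based z indices of the replaced slices.
#' @param plane_range Minimum |z| offset of the reference slice (>= 1).
#' @param flagged 0-based indices never to use as references (defaults to
#'   `target_slices`).
#' @return A data frame with one row per validated slice: `slice`,
#'   `reference`, `frc_before`, `frc_after`, `accepted`. Slices with no
#'   valid reference are skipped with a warning.
#' @export
frc_validation <- function(stack_before, stack_after, target_slices,
                           plane_range = 3, flagged = target_slices) {
  if (!all(dim(stack_before$data) == dim(stack_after$data))) stop("stack shape mismatch")
  if (plane_range < 1) stop("`plane_range` must be >= 1")
  nz <- n_slices(stack_before)
  rows <- list()
  for (z in as.integer(target_slices)) {
    ref <- find_reference_slice(z, nz, plane_range, flagged)
    if (is.na(ref)) {
      warning("no valid reference for slice ", z, " within bounds; skipped")
      next
    }
    refimg <- get_slice(stack_after, ref)
    g_before <- frc(get_slice(stack_before, z), refimg)$global_score
    g_after <- frc(get_slice(stack_after, z), refimg)$global_score
    rows[[length(rows) + 1L]] <- data.frame(
      slice = z, reference = ref,
      frc_before = g_before, frc_after = g_after,
      accepted = g_after >= g_before
    )
  }
  if (!length(rows)) {
    return(data.frame(slice = integer(), reference = integer(),
                      frc_before = numeric(), frc_after = numeric(),
                      accepted = logical()))
  }
  do.call(rbind, rows)
}

# Nearest in-range, non-flagged slice at distance >= plane_range from z
# (0-based); NA when none exists.
find_reference_slice <- function(z, nz, plane_range, flagged) {
  for (d in seq.int(plane_range, nz)) {
    for (cand in c(z + d, z - d)) {
      if (cand >= 0L && cand < nz && !(cand %in% flagged)) return(cand)
    }
  }
  NA_integer_
}
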