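#' Normalize an RGB histology image into myelin and cellularity channels
#'
#' Two-step normalization of a stained section: first pixel-wise, dividing
#' each channel by the pixel's summed RGB intensity (colour shares), then
#' channel-wise min-max rescaling to `[0, 1]` over masked-in pixels. The
#' blue (eriochrome cyanine) share becomes the myelin density channel and
#' the red (neutral red) share the cellularity channel. Pixels with zero
#' total intensity get zero shares; a channel that is constant over the
#' mask maps to all zeros (degenerate range rule).
#'
#' @param rgb Numeric array `rows x cols x 3` (R, G, B), non-negative.
#' @param mask Optional logical matrix; default all `TRUE`.
#' @return List with `blue` and `red` [image_grid()]s (myelin and
#'   cellularity densities).
#' @export
normalize_histology <- function(rgb, mask = NULL) {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] < 3) {
    stop("rgb must be a rows x cols x 3 array")
  }
  if (any(rgb < 0, na.rm = TRUE)) stop("channels must be non-negative")
  chan <- function(i) matrix(rgb[, , i], dim(rgb)[1], dim(rgb)[2])
  total <- chan(1) + chan(2) + chan(3)
  if (!any(total > 0)) stop("all-zero image: no pixel with positive intensity")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(total), ncol(total))
  share <- function(ch) {
    s <- ch / total
    s[total == 0] <- 0
    s
  }
  chans <- lapply(list(blue = chan(3), red = chan(1)), function(ch) {
    s <- share(ch)
    s <- minmax_rescale(s, mask)
    s[!mask] <- 0
    image_grid(s, mask)
  })
  chans
}

# Min-max rescale over masked-in pixels; degenerate (constant) range maps
# to all zeros.
minmax_rescale <- function(values, mask) {
  v <- values[mask]
  lo <- min(v)
  hi <- max(v)
  if (hi - lo <= 0) {
    values[] <- 0
    return(values)
  }
  (values - lo) / (hi - lo)
}

#' Normalize a raw MR image to the unit interval
#'
#' Min-max rescales intensities computed over masked-in pixels only;
#' masked-out pixels are set to 0. Idempotent.
#'
#' @param values Numeric matrix of raw intensities.
#' @param mask Logical matrix (`TRUE` = spinal cord tissue).
#' @return An [image_grid()] with masked-in values spanning `[0, 1]`.
#' @export
normalize_mri <- function(values, mask) {
  values <- as.matrix(values)
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (!any(mask)) stop("mask is empty")
  v <- values[mask]
  if (max(v) - min(v) <= 0) {
    stop("masked region is constant: no intensity contrast to normalize")
  }
  out <- minmax_rescale(values, mask)
  out[!mask] <- 0
  image_grid(out, mask)
}

#' Gaussian-pyramid downsampling
#'
#' Repeatedly blurs with the classic 5-tap binomial kernel
#' `(1, 4, 6, 4, 1)/16` (separable, reflective borders) and decimates by 2
#' until the target shape is reached. Source dimensions must be the target
#' dimensions times a common power of two; pad the image into a uniform
#' background canvas first if they are not.
#'
#' @param image An [image_grid()] or numeric matrix.
#' @param target_shape Integer `(rows, cols)`.
#' @return Downsampled object of the same type; a grid's mask is
#'   downsampled alongside (majority rule).
#' @export
pyramid_downsample <- function(image, target_shape) {
  is_grid <- inherits(image, "image_grid")
  values <- if (is_grid) image$values else as.matrix(image)
  src <- dim(values)
  ratio <- src / target_shape
  k <- log2(ratio[1])
  if (!isTRUE(all.equal(ratio[1], ratio[2])) ||
      k < 0 || !isTRUE(all.equal(k, round(k)))) {
    stop("source dims must be target dims x 2^k for integer k >= 0; ",
         "pad the image into a uniform background canvas first")
  }
  k <- as.integer(round(k))
  maskv <- if (is_grid) image$mask * 1 else NULL
  for (i in seq_len(k)) {
    values <- pyr_reduce(values)
    if (!is.null(maskv)) maskv <- pyr_reduce(maskv)
  }
  if (is_grid) {
    image_grid(values, maskv >= 0.5)
  } else {
    values
  }
}

# One pyramid level: separable binomial blur then decimate by 2.
pyr_reduce <- function(M) {
  kern <- c(1, 4, 6, 4, 1) / 16
  M <- conv_rows(M, kern)
  M <- t(conv_rows(t(M), kern))
  M[seq(1, nrow(M), by = 2), seq(1, ncol(M), by = 2), drop = FALSE]
}

# Convolve each column vertically with a centred odd kernel, reflecting
# at the borders (preserves constants exactly).
conv_rows <- function(M, kern) {
  h <- (length(kern) - 1L) / 2L
  nr <- nrow(M)
  idx <- c(rev(seq_len(h) + 1L), seq_len(nr), nr - seq_len(h))
  Mp <- M[idx, , drop = FALSE]
  out <- matrix(0, nr, ncol(M))
  for (j in seq_along(kern)) {
    out <- out + kern[j] * Mp[(j - 1L) + seq_len(nr), , drop = FALSE]
  }
  out
}
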