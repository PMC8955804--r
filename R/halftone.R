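# Halftoning: continuous CMYK channels to binary ink bitmaps by
# Floyd-Steinberg error diffusion at the largest dot size, with
# nearest-neighbour resampling to the (possibly anisotropic) printer grid.

#' Floyd-Steinberg error diffusion
#'
#' Binarizes a continuous channel by raster-scan error diffusion
#' (top-to-bottom, left-to-right, no serpentine). Each pixel is thresholded
#' at 0.5 (ties fire a dot) and the quantization error is diffused 7/16 to
#' the right neighbour, 3/16 below-left, 5/16 below, 1/16 below-right;
#' diffusion targets outside the image are dropped. Accumulated values are
#' never clamped before thresholding. Deterministic.
#'
#' @param ch numeric matrix with values in `[0, 1]`.
#' @return integer matrix of the same size with values in `{0, 1}`.
#' @export
#' @examples
#' mean(floyd_steinberg(matrix(0.5, 64, 64)))  # ~0.5: tone is preserved
floyd_steinberg <- function(ch) {
  ch <- as.matrix(ch)
  if (any(!is.finite(ch)) || any(ch < 0 | ch > 1)) {
    stop("floyd_steinberg: input values must be finite and in [0, 1]")
  }
  fs_diffuse(ch)
}

#' Halftone a 4-channel CMYK layer
#'
#' Applies [floyd_steinberg()] independently per channel (each channel
#' keeps its own error budget).
#'
#' @param layer `h x w x 4` array, or a list of 4 matrices, with values in
#'   `[0, 1]` (C, M, Y, K order).
#' @return named list of 4 binary matrices (`C`, `M`, `Y`, `K`).
#' @export
halftone_cmyk <- function(layer) {
  chans <- if (is.array(layer) && length(dim(layer)) == 3) {
    stopifnot(dim(layer)[3] == 4)
    lapply(1:4, function(i) layer[, , i])
  } else {
    stopifnot(is.list(layer), length(layer) == 4)
    layer
  }
  out <- lapply(chans, floyd_steinberg)
  names(out) <- c("C", "M", "Y", "K")
  out
}

#' Resample an image to the printer grid
#'
#' Nearest-neighbour scaling with independent horizontal and vertical
#' factors; output dimensions are `round(input * dst_dpi / src_dpi)` per
#' axis. Applied before halftoning so dot statistics live on the printer
#' grid; nearest-neighbour preserves concentration boundaries.
#'
#' @param img numeric matrix.
#' @param src_dpi,dst_dpi length-2 `(horizontal, vertical)` dpi pairs; a
#'   scalar is used for both axes. A 720 (horizontal) x 1200 (vertical)
#'   printer grid is typical for UV flatbed printers.
#' @return resampled matrix.
#' @export
resample_to_printer <- function(img, src_dpi, dst_dpi) {
  img <- as.matrix(img)
  src_dpi <- rep(as.numeric(src_dpi), length.out = 2)
  dst_dpi <- rep(as.numeric(dst_dpi), length.out = 2)
  if (any(src_dpi <= 0) || any(dst_dpi <= 0)) {
    stop("resample_to_printer: dpi values must be positive")
  }
  # dpi pairs are (horizontal, vertical): columns scale by [1], rows by [2]
  out_w <- max(1L, round(ncol(img) * dst_dpi[1] / src_dpi[1]))
  out_h <- max(1L, round(nrow(img) * dst_dpi[2] / src_dpi[2]))
  if (out_w == ncol(img) && out_h == nrow(img) &&
      all(dst_dpi == src_dpi)) {
    return(img)
  }
  src_r <- pmin(nrow(img), floor((seq_len(out_h) - 0.5) * nrow(img) / out_h) + 1L)
  src_c <- pmin(ncol(img), floor((seq_len(out_w) - 0.5) * ncol(img) / out_w) + 1L)
  img[src_r, src_c, drop = FALSE]
}
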