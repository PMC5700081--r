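#' Images and basic raster operations
#'
#' Throughout the package an image is a numeric `H x W x 3` array of
#' intensities on the working range \[0, 255\] (stored as doubles; 8-bit
#' only on disk). These helpers validate, clamp, resize, shift and
#' grey-convert such arrays.
#'
#' @param x Object to validate as an image.
#' @param channels Required channel count (`NA` to accept any).
#' @name image-utils
NULL

#' @describeIn image-utils Validate an image array (finite numeric
#'   `H x W x channels`); returns it invisibly unchanged.
#' @export
as_image <- function(x, channels = 3L) {
  if (!is.numeric(x) || length(dim(x)) != 3L) {
    stop("image must be a numeric H x W x C array", call. = FALSE)
  }
  if (!is.na(channels) && dim(x)[3] != channels) {
    stop("image must have ", channels, " channels, got ", dim(x)[3], call. = FALSE)
  }
  if (!all(is.finite(x))) stop("image contains non-finite values", call. = FALSE)
  invisible(x)
}

#' @describeIn image-utils Clamp intensities to the working range.
#' @param img Image array.
#' @param lo,hi Range bounds (defaults 0 and 255).
#' @export
clamp_image <- function(img, lo = 0, hi = 255) {
  img[img < lo] <- lo
  img[img > hi] <- hi
  img
}

#' @describeIn image-utils Bilinear resize to `height x width`
#'   (half-pixel-centre sampling, edge clamp; exact identity when the size
#'   is unchanged). Accepts `H x W` matrices or `H x W x C` arrays.
#' @param height,width Output size in pixels.
#' @export
resize_image <- function(img, height, width) {
  d <- dim(img)
  was_matrix <- length(d) == 2L
  if (was_matrix) dim(img) <- c(d, 1L)
  if (height < 1 || width < 1) stop("resize target must be at least 1 px", call. = FALSE)
  out <- bilinear_resize_cpp(img, dim(img), as.integer(height), as.integer(width))
  if (was_matrix) dim(out) <- dim(out)[1:2]
  out
}

#' @describeIn image-utils Cyclic (wrap-around) shift by `dy` rows and
#'   `dx` columns; used for dream jitter and as a warp oracle.
#' @param dy,dx Integer shifts (positive moves content down / right).
#' @export
roll_image <- function(img, dy, dx) {
  d <- dim(img)
  ri <- ((seq_len(d[1]) - 1L - as.integer(dy)) %% d[1]) + 1L
  ci <- ((seq_len(d[2]) - 1L - as.integer(dx)) %% d[2]) + 1L
  if (length(d) == 2L) img[ri, ci, drop = FALSE] else img[ri, ci, , drop = FALSE]
}

#' @describeIn image-utils Channel-mean greyscale conversion (`H x W`
#'   matrix out).
#' @export
to_gray <- function(img) {
  if (length(dim(img)) == 2L) return(img)
  m <- img[, , 1]
  for (c in seq_len(dim(img)[3])[-1]) m <- m + img[, , c]
  m / dim(img)[3]
}
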