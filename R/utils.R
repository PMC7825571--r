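# Internal helpers shared across modules.

#' Round half away from zero
#'
#' The rounding convention used for reported metric tables (base `round()`
#' rounds halves to even, which disagrees with table conventions).
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded vector.
#' @export
#' @examples
#' round_half_up(0.845)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Coerce an image-like object (EBImage::Image, matrix or 3-d array with the
# x-by-y-by-channel layout) to a plain grayscale matrix in [0, 1] using the
# Rec. 601 luma weights.
as_gray <- function(img) {
  x <- unclass(if (inherits(img, "Image")) EBImage::imageData(img) else img)
  d <- dim(x)
  if (is.null(d) || length(d) < 2L) {
    stop("expected a matrix or array with at least two dimensions")
  }
  if (length(d) == 2L) return(x)
  if (length(d) == 3L && d[3] >= 3L) {
    return(0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3])
  }
  if (length(d) == 3L && d[3] == 1L) return(x[, , 1])
  stop("unsupported image dimensions: ", paste(d, collapse = "x"))
}

# Frame dimensions in the package's coordinate convention: x along the first
# array dimension (width), y along the second (height), 0-based origin at
# the top-left pixel.
frame_width <- function(img) dim(as_gray_dims(img))[1]
frame_height <- function(img) dim(as_gray_dims(img))[2]

as_gray_dims <- function(img) {
  x <- if (inherits(img, "Image")) EBImage::imageData(img) else img
  x
}

check_same_dims <- function(a, b, what = "frames") {
  da <- dim(if (inherits(a, "Image")) EBImage::imageData(a) else a)[1:2]
  db <- dim(if (inherits(b, "Image")) EBImage::imageData(b) else b)[1:2]
  if (!identical(da, db)) {
    stop(sprintf(
      "%s have mismatched dimensions: %s vs %s",
      what, paste(da, collapse = "x"), paste(db, collapse = "x")
    ))
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
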