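# Labeled crop handling: fixed-size RGB rasters feeding the classifier.
# Pixels are stored as uint8 raw arrays (x-by-y-by-channel) to keep large
# augmented datasets small in memory; conversion helpers go to/from numeric
# [0, 1] arrays.

#' Convert between raw (uint8) and numeric crop rasters
#'
#' @param x A numeric array in \[0, 1\] (`as_crop_raw`) or a raw array
#'   (`crop_raster`), both `size x size x 3`.
#' @return The converted array; dimensions are preserved.
#' @export
as_crop_raw <- function(x) {
  r <- as.raw(pmin(pmax(round(x * 255), 0), 255))
  dim(r) <- dim(x)
  r
}

#' @rdname as_crop_raw
#' @export
crop_raster <- function(x) {
  stopifnot(is.raw(x))
  y <- as.integer(x) / 255
  dim(y) <- dim(x)
  y
}

#' Assemble a labeled crop table
#'
#' @param images List of crop rasters (raw or numeric `size x size x 3`).
#' @param labels Character or factor vector of class labels, one per crop.
#' @param size Expected raster side (default 128).
#' @return A tibble with columns `class` (factor) and `image` (list of raw
#'   arrays).
#' @export
crop_dataset <- function(images, labels, size = 128) {
  stopifnot(length(images) == length(labels))
  images <- lapply(images, function(x) {
    if (!is.raw(x)) x <- as_crop_raw(x)
    x
  })
  out <- tibble::tibble(
    class = if (is.factor(labels)) labels else factor(labels),
    image = images
  )
  validate_crops(out, size)
}

validate_crops <- function(crops, size) {
  stopifnot(is.data.frame(crops), all(c("class", "image") %in% names(crops)))
  need <- as.integer(size) * as.integer(size) * 3L
  ok <- vapply(crops$image, function(x) is.raw(x) && length(x) == need,
               logical(1))
  if (!all(ok)) {
    stop(sprintf("all crops must be raw %dx%dx3 rasters", size, size))
  }
  crops
}

#' Crop and resize a detection for classification
#'
#' Expands the detection's bounding box by `pad_fraction` on each side, grows
#' the shorter side to a square (both clipped to the frame), crops the frame
#' and resizes to the classifier input size. If the resulting crop already
#' has the target size, its pixels are returned untouched.
#'
#' @param image A frame (x-by-y matrix or x-by-y-by-3 array, values in
#'   \[0, 1\]).
#' @param det A single-row detection (with `x_min`, `y_min`, `width`,
#'   `height`, 0-based half-open bbox).
#' @param pad_fraction Padding added on each side as a fraction of the bbox
#'   side (default 0.1; classifier accuracy is sensitive to how tightly the
#'   segmentation box hugs the insect).
#' @param size Output side in pixels (default 128).
#' @return A numeric `size x size x 3` array in \[0, 1\].
#' @export
preprocess_crop <- function(image, det, pad_fraction = 0.1, size = 128) {
  stopifnot(pad_fraction >= 0)
  w <- det$width
  h <- det$height
  if (is.na(w) || is.na(h) || w < 1 || h < 1) {
    stop("degenerate bounding box")
  }
  iw <- dim(image)[1]
  ih <- dim(image)[2]
  # pad, then square-expand the shorter side (0-based half-open box)
  x0 <- det$x_min - pad_fraction * w
  x1 <- det$x_min + w + pad_fraction * w
  y0 <- det$y_min - pad_fraction * h
  y1 <- det$y_min + h + pad_fraction * h
  side <- max(x1 - x0, y1 - y0)
  cx <- (x0 + x1) / 2
  cy <- (y0 + y1) / 2
  x0 <- floor(cx - side / 2); x1 <- ceiling(cx + side / 2)
  y0 <- floor(cy - side / 2); y1 <- ceiling(cy + side / 2)
  x0 <- max(x0, 0); y0 <- max(y0, 0)
  x1 <- min(x1, iw); y1 <- min(y1, ih)
  xs <- (x0 + 1):x1
  ys <- (y0 + 1):y1
  arr <- if (length(dim(image)) == 3) {
    image[xs, ys, 1:3, drop = FALSE]
  } else {
    g <- image[xs, ys, drop = FALSE]
    array(rep(g, 3), c(length(xs), length(ys), 3))
  }
  if (dim(arr)[1] == size && dim(arr)[2] == size) {
    return(unclass(arr))
  }
  out <- EBImage::resize(
    EBImage::Image(arr, colormode = "Color"), w = size, h = size
  )
  clamp01(unclass(EBImage::imageData(out)))
}

#' Augment labeled crops
#'
#' Produces exactly `factor` crops per input: the first copy is the identity,
#' the remaining `factor - 1` apply randomly drawn label-preserving
#' transforms — horizontal/vertical flips, rotation by an arbitrary angle,
#' zoom, and an illumination gain. Draws come from R's RNG, so a fixed
#' `seed` reproduces the augmented set exactly.
#'
#' @param crops A crop tibble ([crop_dataset()]).
#' @param factor Number of output crops per input crop (>= 1).
#' @param seed Optional seed making the augmentation deterministic.
#' @param rotate_range Maximum absolute rotation in degrees (default 180:
#'   resting moths have no preferred orientation on the sheet).
#' @param zoom_range Zoom factor range (default 0.8 to 1.25).
#' @param gain_range Illumination gain range (default 0.7 to 1.3).
#' @return A crop tibble with `factor * nrow(crops)` rows; labels preserved,
#'   input order retained (all copies of crop 1, then crop 2, ...).
#' @export
augment <- function(crops, factor = 32, seed = NULL,
                    rotate_range = 180, zoom_range = c(0.8, 1.25),
                    gain_range = c(0.7, 1.3)) {
  stopifnot(factor >= 1)
  crops <- validate_crops(crops, sqrt(length(crops$image[[1]]) / 3))
  run <- function() {
    out <- vector("list", nrow(crops) * factor)
    for (i in seq_len(nrow(crops))) {
      base <- crops$image[[i]]
      out[[(i - 1) * factor + 1]] <- base
      if (factor > 1) {
        num <- crop_raster(base)
        for (j in 2:factor) {
          out[[(i - 1) * factor + j]] <- as_crop_raw(random_transform(
            num, rotate_range, zoom_range, gain_range
          ))
        }
      }
    }
    tibble::tibble(
      class = rep(crops$class, each = factor),
      image = out
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

random_transform <- function(num, rotate_range, zoom_range, gain_range) {
  if (runif(1) < 0.5) num <- num[dim(num)[1]:1, , , drop = FALSE]
  if (runif(1) < 0.5) num <- num[, dim(num)[2]:1, , drop = FALSE]
  angle <- runif(1, -rotate_range, rotate_range)
  zoom <- runif(1, zoom_range[1], zoom_range[2])
  num <- warp_affine(num, angle, zoom)
  gain <- runif(1, gain_range[1], gain_range[2])
  clamp01(num * gain)
}

# Rotation + zoom about the raster center in a single bilinear resampling
# pass (vectorized; one gather per channel). Out-of-frame samples take the
# border median, which stands in for the sheet background.
warp_affine <- function(num, angle = 0, zoom = 1) {
  s <- dim(num)[1]
  th <- angle * pi / 180
  ct <- cos(th) / zoom
  st <- sin(th) / zoom
  c0 <- (s + 1) / 2
  grid <- seq_len(s) - c0
  gx <- rep(grid, times = s)
  gy <- rep(grid, each = s)
  sx <- ct * gx - st * gy + c0
  sy <- st * gx + ct * gy + c0
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  inside <- x0 >= 1 & x0 < s & y0 >= 1 & y0 < s
  x0c <- pmin(pmax(x0, 1), s - 1)
  y0c <- pmin(pmax(y0, 1), s - 1)
  i00 <- x0c + (y0c - 1) * s
  bg_idx <- c(seq_len(s), (s - 1) * s + seq_len(s),
              1 + (seq_len(s) - 1) * s, s + (seq_len(s) - 1) * s)
  out <- num
  for (ch in 1:3) {
    v <- num[, , ch]
    p <- (1 - fx) * (1 - fy) * v[i00] + fx * (1 - fy) * v[i00 + 1] +
      (1 - fx) * fy * v[i00 + s] + fx * fy * v[i00 + s + 1]
    p[!inside] <- stats::median(v[bg_idx])
    out[, , ch] <- p
  }
  out
}
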