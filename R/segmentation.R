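#' Segmentation configuration
#'
#' Parameters of the blob-detection stage. Frames are subtracted from a fixed
#' background image of the empty sheet, thresholded with Otsu's method, and
#' cleaned with a morphological open (removes small noise blobs) and close
#' (fills holes and gaps) before connected components are extracted.
#'
#' @param min_blob_area Minimum connected-component area, in pixels, for a
#'   blob to become a detection. The default 2500 px matches the magnitude of
#'   the capture software's motion gate, which already suppresses insects
#'   smaller than roughly a 50x50 px patch.
#' @param open_kernel,close_kernel Side length, in pixels, of the square
#'   structuring elements used by the morphological open and close. Even
#'   values are rounded up to the next odd integer.
#' @param motion_gate_pixels Pixel-count threshold of [motion_gate()]; a frame
#'   is accepted when strictly more than this many pixels changed.
#' @param motion_gate_delta Per-pixel gray-level change (on the \[0, 1\] scale)
#'   above which a pixel counts as changed; the capture software leaves this
#'   unspecified, the default corresponds to 10 gray levels of an 8-bit image.
#'
#' @return A list of class `seg_config`.
#' @export
#' @examples
#' seg_config(min_blob_area = 500)
seg_config <- function(min_blob_area = 2500,
                       open_kernel = 5,
                       close_kernel = 7,
                       motion_gate_pixels = 1500,
                       motion_gate_delta = 10 / 255) {
  stopifnot(
    min_blob_area >= 0, open_kernel >= 0, close_kernel >= 0,
    motion_gate_pixels >= 0, motion_gate_delta >= 0
  )
  structure(
    list(
      min_blob_area = min_blob_area,
      open_kernel = open_kernel,
      close_kernel = close_kernel,
      motion_gate_pixels = motion_gate_pixels,
      motion_gate_delta = motion_gate_delta
    ),
    class = "seg_config"
  )
}

#' Motion gate between consecutive frames
#'
#' Emulates the capture software's trigger: a frame is kept only when the
#' scene changed in strictly more than `threshold` pixels, which filters
#' footage of small fast insects (mosquitoes, flies) that the trap is not
#' meant to count.
#'
#' @param current,previous Frames (matrices or x-by-y-by-channel arrays).
#' @param threshold Pixel-count threshold (default 1500).
#' @param delta Per-pixel absolute gray difference (on \[0, 1\]) above which a
#'   pixel counts as changed.
#'
#' @return `TRUE` if the frame passes the gate.
#' @export
motion_gate <- function(current, previous, threshold = 1500, delta = 10 / 255) {
  check_same_dims(current, previous)
  changed <- sum(abs(as_gray(current) - as_gray(previous)) > delta)
  changed > threshold
}

#' Foreground image by background subtraction
#'
#' Per-pixel absolute difference between the grayscale frame and the fixed
#' grayscale background reference. The absolute value makes the stage
#' agnostic to whether an insect is darker or lighter than the sheet.
#'
#' @param image,background Frames with identical dimensions.
#' @return A grayscale matrix in \[0, 1\].
#' @export
foreground <- function(image, background) {
  check_same_dims(image, background)
  abs(as_gray(image) - as_gray(background))
}

#' Otsu threshold of a grayscale raster
#'
#' Chooses the 8-bit threshold maximizing the between-class variance of the
#' gray histogram (computed from cumulative histogram moments). Ties are
#' broken toward the lowest threshold. A constant raster has no foreground;
#' `otsu_threshold()` then returns `NA`.
#'
#' @param gray Grayscale matrix with values in \[0, 1\].
#' @param levels Number of histogram levels (default 256).
#' @return The threshold on the \[0, 1\] scale (upper edge of the background
#'   class), or `NA_real_` for a constant input.
#' @export
otsu_threshold <- function(gray, levels = 256L) {
  g <- as.vector(gray)
  if (length(g) == 0L) stop("empty raster")
  lv <- as.integer(levels)
  q <- pmin(pmax(round(g * (lv - 1)), 0), lv - 1)
  if (min(q) == max(q)) return(NA_real_)
  h <- tabulate(q + 1L, nbins = lv)
  p <- h / sum(h)
  omega <- cumsum(p)               # class-0 weight for T = 0 .. lv-1
  mu <- cumsum(p * (seq_len(lv) - 1L))
  mu_t <- mu[lv]
  # between-class variance for thresholds T = 0 .. lv-2 (class 0: g <= T)
  w0 <- omega[-lv]
  m0 <- mu[-lv]
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, lv - 1L)
  sigma_b[valid] <- (mu_t * w0[valid] - m0[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  t_star <- which.max(sigma_b) - 1L  # lowest maximizer
  t_star / (lv - 1)
}

#' Binarize a foreground image with Otsu's method
#'
#' Pixels strictly above the Otsu threshold become foreground (1); a constant
#' raster yields an all-background image by convention.
#'
#' @inheritParams otsu_threshold
#' @return A 0/1 matrix of the same dimensions.
#' @export
binarize_otsu <- function(gray, levels = 256L) {
  thr <- otsu_threshold(gray, levels)
  if (is.na(thr)) {
    return(array(0, dim = dim(gray)))
  }
  (gray > thr) * 1
}

#' Morphological cleanup of a binary raster
#'
#' Opening with a square structuring element of side `open_kernel` removes
#' blobs thinner than the element; closing with side `close_kernel` fills
#' holes and joins nearby fragments of one insect.
#'
#' @param binary 0/1 matrix.
#' @param config A [seg_config()].
#' @return A cleaned 0/1 matrix.
#' @export
morph_clean <- function(binary, config = seg_config()) {
  x <- EBImage::Image(binary)
  if (config$open_kernel >= 2) {
    x <- EBImage::opening(x, make_box_brush(config$open_kernel))
  }
  if (config$close_kernel >= 2) {
    x <- EBImage::closing(x, make_box_brush(config$close_kernel))
  }
  m <- EBImage::imageData(x)
  dim(m) <- dim(binary)
  (m > 0) * 1
}

make_box_brush <- function(size) {
  s <- as.integer(size)
  if (s %% 2L == 0L) s <- s + 1L  # EBImage brushes must have odd side
  EBImage::makeBrush(s, shape = "box")
}

#' Extract detections from a binary raster
#'
#' Labels connected components (8-connectivity) and returns one detection per
#' component with area at least `min_blob_area`. The bounding box is the
#' component's pixel extent, half-open `[x_min, x_min + width)` with a
#' 0-based top-left origin; the reported centroid is the bounding-box center,
#' which is the position used by the tracker.
#'
#' @param binary 0/1 matrix (x along rows, y along columns).
#' @param frame_index Ordinal frame number recorded in the output.
#' @param config A [seg_config()]; only `min_blob_area` is used here.
#' @return A tibble with columns `frame_index`, `x_min`, `y_min`, `width`,
#'   `height`, `cx`, `cy`, `area`, ordered by (`y_min`, `x_min`).
#' @export
extract_detections <- function(binary, frame_index = 0L, config = seg_config()) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image((binary > 0) * 1)))
  dim(lab) <- dim(binary)
  n <- max(lab)
  if (n == 0) return(empty_detections())
  idx <- which(lab > 0)
  comp <- lab[idx]
  xs <- (idx - 1L) %% nrow(lab)        # 0-based x
  ys <- (idx - 1L) %/% nrow(lab)       # 0-based y
  det <- tibble::tibble(comp = comp, x = xs, y = ys) |>
    dplyr::group_by(.data$comp) |>
    dplyr::summarise(
      x_min = min(.data$x),
      y_min = min(.data$y),
      width = max(.data$x) - min(.data$x) + 1,
      height = max(.data$y) - min(.data$y) + 1,
      area = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$area >= config$min_blob_area) |>
    dplyr::mutate(
      frame_index = as.integer(frame_index),
      cx = .data$x_min + .data$width / 2,
      cy = .data$y_min + .data$height / 2
    ) |>
    dplyr::arrange(.data$y_min, .data$x_min) |>
    dplyr::select(
      "frame_index", "x_min", "y_min", "width", "height", "cx", "cy", "area"
    )
  det
}

empty_detections <- function() {
  tibble::tibble(
    frame_index = integer(), x_min = numeric(), y_min = numeric(),
    width = numeric(), height = numeric(), cx = numeric(), cy = numeric(),
    area = numeric()
  )
}

#' Segment one frame against the background reference
#'
#' Composition of [foreground()], [binarize_otsu()], [morph_clean()] and
#' [extract_detections()]: the full blob-detection stage for a single frame.
#'
#' @inheritParams foreground
#' @inheritParams extract_detections
#' @return A detections tibble (see [extract_detections()]).
#' @export
segment_frame <- function(image, background, frame_index = 0L,
                          config = seg_config()) {
  fg <- foreground(image, background)
  bin <- binarize_otsu(fg)
  extract_detections(morph_clean(bin, config), frame_index, config)
}

#' Segment a sequence of frames
#'
#' Runs [segment_frame()] over an ordered frame source, optionally applying
#' the [motion_gate()] against the previously accepted frame.
#'
#' @param frames Either a character vector of image paths (ordered), a
#'   directory containing frames (natural filename sort), or a list of
#'   in-memory frames.
#' @param background Background frame or path to its image file.
#' @param config A [seg_config()].
#' @param gate Apply the motion gate (default `FALSE`: offline analysis of
#'   already gated captures).
#' @param verbose Print per-frame detection counts.
#' @return A detections tibble covering all accepted frames, with an
#'   `accepted_frames` attribute listing the frame indices processed.
#' @export
segment_frames <- function(frames, background, config = seg_config(),
                           gate = FALSE, verbose = FALSE) {
  src <- frame_source(frames)
  bg_gray <- as_gray(read_frame(background))
  out <- vector("list", src$n)
  accepted <- logical(src$n)
  prev_gray <- NULL
  for (i in seq_len(src$n)) {
    g <- as_gray(src$get(i))
    if (!identical(dim(g), dim(bg_gray))) {
      stop("frame ", i, " does not match the background dimensions")
    }
    if (gate && !is.null(prev_gray) &&
        sum(abs(g - prev_gray) > config$motion_gate_delta) <=
          config$motion_gate_pixels) {
      out[[i]] <- empty_detections()
      next
    }
    accepted[i] <- TRUE
    prev_gray <- g
    bin <- binarize_otsu(abs(g - bg_gray))
    out[[i]] <- extract_detections(morph_clean(bin, config), i, config)
    if (verbose) {
      message(sprintf("frame %d: %d detection(s)", i, nrow(out[[i]])))
    }
  }
  res <- dplyr::bind_rows(out[accepted])
  attr(res, "accepted_frames") <- which(accepted)
  attr(res, "frame_dims") <- dim(bg_gray)
  res
}

#' Read a frame image from disk
#'
#' @param path Path to a JPG/PNG image (or an already in-memory frame, which
#'   is returned unchanged).
#' @return An x-by-y(-by-channel) numeric array with values in \[0, 1\].
#' @export
read_frame <- function(path) {
  if (!is.character(path)) return(path)
  if (!file.exists(path)) stop("frame file not found: ", path)
  EBImage::imageData(EBImage::readImage(path))
}

# An indexed, lazily-read frame source from paths, a directory, or a list.
frame_source <- function(frames) {
  if (is.character(frames) && length(frames) == 1L && dir.exists(frames)) {
    frames <- list_frame_files(frames)
  }
  if (is.character(frames)) {
    paths <- frames
    if (length(paths) == 0L) stop("no frames to process")
    list(n = length(paths), get = function(i) read_frame(paths[i]),
         paths = paths)
  } else if (is.list(frames)) {
    if (length(frames) == 0L) stop("no frames to process")
    list(n = length(frames), get = function(i) frames[[i]], paths = NULL)
  } else {
    stop("`frames` must be a directory, a vector of paths, or a list of frames")
  }
}

# Natural sort: numeric runs inside filenames compare numerically, so
# frame2.png orders before frame10.png.
list_frame_files <- function(dir) {
  f <- list.files(dir, pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE,
                  full.names = TRUE)
  if (length(f) == 0L) stop("no image files found in ", dir)
  f[natural_order(basename(f))]
}

natural_order <- function(x) {
  pieces <- regmatches(x, gregexpr("[0-9]+|[^0-9]+", x))
  maxlen <- max(lengths(pieces))
  keys <- lapply(seq_len(maxlen), function(i) {
    part <- vapply(pieces, function(p) if (i <= length(p)) p[i] else "",
                   character(1))
    num <- suppressWarnings(as.numeric(part))
    if (all(!is.na(num) | part == "")) {
      num[is.na(num)] <- -Inf
      num
    } else {
      part
    }
  })
  do.call(order, keys)
}

#' Write / read a detections table
#'
#' CSV round-trip of the detections schema produced by [segment_frames()].
#'
#' @param detections A detections tibble.
#' @param path Output CSV path.
#' @return `write_detections()` returns `path` invisibly; `read_detections()`
#'   returns the tibble.
#' @export
write_detections <- function(detections, path) {
  readr::write_csv(detections, path)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(frame_index = readr::col_integer()))
}
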