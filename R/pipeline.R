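# Full pipeline: segment -> track -> classify -> count, with file outputs.

#' Pipeline run configuration
#'
#' @param frames Frame directory (or vector of image paths / list of
#'   in-memory frames).
#' @param background Background image path (or in-memory frame).
#' @param output_dir Directory for output artifacts (created if missing).
#' @param model Optional path to a classifier weights file ([write_model()])
#'   or a `moth_cnn` object; without it, tracks are counted but labeled
#'   `unknown`.
#' @param segmentation A [seg_config()].
#' @param cost A [cost_params()].
#' @param min_consecutive Persistence filter threshold (see
#'   [filter_tracks()]).
#' @param unknown_threshold Confidence floor for [track_label()].
#' @param pad_fraction Crop padding for classification (see
#'   [preprocess_crop()]).
#' @param gate Apply the motion gate between frames.
#' @param annotate Write annotated copies of the frames with track boxes.
#' @param seed Seed for any stochastic steps.
#' @param verbose Log per-frame progress.
#' @return A list of class `run_config`.
#' @export
run_config <- function(frames, background, output_dir = tempfile("mcc_run_"),
                       model = NULL, segmentation = seg_config(),
                       cost = cost_params(), min_consecutive = 3,
                       unknown_threshold = 0.5, pad_fraction = 0.1,
                       gate = FALSE, annotate = FALSE, seed = 1,
                       verbose = FALSE) {
  structure(
    list(
      frames = frames, background = background, output_dir = output_dir,
      model = model, segmentation = segmentation, cost = cost,
      min_consecutive = min_consecutive,
      unknown_threshold = unknown_threshold, pad_fraction = pad_fraction,
      gate = gate, annotate = annotate, seed = as.integer(seed),
      verbose = verbose
    ),
    class = "run_config"
  )
}

#' Run the full counting pipeline
#'
#' Executes segmentation, tracking, per-detection classification, track
#' labeling and the survey summary in frame order, writing `detections.csv`,
#' `tracks.csv`, `summary.csv`/`summary.json` (and, optionally, annotated
#' frames) to the configured output directory.
#'
#' @param config A [run_config()].
#' @return An object of class `mcc_run`: list with `summary`
#'   (`survey_summary`), `tracks` (per-track tibble with labels and counted
#'   flag), `detections` (tracked, classified detections) and `paths`.
#' @export
run_mcc <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(config$background) && !file.exists(config$background)) {
    stop("background image not found: ", config$background)
  }
  model <- config$model
  if (is.character(model)) {
    if (!file.exists(model)) stop("model file not found: ", model)
    model <- read_model(model)
  }
  src <- frame_source(config$frames)
  if (src$n < 2) stop("at least two frames are required")
  if (!dir.exists(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE)
  }

  detections <- segment_frames(config$frames, config$background,
                               config$segmentation, gate = config$gate,
                               verbose = config$verbose)
  dims <- attr(detections, "frame_dims")
  tracked <- track_detections(detections, config$cost,
                              height = dims[2], width = dims[1])

  if (!is.null(model)) {
    tracked <- classify_detections(config$frames, tracked, model,
                                   pad_fraction = config$pad_fraction)
  } else {
    tracked <- dplyr::mutate(tracked, label = "unknown", confidence = NA_real_)
  }

  per_track <- filter_tracks(tracked, config$min_consecutive)
  labels <- if (!is.null(model)) {
    label_tracks(tracked, config$unknown_threshold)
  } else {
    tibble::tibble(track_id = per_track$track_id, final_label = "unknown",
                   mean_confidence = NA_real_, n_labels = per_track$n_detections)
  }
  tracks <- dplyr::left_join(per_track, labels, by = "track_id")
  summary <- summarize_tracks(tracks, n_frames = src$n)

  paths <- list(
    detections = file.path(config$output_dir, "detections.csv"),
    tracks = file.path(config$output_dir, "tracks.csv"),
    summary = file.path(config$output_dir, "summary.csv")
  )
  write_detections(dplyr::select(tracked, -dplyr::any_of("track_id")) |>
                     dplyr::select(dplyr::any_of(names(empty_detections()))),
                   paths$detections)
  write_tracks(tracked, paths$tracks)
  write_summary(summary, paths$summary)
  if (isTRUE(config$annotate)) {
    paths$annotated <- annotate_frames(config$frames, tracked,
                                       file.path(config$output_dir, "annotated"))
  }
  structure(
    list(summary = summary, tracks = tracks, detections = tracked,
         paths = paths, config = config),
    class = "mcc_run"
  )
}

#' @export
print.mcc_run <- function(x, ...) {
  cat("MCC pipeline run\n")
  print(x$summary)
  invisible(x)
}

#' Classify every tracked detection
#'
#' Crops each detection out of its frame ([preprocess_crop()]) and predicts
#' its class, adding `label` and `confidence` columns.
#'
#' @param frames Frame source (directory, paths, or list) aligned with the
#'   `frame_index` column.
#' @param tracked Tracked detections tibble.
#' @param model A `moth_cnn`.
#' @param pad_fraction Crop padding (see [preprocess_crop()]).
#' @return `tracked` with `label` and `confidence` columns.
#' @export
classify_detections <- function(frames, tracked, model, pad_fraction = 0.1) {
  src <- frame_source(frames)
  tracked$label <- NA_character_
  tracked$confidence <- NA_real_
  for (f in unique(tracked$frame_index)) {
    rows <- which(tracked$frame_index == f)
    img <- src$get(f)
    crops <- lapply(rows, function(r) {
      preprocess_crop(img, tracked[r, ], pad_fraction,
                      size = model$spec$input_size)
    })
    pred <- predict(model, crops)
    tracked$label[rows] <- pred$label
    tracked$confidence[rows] <- pred$confidence
  }
  tracked
}

# Draw track bounding boxes and IDs into copies of the frames.
annotate_frames <- function(frames, tracked, dir) {
  src <- frame_source(frames)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- character(src$n)
  for (f in seq_len(src$n)) {
    img <- src$get(f)
    if (length(dim(img)) == 2) {
      img <- array(rep(img, 3), c(dim(img), 3))
    }
    rows <- dplyr::filter(tracked, .data$frame_index == f)
    for (r in seq_len(nrow(rows))) {
      img <- draw_box(img, rows[r, ])
    }
    out[f] <- file.path(dir, sprintf("annotated_%04d.png", f))
    EBImage::writeImage(EBImage::Image(img, colormode = "Color"), out[f])
  }
  out
}

draw_box <- function(img, det, thickness = 3) {
  nx <- dim(img)[1]; ny <- dim(img)[2]
  x0 <- max(1, det$x_min + 1); x1 <- min(nx, det$x_min + det$width)
  y0 <- max(1, det$y_min + 1); y1 <- min(ny, det$y_min + det$height)
  t <- thickness - 1
  col <- c(0.9, 0.1, 0.1)
  for (ch in 1:3) {
    img[x0:x1, max(1, y0 - t):y0, ch] <- col[ch]
    img[x0:x1, y1:min(ny, y1 + t), ch] <- col[ch]
    img[max(1, x0 - t):x0, y0:y1, ch] <- col[ch]
    img[x1:min(nx, x1 + t), y0:y1, ch] <- col[ch]
  }
  img
}

#' Read a pipeline configuration file
#'
#' YAML (or JSON) with top-level `paths:`, `segmentation:`, `tracking:` and
#' `counting:` sections; any missing key takes its documented default.
#'
#' @param path Config file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  p <- raw$paths %||% list()
  s <- raw$segmentation %||% list()
  tr <- raw$tracking %||% list()
  co <- raw$counting %||% list()
  run_config(
    frames = p$frames %||% stop("config must set paths: frames"),
    background = p$background %||% stop("config must set paths: background"),
    output_dir = p$output_dir %||% tempfile("mcc_run_"),
    model = p$model,
    segmentation = seg_config(
      min_blob_area = s$min_blob_area %||% 2500,
      open_kernel = s$open_kernel %||% 5,
      close_kernel = s$close_kernel %||% 7,
      motion_gate_pixels = s$motion_gate_pixels %||% 1500,
      motion_gate_delta = s$motion_gate_delta %||% (10 / 255)
    ),
    cost = cost_params(
      wdist = tr$wdist %||% 0.8,
      warea = tr$warea %||% 0.2,
      dummy_cost = tr$dummy_cost
    ),
    min_consecutive = co$min_consecutive %||% 3,
    unknown_threshold = co$unknown_threshold %||% 0.5,
    pad_fraction = co$pad_fraction %||% 0.1,
    gate = raw$gate %||% FALSE,
    annotate = raw$annotate %||% FALSE,
    seed = raw$seed %||% 1,
    verbose = raw$verbose %||% FALSE
  )
}

#' Default configuration as a YAML string
#'
#' @return A character scalar of YAML listing every tunable with its default.
#' @export
default_config_yaml <- function() {
  paste(
    "paths:",
    "  frames: frames/",
    "  background: background.png",
    "  model: null",
    "  output_dir: mcc_out/",
    "segmentation:",
    "  min_blob_area: 2500",
    "  open_kernel: 5",
    "  close_kernel: 7",
    "  motion_gate_pixels: 1500",
    "  motion_gate_delta: 0.0392",
    "tracking:",
    "  wdist: 0.8",
    "  warea: 0.2",
    "  dummy_cost: 2.0",
    "counting:",
    "  min_consecutive: 3",
    "  unknown_threshold: 0.5",
    "  pad_fraction: 0.1",
    "gate: false",
    "annotate: false",
    "seed: 1",
    "verbose: false",
    sep = "\n"
  )
}

#' Plot tracks over the frame area
#'
#' @param tracked Tracked detections tibble.
#' @param dims Frame dimensions `c(width, height)`; defaults to the
#'   `frame_dims` attribute.
#' @return A ggplot.
#' @export
plot_tracks <- function(tracked, dims = attr(tracked, "frame_dims")) {
  p <- ggplot2::ggplot(
    tracked,
    ggplot2::aes(.data$cx, .data$cy, color = factor(.data$track_id),
                 group = .data$track_id)
  ) +
    ggplot2::geom_path(alpha = 0.7) +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (px)", y = "y (px)", color = "track") +
    ggplot2::theme_minimal()
  if (!is.null(dims)) {
    p <- p + ggplot2::coord_fixed(xlim = c(0, dims[1]), ylim = c(dims[2], 0))
  }
  p
}

#' Bar chart of a survey summary
#'
#' @param object A `survey_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.survey_summary <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(stats::reorder(.data$species, .data$count), .data$count)
  ) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "individuals counted") +
    ggplot2::theme_minimal()
}
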