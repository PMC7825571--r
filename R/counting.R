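# Track-level reduction: one species label and one count per real insect.

#' Majority-vote label of one track
#'
#' The species most frequently predicted across the track's frames becomes
#' its final label; ties are broken toward the label seen earliest in the
#' track. A track whose winning label is `background`, or whose mean
#' prediction confidence falls below `unknown_threshold`, is labeled
#' `unknown` (an insect the classifier does not recognize).
#'
#' @param labels Character vector of per-frame predicted labels, in frame
#'   order.
#' @param confidence Optional numeric vector of per-frame confidences.
#' @param unknown_threshold Mean-confidence floor below which the track is
#'   `unknown` (default 0.5).
#' @return A single label string.
#' @export
#' @examples
#' track_label(c("Noctua pronuba", "Noctua pronuba", "background"))
track_label <- function(labels, confidence = NULL, unknown_threshold = 0.5) {
  if (length(labels) == 0) stop("track has an empty label history")
  counts <- table(labels)
  winners <- names(counts)[counts == max(counts)]
  first_seen <- vapply(winners, function(w) match(w, labels), integer(1))
  winner <- winners[which.min(first_seen)]
  mean_conf <- if (is.null(confidence)) 1 else mean(confidence)
  if (winner == "background" || mean_conf < unknown_threshold) "unknown" else winner
}

#' Label all tracks by majority vote
#'
#' @param classified Tibble of per-frame predictions with columns `track_id`,
#'   `frame_index`, `label` and optionally `confidence`.
#' @param unknown_threshold See [track_label()].
#' @return A tibble with one row per track: `track_id`, `final_label`,
#'   `mean_confidence`, `n_labels`.
#' @export
label_tracks <- function(classified, unknown_threshold = 0.5) {
  classified |>
    dplyr::arrange(.data$track_id, .data$frame_index) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      final_label = track_label(
        .data$label,
        if ("confidence" %in% names(classified)) .data$confidence else NULL,
        unknown_threshold
      ),
      mean_confidence = if ("confidence" %in% names(classified)) {
        mean(.data$confidence)
      } else NA_real_,
      n_labels = dplyr::n(),
      .groups = "drop"
    )
}

#' Filter noise tracks by temporal persistence
#'
#' An insect is only counted when its track persists for at least
#' `min_consecutive` consecutive frames; short-lived tracks — typically
#' insects flying close to the camera lens — are kept in the table but
#' flagged `counted = FALSE`.
#'
#' @param tracked Tracked detections tibble (with `track_id` and
#'   `frame_index`), or a per-track tibble already carrying a `frames`
#'   list-column.
#' @param min_consecutive Minimum length of the longest consecutive-frame
#'   run (default 3).
#' @return A per-track tibble: `track_id`, `first_frame`, `last_frame`,
#'   `n_detections`, `longest_run`, `counted`.
#' @export
filter_tracks <- function(tracked, min_consecutive = 3) {
  stopifnot(min_consecutive >= 1)
  tracked |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      first_frame = min(.data$frame_index),
      last_frame = max(.data$frame_index),
      n_detections = dplyr::n(),
      longest_run = max_consecutive(.data$frame_index),
      .groups = "drop"
    ) |>
    dplyr::mutate(counted = .data$longest_run >= min_consecutive)
}

max_consecutive <- function(frames) {
  f <- sort(unique(frames))
  if (length(f) == 0L) return(0L)
  r <- rle(diff(f) == 1)
  runs <- r$lengths[r$values]
  if (length(runs) == 0L) 1L else max(runs) + 1L
}

#' Summarize a survey
#'
#' Reduces labeled, filtered tracks to per-species counts. Only tracks with
#' `counted = TRUE` contribute; tracks labeled `unknown` are tallied
#' separately, and the total equals the number of counted tracks.
#'
#' @param tracks Per-track tibble with `final_label` and `counted` columns
#'   (join of [filter_tracks()] and [label_tracks()] output).
#' @param classes Insect class labels to report (default the nine monitored
#'   classes, i.e. [moth_classes()] without `background`).
#' @param n_frames Optional number of frames processed, recorded in the
#'   summary.
#' @return An object of class `survey_summary`: a tibble with one row per
#'   class plus an `unknown` row, and attributes `total_individuals`,
#'   `unknown_count`, `n_tracks`, `n_frames`.
#' @export
summarize_tracks <- function(tracks,
                             classes = setdiff(moth_classes(), "background"),
                             n_frames = NA_integer_) {
  counted <- dplyr::filter(tracks, .data$counted)
  lab <- counted$final_label
  counts <- vapply(classes, function(cl) sum(lab == cl), integer(1),
                   USE.NAMES = FALSE)
  unknown_count <- sum(!(lab %in% classes))
  out <- tibble::tibble(
    species = c(classes, "unknown"),
    count = c(counts, unknown_count)
  )
  structure(
    out,
    class = c("survey_summary", class(out)),
    total_individuals = nrow(counted),
    unknown_count = unknown_count,
    n_tracks = nrow(tracks),
    n_frames = n_frames
  )
}

#' @export
print.survey_summary <- function(x, ...) {
  cat(sprintf(
    "Survey summary: %d individuals counted (%d unknown) from %d tracks\n",
    attr(x, "total_individuals"), attr(x, "unknown_count"), attr(x, "n_tracks")
  ))
  NextMethod()
}

#' Write / read a survey summary
#'
#' The CSV holds one row per class; the JSON sidecar (same path with
#' `.json`) carries the totals.
#'
#' @param summary A `survey_summary`.
#' @param path Output CSV path.
#' @return `write_summary()` returns `path` invisibly; `read_summary()` the
#'   summary object.
#' @export
write_summary <- function(summary, path) {
  readr::write_csv(tibble::as_tibble(summary), path)
  meta <- list(
    total_individuals = attr(summary, "total_individuals"),
    unknown_count = attr(summary, "unknown_count"),
    n_tracks = attr(summary, "n_tracks"),
    n_frames = attr(summary, "n_frames")
  )
  jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_summary
#' @export
read_summary <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  meta_path <- paste0(tools::file_path_sans_ext(path), ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  structure(
    tab,
    class = c("survey_summary", class(tab)),
    total_individuals = meta$total_individuals %||% sum(tab$count),
    unknown_count = meta$unknown_count %||%
      sum(tab$count[tab$species == "unknown"]),
    n_tracks = meta$n_tracks %||% NA_integer_,
    n_frames = meta$n_frames %||% NA_integer_
  )
}
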