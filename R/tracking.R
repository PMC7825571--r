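#' Tracker cost parameters
#'
#' The matching cost between a detection in the previous frame and one in the
#' current frame is a weighted sum of a normalized centroid distance and a
#' bounding-box area dissimilarity,
#' `cost = (dist / max_dist) * wdist + (1 - area_cost) * warea`.
#' Insects on the sheet are mostly stationary between captures, so distance
#' dominates by default. Dummy rows/columns that square the matrix carry a
#' cost strictly larger than any real pairing so they only absorb genuine
#' entries and exits.
#'
#' @param wdist Weight of the normalized distance term (default 0.8).
#' @param warea Weight of the area term (default 0.2).
#' @param dummy_cost Cost of dummy rows/columns; default `2 * (wdist + warea)`,
#'   strictly above the `wdist + warea` bound of any real pair cost.
#'
#' @return A list of class `cost_params`.
#' @export
#' @examples
#' cost_params()
cost_params <- function(wdist = 0.8, warea = 0.2, dummy_cost = NULL) {
  stopifnot(wdist >= 0, warea >= 0, wdist + warea > 0)
  dummy_cost <- dummy_cost %||% (2 * (wdist + warea))
  if (dummy_cost <= wdist + warea) {
    stop("dummy_cost must strictly exceed wdist + warea")
  }
  structure(
    list(wdist = wdist, warea = warea, dummy_cost = dummy_cost),
    class = "cost_params"
  )
}

#' Euclidean distance between two centroids
#'
#' @param p1,p2 Length-2 numeric vectors `(x, y)` in pixels.
#' @return Distance in pixels.
#' @export
#' @examples
#' centroid_dist(c(0, 0), c(3, 4))
centroid_dist <- function(p1, p2) {
  stopifnot(is.finite(p1), is.finite(p2))
  sqrt(sum((p2 - p1)^2))
}

#' Image-diagonal normalization constant
#'
#' The largest possible centroid displacement in a frame, used to normalize
#' the distance term of the pair cost.
#'
#' @param height,width Frame dimensions in pixels.
#' @return The frame diagonal, `sqrt(height^2 + width^2)`.
#' @export
#' @examples
#' max_dist(2160, 3840)
max_dist <- function(height, width) {
  if (height <= 0 || width <= 0) stop("frame dimensions must be positive")
  sqrt(height^2 + width^2)
}

#' Bounding-box area similarity
#'
#' Ratio of the smaller to the larger bounding-box area: 1 for identical
#' sizes, approaching 0 for very different ones. Symmetric in its arguments.
#'
#' @param area_a,area_b Bounding-box areas in pixels, both positive.
#' @return A value in (0, 1\].
#' @export
#' @examples
#' area_cost(50, 100)
area_cost <- function(area_a, area_b) {
  if (any(area_a <= 0) || any(area_b <= 0)) stop("areas must be positive")
  pmin(area_a, area_b) / pmax(area_a, area_b)
}

#' Pairwise matching cost between two detections
#'
#' @param d_prev,d_curr Single-row detection tibbles (or lists) carrying
#'   `cx`, `cy` and bounding-box `width`/`height`.
#' @param params A [cost_params()].
#' @param height,width Frame dimensions in pixels.
#' @return Cost in `[0, wdist + warea]`; 0 iff same centroid and equal
#'   bounding-box area.
#' @export
pair_cost <- function(d_prev, d_curr, params = cost_params(),
                      height, width) {
  d <- centroid_dist(c(d_prev$cx, d_prev$cy), c(d_curr$cx, d_curr$cy))
  ac <- area_cost(bbox_area(d_prev), bbox_area(d_curr))
  (d / max_dist(height, width)) * params$wdist + (1 - ac) * params$warea
}

# Area entering the cost is the bounding-box area (the tracker reasons about
# boxes, not segmented masks).
bbox_area <- function(det) det$width * det$height

#' Build the padded square cost matrix for one matching step
#'
#' Entry (i, j) is the pair cost of previous detection i against current
#' detection j; dummy rows/columns pad the matrix to
#' `N = max(n_prev, n_curr)` and carry `params$dummy_cost`.
#'
#' @param prev,curr Detection tibbles for the previous and current frame.
#' @inheritParams pair_cost
#' @return An `N x N` matrix with attributes `n_prev` and `n_curr`.
#' @export
build_cost_matrix <- function(prev, curr, params = cost_params(),
                              height, width) {
  np <- nrow(prev)
  nc <- nrow(curr)
  n <- max(np, nc)
  m <- matrix(params$dummy_cost, n, n)
  if (np > 0 && nc > 0) {
    md <- max_dist(height, width)
    dx <- outer(prev$cx, curr$cx, `-`)
    dy <- outer(prev$cy, curr$cy, `-`)
    ap <- bbox_area(prev)
    ac <- bbox_area(curr)
    ratio <- outer(ap, ac, pmin) / outer(ap, ac, pmax)
    m[seq_len(np), seq_len(nc)] <-
      sqrt(dx^2 + dy^2) / md * params$wdist + (1 - ratio) * params$warea
  }
  attr(m, "n_prev") <- np
  attr(m, "n_curr") <- nc
  m
}

#' Solve the assignment problem for one matching step
#'
#' Minimum-cost perfect matching on a square cost matrix via the Hungarian
#' algorithm. Rows/columns beyond `n_prev`/`n_curr` are dummies: a current
#' detection matched to a dummy row has entered the scene; a previous
#' detection matched to a dummy column has left.
#'
#' @param cost Square numeric matrix, e.g. from [build_cost_matrix()].
#' @param n_prev,n_curr Number of real rows/columns; default taken from the
#'   matrix attributes, else the full dimension.
#' @return A list with `matches` (tibble of `prev`, `curr` index pairs),
#'   `entered` (current detection indices), `exited` (previous detection
#'   indices) and `total_cost`.
#' @export
#' @examples
#' solve_assignment(matrix(c(1, 2, 2, 4), 2, byrow = TRUE))
solve_assignment <- function(cost,
                             n_prev = attr(cost, "n_prev") %||% nrow(cost),
                             n_curr = attr(cost, "n_curr") %||% ncol(cost)) {
  if (length(cost) == 0L) {
    return(list(matches = tibble::tibble(prev = integer(), curr = integer()),
                entered = integer(), exited = integer(), total_cost = 0))
  }
  if (nrow(cost) != ncol(cost)) stop("cost matrix must be square")
  assignment <- hungarian(unclass(cost))
  rows <- seq_len(nrow(cost))
  real <- rows <= n_prev & assignment <= n_curr
  list(
    matches = tibble::tibble(prev = rows[real], curr = assignment[real]),
    entered = sort(setdiff(seq_len(n_curr), assignment[real])),
    exited = rows[rows <= n_prev & assignment > n_curr],
    total_cost = sum(cost[cbind(rows, assignment)])
  )
}

#' Advance the tracker by one frame
#'
#' Matches the detections of the current frame against the last detections of
#' the active tracks. Matched detections inherit the track ID; unmatched
#' current detections open fresh tracks; unmatched tracks are closed
#' immediately (no coasting — matching is strictly between consecutive
#' accepted frames).
#'
#' @param active Tibble of active tracks: detection columns plus `track_id`
#'   (their last observed detection). May have zero rows.
#' @param curr Detection tibble for the current frame.
#' @param params A [cost_params()].
#' @param height,width Frame dimensions in pixels.
#' @param next_id Next unused track ID.
#' @return A list with `assigned` (`curr` plus a `track_id` column),
#'   `closed_ids`, and the updated `next_id`.
#' @export
step_tracks <- function(active, curr, params = cost_params(),
                        height, width, next_id = 1L) {
  if (nrow(active) == 0L) {
    ids <- if (nrow(curr)) next_id + seq_len(nrow(curr)) - 1L else integer()
    return(list(
      assigned = dplyr::mutate(curr, track_id = as.integer(ids)),
      closed_ids = integer(),
      next_id = next_id + nrow(curr)
    ))
  }
  if (nrow(curr) == 0L) {
    return(list(
      assigned = dplyr::mutate(curr, track_id = integer()),
      closed_ids = active$track_id,
      next_id = next_id
    ))
  }
  cost <- build_cost_matrix(active, curr, params, height, width)
  res <- solve_assignment(cost)
  track_id <- integer(nrow(curr))
  track_id[res$matches$curr] <- active$track_id[res$matches$prev]
  if (length(res$entered)) {
    track_id[res$entered] <- next_id + seq_along(res$entered) - 1L
    next_id <- next_id + length(res$entered)
  }
  list(
    assigned = dplyr::mutate(curr, track_id = as.integer(track_id)),
    closed_ids = active$track_id[res$exited],
    next_id = next_id
  )
}

#' Track detections across a frame sequence
#'
#' Links a multi-frame detections table into tracks by repeated
#' [step_tracks()] over consecutive accepted frames.
#'
#' @param detections Detections tibble spanning multiple frames (e.g. from
#'   [segment_frames()]).
#' @param params A [cost_params()].
#' @param height,width Frame dimensions in pixels; defaults to the
#'   `frame_dims` attribute left by [segment_frames()].
#' @return The detections tibble with an added `track_id` column.
#' @export
track_detections <- function(detections, params = cost_params(),
                             height = NULL, width = NULL) {
  dims <- attr(detections, "frame_dims")
  width <- width %||% dims[1]
  height <- height %||% dims[2]
  if (is.null(width) || is.null(height)) {
    stop("frame dimensions are required (height/width or a frame_dims attribute)")
  }
  if (nrow(detections) == 0L) {
    return(dplyr::mutate(detections, track_id = integer()))
  }
  frames <- sort(unique(detections$frame_index))
  active <- NULL
  next_id <- 1L
  pieces <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    curr <- dplyr::filter(detections, .data$frame_index == frames[k])
    if (is.null(active)) {
      st <- step_tracks(dplyr::mutate(curr[0, ], track_id = integer()),
                        curr, params, height, width, next_id)
    } else {
      st <- step_tracks(active, curr, params, height, width, next_id)
    }
    next_id <- st$next_id
    pieces[[k]] <- st$assigned
    active <- st$assigned
  }
  out <- dplyr::bind_rows(pieces)
  attr(out, "frame_dims") <- c(width, height)
  out
}

#' Per-track summary table
#'
#' @param tracked Tracked detections (output of [track_detections()]).
#' @return A tibble with one row per track: `track_id`, `first_frame`,
#'   `last_frame`, `n_detections`.
#' @export
tracks_summary <- function(tracked) {
  tracked |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      first_frame = min(.data$frame_index),
      last_frame = max(.data$frame_index),
      n_detections = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$track_id)
}

#' Write / read a tracked-detections table
#'
#' @param tracked Tracked detections tibble.
#' @param path Output CSV path.
#' @return `write_tracks()` returns `path` invisibly; `read_tracks()` the
#'   tibble.
#' @export
write_tracks <- function(tracked, path) {
  readr::write_csv(tracked, path)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(frame_index = readr::col_integer(),
                                          track_id = readr::col_integer()))
}
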