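# Tracking and classification quality metrics.

#' Tracking detection rate
#'
#' Fraction of ground-truth individuals that kept a single correct track ID
#' over their whole presence: `TDR = TP / GT`.
#'
#' @param tp Number of true-positive individuals.
#' @param gt Ground-truth number of unique individuals (>= 1).
#' @return A fraction in \[0, 1\].
#' @export
#' @examples
#' tdr(65, 82)
tdr <- function(tp, gt) {
  if (gt < 1) stop("GT must be at least 1")
  if (tp < 0 || tp > gt) stop("TP must lie in [0, GT]")
  tp / gt
}

#' False alarm rate
#'
#' Fraction of produced tracks that are wrong — duplicates, identity
#' reassignments, or tracks matching no individual: `FAR = FP / (TP + FP)`.
#'
#' @param tp,fp True-positive and false-positive counts with `tp + fp >= 1`.
#' @return A fraction in \[0, 1\].
#' @export
#' @examples
#' far(65, 18)
far <- function(tp, fp) {
  if (tp < 0 || fp < 0) stop("counts must be non-negative")
  if (tp + fp < 1) stop("TP + FP must be at least 1")
  fp / (tp + fp)
}

#' Precision, recall and F1 from TP/FP/FN counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `f1 = 2 TP / (2 TP + FP + FN)`. A metric whose denominator is zero is
#' reported as `NA` (absent), not as zero.
#'
#' @param tp,fp,fn Non-negative counts with `tp + fp + fn >= 1`.
#' @return A one-row tibble with `TP`, `FP`, `FN`, `precision`, `recall`,
#'   `f1`.
#' @export
#' @examples
#' class_metrics(24, 6, 8)  # precision 0.80, recall 0.75, F1 0.77
class_metrics <- function(tp, fp, fn) {
  if (tp < 0 || fp < 0 || fn < 0) stop("counts must be non-negative")
  if (tp + fp + fn < 1) stop("at least one count must be positive")
  tibble::tibble(
    TP = tp, FP = fp, FN = fn,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    f1 = 2 * tp / (2 * tp + fp + fn)
  )
}

#' Per-class metric table with a micro-averaged total row
#'
#' Applies [class_metrics()] to each row of a per-class count table and
#' appends a `Total` row computed from the summed counts.
#'
#' @param counts Tibble with columns `species`, `TP`, `FP`, `FN`.
#' @return A tibble with `precision`, `recall`, `f1` per class plus the
#'   `Total` row.
#' @export
class_metrics_table <- function(counts) {
  per <- purrr::pmap(
    list(counts$TP, counts$FP, counts$FN),
    class_metrics
  ) |> dplyr::bind_rows()
  per <- dplyr::mutate(per, species = counts$species, .before = 1)
  tot <- class_metrics(sum(counts$TP), sum(counts$FP), sum(counts$FN)) |>
    dplyr::mutate(species = "Total", .before = 1)
  dplyr::bind_rows(per, tot)
}

#' Evaluate tracking against ground truth
#'
#' Matches predicted tracks to ground-truth individuals frame by frame: a
#' track owns an individual in a frame when the individual's true centroid
#' falls inside the track's bounding box (nearest track centroid on ties).
#' An individual is a true positive when a single track owns it in every
#' frame where any track owns it, and that track's majority individual is
#' this one (a one-to-one match). False positives are individuals that were
#' split, duplicated, or reassigned, plus predicted tracks owning no
#' individual at all.
#'
#' @param tracked Tracked detections tibble (`track_id`, `frame_index`,
#'   bbox columns).
#' @param truth Ground-truth tibble with columns `individual_id`,
#'   `frame_index`, `cx`, `cy` (one row per individual per frame present).
#' @return An object of class `tracking_evaluation` with elements `TP`,
#'   `FP`, `GT`, `TDR`, `FAR` and a per-individual tibble `individuals`.
#' @export
evaluate_tracking <- function(tracked, truth) {
  if (is.null(truth) || nrow(truth) == 0) stop("ground truth is empty")
  gt_ids <- unique(truth$individual_id)
  owners <- owner_table(tracked, truth)
  per_ind <- owners |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(
      n_tracks = dplyr::n_distinct(.data$track_id),
      main_track = modal_value(.data$track_id),
      n_frames_owned = dplyr::n(),
      .groups = "drop"
    )
  # majority individual of each track (over frames where it owns anyone)
  track_major <- owners |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(major_individual = modal_value(.data$individual_id),
                     .groups = "drop")
  per_ind <- per_ind |>
    dplyr::left_join(track_major, by = c(main_track = "track_id")) |>
    dplyr::mutate(
      tp = .data$n_tracks == 1 & .data$major_individual == .data$individual_id
    )
  missed <- setdiff(gt_ids, per_ind$individual_id)
  individuals <- dplyr::bind_rows(
    dplyr::select(per_ind, "individual_id", "n_tracks", "main_track", "tp"),
    tibble::tibble(individual_id = missed, n_tracks = 0L,
                   main_track = NA_integer_, tp = FALSE)
  )
  tp <- sum(individuals$tp)
  phantom <- setdiff(unique(tracked$track_id), unique(owners$track_id))
  fp <- sum(individuals$n_tracks > 0 & !individuals$tp) + length(phantom)
  gt <- length(gt_ids)
  structure(
    list(
      TP = tp, FP = fp, GT = gt,
      TDR = tdr(tp, gt),
      FAR = if (tp + fp >= 1) far(tp, fp) else 0,
      individuals = individuals,
      phantom_tracks = phantom
    ),
    class = "tracking_evaluation"
  )
}

# For every (individual, frame) of the truth, the track owning it: the
# individual's centroid must fall inside the track detection's bbox; ties go
# to the nearest track centroid.
owner_table <- function(tracked, truth) {
  joined <- dplyr::inner_join(
    truth,
    dplyr::select(tracked, "frame_index", "track_id",
                  tx_min = "x_min", ty_min = "y_min",
                  tw = "width", th = "height", tcx = "cx", tcy = "cy"),
    by = "frame_index", relationship = "many-to-many"
  ) |>
    dplyr::filter(
      .data$cx >= .data$tx_min, .data$cx < .data$tx_min + .data$tw,
      .data$cy >= .data$ty_min, .data$cy < .data$ty_min + .data$th
    ) |>
    dplyr::mutate(
      d2 = (.data$cx - .data$tcx)^2 + (.data$cy - .data$tcy)^2
    ) |>
    dplyr::group_by(.data$individual_id, .data$frame_index) |>
    dplyr::slice_min(.data$d2, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  dplyr::select(joined, "individual_id", "frame_index", "track_id")
}

modal_value <- function(x) {
  tab <- table(x)
  as_original_type <- names(tab)[which.max(tab)]
  if (is.numeric(x) || is.integer(x)) as.integer(as_original_type)
  else as_original_type
}

#' @export
print.tracking_evaluation <- function(x, ...) {
  cat(sprintf(
    "Tracking evaluation: GT %d, TP %d, FP %d  |  TDR %.2f, FAR %.2f\n",
    x$GT, x$TP, x$FP, round_half_up(x$TDR), round_half_up(x$FAR)
  ))
  invisible(x)
}

#' Tidy a tracking evaluation into per-individual rows
#'
#' @param x A `tracking_evaluation`.
#' @param ... Unused.
#' @return A tibble with one row per ground-truth individual.
#' @export
tidy.tracking_evaluation <- function(x, ...) x$individuals

#' One-row summary of a tracking evaluation
#'
#' @param x A `tracking_evaluation`.
#' @param ... Unused.
#' @return A tibble with `GT`, `TP`, `FP`, `TDR`, `FAR`.
#' @export
glance.tracking_evaluation <- function(x, ...) {
  tibble::tibble(GT = x$GT, TP = x$TP, FP = x$FP, TDR = x$TDR, FAR = x$FAR)
}

#' Read / write tracking ground truth
#'
#' Schema: `individual_id`, `frame_index`, `cx`, `cy`, optional `species`
#' and bbox columns.
#'
#' @param truth Ground-truth tibble.
#' @param path CSV path.
#' @return `write_ground_truth()` returns `path` invisibly;
#'   `read_ground_truth()` the tibble.
#' @export
write_ground_truth <- function(truth, path) {
  readr::write_csv(truth, path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(frame_index = readr::col_integer()))
}
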