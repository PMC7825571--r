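# Synthetic trap scenes: near-white noisy sheet, dark textured insects that
# mostly sit still, with known per-frame ground truth. Used to validate the
# whole pipeline end to end without any field imagery.

#' Scene generator configuration
#'
#' Emulates the trap's imaging situation: insects rest on a uniformly lit
#' near-white sheet, stay mostly stationary between captures, occasionally
#' reposition, and sporadic out-of-focus insects pass close to the lens.
#'
#' @param width,height Frame size in pixels (default 1920x1080; the camera's
#'   native 3840x2160 is supported but slower).
#' @param n_frames Number of frames in the sequence.
#' @param n_insects Number of resting insects.
#' @param stationary_prob Per-frame probability that an insect does not
#'   reposition (default 0.9; between captures individuals mostly sit still).
#' @param jitter_sd Standard deviation (px) of the small per-frame position
#'   jitter applied even when stationary.
#' @param jump_prob Per-frame probability of a larger repositioning move.
#' @param jump_dist Distance (px) of a repositioning move.
#' @param bbox_mean,bbox_sd Mean (width, height) and standard deviation (px)
#'   of the insect bounding-box size distribution (defaults 368x353, sd 110).
#' @param bbox_min Lower truncation (px) of sampled box sides.
#' @param background Sheet intensity in \[0, 1\] (default 0.92).
#' @param noise_sd Gaussian sensor-noise standard deviation.
#' @param transient_rate Per-frame probability that a large near-lens
#'   transient blob appears (lasting `transient_frames` frames).
#' @param transient_frames Duration of a transient in frames (default 2).
#' @param touching_pair Place two insects touching each other, to exercise
#'   the known blob-merging failure mode (default `FALSE`).
#' @param entry_frame,exit_frame Optional integer vectors (length
#'   `n_insects`) giving each insect's first and last frame; default full
#'   presence.
#' @param seed Integer seed; the whole scene is a pure function of the
#'   configuration including this seed.
#'
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(width = 1920, height = 1080, n_frames = 50,
                         n_insects = 5, stationary_prob = 0.9,
                         jitter_sd = 2, jump_prob = 0.05, jump_dist = 150,
                         bbox_mean = c(368, 353), bbox_sd = 110,
                         bbox_min = 80, background = 0.92, noise_sd = 0.01,
                         transient_rate = 0, transient_frames = 2,
                         touching_pair = FALSE,
                         entry_frame = NULL, exit_frame = NULL, seed = 1) {
  stopifnot(
    width >= 64, height >= 64, n_frames >= 1, n_insects >= 0,
    stationary_prob >= 0, stationary_prob <= 1,
    jump_prob >= 0, jump_prob <= 1,
    transient_rate >= 0, transient_rate <= 1,
    bbox_sd >= 0, bbox_min > 0, noise_sd >= 0
  )
  structure(
    list(
      width = as.integer(width), height = as.integer(height),
      n_frames = as.integer(n_frames), n_insects = as.integer(n_insects),
      stationary_prob = stationary_prob, jitter_sd = jitter_sd,
      jump_prob = jump_prob, jump_dist = jump_dist,
      bbox_mean = bbox_mean, bbox_sd = bbox_sd, bbox_min = bbox_min,
      background = background, noise_sd = noise_sd,
      transient_rate = transient_rate,
      transient_frames = as.integer(transient_frames),
      touching_pair = touching_pair,
      entry_frame = entry_frame, exit_frame = exit_frame,
      seed = as.integer(seed)
    ),
    class = "scene_config"
  )
}

# Species-specific procedural appearance: a distinct RGB tint plus a striped
# pattern whose frequency and orientation depend on the class. Classes are
# separable by construction (mean color already separates them linearly).
# Tint * pattern stays well below the sheet intensity so every insect pixel
# remains dark in the foreground image, as a moth on a lit sheet does.
species_palette <- function() {
  rbind(
    c(0.50, 0.27, 0.13), c(0.18, 0.18, 0.42), c(0.42, 0.42, 0.13),
    c(0.13, 0.37, 0.18), c(0.50, 0.45, 0.32), c(0.42, 0.18, 0.37),
    c(0.23, 0.23, 0.23), c(0.46, 0.13, 0.13), c(0.18, 0.42, 0.42)
  )
}

# Pattern value in [0.7, 1.3] multiplying the class tint; u, v in [-1, 1].
species_pattern <- function(class_id, u, v) {
  freq <- 2 + (class_id %% 5)
  theta <- class_id * pi / 4.5
  w <- u * cos(theta) + v * sin(theta)
  s <- sin(2 * pi * freq * w)
  if (class_id %% 2 == 0) {
    s <- s * sin(2 * pi * freq * (-u * sin(theta) + v * cos(theta)))
  }
  1 + 0.3 * s
}

sample_bbox_dims <- function(n, config) {
  w <- pmax(config$bbox_min, rnorm(n, config$bbox_mean[1], config$bbox_sd))
  h <- pmax(config$bbox_min, rnorm(n, config$bbox_mean[2], config$bbox_sd))
  cbind(w, h)
}

#' Generate a synthetic trap scene with ground truth
#'
#' Renders a deterministic frame sequence (RGB, values in \[0, 1\]) of dark
#' textured elliptical insects on a bright noisy sheet and returns the exact
#' per-frame ground truth of every individual. Near-lens transients, when
#' enabled, are rendered but listed separately from the individuals.
#'
#' @param config A [scene_config()].
#' @param dir Optional directory: frames are written as numbered image files
#'   and referenced by path instead of being kept in memory (recommended for
#'   long full-resolution sequences).
#' @param format Image format for written frames: `"jpg"` (default; what the
#'   trap's capture software records) or `"png"` (lossless).
#' @return An object of class `mcc_scene`: a list with `frames` (list of
#'   arrays, or character paths when `dir` is used), `truth` (tibble:
#'   `individual_id`, `frame_index`, `species`, `cx`, `cy`, `x_min`,
#'   `y_min`, `width`, `height`), `transients` (same schema, `individual_id`
#'   negative), and `config`.
#' @export
generate_scene <- function(config = scene_config(), dir = NULL,
                           format = c("jpg", "png")) {
  format <- match.arg(format)
  plan <- withr::with_seed(config$seed, plan_scene(config))
  render <- function(i) render_scene_frame(config, plan, i)
  frames <- if (is.null(dir)) {
    lapply(seq_len(config$n_frames), render)
  } else {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    vapply(seq_len(config$n_frames), function(i) {
      path <- file.path(dir, sprintf("frame_%04d.%s", i, format))
      EBImage::writeImage(
        EBImage::Image(render(i), colormode = "Color"), path, quality = 95
      )
      path
    }, character(1))
  }
  structure(
    list(frames = frames, truth = plan$truth, transients = plan$transients,
         config = config, background = config$background),
    class = "mcc_scene"
  )
}

#' Background reference frame for a generated scene
#'
#' The empty sheet as the trap's background image: same deterministic sensor
#' noise field, no insects.
#'
#' @param scene An `mcc_scene`.
#' @return An RGB array matching the scene frames.
#' @export
scene_background <- function(scene) {
  cfg <- scene$config
  noise <- withr::with_seed(cfg$seed + 1L, scene_noise(cfg))
  sheet_array(cfg, noise)
}

plan_scene <- function(config) {
  n <- config$n_insects
  dims <- sample_bbox_dims(max(n, 1), config)[seq_len(n), , drop = FALSE]
  species_id <- if (n > 0) sample(1:9, n, replace = TRUE) else integer()
  entry <- config$entry_frame %||% rep(1L, n)
  exit <- config$exit_frame %||% rep(config$n_frames, n)
  stopifnot(length(entry) == n, length(exit) == n)
  margin_x <- if (n > 0) dims[, 1] / 2 + 10 else numeric()
  margin_y <- if (n > 0) dims[, 2] / 2 + 10 else numeric()
  pos <- place_separated(n, config, dims)
  orient <- runif(max(n, 1))[seq_len(n)] * 2 * pi

  if (config$touching_pair && n >= 2) {
    # put insect 2 flush against insect 1
    pos[2, ] <- pos[1, ] + c((dims[1, 1] + dims[2, 1]) / 2 - 10, 0)
    pos[2, 1] <- min(max(pos[2, 1], margin_x[2]), config$width - margin_x[2])
  }

  truth <- vector("list", config$n_frames)
  cur <- pos
  for (f in seq_len(config$n_frames)) {
    if (n > 0) {
      for (k in seq_len(n)) {
        move <- runif(1)
        if (move > config$stationary_prob) {
          if (runif(1) < config$jump_prob / (1 - config$stationary_prob)) {
            cur[k, ] <- jump_position(cur[k, ], k, cur, dims, config)
          } else {
            cur[k, ] <- cur[k, ] + rnorm(2, 0, config$jitter_sd)
          }
        } else {
          cur[k, ] <- cur[k, ] + rnorm(2, 0, config$jitter_sd / 4)
        }
        cur[k, 1] <- min(max(cur[k, 1], margin_x[k]), config$width - margin_x[k])
        cur[k, 2] <- min(max(cur[k, 2], margin_y[k]), config$height - margin_y[k])
      }
      present <- which(entry <= f & exit >= f)
      truth[[f]] <- tibble::tibble(
        individual_id = present,
        frame_index = f,
        species = moth_classes()[species_id[present]],
        cx = cur[present, 1], cy = cur[present, 2],
        width = dims[present, 1], height = dims[present, 2]
      )
    } else {
      truth[[f]] <- NULL
    }
  }
  truth <- dplyr::bind_rows(truth)
  if (nrow(truth)) {
    truth <- dplyr::mutate(
      truth,
      x_min = .data$cx - .data$width / 2,
      y_min = .data$cy - .data$height / 2,
      .before = "width"
    )
  } else {
    truth <- tibble::tibble(
      individual_id = integer(), frame_index = integer(),
      species = character(), cx = numeric(), cy = numeric(),
      x_min = numeric(), y_min = numeric(), width = numeric(),
      height = numeric()
    )
  }

  transients <- plan_transients(config, truth)
  list(
    truth = truth, transients = transients,
    species_id = species_id, dims = dims, orient = orient,
    noise = withr::with_seed(config$seed + 1L, scene_noise(config))
  )
}

# Static per-scene sensor noise field (the sheet and lighting are fixed, so
# the dominant frame-to-frame change is the insects, as on the real trap).
scene_noise <- function(config) {
  matrix(rnorm(config$width * config$height, 0, config$noise_sd),
         config$width, config$height)
}

# Two insects are well separated when their bounding boxes are at least
# `gap` pixels apart along some axis — enough that the morphological close
# cannot bridge their blobs and the tracker's nearest match is unambiguous.
boxes_separated <- function(p1, d1, p2, d2, gap = 40) {
  abs(p1[1] - p2[1]) > (d1[1] + d2[1]) / 2 + gap ||
    abs(p1[2] - p2[2]) > (d1[2] + d2[2]) / 2 + gap
}

place_separated <- function(n, config, dims) {
  if (n == 0) return(matrix(numeric(), 0, 2))
  if (any(dims[, 1] + 30 > config$width) || any(dims[, 2] + 30 > config$height)) {
    stop("insects of the configured size cannot fit the frame")
  }
  # Greedy sequential placement can dead-end, so place the largest insects
  # first and restart the whole configuration on failure.
  order_big <- order(-apply(dims, 1, max))
  for (attempt in 1:60) {
    pos <- matrix(NA_real_, n, 2)
    done <- TRUE
    for (k in order_big) {
      placed <- FALSE
      prior <- order_big[seq_len(match(k, order_big) - 1)]
      for (try in 1:100) {
        cand <- c(
          runif(1, dims[k, 1] / 2 + 15, config$width - dims[k, 1] / 2 - 15),
          runif(1, dims[k, 2] / 2 + 15, config$height - dims[k, 2] / 2 - 15)
        )
        ok <- all(vapply(prior, function(j) {
          boxes_separated(cand, dims[k, ], pos[j, ], dims[j, ])
        }, logical(1)))
        if (ok) {
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        done <- FALSE
        break
      }
      pos[k, ] <- cand
    }
    if (done) return(pos)
  }
  stop("could not place ", n, " insects without overlap; ",
       "frame too small for the configured sizes")
}

# Repositioning move that lands on free sheet (insects do not settle on top
# of each other); falls back to staying put if no free spot is found.
jump_position <- function(p, k, cur, dims, config) {
  others <- setdiff(seq_len(nrow(cur)), k)
  for (try in 1:20) {
    ang <- runif(1, 0, 2 * pi)
    cand <- p + config$jump_dist * c(cos(ang), sin(ang))
    cand[1] <- min(max(cand[1], dims[k, 1] / 2 + 15),
                   config$width - dims[k, 1] / 2 - 15)
    cand[2] <- min(max(cand[2], dims[k, 2] / 2 + 15),
                   config$height - dims[k, 2] / 2 - 15)
    if (length(others) == 0) return(cand)
    ok <- all(vapply(others, function(j) {
      boxes_separated(cand, dims[k, ], cur[j, ], dims[j, ])
    }, logical(1)))
    if (ok) return(cand)
  }
  p
}

# Transients appear over free sheet: an out-of-focus blur on top of a
# resting insect would make the ground truth ambiguous.
plan_transients <- function(config, truth) {
  out <- list()
  f <- 1L
  id <- 0L
  while (f <= config$n_frames) {
    if (runif(1) < config$transient_rate) {
      span <- f:min(f + config$transient_frames - 1L, config$n_frames)
      r <- runif(1, 150, 300)
      present <- dplyr::filter(truth, .data$frame_index %in% span)
      pos <- NULL
      for (try in 1:200) {
        if (try %% 50 == 0) r <- r * 0.8  # shrink if space is tight
        cand <- c(runif(1, r, config$width - r),
                  runif(1, r, config$height - r))
        if (nrow(present) == 0) { pos <- cand; break }
        d <- sqrt((present$cx - cand[1])^2 + (present$cy - cand[2])^2)
        if (all(d > r + pmax(present$width, present$height) / 2 + 40)) {
          pos <- cand
          break
        }
      }
      if (!is.null(pos)) {   # no free sheet -> no transient this time
        id <- id - 1L
        out[[length(out) + 1]] <- tibble::tibble(
          individual_id = id, frame_index = as.integer(span),
          species = "transient",
          cx = pos[1], cy = pos[2],
          x_min = pos[1] - r, y_min = pos[2] - r,
          width = 2 * r, height = 2 * r
        )
      }
      f <- f + config$transient_frames
    }
    f <- f + 1L
  }
  if (length(out)) dplyr::bind_rows(out) else tibble::tibble(
    individual_id = integer(), frame_index = integer(), species = character(),
    cx = numeric(), cy = numeric(), x_min = numeric(), y_min = numeric(),
    width = numeric(), height = numeric()
  )
}

sheet_array <- function(config, noise) {
  base <- clamp01(config$background + noise)
  array(c(base, base, 0.985 * base), c(config$width, config$height, 3))
}

render_scene_frame <- function(config, plan, f) {
  frame <- sheet_array(config, plan$noise)
  rows <- dplyr::filter(plan$truth, .data$frame_index == f)
  for (r in seq_len(nrow(rows))) {
    frame <- stamp_insect(
      frame, rows$cx[r], rows$cy[r], rows$width[r], rows$height[r],
      match(rows$species[r], moth_classes()),
      plan$orient[rows$individual_id[r]]
    )
  }
  tr <- dplyr::filter(plan$transients, .data$frame_index == f)
  for (r in seq_len(nrow(tr))) {
    frame <- stamp_transient(frame, tr$cx[r], tr$cy[r], tr$width[r] / 2)
  }
  frame
}

stamp_insect <- function(frame, cx, cy, w, h, class_id, orient) {
  nx <- dim(frame)[1]; ny <- dim(frame)[2]
  xs <- max(1, floor(cx - w / 2)):min(nx, ceiling(cx + w / 2))
  ys <- max(1, floor(cy - h / 2)):min(ny, ceiling(cy + h / 2))
  u <- (xs - cx) / (w / 2)
  v <- (ys - cy) / (h / 2)
  uu <- matrix(u, length(u), length(v))
  vv <- matrix(v, length(u), length(v), byrow = TRUE)
  inside <- uu^2 + vv^2 <= 1
  if (!any(inside)) return(frame)
  ur <- uu * cos(orient) + vv * sin(orient)
  vr <- -uu * sin(orient) + vv * cos(orient)
  pat <- species_pattern(class_id, ur, vr)
  tint <- species_palette()[class_id, ]
  for (ch in 1:3) {
    block <- frame[xs, ys, ch]
    block[inside] <- clamp01((pat * tint[ch])[inside])
    frame[xs, ys, ch] <- block
  }
  frame
}

# Out-of-focus insect close to the lens: big, dark, soft-edged.
stamp_transient <- function(frame, cx, cy, r) {
  nx <- dim(frame)[1]; ny <- dim(frame)[2]
  xs <- max(1, floor(cx - r)):min(nx, ceiling(cx + r))
  ys <- max(1, floor(cy - r)):min(ny, ceiling(cy + r))
  dd <- outer((xs - cx)^2, (ys - cy)^2, `+`) / r^2
  shade <- pmax(0, 1 - dd)          # 1 at center -> 0 at radius
  for (ch in 1:3) {
    block <- frame[xs, ys, ch]
    frame[xs, ys, ch] <- block * (1 - 0.75 * shade)
  }
  frame
}

#' Ground truth in the evaluation schema
#'
#' @param scene An `mcc_scene`.
#' @param include_transients Include near-lens transients (default `FALSE`:
#'   they are not ground-truth individuals).
#' @return A tibble usable as `truth` in [evaluate_tracking()].
#' @export
scene_truth <- function(scene, include_transients = FALSE) {
  if (include_transients) {
    dplyr::bind_rows(scene$truth, scene$transients)
  } else {
    scene$truth
  }
}

#' Generate a labeled synthetic crop dataset
#'
#' Class-distinct procedural textures on a bright noisy background, in the
#' classifier's input format. The first nine classes are textured ellipses
#' (the synthetic stand-ins for the insect classes); the tenth is plain
#' background. Classes are separable by construction — even mean color alone
#' separates them — so a correct training procedure must reach a high
#' validation score.
#'
#' @param n_classes Number of classes (2 to 10; 10 adds the background
#'   class).
#' @param n_per_class Crops per class.
#' @param seed Integer seed.
#' @param size Crop side in pixels (default 128, the classifier input size).
#' @return A crop tibble ([crop_dataset()] schema) with
#'   `n_classes * n_per_class` rows.
#' @export
#' @examples
#' crops <- generate_crop_dataset(n_classes = 2, n_per_class = 3, seed = 1, size = 32)
generate_crop_dataset <- function(n_classes = 10, n_per_class = 100,
                                  seed = 1, size = 128) {
  stopifnot(n_classes >= 2, n_classes <= 10, n_per_class >= 1, size >= 16)
  classes <- moth_classes()[seq_len(n_classes)]
  if (n_classes == 10) classes[10] <- "background"
  withr::with_seed(seed, {
    images <- vector("list", n_classes * n_per_class)
    labels <- character(n_classes * n_per_class)
    i <- 0L
    for (k in seq_len(n_classes)) {
      for (j in seq_len(n_per_class)) {
        i <- i + 1L
        labels[i] <- classes[k]
        images[[i]] <- as_crop_raw(render_crop(
          if (classes[k] == "background") 0L else k, size
        ))
      }
    }
    crop_dataset(images, factor(labels, levels = classes), size = size)
  })
}

render_crop <- function(class_id, size) {
  base <- clamp01(0.92 + matrix(rnorm(size * size, 0, 0.015), size, size))
  arr <- array(c(base, base, 0.985 * base), c(size, size, 3))
  if (class_id == 0L) return(arr)   # background crop: just sheet
  cx <- size / 2 + runif(1, -size * 0.06, size * 0.06)
  cy <- size / 2 + runif(1, -size * 0.06, size * 0.06)
  w <- size * runif(1, 0.55, 0.8)
  h <- size * runif(1, 0.5, 0.75)
  stamp_insect(arr, cx, cy, w, h, class_id, runif(1, 0, 2 * pi))
}

#' Plot the planned trajectories of a scene
#'
#' @param object An `mcc_scene`.
#' @param ... Unused.
#' @return A ggplot of per-individual trajectories, colored by species.
#' @export
autoplot.mcc_scene <- function(object, ...) {
  ggplot2::ggplot(
    object$truth,
    ggplot2::aes(.data$cx, .data$cy, color = .data$species,
                 group = .data$individual_id)
  ) +
    ggplot2::geom_path(alpha = 0.6) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(
      xlim = c(0, object$config$width), ylim = c(object$config$height, 0)
    ) +
    ggplot2::labs(
      title = "Synthetic scene ground truth",
      x = "x (px)", y = "y (px)", color = "species"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
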