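# Independent oracles and small geometric fixtures used across the suite.

# All permutations of 1..n as a matrix (one permutation per row).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, ifelse(sub >= i, sub + 1L, sub))
  }))
}

# Brute-force minimum-cost perfect matching by enumerating all permutations
# (flat-index vectorization keeps 7! x 7 enumeration fast).
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  pm <- all_permutations(n)
  idx <- sweep((pm - 1L) * n, 2L, seq_len(n), `+`)
  min(rowSums(matrix(cost[as.vector(idx)], nrow(pm))))
}

# Exhaustive-sweep Otsu oracle: for every candidate 8-bit threshold compute
# the two class weights/means directly from the raw pixel values and return
# the (lowest) threshold maximizing the between-class variance.
otsu_sweep_oracle <- function(gray, levels = 256L) {
  q <- pmin(pmax(round(as.vector(gray) * (levels - 1)), 0), levels - 1)
  if (min(q) == max(q)) return(NA_real_)
  best <- -Inf
  best_t <- NA_integer_
  for (t in 0:(levels - 2)) {
    lo <- q[q <= t]
    hi <- q[q > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(q)
    sb <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (sb > best + 1e-12) {
      best <- sb
      best_t <- t
    }
  }
  best_t / (levels - 1)
}

# Binary raster with a filled disk (x-by-y orientation, 1-based center).
disk_raster <- function(nx, ny, cx, cy, r) {
  xs <- matrix(seq_len(nx), nx, ny)
  ys <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  ((xs - cx)^2 + (ys - cy)^2 <= r^2) * 1
}

# Single-row detection tibble from centroid and bbox size (0-based bbox).
make_detection <- function(cx, cy, w, h, frame_index = 1L) {
  tibble::tibble(
    frame_index = as.integer(frame_index),
    x_min = cx - w / 2, y_min = cy - h / 2,
    width = w, height = h, cx = cx, cy = cy, area = w * h
  )
}

# Small-frame scene configuration used by image-level tests (smaller insects
# and frames keep segmentation fast; geometry is otherwise the same).
small_scene_config <- function(...) {
  scene_config(
    width = 480, height = 360, bbox_mean = c(60, 56), bbox_sd = 8,
    bbox_min = 30, ...
  )
}

small_seg_config <- function(...) {
  seg_config(min_blob_area = 300, open_kernel = 3, close_kernel = 5, ...)
}
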