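test_that("distance, diagonal and area terms evaluate exactly", {
  expect_equal(centroid_dist(c(0, 0), c(3, 4)), 5)
  expect_equal(centroid_dist(c(7, 7), c(7, 7)), 0)
  expect_equal(centroid_dist(c(100, 200), c(400, 600)), 500)

  expect_equal(max_dist(3, 4), 5)
  expect_equal(max_dist(2160, 3840), sqrt(2160^2 + 3840^2))
  expect_gt(max_dist(2161, 3840), max_dist(2160, 3840))
  expect_error(max_dist(0, 100), "positive")

  expect_equal(area_cost(100, 100), 1)
  expect_equal(area_cost(50, 100), 0.5)
  expect_equal(area_cost(100, 50), 0.5)
  expect_error(area_cost(0, 10), "positive")
})

test_that("pair cost combines normalized distance and area dissimilarity", {
  p <- cost_params(wdist = 0.8, warea = 0.2)
  d1 <- make_detection(100, 100, 50, 40)
  expect_equal(pair_cost(d1, d1, p, 1080, 1920), 0)

  # maximal displacement, equal areas -> the full distance weight
  h <- 300; w <- 400   # diagonal 500
  a <- make_detection(0, 0, 20, 20)
  b <- make_detection(400, 300, 20, 20)
  expect_equal(pair_cost(a, b, p, h, w), 0.8)

  # no displacement, area ratio 1/2 -> half the area weight
  c1 <- make_detection(50, 50, 20, 20)
  c2 <- make_detection(50, 50, 40, 20)
  expect_equal(pair_cost(c1, c2, p, h, w), 0.1)
})

test_that("pair cost is symmetric and bounded by wdist + warea", {
  p <- cost_params(0.8, 0.2)
  withr::with_seed(31, {
    for (i in 1:25) {
      a <- make_detection(runif(1, 0, 1920), runif(1, 0, 1080),
                          runif(1, 10, 400), runif(1, 10, 400))
      b <- make_detection(runif(1, 0, 1920), runif(1, 0, 1080),
                          runif(1, 10, 400), runif(1, 10, 400))
      cab <- pair_cost(a, b, p, 1080, 1920)
      expect_equal(cab, pair_cost(b, a, p, 1080, 1920))
      expect_gte(cab, 0)
      expect_lte(cab, 1)
    }
  })
})

test_that("cost matrix is padded square with dummy rows/columns", {
  p <- cost_params(0.8, 0.2)
  prev <- dplyr::bind_rows(make_detection(100, 100, 30, 30),
                           make_detection(500, 500, 30, 30))
  curr <- dplyr::bind_rows(make_detection(102, 100, 30, 30),
                           make_detection(500, 502, 30, 30),
                           make_detection(900, 300, 30, 30))
  m <- build_cost_matrix(prev, curr, p, 1080, 1920)
  expect_equal(dim(m), c(3, 3))
  expect_equal(m[3, ], rep(p$dummy_cost, 3))     # one dummy row
  expect_true(all(is.finite(m)) && all(m <= p$dummy_cost))

  single <- build_cost_matrix(make_detection(10, 10, 5, 5),
                              make_detection(10, 10, 5, 5), p, 100, 100)
  expect_equal(unclass(single)[1, 1], 0, ignore_attr = TRUE)
})

test_that("assignment solver minimizes total cost and reports entries/exits", {
  res <- solve_assignment(matrix(c(1, 2, 2, 4), 2, byrow = TRUE))
  expect_equal(res$total_cost, 4)
  expect_equal(dplyr::arrange(res$matches, prev)$curr, c(2, 1))

  z <- solve_assignment(matrix(0, 3, 3))
  expect_equal(z$total_cost, 0)
  expect_equal(nrow(z$matches), 3)

  # dummy-padded rectangle: the far current detection goes to the dummy row
  p <- cost_params(0.8, 0.2)
  prev <- make_detection(100, 100, 30, 30)
  curr <- dplyr::bind_rows(make_detection(101, 100, 30, 30),
                           make_detection(1800, 1000, 30, 30))
  res <- solve_assignment(build_cost_matrix(prev, curr, p, 1080, 1920))
  expect_equal(res$matches, tibble::tibble(prev = 1L, curr = 1L))
  expect_equal(res$entered, 2L)
  expect_equal(res$exited, integer(0))

  expect_error(solve_assignment(matrix(1, 2, 3)), "square")
})

test_that("assignment equals the brute-force permutation oracle", {
  withr::with_seed(41, {
    for (i in 1:60) {
      n <- sample(2:6, 1)
      m <- matrix(runif(n * n), n)
      res <- solve_assignment(m)
      expect_equal(res$total_cost, brute_force_assignment(m),
                   tolerance = 1e-12, info = paste("matrix", i))
    }
  })
})

test_that("step_tracks preserves, opens and closes identities", {
  p <- cost_params(0.8, 0.2)
  dets <- dplyr::bind_rows(make_detection(100, 100, 40, 40),
                           make_detection(700, 500, 40, 40))
  first <- step_tracks(dplyr::mutate(dets[0, ], track_id = integer()),
                       dets, p, 1080, 1920, next_id = 1L)
  expect_equal(first$assigned$track_id, c(1L, 2L))

  # identical detections keep their IDs, nothing opens or closes
  again <- step_tracks(first$assigned,
                       dplyr::mutate(dets, frame_index = 2L), p, 1080, 1920,
                       next_id = first$next_id)
  expect_equal(again$assigned$track_id, c(1L, 2L))
  expect_equal(again$closed_ids, integer(0))

  # a new far detection opens exactly one fresh track
  curr <- dplyr::bind_rows(dplyr::mutate(dets, frame_index = 2L),
                           make_detection(1500, 200, 40, 40, 2))
  st <- step_tracks(first$assigned, curr, p, 1080, 1920, first$next_id)
  expect_equal(sort(st$assigned$track_id), c(1L, 2L, 3L))
  expect_equal(st$next_id, 4L)

  # a vanished detection closes its track
  st2 <- step_tracks(first$assigned, dets[1, ], p, 1080, 1920, 3L)
  expect_equal(st2$assigned$track_id, 1L)
  expect_equal(st2$closed_ids, 2L)
})

test_that("stationary insects keep one track each across a sequence", {
  withr::with_seed(51, {
    k <- 4
    base <- dplyr::bind_rows(lapply(seq_len(k), function(i) {
      make_detection(200 + 400 * ((i - 1) %% 3), 250 + 400 * ((i - 1) %/% 3),
                     60, 55)
    }))
    frames <- dplyr::bind_rows(lapply(1:20, function(f) {
      dplyr::mutate(base,
                    frame_index = as.integer(f),
                    cx = cx + rnorm(k, 0, 2), cy = cy + rnorm(k, 0, 2))
    }))
    tracked <- track_detections(frames, cost_params(), height = 1080,
                                width = 1920)
    expect_equal(dplyr::n_distinct(tracked$track_id), k)
    # no frame assigns one ID twice
    dup <- tracked |>
      dplyr::count(frame_index, track_id) |>
      dplyr::filter(n > 1)
    expect_equal(nrow(dup), 0)
  })
})

test_that("tracks round-trip through CSV", {
  tr <- dplyr::mutate(make_detection(10, 10, 5, 5), track_id = 1L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks(tr, path)
  expect_equal(as.data.frame(read_tracks(path)), as.data.frame(tr))
})
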