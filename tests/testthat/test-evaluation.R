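test_that("tracking rates follow their defining ratios", {
  expect_equal(round_half_up(tdr(65, 82)), 0.79)
  expect_equal(tdr(0, 82), 0)
  expect_equal(tdr(82, 82), 1)
  expect_error(tdr(5, 0), "GT")

  expect_equal(round_half_up(far(65, 18)), 0.22)
  expect_equal(far(10, 0), 0)
  expect_equal(far(0, 5), 1)
  expect_error(far(0, 0), "TP \\+ FP")

  # scale invariance
  expect_equal(tdr(65, 82), tdr(650, 820))
  expect_equal(far(65, 18), far(650, 180))
})

test_that("class metrics reproduce their formulas and edge conventions", {
  m <- class_metrics(24, 6, 8)
  expect_equal(round_half_up(c(m$precision, m$recall, m$f1)),
               c(0.80, 0.75, 0.77))

  z <- class_metrics(0, 0, 5)
  expect_equal(z$recall, 0)
  expect_true(is.na(z$precision))
  expect_error(class_metrics(0, 0, 0), "positive")

  # F1 equals the harmonic mean of precision and recall when both defined
  withr::with_seed(61, {
    for (i in 1:20) {
      tp <- sample(1:200, 1); fp <- sample(0:100, 1); fn <- sample(0:100, 1)
      m <- class_metrics(tp, fp, fn)
      expect_equal(m$f1,
                   2 * m$precision * m$recall / (m$precision + m$recall))
      m10 <- class_metrics(10 * tp, 10 * fp, 10 * fn)
      expect_equal(m10$f1, m$f1)
    }
  })
})

test_that("perfect synthetic tracking scores TDR 1, FAR 0", {
  truth <- dplyr::bind_rows(lapply(1:3, function(id) {
    tibble::tibble(individual_id = id, frame_index = 1:5,
                   cx = 100 * id, cy = 100 * id)
  }))
  tracked <- dplyr::bind_rows(lapply(1:3, function(id) {
    dplyr::mutate(
      dplyr::bind_rows(lapply(1:5, function(f) {
        make_detection(100 * id, 100 * id, 40, 40, f)
      })),
      track_id = id * 10L
    )
  }))
  ev <- evaluate_tracking(tracked, truth)
  expect_equal(ev$TP, 3)
  expect_equal(ev$FP, 0)
  expect_equal(ev$TDR, 1)
  expect_equal(ev$FAR, 0)
  expect_equal(nrow(tidy(ev)), 3)
  expect_equal(glance(ev)$GT, 3)
})

test_that("a split individual contributes one FP and no TP", {
  truth <- tibble::tibble(individual_id = 1L, frame_index = 1:6,
                          cx = 100, cy = 100)
  tracked <- dplyr::mutate(
    dplyr::bind_rows(lapply(1:6, function(f) make_detection(100, 100, 40, 40, f))),
    track_id = rep(c(1L, 2L), each = 3)   # identity reassigned mid-sequence
  )
  ev <- evaluate_tracking(tracked, truth)
  expect_equal(ev$TP, 0)
  expect_equal(ev$FP, 1)
  expect_equal(ev$TDR, 0)
  expect_equal(ev$FAR, 1)
})

test_that("an identity swap between two individuals reduces TDR", {
  truth <- dplyr::bind_rows(
    tibble::tibble(individual_id = 1L, frame_index = 1:6, cx = 100, cy = 100),
    tibble::tibble(individual_id = 2L, frame_index = 1:6, cx = 500, cy = 500)
  )
  pos <- function(id, f) if ((f <= 3) == (id == 1)) c(100, 100) else c(500, 500)
  tracked <- dplyr::bind_rows(lapply(1:2, function(id) {
    dplyr::mutate(
      dplyr::bind_rows(lapply(1:6, function(f) {
        p <- pos(id, f)
        make_detection(p[1], p[2], 40, 40, f)
      })),
      track_id = as.integer(id)
    )
  }))
  ev <- evaluate_tracking(tracked, truth)
  expect_equal(ev$TP, 0)
  expect_equal(ev$GT, 2)
  expect_lt(ev$TDR, 1)
})

test_that("phantom tracks matching no individual count as false alarms", {
  truth <- tibble::tibble(individual_id = 1L, frame_index = 1:4,
                          cx = 100, cy = 100)
  tracked <- dplyr::bind_rows(
    dplyr::mutate(dplyr::bind_rows(lapply(1:4, function(f) {
      make_detection(100, 100, 40, 40, f)
    })), track_id = 1L),
    dplyr::mutate(dplyr::bind_rows(lapply(1:2, function(f) {
      make_detection(900, 900, 200, 200, f)
    })), track_id = 2L)
  )
  ev <- evaluate_tracking(tracked, truth)
  expect_equal(ev$TP, 1)
  expect_equal(ev$FP, 1)
  expect_equal(ev$phantom_tracks, 2L)

  expect_error(evaluate_tracking(tracked, truth[0, ]), "empty")
})

test_that("ground truth round-trips through CSV", {
  truth <- tibble::tibble(individual_id = 1:2, frame_index = c(1L, 1L),
                          cx = c(10, 20), cy = c(30, 40),
                          species = c("a", "b"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth(truth, path)
  expect_equal(as.data.frame(read_ground_truth(path)), as.data.frame(truth))
})
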