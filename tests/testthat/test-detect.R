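test_that("fit_ellipse matches closed-form moments for rectangles and disks", {
  for (dims in list(c(21, 9), c(35, 15), c(15, 15))) {
    px <- expand.grid(x = seq_len(dims[1]) - 1, y = seq_len(dims[2]) - 1)
    fit <- fit_ellipse(px)
    want <- oracle_rect_axes(dims[1], dims[2])
    expect_equal(fit$major_axis, unname(want["major"]), tolerance = 0.02)
    expect_equal(fit$minor_axis, unname(want["minor"]), tolerance = 0.02)
    expect_equal(fit$centroid_x, (dims[1] - 1) / 2)
    expect_equal(fit$centroid_y, (dims[2] - 1) / 2)
  }
  for (r in c(8, 12, 20)) {
    g <- expand.grid(x = -r:r, y = -r:r)
    px <- g[g$x^2 + g$y^2 <= r^2, ]
    fit <- fit_ellipse(px)
    want <- oracle_disk_axes(r)
    expect_equal(fit$major_axis, unname(want["major"]), tolerance = 0.02)
    expect_equal(fit$minor_axis, unname(want["minor"]), tolerance = 0.02)
  }
})

test_that("fit_ellipse handles degenerate pixel sets with a 1 px floor", {
  one <- fit_ellipse(cbind(5, 7))
  expect_equal(one$centroid_x, 5)
  expect_equal(one$centroid_y, 7)
  expect_equal(one$major_axis, 1)
  expect_equal(one$minor_axis, 1)

  line <- fit_ellipse(cbind(0:9, 0))  # collinear
  expect_equal(line$minor_axis, 1)
  expect_gt(line$major_axis, 1)
  expect_equal(line$orientation, 0)
  expect_error(fit_ellipse(cbind(numeric(0), numeric(0))), "non-empty")
})

test_that("orientation is reported modulo pi and recovers the rendered pose", {
  ar <- arena_spec(200, 200, food_radius = 30)
  for (theta in c(0.3, 1.2, 2.6)) {
    img <- matrix(0.9, 200, 200)
    px <- socialfly:::ellipse_pixels(100, 100, 20, 6, theta, 200, 200)
    img[px] <- 0.1
    det <- detect_flies(img, threshold = 0.5, expected_body_area_px = pi * 40 * 12 / 4)
    expect_equal(nrow(det), 1)
    expect_gte(det$orientation, 0)
    expect_lt(det$orientation, pi)
    expect_equal(det$orientation, theta %% pi, tolerance = 0.05)
  }
})

test_that("detection on clean renders recovers flies, with area and merge rules", {
  expect_equal(nrow(detect_flies(matrix(0.9, 50, 50), threshold = 0.5)), 0)
  expect_error(detect_flies(matrix(numeric(0), 0, 0)), "empty")

  ar <- arena_spec(400, 400, food_radius = 60)
  sc <- gen_scene(ar, n_flies = 3, spacing_px = 40, seed = 4,
                  body_major = 24, body_minor = 10)
  r <- render_frames(sc)
  det <- detect_flies(r$images[[1]], threshold = 0.5,
                      expected_body_area_px = pi * 24 * 10 / 4)
  expect_equal(nrow(det), 3)
  ## each centroid within 1 px of ground truth
  for (i in seq_len(3)) {
    d <- sqrt((det$centroid_x - sc$flies$x[i])^2 +
                (det$centroid_y - sc$flies$y[i])^2)
    expect_lt(min(d), 1)
  }
  expect_false(any(det$merged_flag))

  ## two overlapping bodies become one oversized component flagged merged
  img <- matrix(0.9, 200, 200)
  img[socialfly:::ellipse_pixels(90, 100, 12, 5, 0, 200, 200)] <- 0.1
  img[socialfly:::ellipse_pixels(112, 100, 12, 5, 0, 200, 200)] <- 0.1
  det2 <- detect_flies(img, threshold = 0.5,
                       expected_body_area_px = pi * 24 * 10 / 4)
  expect_equal(nrow(det2), 1)
  expect_true(det2$merged_flag)
})

test_that("automatic thresholding segments clean frames like the fixed threshold", {
  ar <- arena_spec(300, 300, food_radius = 50)
  sc <- gen_scene(ar, n_flies = 4, spacing_px = 30, seed = 6,
                  body_major = 20, body_minor = 8)
  r <- render_frames(sc)
  fixed <- detect_flies(r$images[[1]], threshold = 0.5,
                        expected_body_area_px = pi * 20 * 8 / 4)
  auto <- detect_flies(r$images[[1]], threshold = NULL,
                       expected_body_area_px = pi * 20 * 8 / 4)
  expect_equal(nrow(auto), nrow(fixed))
  expect_equal(sort(auto$centroid_x), sort(fixed$centroid_x), tolerance = 1e-9)
})

test_that("painted flies are found by color with correct labels", {
  ar <- arena_spec(300, 300, food_radius = 50)
  empty <- array(0.9, dim = c(50, 50, 3))
  expect_equal(nrow(detect_painted(empty)), 0)

  sc <- gen_scene(ar, n_flies = 5, spacing_px = 30, painted_ids = c(1, 3),
                  seed = 8, body_major = 24, body_minor = 10)
  r <- render_frames(sc)
  marks <- detect_painted(r$images[[1]])
  expect_setequal(marks$label, c("blue", "pink"))
  truth1 <- sc$flies[sc$flies$id == 1, ]
  m1 <- marks[marks$label == "blue", ]
  expect_lt(sqrt((m1$x - truth1$x)^2 + (m1$y - truth1$y)^2), 2)
})

test_that("ROI assignment uses closed boundaries and mutually exclusive flags", {
  roi <- food_roi(c(50, 50), radius_on = 10, radius_near = 20)
  det <- tibble::tibble(
    centroid_x = c(50, 60, 65, 75),   # center, on boundary, near, outside
    centroid_y = c(50, 50, 50, 50)
  )
  out <- assign_roi(det, roi)
  expect_equal(out$on_food, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(out$near_food, c(FALSE, FALSE, TRUE, FALSE))
  expect_false(any(out$on_food & out$near_food))
})

test_that("windowed counts average frames inside each stride window", {
  ## frames at 0, 2, 4, ... seconds; counts 4, 5, 6 inside the first window
  mk <- function(t_s, n_on) {
    tibble::tibble(time_min = t_s / 60,
                   centroid_x = 0, centroid_y = 0,
                   on_food = rep(c(TRUE, FALSE), c(n_on, 10 - n_on)),
                   near_food = FALSE)
  }
  det <- dplyr::bind_rows(mk(0, 4), mk(3, 5), mk(6, 6), mk(45, 7), mk(48, 7))
  ws <- windowed_counts(det, total_in_chamber = 10)
  expect_equal(ws$n_on[1], 5)       # mean of 4, 5, 6
  expect_equal(ws$n_on[2], 7)
  expect_equal(ws$time_min, c(0, 0.75))

  ## a stride with no frames is a missing record, not zero
  det2 <- dplyr::bind_rows(mk(0, 4), mk(95, 6))
  ws2 <- windowed_counts(det2, total_in_chamber = 10,
                         frame_times_min = c(0, 95 / 60))
  expect_true(is.na(ws2$n_on[2]))
  expect_equal(ws2$n_on[3], 6)
  expect_error(windowed_counts(det2, 10, window_s = 60, stride_s = 45))
})

test_that("windowed counts match a brute-force windowing of a generated scene", {
  ar <- arena_spec(500, 500, food_radius = 80)
  sc <- gen_scene(ar, n_flies = 10, spacing_px = 20, clustering = 0.5,
                  n_frames = 20, dt_s = 15, seed = 10,
                  body_major = 20, body_minor = 8, jitter_sd_px = 3)
  det <- truth_as_detections(sc)
  ws <- windowed_counts(det, total_in_chamber = 10, window_s = 10,
                        stride_s = 45)
  ## brute force: per-frame on-food counts, averaged per [t, t + 10 s)
  per_frame <- tapply(det$on_food, det$time_min, sum)
  times <- as.numeric(names(per_frame))
  for (i in seq_len(nrow(ws))) {
    sel <- times >= ws$time_min[i] & times < ws$time_min[i] + 10 / 60
    expect_equal(ws$n_on[i], mean(per_frame[sel]))
  }
})
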