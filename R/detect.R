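#' Fit an equivalent ellipse to a set of pixels by second-order moments
#'
#' The classic moments-of-inertia fit used for fly bodies: the centroid is
#' the pixel mean, the axes come from the eigenvalues of the 2x2 central
#' second-moment matrix (full axis length `4 * sqrt(eigenvalue)`, which
#' reproduces the true axis lengths for a uniformly filled ellipse), and the
#' orientation is the principal eigenvector angle reported modulo pi (a fly
#' has no distinguishable head/tail at this resolution). Degenerate pixel
#' sets (single pixel, collinear) have their axes floored at 1 px so the
#' body-size normalization downstream never divides by or subtracts zero
#' spuriously.
#'
#' @param pixel_set Two-column matrix or data frame of pixel-center
#'   coordinates `(x, y)`.
#' @return One-row tibble: `centroid_x`, `centroid_y`, `major_axis`,
#'   `minor_axis`, `orientation` (radians in `[0, pi)`).
#' @examples
#' # a filled 21 x 9 rectangle: axes approach 21*2/sqrt(3), 9*2/sqrt(3)
#' px <- expand.grid(x = 0:20, y = 0:8)
#' fit_ellipse(px)
#' @export
fit_ellipse <- function(pixel_set) {
  px <- as.matrix(pixel_set)
  if (nrow(px) == 0) stop("`pixel_set` must be non-empty", call. = FALSE)
  cx <- mean(px[, 1]); cy <- mean(px[, 2])
  dx <- px[, 1] - cx; dy <- px[, 2] - cy
  mxx <- mean(dx * dx); myy <- mean(dy * dy); mxy <- mean(dx * dy)
  m <- matrix(c(mxx, mxy, mxy, myy), 2)
  e <- eigen(m, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  major <- max(4 * sqrt(lam[1]), 1)
  minor <- max(4 * sqrt(lam[2]), 1)
  v <- e$vectors[, 1]
  theta <- atan2(v[2], v[1]) %% pi
  if (lam[1] - lam[2] < .Machine$double.eps) theta <- 0
  tibble::tibble(centroid_x = cx, centroid_y = cy,
                 major_axis = major, minor_axis = minor, orientation = theta)
}

#' Detect flies in a grayscale arena frame
#'
#' Thresholds the frame (flies are dark on a light background), labels
#' connected components, and fits an equivalent ellipse to each component's
#' pixel set. Components smaller than `min_area` are discarded as debris;
#' components larger than `max_area` — typically several touching flies —
#' are emitted once with `merged_flag = TRUE` rather than split, since
#' nothing downstream depends on resolving occlusions.
#'
#' Area defaults are expressed relative to the expected body area: debris
#' cutoff at 25% and merge cutoff at 180% of one body.
#'
#' @param image Numeric matrix, intensities in `[0, 1]`, indexed
#'   `[row, col]` = `[y + 1, x + 1]` (0-based pixel centers).
#' @param threshold Global intensity threshold; pixels strictly below it are
#'   foreground. `NULL` selects the threshold automatically by the
#'   inter-class-variance (Otsu) criterion.
#' @param expected_body_area_px Expected single-fly area in pixels, used
#'   only for the area defaults.
#' @param min_area,max_area Component area bounds in pixels.
#' @param roi Optional [food_roi()]; when given, detections are passed
#'   through [assign_roi()].
#' @param frame_index Integer tag copied into the output rows.
#' @return A tibble with one row per detection: `frame_index`, `centroid_x`,
#'   `centroid_y`, `major_axis`, `minor_axis`, `orientation`, `area_px`,
#'   `on_food`, `near_food`, `paint`, `merged_flag`.
#' @export
detect_flies <- function(image, threshold = NULL,
                         expected_body_area_px = pi * 55 * 18 / 4,
                         min_area = 0.25 * expected_body_area_px,
                         max_area = 1.8 * expected_body_area_px,
                         roi = NULL, frame_index = 1L) {
  if (length(dim(image)) == 3) image <- rowMeans(image, dims = 2)
  image <- as.matrix(image)
  if (nrow(image) == 0 || ncol(image) == 0) {
    stop("image has empty dimensions", call. = FALSE)
  }
  if (is.null(threshold)) {
    threshold <- EBImage::otsu(EBImage::Image(image))
  }
  stopifnot(threshold > 0, threshold < 1)

  mask <- image < threshold
  lab <- EBImage::bwlabel(mask)
  n_comp <- max(lab)
  rows <- list()
  if (n_comp > 0) {
    idx <- which(lab > 0)
    comp <- lab[idx]
    ys <- (idx - 1) %% nrow(image)        # 0-based row = y
    xs <- (idx - 1) %/% nrow(image)       # 0-based col = x
    areas <- tabulate(comp, nbins = n_comp)
    for (k in seq_len(n_comp)) {
      if (areas[k] < min_area) next
      sel <- comp == k
      fit <- fit_ellipse(cbind(xs[sel], ys[sel]))
      rows[[length(rows) + 1]] <- dplyr::mutate(
        fit, area_px = areas[k], merged_flag = areas[k] > max_area
      )
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(centroid_x = numeric(), centroid_y = numeric(),
                   major_axis = numeric(), minor_axis = numeric(),
                   orientation = numeric(), area_px = integer(),
                   merged_flag = logical())
  }
  out <- dplyr::mutate(out,
    frame_index = as.integer(frame_index), on_food = NA, near_food = NA,
    paint = NA_character_, .before = 1
  )
  out <- dplyr::relocate(out, "frame_index")
  if (!is.null(roi)) out <- assign_roi(out, roi) else {
    out$on_food <- rep(NA, nrow(out)); out$near_food <- rep(NA, nrow(out))
  }
  out
}

#' Detect flies in every frame of a rendered scene
#'
#' Convenience wrapper running [detect_flies()] (and, for RGB frames with a
#' palette, [detect_painted()] to transfer paint labels onto the nearest
#' detection) over all frames of a [render_frames()] result, tagging rows
#' with frame index and time.
#'
#' @param rendered A `rendered_scene`.
#' @param ... Passed to [detect_flies()].
#' @param match_paint_px Maximum distance (px) between a paint mark and a
#'   detection centroid for the label to be transferred.
#' @inheritParams detect_flies
#' @return Combined detection tibble with a `time_min` column.
#' @export
detect_scene <- function(rendered, ..., roi = NULL, match_paint_px = 15) {
  stopifnot(inherits(rendered, "rendered_scene"))
  times <- unique(rendered$truth[, c("frame_index", "time_min")])
  purrr::map_dfr(seq_along(rendered$images), function(f) {
    img <- rendered$images[[f]]
    det <- detect_flies(img, ..., roi = roi, frame_index = f)
    if (length(dim(img)) == 3 && nrow(det)) {
      marks <- detect_painted(img)
      for (i in seq_len(nrow(marks))) {
        d2 <- (det$centroid_x - marks$x[i])^2 + (det$centroid_y - marks$y[i])^2
        j <- which.min(d2)
        if (length(j) && d2[j] <= match_paint_px^2) det$paint[j] <- marks$label[i]
      }
    }
    det$time_min <- times$time_min[match(f, times$frame_index)]
    det
  })
}

#' Locate paint-marked flies by color thresholding
#'
#' For each reference color, pixels within `tolerance` (Euclidean distance
#' in RGB) form candidate groups; the largest connected group per label is
#' reported by its centroid, so at most one position per label per frame.
#' Pixels within tolerance of more than one reference color raise an
#' ambiguity warning and are assigned to the nearest color.
#'
#' @param image RGB array `[row, col, channel]`, values in `[0, 1]`.
#' @param reference_colors Tibble with columns `label`, `r`, `g`, `b`;
#'   defaults to [paint_palette()].
#' @param tolerance Euclidean RGB distance (> 0) below which a pixel
#'   matches a reference color.
#' @return Tibble `label`, `x`, `y` (0-based pixel-center centroid).
#' @export
detect_painted <- function(image, reference_colors = paint_palette(),
                           tolerance = 0.15) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3, tolerance > 0)
  h <- dim(image)[1]; w <- dim(image)[2]
  n_col <- nrow(reference_colors)
  d2 <- array(0, dim = c(h, w, n_col))
  for (k in seq_len(n_col)) {
    d2[, , k] <- (image[, , 1] - reference_colors$r[k])^2 +
      (image[, , 2] - reference_colors$g[k])^2 +
      (image[, , 3] - reference_colors$b[k])^2
  }
  within <- d2 <= tolerance^2
  n_match <- rowSums(within, dims = 2)
  if (any(n_match > 1)) {
    warning("pixels within tolerance of multiple reference colors; ",
            "assigned to the nearest", call. = FALSE)
  }
  nearest <- apply(d2, c(1, 2), which.min)

  out <- list()
  for (k in seq_len(n_col)) {
    mask <- within[, , k] & (n_match <= 1 | nearest == k)
    if (!any(mask)) next
    lab <- EBImage::bwlabel(mask)
    areas <- tabulate(lab[lab > 0])
    best <- which.max(areas)
    idx <- which(lab == best)
    ys <- (idx - 1) %% h
    xs <- (idx - 1) %/% h
    out[[length(out) + 1]] <- tibble::tibble(
      label = reference_colors$label[k], x = mean(xs), y = mean(ys)
    )
  }
  if (length(out)) dplyr::bind_rows(out) else {
    tibble::tibble(label = character(), x = numeric(), y = numeric())
  }
}

#' Flag detections as on or near the food dish
#'
#' Closed-boundary membership: a fly is on the food when its centroid is
#' within `radius_on` of the ROI center (boundary inclusive), and near the
#' food when within `radius_near` but not on it; the two flags are never
#' both true.
#'
#' @param detections Detection tibble with `centroid_x`, `centroid_y`.
#' @param roi A [food_roi()].
#' @return The tibble with `on_food` and `near_food` filled in.
#' @export
assign_roi <- function(detections, roi) {
  stopifnot(inherits(roi, "food_roi"))
  d <- dist_to_point(detections$centroid_x, detections$centroid_y, roi$center)
  dplyr::mutate(detections,
                on_food = d <= roi$radius_on,
                near_food = d <= roi$radius_near & !(d <= roi$radius_on))
}

#' Windowed on-food and near-food counts
#'
#' Averages per-frame on-food and near-food counts over a short window at
#' regular strides, the standard way chamber videos are reduced to an
#' aggregation time series: counts are taken for every frame inside a
#' `window_s`-second window starting at each `stride_s` increment and
#' averaged. Strides whose window contains no frames yield a missing
#' record (`NA`), never a zero.
#'
#' @param detections Detection tibble covering multiple frames; must carry
#'   `time_min` and filled `on_food` / `near_food` flags (see
#'   [assign_roi()]).
#' @param total_in_chamber Total number of flies loaded in the chamber.
#' @param window_s,stride_s Averaging window and stride, seconds; the
#'   window may not exceed the stride.
#' @param frame_times_min Times of *all* frames, including frames with no
#'   detections; defaults to the times present in `detections`.
#' @param replicate_id Label for downstream replicate averaging.
#' @return An `aggregation_series` tibble (`time_min`, `n_on`, `n_near`,
#'   `total_in_chamber`, `replicate_id`), timestamps at window starts.
#' @export
windowed_counts <- function(detections, total_in_chamber, window_s = 10,
                            stride_s = 45,
                            frame_times_min = sort(unique(detections$time_min)),
                            replicate_id = "r1") {
  stopifnot(window_s > 0, stride_s > 0, window_s <= stride_s,
            total_in_chamber >= 0)
  if (is.unsorted(frame_times_min)) {
    stop("frame times must be sorted", call. = FALSE)
  }
  per_frame <- detections |>
    dplyr::group_by(.data$time_min) |>
    dplyr::summarise(n_on = sum(.data$on_food), n_near = sum(.data$near_food),
                     .groups = "drop")
  ## frames with no detections contribute zero counts
  per_frame <- dplyr::left_join(
    tibble::tibble(time_min = frame_times_min), per_frame, by = "time_min"
  ) |>
    dplyr::mutate(n_on = dplyr::coalesce(.data$n_on, 0L),
                  n_near = dplyr::coalesce(.data$n_near, 0L))

  t_max <- max(frame_times_min)
  starts <- seq(0, t_max, by = stride_s / 60)
  out <- purrr::map_dfr(starts, function(t0) {
    sel <- per_frame$time_min >= t0 & per_frame$time_min < t0 + window_s / 60
    if (!any(sel)) {
      tibble::tibble(time_min = t0, n_on = NA_real_, n_near = NA_real_)
    } else {
      tibble::tibble(time_min = t0, n_on = mean(per_frame$n_on[sel]),
                     n_near = mean(per_frame$n_near[sel]))
    }
  })
  out <- dplyr::mutate(out, total_in_chamber = as.integer(total_in_chamber),
                       replicate_id = replicate_id)
  class(out) <- c("aggregation_series", class(out))
  out
}
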