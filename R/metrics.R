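#' Average aggregation curves across replicates
#'
#' Converts each replicate's on-food counts to fractions of the chamber
#' total and averages them per time point, with the standard error of the
#' mean across replicates. Replicates recorded on different time grids are
#' resampled onto the first replicate's grid by nearest record (grids
#' produced at a fixed stride are already aligned, so this is normally a
#' no-op).
#'
#' @param replicates A list of `aggregation_series` tibbles, or one tibble
#'   containing several `replicate_id`s.
#' @return A tibble of class `aggregation_curve`: `time_min`,
#'   `mean_fraction_on`, `sem_fraction_on` (`NA` with fewer than 2
#'   replicates), `n_replicates`.
#' @export
aggregation_curve <- function(replicates) {
  if (inherits(replicates, "data.frame")) {
    replicates <- split(replicates, replicates$replicate_id)
  }
  stopifnot(length(replicates) >= 1)
  grid <- replicates[[1]]$time_min
  frac <- purrr::map(replicates, function(s) {
    idx <- purrr::map_int(grid, function(t) which.min(abs(s$time_min - t)))
    s$n_on[idx] / s$total_in_chamber[idx]
  })
  m <- do.call(cbind, frac)
  k <- ncol(m)
  out <- tibble::tibble(
    time_min = grid,
    mean_fraction_on = rowMeans(m, na.rm = TRUE),
    sem_fraction_on = if (k < 2) NA_real_ else
      apply(m, 1, stats::sd, na.rm = TRUE) / sqrt(k),
    n_replicates = k
  )
  class(out) <- c("aggregation_curve", class(out))
  out
}

#' Time for 40% of the chamber to reach the food (T-40)
#'
#' Returns the first sampled time at which the on-food count meets the
#' closed threshold `n_on >= threshold_fraction * total_in_chamber` — no
#' interpolation, since the sampling stride is far finer than any effect of
#' interest. A series that never reaches the threshold yields an undefined
#' (`NA`) T-40, which is a legal outcome, not an error: poorly aggregating
#' groups simply have no measurable T-40.
#'
#' @param series An `aggregation_series` tibble.
#' @param threshold_fraction Fraction of the chamber that must be on the
#'   food; default 0.40.
#' @return One-row tibble: `t40_min` (`NA` if never reached),
#'   `threshold_fraction`, `density` (chamber total).
#' @export
t40 <- function(series, threshold_fraction = 0.40) {
  stopifnot(threshold_fraction > 0, threshold_fraction <= 1)
  total <- series$total_in_chamber[1]
  ok <- !is.na(series$n_on) & series$n_on >= threshold_fraction * total
  tibble::tibble(
    t40_min = if (any(ok)) series$time_min[which(ok)[1]] else NA_real_,
    threshold_fraction = threshold_fraction,
    density = as.integer(total)
  )
}

#' Cooperativity coefficient: regression of T-40 on fly density
#'
#' Fits ordinary least squares of T-40 on the number of flies in the
#' chamber. The slope (minutes per fly) is the cooperativity coefficient: a
#' negative slope means groups find food faster at higher density —
#' cooperativity in the binding-kinetics sense of density-dependent rates —
#' while a slope of zero is the non-cooperative signature. Densities whose
#' T-40 is undefined are excluded before fitting.
#'
#' @param points Tibble (or data frame) with columns `density` and
#'   `t40_min`, one row per density (e.g. stacked [t40()] results).
#' @return An object of class `coop_fit`; see [tidy.coop_fit()] and
#'   [glance.coop_fit()].
#' @examples
#' fit <- cooperativity_coefficient(
#'   data.frame(density = c(25, 50, 75, 100), t40_min = c(100, 80, 60, 40)))
#' glance(fit)$slope  # -0.8 min/fly
#' @export
cooperativity_coefficient <- function(points) {
  pts <- dplyr::filter(tibble::as_tibble(points), !is.na(.data$t40_min))
  if (nrow(pts) < 2) {
    stop(structure(class = c("socialfly_insufficient_data", "error", "condition"),
                   list(message = "need >= 2 densities with a defined T-40",
                        call = NULL)))
  }
  if (stats::var(pts$t40_min) == 0) {
    ## constant T-40 across densities: the non-cooperative signature
    fit <- stats::lm(t40_min ~ density, data = pts)
    return(structure(
      list(slope = 0, intercept = pts$t40_min[1], r_squared = 0,
           densities_used = pts$density, model = fit, data = pts),
      class = "coop_fit"))
  }
  fit <- stats::lm(t40_min ~ density, data = pts)
  r2 <- if (nrow(pts) == 2) 1 else
    suppressWarnings(summary(fit)$r.squared)
  if (!is.finite(r2)) r2 <- 0
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2,
         densities_used = pts$density,
         model = fit, data = pts),
    class = "coop_fit"
  )
}

#' @export
print.coop_fit <- function(x, ...) {
  cat(sprintf(
    "<coop_fit> cooperativity coefficient %.4g min/fly (intercept %.4g, R^2 %.3f, %d densities)\n",
    x$slope, x$intercept, x$r_squared, length(x$densities_used)))
  invisible(x)
}

#' Social space of one frame
#'
#' The mean minimum nearest-neighbor distance between fly ellipse centers,
#' with the mutual-pair rule: when two flies are each other's nearest
#' neighbor, their shared distance enters the mean once. The raw value is
#' then body-size-normalized by subtracting the frame's mean pooled body
#' extent (the mean of every fitted major and minor axis), turning a
#' center-to-center distance into an edge-to-edge one that is independent
#' of fly size. Degenerate frames (coincident flies) legally produce zero
#' or negative normalized values.
#'
#' @param detections Detection tibble for a single frame (>= 2 rows) with
#'   `centroid_x`, `centroid_y`, `major_axis`, `minor_axis`.
#' @return One-row tibble: `raw_px`, `normalized_px`,
#'   `mean_body_extent_px`, `n_flies`, `frame_index`.
#' @export
social_space <- function(detections) {
  n <- nrow(detections)
  if (n < 2) {
    stop(structure(class = c("socialfly_insufficient_data", "error", "condition"),
                   list(message = "social space is undefined for fewer than 2 flies",
                        call = NULL)))
  }
  nn <- nn_dist_index(detections$centroid_x, detections$centroid_y)
  ## drop the second member of each mutual nearest-neighbor pair
  keep <- !(nn$index[nn$index] == seq_len(n) & seq_len(n) > nn$index)
  raw <- mean(nn$dist[keep])
  ext <- mean_body_extent(detections$major_axis, detections$minor_axis)
  tibble::tibble(
    raw_px = raw, normalized_px = raw - ext, mean_body_extent_px = ext,
    n_flies = as.integer(n),
    frame_index = as.integer(detections$frame_index[1] %||% NA_integer_)
  )
}

#' Social space for every frame of a detection table
#'
#' @param detections Multi-frame detection tibble with a `frame_index`
#'   column; frames with fewer than 2 detections are skipped.
#' @return Tibble of per-frame [social_space()] rows.
#' @export
social_space_frames <- function(detections) {
  detections |>
    dplyr::group_by(.data$frame_index) |>
    dplyr::group_map(function(fr, key) {
      if (nrow(fr) < 2) return(NULL)
      res <- social_space(dplyr::mutate(fr, frame_index = key$frame_index))
      res
    }) |>
    dplyr::bind_rows()
}

#' Density-binned social-space profile
#'
#' Social space shrinks as more flies crowd the food, so interspecies
#' comparisons are made within density bins. Frames are binned by the
#' number of flies detected in the frame into half-open bins
#' `[lo, lo + bin_width)` anchored at `anchor`, and the normalized social
#' space is averaged per bin with its SEM. Empty bins are absent from the
#' output.
#'
#' @param frames Tibble of per-frame [social_space()] results.
#' @param bin_width Bin width in flies (default 10).
#' @param anchor Left edge of the first bin (default 5, giving bins
#'   5–14, 15–24, ...).
#' @return Tibble `bin_lo`, `mean_normalized_px`, `sem_normalized_px`,
#'   `sd_normalized_px`, `n_frames`, of class `social_space_profile`.
#' @export
density_binned_social_space <- function(frames, bin_width = 10, anchor = 5) {
  stopifnot(bin_width > 0)
  out <- frames |>
    dplyr::mutate(bin_lo = anchor +
                    floor((.data$n_flies - anchor) / bin_width) * bin_width) |>
    dplyr::group_by(.data$bin_lo) |>
    dplyr::summarise(
      mean_normalized_px = mean(.data$normalized_px),
      sd_normalized_px = stats::sd(.data$normalized_px),
      sem_normalized_px = stats::sd(.data$normalized_px) / sqrt(dplyr::n()),
      n_frames = dplyr::n(), .groups = "drop"
    )
  class(out) <- c("social_space_profile", class(out))
  out
}

#' Social space in a fly-density band
#'
#' Convenience selector for the low-density band used for interspecies
#' comparison: frames with `lo` to `hi` flies (inclusive). Both the
#' frame-level SD and the SEM are reported, since either can serve as the
#' unit of spread depending on whether frames or experiments are treated as
#' replicates.
#'
#' @param frames Tibble of per-frame [social_space()] results.
#' @param lo,hi Inclusive fly-count band, default 15–25.
#' @return One-row tibble with mean, SD, SEM and frame count.
#' @export
social_space_band <- function(frames, lo = 15, hi = 25) {
  sel <- dplyr::filter(frames, .data$n_flies >= lo, .data$n_flies <= hi)
  tibble::tibble(
    band_lo = lo, band_hi = hi,
    mean_normalized_px = mean(sel$normalized_px),
    sd_normalized_px = stats::sd(sel$normalized_px),
    sem_normalized_px = stats::sd(sel$normalized_px) / sqrt(nrow(sel)),
    n_frames = nrow(sel)
  )
}

#' Z-score relative positioning of painted flies
#'
#' For each paint-marked fly, in frames sampled every `sample_interval_s`
#' seconds: the fly's nearest-neighbor distance is expressed as the number
#' of standard deviations from the mean of the nearest-neighbor
#' distribution over *all* flies in that frame. Note this per-fly
#' distribution keeps every fly's nearest-neighbor distance (no mutual-pair
#' deduplication — that rule belongs to the frame-mean social space, a
#' different statistic). A distribution of Z-scores across sampled frames
#' shows whether a focal fly sits systematically tighter (negative) or
#' looser (positive) than the group.
#'
#' Frames with fewer than 3 flies or zero spread are skipped; the number of
#' skipped frames is recorded in the `skipped` attribute.
#'
#' @param detections Multi-frame detection tibble with `time_min` and a
#'   `paint` column (non-`NA` for marked flies).
#' @param sample_interval_s Sampling interval in seconds (default 40).
#' @param sd_mode `"population"` (divide by n, default — the frame is the
#'   entire population of interest) or `"sample"` (n - 1).
#' @return Tibble of class `zscore_series`: `fly_label`, `frame_index`,
#'   `time_min`, `z`.
#' @export
zscore_positioning <- function(detections, sample_interval_s = 40,
                               sd_mode = c("population", "sample")) {
  sd_mode <- match.arg(sd_mode)
  times <- sort(unique(detections$time_min))
  wanted <- seq(0, max(times), by = sample_interval_s / 60)
  sampled <- unique(times[purrr::map_int(wanted, function(t) {
    which.min(abs(times - t))
  })])

  skipped <- 0L
  rows <- purrr::map(sampled, function(t) {
    fr <- detections[detections$time_min == t, ]
    painted <- fr[!is.na(fr$paint), , drop = FALSE]
    if (nrow(painted) == 0) return(NULL)
    if (nrow(fr) < 3) { skipped <<- skipped + 1L; return(NULL) }
    nn <- nn_dist_index(fr$centroid_x, fr$centroid_y)
    mu <- mean(nn$dist)
    s <- stats::sd(nn$dist)
    if (sd_mode == "population") s <- s * sqrt((nrow(fr) - 1) / nrow(fr))
    if (!is.finite(s) || s == 0) { skipped <<- skipped + 1L; return(NULL) }
    idx <- which(!is.na(fr$paint))
    tibble::tibble(
      fly_label = fr$paint[idx],
      frame_index = fr$frame_index[idx],
      time_min = t,
      z = (nn$dist[idx] - mu) / s
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("zscore_series", class(out))
  attr(out, "skipped") <- skipped
  attr(out, "sample_interval_s") <- sample_interval_s
  out
}

#' Per-frame on-food and near-food fractions
#'
#' For each frame, the fraction of detected flies on the food and the
#' fraction next to it — the coordinates of the food-preference scatter.
#' The summary attribute `fraction_all_on` gives the fraction of frames in
#' which every detected fly was on the food (the diagonal of that scatter).
#'
#' @param detections Multi-frame detection tibble with filled ROI flags, or
#'   raw detections plus `roi`.
#' @param roi Optional [food_roi()] applied first.
#' @return Tibble of class `food_preference`: `frame_index`, `n_flies`,
#'   `fraction_on`, `fraction_near`.
#' @export
food_preference <- function(detections, roi = NULL) {
  if (!is.null(roi)) detections <- assign_roi(detections, roi)
  out <- detections |>
    dplyr::group_by(.data$frame_index) |>
    dplyr::summarise(
      n_flies = dplyr::n(),
      fraction_on = mean(.data$on_food),
      fraction_near = mean(.data$near_food),
      .groups = "drop"
    )
  class(out) <- c("food_preference", class(out))
  attr(out, "fraction_all_on") <- mean(out$fraction_on == 1)
  out
}

#' Wilcoxon rank-sum comparison of two count samples
#'
#' Two-sided Mann–Whitney test as used for group comparisons of aggression
#' counts. For combined sample sizes up to `exact_max_n` the null
#' distribution of U is enumerated exactly over all group assignments of
#' the (mid-)ranks, which remains valid under ties; larger samples use the
#' normal approximation with the tie-corrected variance.
#'
#' @param a,b Numeric vectors of counts; both non-empty.
#' @param exact_max_n Combined size at or below which exact enumeration is
#'   used (default 20).
#' @return One-row tibble: `statistic` (U of sample `a`), `p_value`,
#'   `method`.
#' @examples
#' rank_sum_compare(c(1, 2), c(3, 4))  # U = 0, p = 1/3 by enumeration
#' @export
rank_sum_compare <- function(a, b, exact_max_n = 20) {
  if (length(a) == 0 || length(b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (n <= exact_max_n) {
    combos <- utils::combn(n, n1)
    u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(u_all <= u_obs + 1e-9),
                        mean(u_all >= u_obs - 1e-9)))
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u_obs - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation, tie-corrected"
  }
  tibble::tibble(statistic = u_obs, p_value = p, method = method)
}

#' Regression of aggression on fly density at arrival
#'
#' Fits, per rearing-condition group, ordinary least squares of lunge
#' counts (scored over each fly's first 150 s at the food) on the fly
#' density when that fly arrived — the check that apparent aggression
#' differences are not an artifact of crowding.
#'
#' @param records Tibble with columns `lunges_150s`,
#'   `density_at_arrival` and optionally `condition` (one fit per
#'   condition).
#' @return Tibble: `condition`, `slope`, `intercept`, `r_squared`, `n`.
#' @export
aggression_density_regression <- function(records) {
  records <- tibble::as_tibble(records)
  if (!"condition" %in% names(records)) records$condition <- "all"
  records |>
    dplyr::group_by(.data$condition) |>
    dplyr::group_map(function(g, key) {
      if (nrow(g) < 3) {
        stop(structure(
          class = c("socialfly_insufficient_data", "error", "condition"),
          list(message = sprintf(
            "need >= 3 records per group (got %d for '%s')", nrow(g),
            key$condition), call = NULL)))
      }
      if (stats::var(g$lunges_150s) == 0) {
        ## constant response: flat line, nothing to explain
        return(tibble::tibble(condition = key$condition, slope = 0,
                              intercept = g$lunges_150s[1], r_squared = 0,
                              n = nrow(g)))
      }
      fit <- stats::lm(lunges_150s ~ density_at_arrival, data = g)
      r2 <- suppressWarnings(summary(fit)$r.squared)
      if (!is.finite(r2)) r2 <- 0
      tibble::tibble(condition = key$condition,
                     slope = unname(stats::coef(fit)[2]),
                     intercept = unname(stats::coef(fit)[1]),
                     r_squared = r2, n = nrow(g))
    }) |>
    dplyr::bind_rows()
}
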