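#' Generate a synthetic chamber scene with ground-truth fly poses
#'
#' Places `n_flies` elliptical fly bodies in an arena at a target
#' nearest-neighbor spacing, optionally clustered on the food dish, and
#' carries them through `n_frames` time points. The generator keeps full
#' ground-truth bookkeeping: per-frame brute-force nearest-neighbor
#' statistics, on-food counts and the body-size-normalized social space of
#' the placed configuration, so downstream estimators can be tested for
#' parameter recovery without any external data.
#'
#' Placement targets a mean nearest-neighbor *edge-to-edge* gap of
#' `spacing_px`: centers are placed at distance `spacing_px` plus the mean
#' pooled body extent (mean of all major and minor axes), which is the same
#' convention the social-space normalization inverts. `clustering` sets the
#' fraction of flies confined to the food circle: 1 puts every fly on the
#' food, 0 spreads them uniformly through the arena.
#'
#' Fly bodies default to the scale of the study system: a fly is roughly 55
#' px long at the standard chamber magnification.
#'
#' @param arena An [arena_spec()].
#' @param n_flies Number of flies (>= 0).
#' @param spacing_px Target mean nearest-neighbor gap between ellipse edges,
#'   in pixels (> 0).
#' @param clustering Fraction in `[0, 1]` of flies placed inside the food
#'   circle.
#' @param painted_ids Integer ids of flies to receive distinct paint labels.
#' @param n_frames,dt_s Number of frames and the time step between them in
#'   seconds.
#' @param seed Integer seed; the scene is a pure function of its arguments.
#' @param body_major,body_minor Ellipse axis lengths in pixels.
#' @param jitter_sd_px Per-frame positional jitter (standard deviation, px)
#'   applied around each fly's base position; 0 gives a static scene.
#' @param max_tries Placement attempts per fly before the scene is declared
#'   infeasible.
#' @return An object of class `fly_scene`: a list with elements `arena`,
#'   `flies` (tibble of per-frame ground-truth poses), `stats` (per-frame
#'   brute-force spacing/occupancy bookkeeping), `params` and `seed`.
#' @examples
#' ar <- arena_spec(400, 400, food_radius = 60)
#' sc <- gen_scene(ar, n_flies = 5, spacing_px = 40, seed = 1,
#'                 body_major = 20, body_minor = 8)
#' sc$stats
#' @export
gen_scene <- function(arena, n_flies, spacing_px = 30, clustering = 0,
                      painted_ids = integer(), n_frames = 1, dt_s = 45,
                      seed = 1, body_major = 55, body_minor = 18,
                      jitter_sd_px = 0, max_tries = 4000) {
  stopifnot(inherits(arena, "arena_spec"), n_flies >= 0, spacing_px > 0,
            clustering >= 0, clustering <= 1, n_frames >= 1, dt_s > 0,
            body_major >= body_minor, body_minor > 0)
  painted_ids <- as.integer(painted_ids)
  if (length(painted_ids) && (any(painted_ids < 1) || any(painted_ids > n_flies))) {
    stop("`painted_ids` must be fly ids in 1..n_flies", call. = FALSE)
  }

  extent <- mean_body_extent(rep(body_major, max(n_flies, 1)),
                             rep(body_minor, max(n_flies, 1)))
  d_target <- spacing_px + extent

  with_seed(seed, {
    placement <- place_flies(arena, n_flies, d_target, clustering,
                             body_major, max_tries)
    orientation <- stats::runif(n_flies, 0, pi)

    paint <- rep(NA_character_, n_flies)
    palette <- c("blue", "pink", "green", "orange", "white", "red", "yellow")
    if (length(painted_ids)) {
      if (length(painted_ids) > length(palette)) {
        stop("at most ", length(palette), " painted flies supported", call. = FALSE)
      }
      paint[painted_ids] <- palette[seq_along(painted_ids)]
    }

    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      if (jitter_sd_px > 0 && n_flies > 0) {
        jx <- stats::rnorm(n_flies, 0, jitter_sd_px)
        jy <- stats::rnorm(n_flies, 0, jitter_sd_px)
      } else {
        jx <- jy <- rep(0, n_flies)
      }
      margin <- body_major / 2
      x <- pmin(pmax(placement$x + jx, margin), arena$width_px - margin)
      y <- pmin(pmax(placement$y + jy, margin), arena$height_px - margin)
      frames[[f]] <- tibble::tibble(
        frame_index = f,
        time_min = (f - 1) * dt_s / 60,
        id = seq_len(n_flies),
        x = x, y = y,
        body_major = rep(body_major, n_flies),
        body_minor = rep(body_minor, n_flies),
        orientation = orientation,
        paint = paint,
        on_food = dist_to_point(x, y, arena$food_center) <= arena$food_radius
      )
    }
    flies <- dplyr::bind_rows(frames)
    stats_tbl <- scene_stats(flies, n_frames, dt_s)

    structure(
      list(
        arena = arena, flies = flies, stats = stats_tbl,
        params = list(
          n_flies = n_flies, spacing_px = spacing_px, clustering = clustering,
          painted_ids = painted_ids, n_frames = n_frames, dt_s = dt_s,
          body_major = body_major, body_minor = body_minor,
          jitter_sd_px = jitter_sd_px, target_center_nn_px = d_target
        ),
        seed = as.integer(seed)
      ),
      class = "fly_scene"
    )
  })
}

## Sequential placement: the first fly lands uniformly in its region, each
## later fly at the target center distance from a random placed fly, with
## rejection until no pair is closer than the target. Falls back to uniform
## proposals before declaring the scene infeasible.
place_flies <- function(arena, n_flies, d_target, clustering, body_major,
                        max_tries) {
  if (n_flies == 0) return(list(x = numeric(0), y = numeric(0)))
  margin <- body_major / 2
  n_food <- round(clustering * n_flies)
  in_food <- c(rep(TRUE, n_food), rep(FALSE, n_flies - n_food))

  draw_uniform <- function(food) {
    if (food) {
      repeat {
        r <- arena$food_radius * sqrt(stats::runif(1))
        th <- stats::runif(1, 0, 2 * pi)
        p <- arena$food_center + r * c(cos(th), sin(th))
        if (p[1] >= margin && p[1] <= arena$width_px - margin &&
            p[2] >= margin && p[2] <= arena$height_px - margin) return(p)
      }
    } else {
      c(stats::runif(1, margin, arena$width_px - margin),
        stats::runif(1, margin, arena$height_px - margin))
    }
  }
  ok_region <- function(p, food) {
    inside <- p[1] >= margin && p[1] <= arena$width_px - margin &&
      p[2] >= margin && p[2] <= arena$height_px - margin
    if (!inside) return(FALSE)
    if (food) dist_to_point(p[1], p[2], arena$food_center) <= arena$food_radius else TRUE
  }

  x <- y <- numeric(n_flies)
  for (k in seq_len(n_flies)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      if (k == 1) {
        p <- draw_uniform(in_food[k])
      } else if (try <= max_tries / 2) {
        a <- sample.int(k - 1, 1)
        th <- stats::runif(1, 0, 2 * pi)
        p <- c(x[a], y[a]) + d_target * c(cos(th), sin(th))
      } else {
        p <- draw_uniform(in_food[k])
      }
      if (!ok_region(p, in_food[k])) next
      if (k > 1) {
        dmin <- min(sqrt((x[seq_len(k - 1)] - p[1])^2 +
                           (y[seq_len(k - 1)] - p[2])^2))
        if (dmin < d_target - 1e-9) next
      }
      x[k] <- p[1]; y[k] <- p[2]
      placed <- TRUE
      break
    }
    if (!placed) {
      stop(structure(
        class = c("socialfly_placement_infeasible", "error", "condition"),
        list(message = sprintf(
          "could not place fly %d of %d at spacing target %.1f px; arena too crowded",
          k, n_flies, d_target),
          call = NULL)
      ))
    }
  }
  list(x = x, y = y)
}

## Brute-force per-frame bookkeeping: nearest-neighbor distances from the
## full pairwise matrix, on-food counts, and the mutual-pair social space of
## the generating configuration.
scene_stats <- function(flies, n_frames, dt_s) {
  purrr::map_dfr(seq_len(n_frames), function(f) {
    fr <- flies[flies$frame_index == f, ]
    n <- nrow(fr)
    if (n < 2) {
      return(tibble::tibble(
        frame_index = f, time_min = (f - 1) * dt_s / 60, n_flies = n,
        n_on_food = sum(fr$on_food), mean_nn_center_px = NA_real_,
        mean_gap_px = NA_real_, social_space_raw_px = NA_real_,
        mean_body_extent_px = if (n) mean_body_extent(fr$body_major, fr$body_minor) else NA_real_
      ))
    }
    ext <- mean_body_extent(fr$body_major, fr$body_minor)
    nn <- nn_dist_index(fr$x, fr$y)
    tibble::tibble(
      frame_index = f, time_min = (f - 1) * dt_s / 60, n_flies = n,
      n_on_food = sum(fr$on_food),
      mean_nn_center_px = mean(nn$dist),
      mean_gap_px = mean(nn$dist) - ext,
      social_space_raw_px = mean_nn_mutual(fr$x, fr$y),
      mean_body_extent_px = ext
    )
  })
}

#' @export
print.fly_scene <- function(x, ...) {
  cat(sprintf(
    "<fly_scene> %d flies, %d frame(s), arena %g x %g px, seed %d\n",
    x$params$n_flies, x$params$n_frames, x$arena$width_px, x$arena$height_px,
    x$seed
  ))
  if (x$params$n_flies >= 2) {
    cat(sprintf("  spacing target %g px (gap); achieved mean gap %.2f px\n",
                x$params$spacing_px, mean(x$stats$mean_gap_px)))
  }
  invisible(x)
}

#' Ground-truth poses as a detection table
#'
#' Reshapes a scene's ground truth into the detection-table layout produced
#' by [detect_flies()], so behavioral metrics can be computed directly on
#' the generating configuration (bypassing rendering and segmentation) for
#' parameter-recovery checks.
#'
#' @param scene A `fly_scene`.
#' @return A detection tibble (`frame_index`, `time_min`, `centroid_x`,
#'   `centroid_y`, `major_axis`, `minor_axis`, `orientation`, `area_px`,
#'   `on_food`, `near_food`, `paint`, `merged_flag`).
#' @export
truth_as_detections <- function(scene) {
  stopifnot(inherits(scene, "fly_scene"))
  fl <- scene$flies
  tibble::tibble(
    frame_index = fl$frame_index,
    time_min = fl$time_min,
    centroid_x = fl$x, centroid_y = fl$y,
    major_axis = fl$body_major, minor_axis = fl$body_minor,
    orientation = fl$orientation,
    area_px = as.integer(round(pi * fl$body_major * fl$body_minor / 4)),
    on_food = fl$on_food,
    near_food = FALSE,
    paint = fl$paint,
    merged_flag = FALSE
  )
}
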