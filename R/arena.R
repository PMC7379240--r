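#' Describe a filming arena with a circular food region
#'
#' The arena is the unit of geometry shared by the synthetic frame generator
#' and the detection stage: a rectangular chamber imaged from above, with a
#' circular food dish somewhere inside it. Flies are rendered (and detected)
#' as dark ellipses on a light background, so `fly_level` must be darker than
#' `background_level`.
#'
#' Coordinates are pixel-centered and 0-based, with x increasing rightwards
#' and y increasing downwards (image convention). All lengths are in pixels.
#'
#' @param width_px,height_px Arena dimensions in pixels.
#' @param food_center Numeric length-2, `(x, y)` of the food dish center.
#' @param food_radius Food dish radius in pixels. The food circle must lie
#'   fully inside the arena.
#' @param background_level,fly_level Grayscale intensities in `[0, 1]`;
#'   flies are dark on light, so `fly_level < background_level`.
#' @return An object of class `arena_spec`.
#' @examples
#' arena_spec(600, 600, food_center = c(300, 300), food_radius = 80)
#' @export
arena_spec <- function(width_px, height_px,
                       food_center = c(width_px / 2, height_px / 2),
                       food_radius = min(width_px, height_px) / 6,
                       background_level = 0.85, fly_level = 0.15) {
  stopifnot(
    length(width_px) == 1, length(height_px) == 1,
    width_px >= 1, height_px >= 1,
    length(food_center) == 2, food_radius > 0,
    background_level >= 0, background_level <= 1,
    fly_level >= 0, fly_level <= 1
  )
  if (fly_level >= background_level) {
    stop("flies are dark on light: `fly_level` must be < `background_level`",
         call. = FALSE)
  }
  if (food_center[1] - food_radius < 0 || food_center[1] + food_radius > width_px ||
      food_center[2] - food_radius < 0 || food_center[2] + food_radius > height_px) {
    stop("food circle must lie fully inside the arena", call. = FALSE)
  }
  structure(
    list(
      width_px = as.numeric(width_px), height_px = as.numeric(height_px),
      food_center = as.numeric(food_center), food_radius = as.numeric(food_radius),
      background_level = background_level, fly_level = fly_level
    ),
    class = "arena_spec"
  )
}

#' @export
print.arena_spec <- function(x, ...) {
  cat(sprintf(
    "<arena_spec> %g x %g px, food at (%g, %g) r = %g px\n",
    x$width_px, x$height_px, x$food_center[1], x$food_center[2], x$food_radius
  ))
  invisible(x)
}

#' Define the food region of interest
#'
#' A food ROI has two concentric circles: flies within `radius_on` of the
#' center count as on the food, flies between `radius_on` and `radius_near`
#' count as proximal ("near") to it. Both boundaries are closed (`<=`).
#' The proximal radius defaults to 1.5 times the on-food radius.
#'
#' @param center Numeric length-2 `(x, y)` in pixels.
#' @param radius_on On-food radius in pixels.
#' @param radius_near Proximal radius in pixels; must exceed `radius_on`.
#' @return An object of class `food_roi`.
#' @export
food_roi <- function(center, radius_on, radius_near = 1.5 * radius_on) {
  stopifnot(length(center) == 2, radius_on > 0)
  if (radius_near <= radius_on) {
    stop("`radius_near` must be greater than `radius_on`", call. = FALSE)
  }
  structure(
    list(center = as.numeric(center), radius_on = as.numeric(radius_on),
         radius_near = as.numeric(radius_near)),
    class = "food_roi"
  )
}

#' @export
print.food_roi <- function(x, ...) {
  cat(sprintf("<food_roi> center (%g, %g), on <= %g px, near <= %g px\n",
              x$center[1], x$center[2], x$radius_on, x$radius_near))
  invisible(x)
}

## Euclidean distance from points to the ROI/arena food center.
dist_to_point <- function(x, y, center) {
  sqrt((x - center[1])^2 + (y - center[2])^2)
}
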