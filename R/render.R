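#' Reference paint colors for marked flies
#'
#' Saturated reference colors used both when rendering painted flies and as
#' the default targets for color thresholding in [detect_painted()].
#'
#' @return A tibble with columns `label`, `r`, `g`, `b` (values in `[0, 1]`).
#' @export
paint_palette <- function() {
  tibble::tribble(
    ~label,   ~r,   ~g,   ~b,
    "blue",   0.0,  0.1,  1.0,
    "pink",   1.0,  0.3,  0.7,
    "green",  0.0,  0.9,  0.1,
    "orange", 1.0,  0.55, 0.0,
    "white",  1.0,  1.0,  1.0,
    "red",    1.0,  0.0,  0.0,
    "yellow", 1.0,  0.95, 0.0
  )
}

#' Render a synthetic scene to image frames plus a ground-truth table
#'
#' Draws each fly as a filled dark ellipse at its ground-truth pose on a
#' light background; painted flies additionally carry a small saturated
#' color disk at the body centroid (grayscale frames are promoted to RGB
#' whenever any fly is painted). Gaussian pixel noise is optional. One image
#' is produced per frame, together with a tidy row-per-fly-per-frame
#' ground-truth table suitable for scoring detections against.
#'
#' Image arrays are indexed `[row, col]` = `[y + 1, x + 1]` with 0-based
#' pixel-center coordinates, matching the detection stage.
#'
#' @param scene A [gen_scene()] result.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise
#'   (intensities are clipped back to `[0, 1]`).
#' @param dir Optional directory; when given, frames are written as
#'   zero-padded PNGs (`frame_0001.png`, ...) and the ground truth as
#'   `truth.tsv`.
#' @param paint_radius_px Radius of the paint disk, default 5 px.
#' @param seed Seed for the noise draw; defaults to the scene seed so a
#'   scene renders identically every time.
#' @return A list of class `rendered_scene` with `images` (list of numeric
#'   arrays), `truth` (tibble) and `files` (paths, when `dir` was given).
#' @export
render_frames <- function(scene, noise_sd = 0, dir = NULL,
                          paint_radius_px = 5, seed = scene$seed) {
  stopifnot(inherits(scene, "fly_scene"), noise_sd >= 0)
  arena <- scene$arena
  w <- as.integer(arena$width_px)
  h <- as.integer(arena$height_px)
  any_paint <- any(!is.na(scene$flies$paint))
  pal <- paint_palette()

  images <- with_seed(seed, {
    purrr::map(seq_len(scene$params$n_frames), function(f) {
      fr <- scene$flies[scene$flies$frame_index == f, ]
      img <- matrix(arena$background_level, nrow = h, ncol = w)
      for (i in seq_len(nrow(fr))) {
        px <- ellipse_pixels(fr$x[i], fr$y[i], fr$body_major[i] / 2,
                             fr$body_minor[i] / 2, fr$orientation[i], w, h)
        img[px] <- arena$fly_level
      }
      if (noise_sd > 0) {
        img <- img + matrix(stats::rnorm(h * w, 0, noise_sd), nrow = h)
        img <- pmin(pmax(img, 0), 1)
      }
      if (!any_paint) return(img)
      rgb <- array(img, dim = c(h, w, 3))
      painted <- fr[!is.na(fr$paint), , drop = FALSE]
      for (i in seq_len(nrow(painted))) {
        col <- pal[pal$label == painted$paint[i], ]
        px <- disk_pixels(painted$x[i], painted$y[i], paint_radius_px, w, h)
        for (ch in 1:3) {
          plane <- rgb[, , ch]
          plane[px] <- as.numeric(col[c("r", "g", "b")][[ch]])
          rgb[, , ch] <- plane
        }
      }
      rgb
    })
  })

  truth <- scene$flies
  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- purrr::map_chr(seq_along(images), function(f) {
      path <- file.path(dir, sprintf("frame_%04d.png", f))
      png::writePNG(images[[f]], path)
      path
    })
    write_table(truth, file.path(dir, "truth.tsv"))
    files <- c(files, file.path(dir, "truth.tsv"))
  }
  structure(list(images = images, truth = truth, files = files),
            class = "rendered_scene")
}

## Matrix of [row, col] indices whose 0-based pixel centers fall inside the
## ellipse with semi-axes a >= b at angle theta.
ellipse_pixels <- function(cx, cy, a, b, theta, w, h) {
  x0 <- max(0L, floor(cx - a)); x1 <- min(w - 1L, ceiling(cx + a))
  y0 <- max(0L, floor(cy - a)); y1 <- min(h - 1L, ceiling(cy + a))
  xs <- x0:x1; ys <- y0:y1
  gx <- rep(xs, times = length(ys)) - cx
  gy <- rep(ys, each = length(xs)) - cy
  u <- gx * cos(theta) + gy * sin(theta)
  v <- -gx * sin(theta) + gy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  cbind(rep(ys, each = length(xs))[inside] + 1L,
        rep(xs, times = length(ys))[inside] + 1L)
}

disk_pixels <- function(cx, cy, r, w, h) {
  ellipse_pixels(cx, cy, r, r, 0, w, h)
}

#' @export
print.rendered_scene <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("<rendered_scene> %d frame(s), %d x %d px%s\n",
              length(x$images), d[2], d[1],
              if (length(d) == 3) " (RGB)" else ""))
  invisible(x)
}
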