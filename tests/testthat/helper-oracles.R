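## Independent brute-force oracles, deliberately written as plain loops so
## they share no code path with the package implementations they check.

## Social space: nearest neighbor by explicit double loop, mutual pairs
## counted once, body-size normalization by pooled axis mean.
oracle_social_space <- function(x, y, major, minor) {
  n <- length(x)
  stopifnot(n >= 2)
  nnd <- rep(Inf, n)
  nni <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dij <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
      if (dij < nnd[i]) {
        nnd[i] <- dij
        nni[i] <- j
      }
    }
  }
  vals <- numeric(0)
  used <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (used[i]) next
    j <- nni[i]
    if (!used[j] && nni[j] == i) {
      vals <- c(vals, nnd[i])
      used[i] <- TRUE
      used[j] <- TRUE
    } else {
      vals <- c(vals, nnd[i])
      used[i] <- TRUE
    }
  }
  raw <- mean(vals)
  ext <- mean(c(major, minor))
  list(raw = raw, normalized = raw - ext, n_values = length(vals))
}

## Continuous-limit moment axes of a filled axis-aligned w x h rectangle
## and a disk of radius r: full axis = 4 * sqrt(second moment).
oracle_rect_axes <- function(w, h) {
  c(major = max(w, h) * 2 / sqrt(3), minor = min(w, h) * 2 / sqrt(3))
}
oracle_disk_axes <- function(r) c(major = 2 * r, minor = 2 * r)

## Connected dark components by explicit 8-neighborhood flood fill.
oracle_count_components <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  count <- 0L
  for (r0 in seq_len(h)) {
    for (c0 in seq_len(w)) {
      if (!mask[r0, c0] || seen[r0, c0]) next
      count <- count + 1L
      stack <- list(c(r0, c0))
      seen[r0, c0] <- TRUE
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (dr in -1:1) for (dc in -1:1) {
          rr <- p[1] + dr
          cc <- p[2] + dc
          if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
              mask[rr, cc] && !seen[rr, cc]) {
            seen[rr, cc] <- TRUE
            stack[[length(stack) + 1]] <- c(rr, cc)
          }
        }
      }
    }
  }
  count
}

## Hypergeometric upper-tail probability P(overlap >= k) for |A| draws from
## a universe containing |B| "successes".
oracle_hyper_tail <- function(k, size_a, size_b, universe) {
  sum(stats::dhyper(k:min(size_a, size_b), size_b, universe - size_b, size_a))
}

## Random single-frame detection table (no rendering involved).
random_frame <- function(n, seed, width = 1000) {
  set.seed(seed)
  tibble::tibble(
    frame_index = 1L,
    time_min = 0,
    centroid_x = stats::runif(n, 0, width),
    centroid_y = stats::runif(n, 0, width),
    major_axis = stats::runif(n, 10, 60),
    minor_axis = stats::runif(n, 4, 10),
    orientation = stats::runif(n, 0, pi),
    area_px = 100L, on_food = FALSE, near_food = FALSE,
    paint = NA_character_, merged_flag = FALSE
  )
}
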