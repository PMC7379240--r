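## Internal helpers shared across modules.

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG state. Every stochastic generator routes through this, which is what
## makes the generators pure functions of their arguments.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Full pairwise center-distance matrix for one frame; diagonal set to Inf
## so row minima are nearest-neighbor distances.
pairwise_nn <- function(x, y) {
  n <- length(x)
  d <- as.matrix(stats::dist(cbind(x, y)))
  diag(d) <- Inf
  d
}

## Per-fly nearest-neighbor distance and neighbor index.
nn_dist_index <- function(x, y) {
  d <- pairwise_nn(x, y)
  list(dist = unname(apply(d, 1, min)),
       index = unname(apply(d, 1, which.min)), d = d)
}

## Mean minimum nearest-neighbor distance with the mutual-pair rule: if two
## flies are each other's nearest neighbor, their shared distance enters the
## mean once. Used both by the generator's bookkeeping and (independently
## re-stated) by the analysis stage; the test suite holds the two to exact
## agreement.
mean_nn_mutual <- function(x, y) {
  n <- length(x)
  if (n < 2) stop("need at least 2 flies", call. = FALSE)
  nn <- nn_dist_index(x, y)
  vals <- numeric(0)
  counted <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (counted[i]) next
    j <- nn$index[i]
    if (nn$index[j] == i && !counted[j]) {
      vals <- c(vals, nn$dist[i])
      counted[i] <- TRUE
      counted[j] <- TRUE
    } else {
      vals <- c(vals, nn$dist[i])
      counted[i] <- TRUE
    }
  }
  mean(vals)
}

## Mean pooled body extent: the mean of all major and minor axis lengths in
## the frame, the quantity subtracted for body-size normalization.
mean_body_extent <- function(major, minor) {
  mean(c(major, minor))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
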