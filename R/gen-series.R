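#' Simulate an aggregation time series with tunable cooperativity
#'
#' Generates the arrival of flies onto a food source as a discrete-time
#' stochastic process: each fly still off the food arrives during a step of
#' length `dt_min` with hazard
#' `rate_per_min * (1 + n_on_food)^coop_exponent`, so `coop_exponent = 0`
#' gives density-independent (first-order) arrival kinetics and positive
#' exponents make occupied food increasingly attractive — the minimal
#' process exhibiting the cooperativity that the T-40 statistics are meant
#' to detect.
#'
#' Arrivals are coupled across calls through per-fly uniform draws fixed by
#' the seed: for the same seed, raising `coop_exponent` can only move each
#' fly's arrival earlier, which makes ordered comparisons across exponents
#' exact rather than merely statistical.
#'
#' @param total_flies Number of flies in the chamber (>= 1).
#' @param rate_per_min Baseline per-capita arrival hazard (1/min, >= 0).
#' @param coop_exponent Cooperativity exponent (>= 0 for attraction).
#' @param t_end_min,dt_min Duration and step of the series, minutes.
#' @param seed Integer seed.
#' @param replicate_id Label carried through to downstream averaging.
#' @return A tibble of class `aggregation_series` with columns `time_min`,
#'   `n_on`, `n_near`, `total_in_chamber`, `replicate_id`.
#' @examples
#' gen_aggregation_series(100, rate_per_min = 0.02, coop_exponent = 1,
#'                        t_end_min = 30, seed = 1)
#' @export
gen_aggregation_series <- function(total_flies, rate_per_min,
                                   coop_exponent = 0, t_end_min = 120,
                                   dt_min = 0.75, seed = 1,
                                   replicate_id = "r1") {
  stopifnot(total_flies >= 1, rate_per_min >= 0, coop_exponent >= 0,
            t_end_min > 0, dt_min > 0)
  n_steps <- ceiling(t_end_min / dt_min)
  times <- seq(0, by = dt_min, length.out = n_steps + 1)

  with_seed(seed, {
    u <- matrix(stats::runif(n_steps * total_flies), nrow = n_steps)
    arrived <- rep(FALSE, total_flies)
    n_on <- numeric(n_steps + 1)
    n_on[1] <- 0
    for (s in seq_len(n_steps)) {
      hazard <- rate_per_min * (1 + sum(arrived))^coop_exponent
      p_arrive <- 1 - exp(-hazard * dt_min)
      newly <- !arrived & u[s, ] < p_arrive
      arrived <- arrived | newly
      n_on[s + 1] <- sum(arrived)
    }
    out <- tibble::tibble(
      time_min = times,
      n_on = n_on,
      n_near = 0,
      total_in_chamber = as.integer(total_flies),
      replicate_id = replicate_id
    )
    class(out) <- c("aggregation_series", class(out))
    attr(out, "params") <- list(rate_per_min = rate_per_min,
                                coop_exponent = coop_exponent,
                                dt_min = dt_min, seed = as.integer(seed))
    out
  })
}
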