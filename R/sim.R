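#' Parameters for the cooperative food-search simulation
#'
#' Configures an agent-based model of flies searching a closed arena for a
#' circular food patch: each agent performs a correlated random walk in
#' bouts (turn, then move straight for an exponentially distributed bout
#' length), and the food exerts an attraction `A` that straightens turns
#' toward it. Attraction grows as the agent nears the food and — when
#' `cooperativity > 0` — with the number of flies already on the food, up
#' to a saturation count beyond which more flies add nothing:
#'
#' `A = clamp(a0 * exp(-dist / lambda) * (1 + c * min(n_on, n_sat)), 0, 1)`
#'
#' Time is unitless ticks; lengths are arbitrary units.
#'
#' @param arena_size Length-2 `(w, h)`.
#' @param food_center,food_radius Food patch geometry; must lie inside the
#'   arena.
#' @param n_flies Number of agents.
#' @param base_attractiveness `a0 >= 0`, attraction at distance 0 with an
#'   empty patch.
#' @param proximity_scale Length constant `lambda > 0` of the exponential
#'   proximity kernel.
#' @param cooperativity `c >= 0`; 0 turns the social term off entirely.
#' @param saturation_count `n_sat >= 1`, on-food count at which the social
#'   term saturates.
#' @param bout_length_mean Mean straight-run length between turns.
#' @param turn_sd_free Turning-angle SD (radians) of an unattracted agent.
#' @param step_length Distance moved per tick.
#' @param max_ticks Simulation horizon.
#' @param sticky_food Do arrived agents stay on the food (default TRUE)?
#' @param seed Integer seed.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(arena_size = c(400, 400),
                       food_center = c(200, 200), food_radius = 25,
                       n_flies = 100, base_attractiveness = 0.25,
                       proximity_scale = 120, cooperativity = 0.4,
                       saturation_count = 12, bout_length_mean = 8,
                       turn_sd_free = 2, step_length = 3,
                       max_ticks = 3000, sticky_food = TRUE, seed = 1) {
  p <- list(
    arena_size = as.numeric(arena_size), food_center = as.numeric(food_center),
    food_radius = as.numeric(food_radius), n_flies = as.integer(n_flies),
    base_attractiveness = base_attractiveness,
    proximity_scale = proximity_scale, cooperativity = cooperativity,
    saturation_count = saturation_count, bout_length_mean = bout_length_mean,
    turn_sd_free = turn_sd_free, step_length = step_length,
    max_ticks = as.integer(max_ticks), sticky_food = isTRUE(sticky_food),
    seed = as.integer(seed)
  )
  stopifnot(p$n_flies >= 1, p$base_attractiveness >= 0,
            p$proximity_scale > 0, p$cooperativity >= 0,
            p$saturation_count >= 1, p$turn_sd_free > 0,
            p$step_length > 0, p$max_ticks >= 1,
            p$food_radius > 0, all(p$arena_size > 0))
  if (p$food_center[1] - p$food_radius < 0 ||
      p$food_center[1] + p$food_radius > p$arena_size[1] ||
      p$food_center[2] - p$food_radius < 0 ||
      p$food_center[2] + p$food_radius > p$arena_size[2]) {
    stop("food circle must lie inside the arena", call. = FALSE)
  }
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    "<sim_params> %d flies, arena %g x %g, a0 = %g, lambda = %g, c = %g (n_sat = %d)\n",
    x$n_flies, x$arena_size[1], x$arena_size[2], x$base_attractiveness,
    x$proximity_scale, x$cooperativity, x$saturation_count))
  invisible(x)
}

#' Food attractiveness felt by a searching agent
#'
#' `A = clamp(a0 * exp(-dist / lambda) * (1 + c * min(n_on_food, n_sat)), 0, 1)`.
#' With `cooperativity = 0` the social factor is identically 1, so the
#' on-food count has no effect; with any `c`, counts at or beyond the
#' saturation count are equivalent.
#'
#' @param dist_to_food Distance(s) from the food edge-center, `>= 0`.
#' @param n_on_food Current number of flies on the food.
#' @param p A [sim_params()].
#' @return Attractiveness value(s) in `[0, 1]`.
#' @export
attractiveness <- function(dist_to_food, n_on_food, p) {
  stopifnot(all(dist_to_food >= 0))
  social <- 1 + p$cooperativity * pmin(n_on_food, p$saturation_count)
  pmin(pmax(p$base_attractiveness * exp(-dist_to_food / p$proximity_scale) *
              social, 0), 1)
}

## Vectorized one-tick update over all active agents. state is a list of
## parallel vectors; rng comes from the calling environment's stream.
step_agents <- function(state, p, n_on_food) {
  active <- if (p$sticky_food) !state$arrived else rep(TRUE, length(state$x))
  if (!any(active)) return(state)

  ## agents whose bout is exhausted re-draw bout length and heading
  redraw <- active & state$remaining_bout <= 0
  if (any(redraw)) {
    idx <- which(redraw)
    d <- sqrt((state$x[idx] - p$food_center[1])^2 +
                (state$y[idx] - p$food_center[2])^2)
    A <- attractiveness(pmax(d - p$food_radius, 0), n_on_food, p)
    eps <- stats::rnorm(length(idx), 0, p$turn_sd_free * (1 - A))
    h_free <- state$heading[idx] + eps
    h_food <- atan2(p$food_center[2] - state$y[idx],
                    p$food_center[1] - state$x[idx])
    ## circular blend of the noisy free heading toward the food bearing
    state$heading[idx] <- atan2((1 - A) * sin(h_free) + A * sin(h_food),
                                (1 - A) * cos(h_free) + A * cos(h_food))
    state$remaining_bout[idx] <- stats::rexp(length(idx),
                                             rate = 1 / p$bout_length_mean)
  }

  idx <- which(active)
  state$x[idx] <- state$x[idx] + p$step_length * cos(state$heading[idx])
  state$y[idx] <- state$y[idx] + p$step_length * sin(state$heading[idx])
  state$remaining_bout[idx] <- state$remaining_bout[idx] - p$step_length

  ## reflecting walls
  w <- p$arena_size[1]; h <- p$arena_size[2]
  lo_x <- state$x < 0; hi_x <- state$x > w
  state$x[lo_x] <- -state$x[lo_x]; state$x[hi_x] <- 2 * w - state$x[hi_x]
  state$heading[lo_x | hi_x] <- pi - state$heading[lo_x | hi_x]
  lo_y <- state$y < 0; hi_y <- state$y > h
  state$y[lo_y] <- -state$y[lo_y]; state$y[hi_y] <- 2 * h - state$y[hi_y]
  state$heading[lo_y | hi_y] <- -state$heading[lo_y | hi_y]
  state
}

#' Advance one agent by one tick
#'
#' Single-agent wrapper over the simulator's update rule, mostly useful for
#' inspecting the walk model: an agent mid-bout moves `step_length` along
#' its heading; an agent whose bout is exhausted draws a fresh exponential
#' bout length and a new heading — its previous heading plus turning noise
#' of SD `turn_sd_free * (1 - A)`, blended circularly toward the food
#' bearing with weight `A`. Walls reflect.
#'
#' @param s List with `x`, `y`, `heading`, `remaining_bout`, `arrived`.
#' @param A Attractiveness override; `NULL` (default) computes it from the
#'   agent's position and `n_on_food`.
#' @param p A [sim_params()].
#' @param n_on_food On-food count used when computing `A`.
#' @return The updated agent state, with `arrived` set when the agent is
#'   within the food radius.
#' @export
step_agent <- function(s, A = NULL, p = sim_params(), n_on_food = 0) {
  state <- list(x = s$x, y = s$y, heading = s$heading,
                remaining_bout = s$remaining_bout,
                arrived = isTRUE(s$arrived))
  if (!is.null(A)) {
    ## fixed-A variant: substitute a kernel that returns the given A
    p2 <- p
    p2$base_attractiveness <- A
    p2$proximity_scale <- Inf
    p2$cooperativity <- 0
    state <- step_agents(state, p2, n_on_food)
  } else {
    state <- step_agents(state, p, n_on_food)
  }
  d <- sqrt((state$x - p$food_center[1])^2 + (state$y - p$food_center[2])^2)
  state$arrived <- state$arrived | d <= p$food_radius
  state
}

#' Run the cooperative food-search simulation
#'
#' Agents start uniformly at random outside the food patch and walk in
#' synchronous ticks; the on-food occupancy is recomputed every tick and
#' fed back into the attractiveness, which is what couples the searchers
#' when cooperativity is on. An agent arriving within the food radius is
#' marked arrived (and frozen there when `sticky_food`). T-40 is the first
#' tick at which at least 40% of the agents have arrived, undefined (`NA`)
#' if never within `max_ticks`.
#'
#' @param p A [sim_params()].
#' @param t40_fraction Arrival fraction defining T-40 (default 0.4).
#' @return An object of class `sim_result`: `arrival_ticks` (per agent,
#'   `NA` if it never arrived), `occupancy` tibble (`tick`, `n_on_food`),
#'   `t40_ticks`, `params`.
#' @examples
#' res <- run_simulation(sim_params(n_flies = 20, max_ticks = 500, seed = 2))
#' glance(res)
#' @export
run_simulation <- function(p, t40_fraction = 0.4) {
  stopifnot(inherits(p, "sim_params"))
  with_seed(p$seed, {
    n <- p$n_flies
    ## uniform start positions outside the food
    x <- y <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        cand <- stats::runif(2) * p$arena_size
        if (sqrt(sum((cand - p$food_center)^2)) > p$food_radius) break
      }
      x[i] <- cand[1]; y[i] <- cand[2]
    }
    state <- list(
      x = x, y = y,
      heading = stats::runif(n, -pi, pi),
      remaining_bout = rep(0, n),
      arrived = rep(FALSE, n)
    )
    arrival_tick <- rep(NA_integer_, n)
    d0 <- sqrt((x - p$food_center[1])^2 + (y - p$food_center[2])^2)
    state$arrived <- d0 <= p$food_radius
    arrival_tick[state$arrived] <- 0L

    occ <- integer(p$max_ticks + 1)
    occ[1] <- sum(state$arrived)
    target <- t40_fraction * n
    t40 <- if (occ[1] >= target) 0L else NA_integer_

    for (tick in seq_len(p$max_ticks)) {
      state <- step_agents(state, p, n_on_food = occ[tick])
      d <- sqrt((state$x - p$food_center[1])^2 +
                  (state$y - p$food_center[2])^2)
      newly <- !state$arrived & d <= p$food_radius
      state$arrived <- state$arrived | newly
      arrival_tick[newly] <- tick
      occ[tick + 1] <- sum(state$arrived)
      if (is.na(t40) && occ[tick + 1] >= target) t40 <- tick
      if (p$sticky_food && all(state$arrived)) {
        occ <- occ[seq_len(tick + 1)]
        break
      }
    }
    structure(
      list(arrival_ticks = arrival_tick,
           occupancy = tibble::tibble(tick = seq_along(occ) - 1L,
                                      n_on_food = occ),
           t40_ticks = t40, params = p),
      class = "sim_result"
    )
  })
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "<sim_result> %d flies, %d arrived, T-40 = %s ticks\n",
    x$params$n_flies, sum(!is.na(x$arrival_ticks)),
    if (is.na(x$t40_ticks)) "undefined" else x$t40_ticks))
  invisible(x)
}

#' Sweep fly density for cooperative and diffusive search
#'
#' Runs the simulation over a range of densities, `reps` independent
#' replicates each, under two conditions: cooperative (the template's
#' `cooperativity`, which must be > 0) and diffusive (`cooperativity = 0`,
#' the free-search control). Per density and condition the mean and SD of
#' T-40 are reported over the replicates in which T-40 was defined;
#' undefined runs are counted separately and excluded from the mean.
#' Replicates use consecutive seeds derived from the template seed.
#'
#' @param p_template A [sim_params()]; `n_flies` is overridden per density.
#' @param densities Integer vector of chamber densities (default 25–200 by
#'   25).
#' @param reps Replicates per density and condition.
#' @return Tibble of class `density_sweep`: `density`, `condition`,
#'   `mean_t40`, `sd_t40` (`NA` when fewer than 2 defined runs),
#'   `n_defined`, `n_runs`.
#' @export
density_sweep <- function(p_template, densities = seq(25, 200, by = 25),
                          reps = 100) {
  stopifnot(inherits(p_template, "sim_params"), reps >= 1,
            p_template$cooperativity > 0)
  grid <- tidyr::expand_grid(
    condition = c("cooperative", "diffusive"),
    density = as.integer(densities)
  )
  out <- purrr::pmap_dfr(grid, function(condition, density) {
    t40s <- purrr::map_int(seq_len(reps), function(r) {
      p <- p_template
      p$n_flies <- density
      p$cooperativity <- if (condition == "cooperative") {
        p_template$cooperativity
      } else 0
      p$seed <- p_template$seed + 7919L * match(condition, c("cooperative", "diffusive")) +
        31L * which(densities == density) * reps + r
      res <- run_simulation(p)
      res$t40_ticks %||% NA_integer_
    })
    def <- t40s[!is.na(t40s)]
    tibble::tibble(
      density = density, condition = condition,
      mean_t40 = if (length(def)) mean(def) else NA_real_,
      sd_t40 = if (length(def) >= 2) stats::sd(def) else NA_real_,
      n_defined = length(def), n_runs = reps
    )
  })
  class(out) <- c("density_sweep", class(out))
  out
}
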