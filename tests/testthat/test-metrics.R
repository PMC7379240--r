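mk_series <- function(times, n_on, total, id = "r1") {
  s <- tibble::tibble(time_min = times, n_on = n_on, n_near = 0,
                      total_in_chamber = as.integer(total), replicate_id = id)
  class(s) <- c("aggregation_series", class(s))
  s
}

test_that("aggregation curves average replicates with the right SEM", {
  t <- seq(0, 10, by = 1)
  a <- mk_series(t, rep(20, 11), 100, "a")
  b <- mk_series(t, rep(40, 11), 100, "b")
  cv <- aggregation_curve(list(a, b))
  expect_equal(cv$mean_fraction_on, rep(0.3, 11))
  expect_equal(cv$sem_fraction_on, rep(0.1, 11))  # sd(0.2, 0.4)/sqrt(2)

  same <- aggregation_curve(list(a, a, a))
  expect_equal(same$sem_fraction_on, rep(0, 11))

  single <- aggregation_curve(list(a))
  expect_true(all(is.na(single$sem_fraction_on)))
})

test_that("T-40 takes the first sampled time at the closed threshold", {
  t <- seq(0, 60, by = 0.75)
  n <- pmin(100, t * 1.5)
  s <- mk_series(t, n, 100)
  ## first sampled n_on >= 40 occurs at the first grid point past 40/1.5
  expect_equal(t40(s)$t40_min, t[which(n >= 40)[1]])

  never <- mk_series(t, pmin(35, t), 100)
  expect_true(is.na(t40(never)$t40_min))

  exact <- mk_series(c(0, 10, 20), c(0, 40, 80), 100)
  expect_equal(t40(exact)$t40_min, 10)   # >= is inclusive

  ## earlier arrivals can only decrease or preserve T-40
  s_late <- mk_series(c(0, 10, 20, 30), c(0, 10, 40, 60), 100)
  s_early <- mk_series(c(0, 10, 20, 30), c(0, 40, 40, 60), 100)
  expect_lte(t40(s_early)$t40_min, t40(s_late)$t40_min)
})

test_that("cooperativity coefficient is the OLS slope of T-40 on density", {
  pts <- data.frame(density = c(25, 50, 75, 100),
                    t40_min = c(100, 80, 60, 40))
  fit <- cooperativity_coefficient(pts)
  expect_equal(fit$slope, -0.8, tolerance = 1e-12)   # -2500/3125 by hand
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  const <- cooperativity_coefficient(
    data.frame(density = c(25, 50, 75), t40_min = c(30, 30, 30)))
  expect_equal(const$slope, 0, tolerance = 1e-12)

  two <- cooperativity_coefficient(
    data.frame(density = c(50, 100), t40_min = c(60, 20)))
  expect_equal(two$slope, (20 - 60) / 50)
  expect_equal(two$r_squared, 1)

  ## undefined T-40 densities are excluded before fitting
  with_na <- cooperativity_coefficient(
    data.frame(density = c(25, 50, 75, 100),
               t40_min = c(NA, 80, 60, 40)))
  expect_equal(with_na$densities_used, c(50, 75, 100))
  expect_error(
    cooperativity_coefficient(data.frame(density = 25, t40_min = 10)),
    class = "socialfly_insufficient_data")

  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "density"], -0.8, tolerance = 1e-12)
  expect_equal(glance(fit)$n_densities, 4)
})

test_that("social space applies the mutual-pair rule and normalization", {
  two <- tibble::tibble(frame_index = 1L,
                        centroid_x = c(0, 20), centroid_y = c(0, 0),
                        major_axis = 10, minor_axis = 4)
  res <- social_space(two)
  expect_equal(res$raw_px, 20)
  expect_equal(res$mean_body_extent_px, 7)   # (10+4+10+4)/4
  expect_equal(res$normalized_px, 13)

  tri <- tibble::tibble(frame_index = 1L,
                        centroid_x = c(0, 1, 3), centroid_y = 0,
                        major_axis = 1, minor_axis = 1)
  ## NN distances {1 (mutual, once), 2} -> raw = 1.5
  expect_equal(social_space(tri)$raw_px, 1.5)

  same <- tibble::tibble(frame_index = 1L, centroid_x = c(5, 5, 5),
                         centroid_y = 5, major_axis = 10, minor_axis = 4)
  expect_equal(social_space(same)$raw_px, 0)
  expect_lt(social_space(same)$normalized_px, 0)

  expect_error(social_space(two[1, ]), class = "socialfly_insufficient_data")
})

test_that("social space equals the brute-force oracle on 1,000 random frames", {
  for (i in 1:1000) {
    n <- sample(2:50, 1)
    fr <- random_frame(n, seed = i)
    res <- social_space(fr)
    o <- oracle_social_space(fr$centroid_x, fr$centroid_y,
                             fr$major_axis, fr$minor_axis)
    expect_identical(res$raw_px, o$raw)
    expect_identical(res$normalized_px, o$normalized)
  }
})

test_that("density binning is half-open and anchored at 5", {
  fr <- tibble::tibble(n_flies = c(18, 18, 18, 25),
                       normalized_px = c(10, 12, 14, 99),
                       frame_index = 1:4)
  prof <- density_binned_social_space(fr)
  b15 <- prof[prof$bin_lo == 15, ]
  expect_equal(b15$mean_normalized_px, 12)
  expect_equal(b15$n_frames, 3)
  expect_true(25 %in% prof$bin_lo)   # n = 25 goes to the next bin

  band <- social_space_band(fr, 15, 25)
  expect_equal(band$n_frames, 4)
})

test_that("Z-score positioning is the per-fly distribution statistic", {
  ## 4 flies on a line: NN distances 10, 10, 10, 20 (no dedup for Z-scores)
  fr <- tibble::tibble(
    frame_index = 1L, time_min = 0,
    centroid_x = c(0, 10, 20, 40), centroid_y = 0,
    major_axis = 5, minor_axis = 2,
    paint = c("blue", NA, NA, NA)
  )
  zs <- zscore_positioning(fr, sd_mode = "population")
  d <- c(10, 10, 10, 20)
  expect_equal(zs$z, (10 - mean(d)) / (stats::sd(d) * sqrt(3 / 4)))

  ## painted fly at the frame mean gives z = 0
  fr2 <- tibble::tibble(
    frame_index = 1L, time_min = 0,
    centroid_x = c(0, 10, 20), centroid_y = 0,
    major_axis = 5, minor_axis = 2, paint = c(NA, "blue", NA)
  )
  ## NN distances are 10, 10, 10 -> sd 0 -> frame skipped
  zs2 <- zscore_positioning(fr2)
  expect_equal(nrow(zs2), 0)
  expect_equal(attr(zs2, "skipped"), 1L)
})

test_that("exchangeable painted flies have Z-scores centered at zero", {
  ar <- arena_spec(700, 700, food_radius = 90)
  ## exchangeability: paint a uniformly random fly, not a structurally
  ## distinguished one (the first-placed fly sits deeper in the cluster)
  set.seed(99)
  ids <- sample.int(8, 220, replace = TRUE)
  zs <- vapply(1:220, function(seed) {
    sc <- gen_scene(ar, n_flies = 8, spacing_px = 35,
                    painted_ids = ids[seed],
                    seed = seed, body_major = 20, body_minor = 8)
    zscore_positioning(truth_as_detections(sc))$z
  }, numeric(1))
  se <- stats::sd(zs) / sqrt(length(zs))
  expect_lt(abs(mean(zs)), 3 * se)
})

test_that("food preference fractions and the all-on-food summary", {
  roi <- food_roi(c(0, 0), 10, 20)
  fr <- tibble::tibble(
    frame_index = rep(1:2, c(10, 4)),
    centroid_x = c(rep(5, 6), rep(15, 2), rep(50, 2), rep(5, 4)),
    centroid_y = 0
  )
  fp <- food_preference(fr, roi)
  expect_equal(fp$fraction_on, c(0.6, 1))
  expect_equal(fp$fraction_near, c(0.2, 0))
  expect_equal(attr(fp, "fraction_all_on"), 0.5)
})

test_that("rank-sum comparison: exact enumeration and approximation agree with references", {
  r <- rank_sum_compare(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1 / 3)   # 2 * (1/6) over all 6 orderings

  expect_equal(rank_sum_compare(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(rank_sum_compare(numeric(0), 1), "non-empty")

  ## approximation path matches the tie-corrected normal reference
  set.seed(1)
  a <- rpois(15, 5); b <- rpois(15, 5)
  mine <- rank_sum_compare(a, b)
  ref <- suppressWarnings(stats::wilcox.test(a, b, correct = FALSE,
                                             exact = FALSE))
  expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-9)
  expect_equal(mine$statistic, unname(ref$statistic))
})

test_that("exact rank-sum test holds its size under the null", {
  n1 <- 6; n2 <- 6
  ## exact attainable rejection rate at alpha = 0.05 from the enumerated null
  combos <- utils::combn(n1 + n2, n1)
  u_all <- colSums(matrix(rank(1:(n1 + n2))[combos], nrow = n1)) -
    n1 * (n1 + 1) / 2
  p_of_u <- vapply(u_all, function(u) {
    min(1, 2 * min(mean(u_all <= u), mean(u_all >= u)))
  }, numeric(1))
  exact_rate <- mean(p_of_u <= 0.05)

  set.seed(42)
  rej <- mean(replicate(2000, {
    rank_sum_compare(stats::rnorm(n1), stats::rnorm(n2))$p_value <= 0.05
  }))
  ci_half <- 3 * sqrt(exact_rate * (1 - exact_rate) / 2000)
  expect_lt(abs(rej - exact_rate), ci_half)
  expect_lte(exact_rate, 0.05)
})

test_that("aggression-density regression reports slope and R^2 per group", {
  const <- tibble::tibble(lunges_150s = rep(4, 6),
                          density_at_arrival = c(10, 20, 30, 40, 50, 60))
  f1 <- aggression_density_regression(const)
  expect_equal(f1$slope, 0)
  expect_equal(f1$r_squared, 0)

  lin <- tibble::tibble(lunges_150s = 2 * c(10, 20, 30, 40),
                        density_at_arrival = c(10, 20, 30, 40))
  expect_equal(aggression_density_regression(lin)$r_squared, 1)

  set.seed(3)
  rnd <- tibble::tibble(lunges_150s = sample(0:20, 12, TRUE),
                        density_at_arrival = sample(10:80, 12),
                        condition = rep(c("social", "naive"), each = 6))
  fits <- aggression_density_regression(rnd)
  for (g in c("social", "naive")) {
    gd <- rnd[rnd$condition == g, ]
    fit <- fits[fits$condition == g, ]
    res <- gd$lunges_150s -
      (fit$intercept + fit$slope * gd$density_at_arrival)
    r2 <- 1 - sum(res^2) / sum((gd$lunges_150s - mean(gd$lunges_150s))^2)
    expect_equal(fit$r_squared, r2, tolerance = 1e-9)
  }
  expect_error(aggression_density_regression(lin[1:2, ]),
               class = "socialfly_insufficient_data")
})
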