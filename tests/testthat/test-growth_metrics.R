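test_that("interval velocities normalize by the interval length", {
  cards <- as_cards(make_card("A", dates = as.Date("2012-01-01") + c(0, 14),
                              muac = c(100, 104), weight = c(5.0, 5.2)),
                    make_card("B", dates = as.Date("2012-02-01") + c(0, 7),
                              muac = c(110, 110), weight = c(5.0, 5.35)))
  obs <- interval_changes(cards)
  # two-week change divided in half to reflect one-week change
  expect_equal(obs$muac_velocity[obs$card_id == "A"], 2.0)
  # 350 g over 7 days on 5.0 kg = 10 g/kg/day
  expect_equal(obs$weight_gain_rate[obs$card_id == "B"], 10.0)
  # no change -> both velocities zero
  flat <- as_cards(make_card("C", muac = c(110, 110), weight = c(5, 5)))
  o <- interval_changes(flat)
  expect_equal(o$muac_velocity, 0)
  expect_equal(o$weight_gain_rate, 0)
})

test_that("halving every interval and every change leaves velocities unchanged", {
  base <- as.Date("2012-01-01")
  full <- as_cards(make_card("A", dates = base + c(0, 14, 28),
                             muac = c(100, 104, 108),
                             weight = c(5.0, 5.3, 5.6)))
  # same trajectory sampled twice as often with half the change per step
  half <- as_cards(make_card("A", dates = base + c(0, 7, 14, 21, 28),
                             muac = c(100, 102, 104, 106, 108),
                             weight = c(5.0, 5.15, 5.3, 5.45, 5.6)))
  v_full <- interval_changes(full)$muac_velocity
  v_half <- interval_changes(half)$muac_velocity
  expect_equal(unique(round(v_full, 10)), unique(round(v_half, 10)))
})

test_that("the smoother reproduces constants and linear functions exactly", {
  set.seed(1)
  x <- runif(60, 100, 130)
  for (k in c("epanechnikov", "uniform", "gaussian")) {
    sc <- local_poly_smooth(x, rep(3.5, 60), grid = 101:129, kernel = k,
                            bandwidth = 4, degree = 0)
    expect_equal(sc$estimate, rep(3.5, 29), tolerance = 1e-10)
  }
  y <- 2 - 0.05 * x
  sc <- local_poly_smooth(x, y, grid = 101:129, bandwidth = 3, degree = 1)
  expect_equal(sc$estimate, 2 - 0.05 * (101:129), tolerance = 1e-8)
})

test_that("degree-0 uniform smoothing equals a brute-force windowed mean", {
  set.seed(2)
  x <- runif(20, 0, 50)
  y <- rnorm(20)
  grid <- seq(5, 45, by = 2.5)
  sc <- local_poly_smooth(x, y, grid = grid, kernel = "uniform",
                          bandwidth = 5, degree = 0)
  oracle <- vapply(grid, function(g) {
    inside <- abs(x - g) <= 5
    if (!any(inside)) NA_real_ else mean(y[inside])
  }, numeric(1))
  expect_equal(sc$estimate, oracle, tolerance = 1e-12)
})

test_that("grid points with no mass are missing; singular designs fall back", {
  sc <- local_poly_smooth(c(1, 1.1, 8), c(2, 2.2, 5), grid = c(1, 4.5, 8),
                          kernel = "uniform", bandwidth = 1, degree = 1)
  expect_true(is.na(sc$estimate[2]))        # empty window
  expect_false(is.na(sc$estimate[3]))       # single point: degree-0 fallback
  expect_equal(sc$estimate[3], 5)
})

test_that("the trend test is invariant to affine transforms of a curve", {
  g <- 100:120
  s <- 2 - 0.03 * (g - 100) + 0.2 * cos(g / 4)
  a <- list(grid = g, estimate = s)
  b <- list(grid = g, estimate = 3 * s + 7)   # affine image of a
  tt <- normalized_difference_trend_test(a, b)
  expect_equal(tt$slope, 0, tolerance = 1e-12)
  expect_false(tt$significant)
})

test_that("an exactly linear normalized difference is always significant", {
  g <- 100:120
  up <- (g - 100) / 20                      # normalizes to itself
  down <- 1 - up
  tt <- normalized_difference_trend_test(list(grid = g, estimate = up),
                                         list(grid = g, estimate = down))
  expect_lt(tt$p_value, 1e-10)
  expect_true(tt$significant)
})

test_that("trend-test slope matches a hand-computed OLS slope on 5 points", {
  g <- c(100, 105, 110, 115, 120)
  a <- list(grid = g, estimate = c(0, 0.2, 0.7, 0.9, 1.0))
  b <- list(grid = g, estimate = c(0, 0.4, 0.5, 0.8, 1.0))
  # both curves already span [0,1] so normalization is the identity
  d <- a$estimate - b$estimate
  slope_hand <- sum((g - mean(g)) * (d - mean(d))) / sum((g - mean(g))^2)
  tt <- normalized_difference_trend_test(a, b)
  expect_equal(tt$slope, slope_hand, tolerance = 1e-12)
})

test_that("a constant curve normalizes to 0.5 with a log note", {
  g <- 100:110
  expect_message(
    tt <- normalized_difference_trend_test(
      list(grid = g, estimate = rep(2, 11)),
      list(grid = g, estimate = seq(1, 2, length.out = 11))),
    "constant")
  expect_true(is.finite(tt$slope))
})

test_that("velocity regression recovers exact linear slopes and is permutation-invariant", {
  obs <- data.frame(prior_muac = seq(100, 130, length.out = 40))
  obs$muac_velocity <- 2 - 0.06 * (obs$prior_muac - 105)
  r <- velocity_regression(obs, "muac_velocity")
  expect_equal(r$slope, -0.06, tolerance = 1e-12)
  perm <- obs[sample.int(40), ]
  expect_equal(velocity_regression(perm, "muac_velocity")$slope, r$slope)
})

test_that("velocity regression matches a hand-computed slope on 10 points", {
  x <- c(100, 103, 106, 109, 112, 115, 118, 121, 124, 127)
  y <- c(2.1, 1.8, 1.9, 1.6, 1.4, 1.5, 1.1, 1.0, 0.8, 0.9)
  slope_hand <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  r <- velocity_regression(data.frame(prior_muac = x, muac_velocity = y))
  expect_equal(r$slope, slope_hand, tolerance = 1e-12)
  expect_lt(r$p_value, 0.001)
})

test_that("resampled trend analysis is seed-reproducible and degrades gracefully", {
  cfg <- generator_config(n_per_country = 40, rng_seed = 31)
  obs <- eligible_observations(generate_cohort(cfg))
  t1 <- suppressMessages(resample_trend_analysis(obs, per_country = 100,
                                                 replicates = 5, seed = 2))
  t2 <- suppressMessages(resample_trend_analysis(obs, per_country = 100,
                                                 replicates = 5, seed = 2))
  expect_identical(t1, t2)
  # per_country larger than a stratum: reported, not an error
  expect_message(resample_trend_analysis(obs, per_country = 1e6,
                                         replicates = 2, seed = 2),
                 "using all available")
  # empty stratum is an error naming the country
  expect_error(muacdose:::stratified_sample_idx(
    data.frame(country = factor("Kenya", levels = c("Kenya", "Chad")),
               card_id = "x"), 10), "Chad")
})

test_that("a noise-free affine-linked cohort yields zero trend slope", {
  cfg <- noise_free_config(n_per_country = 30)
  obs <- eligible_observations(generate_cohort(cfg, seed = 17))
  tt <- suppressMessages(resample_trend_analysis(obs, per_country = 200,
                                                 replicates = 3, seed = 4))
  expect_lt(max(abs(tt$slopes)), 1e-9)
})
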