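# Interval-normalized growth velocities, local polynomial smoothing,
# the normalized-difference trend test and the country-stratified
# resampling harness.

#' Interval-normalized growth velocities
#'
#' One observation per consecutive visit pair with both MUAC and weight
#' present at both ends. MUAC velocity is the MUAC change divided by the
#' interval length in weeks (a two-week change is halved to a one-week
#' change); proportional weight gain is grams gained per kilogram of
#' prior-visit weight per day. Change is assumed constant across the
#' interval; each interval contributes a single observation regardless of
#' its length.
#'
#' @param cards A `patient_cards` data frame.
#' @return Data frame of class `interval_obs`: `card_id`, `country`,
#'   `facility`, `sex`, `age_months` (age at the interval's start),
#'   `visit_date` (interval end), `prior_muac` (mm), `prior_weight` (kg),
#'   `interval_days`, `muac_velocity` (mm/week), `weight_gain_rate`
#'   (g/kg/day).
#' @export
interval_changes <- function(cards) {
  df <- as.data.frame(cards)
  n <- nrow(df)
  if (n < 2L) return(empty_interval_obs())
  i2 <- which(c(FALSE, df$card_id[-1L] == df$card_id[-n]))
  i1 <- i2 - 1L
  days <- as.numeric(df$visit_date[i2] - df$visit_date[i1])
  ok <- is_true(days >= 1) &
    !is.na(df$muac_mm[i1]) & !is.na(df$muac_mm[i2]) &
    !is.na(df$weight_kg[i1]) & !is.na(df$weight_kg[i2])
  i1 <- i1[ok]; i2 <- i2[ok]; days <- days[ok]
  adm_date <- stats::ave(as.numeric(df$visit_date), df$card_id,
                         FUN = function(d) min(d, na.rm = TRUE))
  age_at <- df$age_months[i1] +
    floor((as.numeric(df$visit_date[i1]) - adm_date[i1]) / DAYS_PER_MONTH)
  out <- data.frame(
    card_id = df$card_id[i1], country = df$country[i1],
    facility = df$facility[i1], sex = df$sex[i1],
    age_months = age_at, visit_date = df$visit_date[i2],
    prior_muac = df$muac_mm[i1], prior_weight = df$weight_kg[i1],
    interval_days = days,
    muac_velocity = (df$muac_mm[i2] - df$muac_mm[i1]) / (days / 7),
    weight_gain_rate = (df$weight_kg[i2] - df$weight_kg[i1]) * 1000 /
      df$weight_kg[i1] / days,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("interval_obs", "data.frame")
  out
}

empty_interval_obs <- function() {
  out <- data.frame(card_id = character(0), country = character(0),
                    facility = character(0), sex = character(0),
                    age_months = numeric(0),
                    visit_date = as.Date(character(0)),
                    prior_muac = numeric(0), prior_weight = numeric(0),
                    interval_days = numeric(0), muac_velocity = numeric(0),
                    weight_gain_rate = numeric(0), stringsAsFactors = FALSE)
  class(out) <- c("interval_obs", "data.frame")
  out
}

kernel_fn <- function(kernel) {
  switch(kernel,
         epanechnikov = function(u) ifelse(abs(u) <= 1, 0.75 * (1 - u^2), 0),
         uniform = function(u) ifelse(abs(u) <= 1, 0.5, 0),
         triangle = function(u) ifelse(abs(u) <= 1, 1 - abs(u), 0),
         gaussian = function(u) stats::dnorm(u),
         stop("unknown kernel: ", kernel, call. = FALSE))
}

#' Rule-of-thumb bandwidth for local polynomial smoothing
#'
#' Plug-in rule: a global quartic fit supplies the curvature estimate and
#' residual variance, giving
#' `h = C(K) * (sigma^2 * range(x) / sum(m''(x_i)^2))^(1/5)` with the
#' kernel constant `C` (1.719 for Epanechnikov). To preserve band-level
#' resolution the result is capped at one-eighth of the x-range, and floored
#' at half the mean x-spacing.
#'
#' @param x,y Observation vectors.
#' @param kernel Kernel name.
#' @return Bandwidth in x units.
#' @export
rot_bandwidth <- function(x, y, kernel = "epanechnikov") {
  n <- length(x)
  rng <- diff(range(x))
  fallback <- max(rng / 8, 1e-8)
  if (n < 10L || rng <= 0) return(fallback)
  fit <- stats::lm(y ~ poly(x, degree = 4, raw = TRUE))
  co <- stats::coef(fit)
  co[is.na(co)] <- 0
  sigma2 <- sum(stats::residuals(fit)^2) / max(stats::df.residual(fit), 1L)
  m2 <- 2 * co[3] + 6 * co[4] * x + 12 * co[5] * x^2
  denom <- sum(m2^2)
  C <- switch(kernel, epanechnikov = 1.719, uniform = 1.351,
              triangle = 1.888, gaussian = 0.776, 1.719)
  if (!is.finite(denom) || denom < 1e-12 || sigma2 <= 0) return(fallback)
  h <- C * (sigma2 * rng / denom)^(1 / 5)
  min(max(h, rng / (2 * n)), rng / 8)
}

#' Local polynomial kernel smoothing
#'
#' At each grid point `g`, fits a weighted polynomial of the configured
#' degree to `(x, y)` with kernel weights `K((x - g)/h)` and returns the
#' fitted value at `g`. Grid points with no kernel weight yield `NA`. A
#' singular local design (all x identical within the bandwidth with
#' degree >= 1) falls back to a local constant fit at that point.
#'
#' @param x Covariate values (prior-visit MUAC, mm).
#' @param y Response values (a growth velocity).
#' @param grid Evaluation points; defaults to integer mm spanning `x`.
#' @param kernel `"epanechnikov"` (default), `"uniform"`, `"triangle"` or
#'   `"gaussian"`.
#' @param bandwidth Kernel half-width in x units; default [rot_bandwidth()].
#' @param degree Local polynomial degree (default 0, a kernel-weighted
#'   moving average).
#' @return Object of class `smooth_curve`: list with `grid`, `estimate`,
#'   `bandwidth`, `kernel`, `degree`, `n`.
#' @export
local_poly_smooth <- function(x, y, grid = NULL,
                              kernel = c("epanechnikov", "uniform",
                                         "triangle", "gaussian"),
                              bandwidth = NULL, degree = 0) {
  kernel <- match.arg(kernel)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  assert_that(length(x) >= degree + 1,
              "need at least degree + 1 observations")
  if (is.null(grid)) grid <- seq(ceiling(min(x)), floor(max(x)), by = 1)
  bandwidth <- bandwidth %||% rot_bandwidth(x, y, kernel)
  assert_that(bandwidth > 0, "bandwidth must be positive")
  K <- kernel_fn(kernel)
  est <- vapply(grid, function(g) {
    w <- K((x - g) / bandwidth)
    if (sum(w) <= 0) return(NA_real_)
    use <- w > 0
    xg <- x[use] - g
    if (degree == 0 || length(unique(xg)) <= degree) {
      # local constant (also the fallback for a singular local design)
      sum(w[use] * y[use]) / sum(w[use])
    } else {
      X <- outer(xg, 0:degree, `^`)
      fit <- stats::lm.wfit(X, y[use], w[use])
      if (is.na(fit$coefficients[1L]))
        sum(w[use] * y[use]) / sum(w[use])
      else fit$coefficients[1L]
    }
  }, numeric(1))
  structure(list(grid = as.numeric(grid), estimate = est,
                 bandwidth = bandwidth, kernel = kernel, degree = degree,
                 n = length(x)),
            class = "smooth_curve")
}

#' @export
print.smooth_curve <- function(x, ...) {
  cat(sprintf("Local polynomial smooth: degree %d, %s kernel, bandwidth %.3g, n = %d\n",
              x$degree, x$kernel, x$bandwidth, x$n))
  cat(sprintf("  grid [%g, %g] (%d points), estimate range [%.3g, %.3g]\n",
              min(x$grid), max(x$grid), length(x$grid),
              min(x$estimate, na.rm = TRUE), max(x$estimate, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.smooth_curve <- function(x, ..., xlab = "MUAC at prior visit (mm)",
                              ylab = "Smoothed estimate", type = "l") {
  graphics::plot(x$grid, x$estimate, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Band average of a smoothed curve
#'
#' Mean of the smoothed estimates at grid points in the closed-open band
#' `[band[1], band[2])`, ignoring `NA` grid points.
#'
#' @param curve A `smooth_curve`.
#' @param band Length-2 numeric band in x units.
#' @return Scalar mean.
#' @export
band_average <- function(curve, band) {
  sel <- curve$grid >= band[1] & curve$grid < band[2]
  mean(curve$estimate[sel], na.rm = TRUE)
}

# Min-max normalization to [0, 1]; a constant curve maps to 0.5.
minmax_normalize <- function(v) {
  rng <- range(v)
  if (!is.finite(diff(rng)) || diff(rng) < .Machine$double.eps) {
    message("minmax_normalize: constant curve, normalized value set to 0.5")
    return(rep(0.5, length(v)))
  }
  (v - rng[1]) / diff(rng)
}

#' Trend test on the difference of two normalized curves
#'
#' Min-max normalizes both curves' estimates to [0, 1] over their shared
#' grid, regresses the normalized difference on the grid by ordinary least
#' squares, and returns the slope with the F-test p-value for the slope
#' term. Grid points where either curve is `NA` are dropped.
#'
#' @param curveA,curveB `smooth_curve` objects on identical grids.
#' @param level Significance level used for the `significant` field.
#' @return List: `slope`, `p_value`, `significant`, `n_grid`.
#' @export
normalized_difference_trend_test <- function(curveA, curveB, level = 0.05) {
  assert_that(length(curveA$grid) == length(curveB$grid) &&
                all(curveA$grid == curveB$grid),
              "curves must share an identical grid")
  ok <- is.finite(curveA$estimate) & is.finite(curveB$estimate)
  g <- curveA$grid[ok]
  assert_that(length(g) >= 3L, "need at least 3 shared grid points")
  d <- minmax_normalize(curveA$estimate[ok]) -
    minmax_normalize(curveB$estimate[ok])
  fit <- stats::lm(d ~ g)
  slope <- unname(stats::coef(fit)[2L])
  rss <- sum(stats::residuals(fit)^2)
  mss <- sum((stats::fitted(fit) - mean(d))^2)
  p <- if (rss < 1e-20 * max(mss, 1)) {
    if (abs(slope) > 1e-12) 0 else 1
  } else {
    stats::anova(fit)[["Pr(>F)"]][1L]
  }
  list(slope = slope, p_value = p, significant = is_true(p < level),
       n_grid = length(g))
}

#' OLS regression of a growth velocity on prior MUAC
#'
#' Fits `velocity ~ prior_muac` by ordinary least squares and returns the
#' signed slope (mm/week per mm, or g/kg/day per mm) with the F-test
#' p-value.
#'
#' @param observations An `interval_obs` data frame.
#' @param response `"muac_velocity"` or `"weight_gain_rate"`.
#' @return List: `slope`, `p_value`, `n`.
#' @export
velocity_regression <- function(observations,
                                response = c("muac_velocity",
                                             "weight_gain_rate")) {
  response <- match.arg(response)
  x <- observations$prior_muac
  y <- observations[[response]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  assert_that(length(x) >= 3L && length(unique(x)) >= 2L,
              "need >= 3 observations with distinct prior MUAC")
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  rss <- sum(stats::residuals(fit)^2)
  p <- if (rss < 1e-20) {
    if (abs(slope) > 1e-12) 0 else 1
  } else {
    stats::anova(fit)[["Pr(>F)"]][1L]
  }
  list(slope = slope, p_value = p, n = length(x))
}

# Draw a country-stratified subsample of observation row indices.
# unit = "visits": sample rows without replacement within country;
# unit = "cards": sample card ids without replacement, keep their rows.
stratified_sample_idx <- function(observations, per_country, unit = "visits") {
  idx_by_country <- split(seq_len(nrow(observations)), observations$country)
  empty <- names(idx_by_country)[lengths(idx_by_country) == 0L]
  if (length(empty) > 0L) {
    stop("empty country stratum: ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  unlist(lapply(idx_by_country, function(rows) {
    if (unit == "cards") {
      ids <- unique(observations$card_id[rows])
      take <- if (length(ids) <= per_country) ids else
        sample(ids, per_country)
      rows[observations$card_id[rows] %in% take]
    } else {
      if (length(rows) <= per_country) rows else sample(rows, per_country)
    }
  }), use.names = FALSE)
}

#' Country-stratified resampled trend analysis
#'
#' Per replicate: draws `per_country` observations from each country
#' without replacement (countries with fewer contribute all they have,
#' reported once via `message()`), smooths MUAC velocity and proportional
#' weight gain against prior MUAC on a shared integer-mm grid restricted to
#' `muac_range`, and runs [normalized_difference_trend_test()]. Results
#' aggregate into mean/min/max slope and the fraction of replicates
#' non-significant at `level`.
#'
#' @param observations An `interval_obs` data frame.
#' @param per_country Observations drawn per country (default 1000).
#' @param replicates Number of replicates (default 100).
#' @param muac_range Closed-open MUAC range for the comparison grid.
#' @param seed RNG seed.
#' @param level Significance level (default 0.05).
#' @param kernel,bandwidth,degree Smoother settings.
#' @param unit Sampling unit, `"visits"` (default) or `"cards"`.
#' @return Object of class `trend_test_result`: per-replicate `slopes` and
#'   `p_values`, plus `mean_slope`, `min_slope`, `max_slope`,
#'   `frac_nonsignificant`, `level`, `replicates`.
#' @export
resample_trend_analysis <- function(observations, per_country = 1000,
                                    replicates = 100,
                                    muac_range = c(100, 125), seed = 1L,
                                    level = 0.05,
                                    kernel = "epanechnikov",
                                    bandwidth = NULL, degree = 0,
                                    unit = c("visits", "cards")) {
  unit <- match.arg(unit)
  counts <- table(observations$country)
  short <- names(counts)[counts < per_country]
  if (length(short) > 0L) {
    message("resample_trend_analysis: stratum smaller than per_country, using all available: ",
            paste(short, collapse = ", "))
  }
  grid <- seq(muac_range[1], muac_range[2] - 1, by = 1)
  with_seed(seed, {
    slopes <- numeric(replicates)
    p_values <- numeric(replicates)
    for (r in seq_len(replicates)) {
      idx <- stratified_sample_idx(observations, per_country, unit)
      sub <- observations[idx, , drop = FALSE]
      cm <- local_poly_smooth(sub$prior_muac, sub$muac_velocity, grid = grid,
                              kernel = kernel, bandwidth = bandwidth,
                              degree = degree)
      cw <- local_poly_smooth(sub$prior_muac, sub$weight_gain_rate,
                              grid = grid, kernel = kernel,
                              bandwidth = bandwidth, degree = degree)
      tt <- normalized_difference_trend_test(cm, cw, level = level)
      slopes[r] <- tt$slope
      p_values[r] <- tt$p_value
    }
    structure(list(slopes = slopes, p_values = p_values,
                   mean_slope = mean(slopes), min_slope = min(slopes),
                   max_slope = max(slopes),
                   frac_nonsignificant = mean(p_values >= level),
                   level = level, replicates = replicates,
                   per_country = per_country, muac_range = muac_range),
              class = "trend_test_result")
  })
}

#' @export
print.trend_test_result <- function(x, ...) {
  cat(sprintf("Normalized-difference trend test over MUAC [%g, %g): %d replicates\n",
              x$muac_range[1], x$muac_range[2], x$replicates))
  cat(sprintf("  slope mean %.4g (range %.4g to %.4g)\n",
              x$mean_slope, x$min_slope, x$max_slope))
  cat(sprintf("  non-significant at level %.2g in %.0f%% of replicates\n",
              x$level, 100 * x$frac_nonsignificant))
  invisible(x)
}
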