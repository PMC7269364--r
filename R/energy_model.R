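# Per-visit energy needs and band-wise percentile dosage derivation.
#
# Energy needed to support the growth observed over an interval:
#   need (kcal/day) = prior weight (kg) * maintenance (kcal/kg/day)
#                   + daily gain (g/day) * tissue cost (kcal/g)
# with maintenance 82 kcal/kg/day and tissue deposition 5 kcal/g. The
# prior-visit weight anchors both terms (it is the same weight that
# normalizes the proportional gain). Negative gains contribute negatively
# and are never clamped.

#' Energy-model constants
#'
#' @param maintenance Resting energy need, kcal per kg body weight per day
#'   (default 82).
#' @param tissue_cost Energy cost of adding one gram of tissue, kcal/g
#'   (default 5).
#' @return Object of class `energy_params`.
#' @export
energy_params <- function(maintenance = 82, tissue_cost = 5) {
  assert_that(maintenance > 0 && tissue_cost > 0,
              "energy parameters must be strictly positive")
  structure(list(maintenance = maintenance, tissue_cost = tissue_cost),
            class = "energy_params")
}

#' Daily energy need of an interval observation
#'
#' @param obs An `interval_obs` data frame (columns `prior_weight` and
#'   `weight_gain_rate`), or a list with those fields.
#' @param params An [energy_params()].
#' @return Numeric vector of kcal/day, one per observation.
#' @examples
#' daily_energy_need(list(prior_weight = 6, weight_gain_rate = 4))  # 612
#' @export
daily_energy_need <- function(obs, params = energy_params()) {
  w <- obs$prior_weight
  assert_that(all(is_true(w > 0)), "prior_weight must be positive")
  daily_gain_g <- obs$weight_gain_rate * w
  as.numeric(w * params$maintenance + daily_gain_g * params$tissue_cost)
}

#' Attach energy needs to interval observations
#'
#' @inheritParams daily_energy_need
#' @return `obs` with a `need_kcal` column, classed `energy_estimates`.
#' @export
energy_estimates <- function(obs, params = energy_params()) {
  obs$need_kcal <- daily_energy_need(obs, params)
  class(obs) <- unique(c("energy_estimates", class(obs)))
  obs
}

band_labels <- function(lo, width, x) {
  band_lo <- lo + width * floor((x - lo) / width)
  sprintf("[%g,%g)", band_lo, band_lo + width)
}

#' Band-wise energy-need percentiles
#'
#' Empirical percentile of per-visit energy needs within closed-open MUAC
#' bands (keyed by prior-visit MUAC) tiling `window`, optionally split by a
#' subgroup column. Percentiles use linear interpolation between closest
#' ranks (R quantile type 7). Bands with no visits are omitted, with a
#' `message()`.
#'
#' @param estimates An `energy_estimates` data frame.
#' @param band_width Band width in mm (default 5).
#' @param level Percentile level in (0, 1) (default 0.95).
#' @param groupby Optional name of a column in `estimates` to stratify by.
#' @param window Closed-open MUAC window to tile (default `c(100, 125)`,
#'   the protocol design range).
#' @return Data frame of class `band_percentile_table`: `band`, `band_lo`,
#'   `band_hi`, `group`, `n`, `level`, `kcal`.
#' @export
band_percentile <- function(estimates, band_width = 5, level = 0.95,
                            groupby = NULL, window = c(100, 125)) {
  assert_that(level > 0 && level < 1, "level must lie in (0,1)")
  keep <- is_true(estimates$prior_muac >= window[1] &
                    estimates$prior_muac < window[2])
  df <- estimates[keep, , drop = FALSE]
  band_lo <- window[1] + band_width * floor((df$prior_muac - window[1]) /
                                              band_width)
  group <- if (is.null(groupby)) rep("all", nrow(df)) else
    as.character(df[[groupby]])
  all_lo <- seq(window[1], window[2] - band_width, by = band_width)
  cells <- expand.grid(band_lo = all_lo,
                       group = unique(stats::na.omit(group)),
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- is_true(band_lo == cells$band_lo[i]) & is_true(group == cells$group[i])
    n <- sum(sel)
    if (n == 0L) return(NULL)
    data.frame(band = sprintf("[%g,%g)", cells$band_lo[i],
                              cells$band_lo[i] + band_width),
               band_lo = cells$band_lo[i],
               band_hi = cells$band_lo[i] + band_width,
               group = cells$group[i], n = n, level = level,
               kcal = unname(stats::quantile(df$need_kcal[sel], level,
                                             type = 7)),
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0L) {
    message(sprintf("band_percentile: %d empty band/group cell(s) omitted",
                    dropped))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(band = character(0),
                                      band_lo = numeric(0),
                                      band_hi = numeric(0),
                                      group = character(0), n = integer(0),
                                      level = numeric(0), kcal = numeric(0))
  rownames(out) <- NULL
  class(out) <- c("band_percentile_table", "data.frame")
  out
}

#' Subgroup comparison of band percentiles
#'
#' Runs [band_percentile()] stratified by admission MUAC category
#' (`< 115` vs `115 to <125` mm at the card's first visit; bands restricted
#' to the MUAC range such children share, 110 to <125 mm), by continent, or
#' by age group (6-23 vs 24-59 months at the interval).
#'
#' @param estimates An `energy_estimates` data frame.
#' @param scheme `"admission_muac"`, `"continent"` or `"age_group"`.
#' @param continent_map Named country -> continent vector.
#' @inheritParams band_percentile
#' @return A `band_percentile_table` with `group` set by the scheme.
#' @export
subgroup_comparison <- function(estimates,
                                scheme = c("admission_muac", "continent",
                                           "age_group"),
                                continent_map = default_continent_map(),
                                band_width = 5, level = 0.95,
                                window = c(100, 125)) {
  scheme <- match.arg(scheme)
  df <- estimates
  if (scheme == "admission_muac") {
    adm <- stats::ave(df$prior_muac, df$card_id, FUN = function(x) x[1L])
    df$.group <- ifelse(adm < 115, "admitted <115mm", "admitted 115-<125mm")
    df$.group[adm >= 125] <- NA_character_
    window <- c(max(window[1], 110), window[2])
  } else if (scheme == "continent") {
    df$.group <- map_continent(df$country, continent_map)
  } else {
    df$.group <- ifelse(df$age_months < 24, "6-23m", "24-59m")
  }
  band_percentile(df, band_width = band_width, level = level,
                  groupby = ".group", window = window)
}
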