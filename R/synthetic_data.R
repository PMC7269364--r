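# Synthetic patient-card cohorts.
#
# Children enter a therapeutic (TFP, SAM) or supplementary (SFP, MAM) feeding
# program and are measured at (two-)weekly clinic visits until their MUAC
# reaches the discharge threshold. Growth is driven by MUAC-dependent mean
# velocity functions with additive per-interval Gaussian noise, so the true
# generating curves are known and every downstream stage can be checked by
# parameter recovery.

#' Velocity-function presets
#'
#' `fig2_anchor` interpolates linearly between two anchors — weekly MUAC
#' velocity 2.0 mm/week at MUAC 105 mm and 1.0 mm/week at 122.5 mm;
#' proportional weight gain 3.9 g/kg/day at 105 mm and 2.4 g/kg/day at
#' 122.5 mm — and extrapolates flat beyond them (band means give no
#' functional form outside the anchors). `linear_slope` is globally linear
#' with slopes -0.06 mm/week per mm and -0.05 g/kg/day per mm, anchored at
#' MUAC 105 mm to the same 2.0 / 3.9 levels.
#'
#' @param name `"fig2_anchor"` or `"linear_slope"`.
#' @return List with functions `muac_velocity_fn(muac)` (mm/week) and
#'   `weight_gain_fn(muac)` (g/kg/day).
#' @export
velocity_preset <- function(name = c("fig2_anchor", "linear_slope")) {
  name <- match.arg(name)
  anchor_interp <- function(x1, y1, x2, y2) {
    force(x1); force(y1); force(x2); force(y2)
    function(muac) {
      m <- pmin(pmax(muac, x1), x2)
      y1 + (y2 - y1) * (m - x1) / (x2 - x1)
    }
  }
  linear_fn <- function(y0, slope, x0 = 105) {
    force(y0); force(slope); force(x0)
    function(muac) y0 + slope * (muac - x0)
  }
  switch(name,
    fig2_anchor = list(
      name = name,
      muac_velocity_fn = anchor_interp(105, 2.0, 122.5, 1.0),
      weight_gain_fn = anchor_interp(105, 3.9, 122.5, 2.4)),
    linear_slope = list(
      name = name,
      muac_velocity_fn = linear_fn(2.0, -0.06),
      weight_gain_fn = linear_fn(3.9, -0.05)))
}

#' Synthetic-cohort generator configuration
#'
#' Defaults reproduce the study-population structure of a five-country
#' CMAM program sample: age-group mix 29/40/18/13% across 6-11, 12-23,
#' 24-35 and 36-59 months, 54% female, country-specific TFP/SFP admission
#' mix, weekly (TFP) or two-weekly (SFP) visit spacing, TFP admissions at
#' MUAC 100 to <115 mm and SFP admissions at 115 to <125 mm, and discharge
#' once MUAC reaches 125 mm.
#'
#' @param n_per_country Cards per country (scalar or named vector).
#' @param countries Country labels.
#' @param tfp_fraction Named fraction of cards admitted to TFP per country.
#' @param age_group_probs Mix over age groups 6-11/12-23/24-35/36-59 months.
#' @param female_fraction Fraction female.
#' @param admission_muac_tfp,admission_muac_sfp Integer mm support (and
#'   optional `probs` attribute) of the admission-MUAC distributions.
#' @param preset Name of a [velocity_preset()], used when the velocity
#'   functions are not supplied directly.
#' @param muac_velocity_fn,weight_gain_fn Mean velocity functions; override
#'   the preset when given.
#' @param sd_muac_change SD (mm) of the additive noise on each between-visit
#'   MUAC change; default 2 mm, the order of MUAC tape measurement error.
#' @param sd_weight_change SD (kg) of the additive noise on each
#'   between-visit weight change; default 0.1 kg, the card recording
#'   precision.
#' @param visit_interval_days Named vector, days between visits (TFP 7,
#'   SFP 14).
#' @param missed_visit_prob Probability that a scheduled visit is missed, in
#'   which case the interval doubles (default 0.1; a modelling choice, visit
#'   irregularity of the source programs is not reported).
#' @param discharge_muac MUAC (mm) at or above which a child is discharged
#'   as recovered (default 125).
#' @param max_visits Cap on visits per card; cards hitting it are censored
#'   with status `"other"`.
#' @param nonresponse_fraction Fraction of cards that default before
#'   recovery (status `"other"`), exercising the outcome-eligibility filter.
#' @param oedema_missing_prob,oedema_present_prob Marginal probabilities of
#'   a missing or positive admission oedema code.
#' @param rng_seed Default seed used by [generate_cohort()].
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_per_country = 250,
                             countries = c("Kenya", "Pakistan", "Chad",
                                           "Yemen", "South Sudan"),
                             tfp_fraction = c("Kenya" = 0.28, "Pakistan" = 0.14,
                                              "Chad" = 0.27, "Yemen" = 0.24,
                                              "South Sudan" = 1.0),
                             age_group_probs = c(0.29, 0.40, 0.18, 0.13),
                             female_fraction = 0.54,
                             admission_muac_tfp = 100:114,
                             admission_muac_sfp = 115:124,
                             preset = "fig2_anchor",
                             muac_velocity_fn = NULL, weight_gain_fn = NULL,
                             sd_muac_change = 2.0, sd_weight_change = 0.1,
                             visit_interval_days = c(TFP = 7, SFP = 14),
                             missed_visit_prob = 0.1,
                             discharge_muac = 125, max_visits = 40,
                             nonresponse_fraction = 0.05,
                             oedema_missing_prob = 0.26,
                             oedema_present_prob = 0.002,
                             rng_seed = 1L) {
  if (length(n_per_country) == 1L) {
    n_per_country <- stats::setNames(rep(n_per_country, length(countries)),
                                     countries)
  }
  assert_that(all(countries %in% names(n_per_country)),
              "n_per_country must cover every country")
  assert_that(all(n_per_country >= 0) && sum(n_per_country[countries]) > 0,
              "cohort must contain at least one card")
  assert_that(all(countries %in% names(tfp_fraction)),
              "tfp_fraction must cover every country")
  assert_that(all(tfp_fraction >= 0 & tfp_fraction <= 1),
              "tfp_fraction must lie in [0,1]")
  assert_that(abs(sum(age_group_probs) - 1) < 1e-9 && all(age_group_probs >= 0),
              "age_group_probs must be a probability vector")
  assert_that(female_fraction >= 0 && female_fraction <= 1,
              "female_fraction must lie in [0,1]")
  assert_that(sd_muac_change >= 0 && sd_weight_change >= 0,
              "noise SDs must be non-negative")
  assert_that(all(visit_interval_days >= 1), "visit interval must be >= 1 day")
  assert_that(missed_visit_prob >= 0 && missed_visit_prob < 1,
              "missed_visit_prob must lie in [0,1)")
  assert_that(all(admission_muac_tfp >= 100 & admission_muac_tfp < 115),
              "TFP admission MUAC support must lie in [100,115)")
  assert_that(all(admission_muac_sfp >= 115 & admission_muac_sfp < 125),
              "SFP admission MUAC support must lie in [115,125)")
  fns <- velocity_preset(preset)
  muac_velocity_fn <- muac_velocity_fn %||% fns$muac_velocity_fn
  weight_gain_fn <- weight_gain_fn %||% fns$weight_gain_fn
  assert_that(all(is.finite(muac_velocity_fn(seq(65, 200, by = 5)))) &&
                all(is.finite(weight_gain_fn(seq(65, 200, by = 5)))),
              "velocity functions must be finite on [65, 200] mm")
  structure(list(n_per_country = n_per_country[countries],
                 countries = countries,
                 tfp_fraction = tfp_fraction,
                 age_group_probs = age_group_probs,
                 female_fraction = female_fraction,
                 admission_muac_tfp = admission_muac_tfp,
                 admission_muac_sfp = admission_muac_sfp,
                 preset = preset,
                 muac_velocity_fn = muac_velocity_fn,
                 weight_gain_fn = weight_gain_fn,
                 sd_muac_change = sd_muac_change,
                 sd_weight_change = sd_weight_change,
                 visit_interval_days = visit_interval_days,
                 missed_visit_prob = missed_visit_prob,
                 discharge_muac = discharge_muac,
                 max_visits = max_visits,
                 nonresponse_fraction = nonresponse_fraction,
                 oedema_missing_prob = oedema_missing_prob,
                 oedema_present_prob = oedema_present_prob,
                 rng_seed = as.integer(rng_seed)),
            class = "generator_config")
}

# Admission weight (kg): log-normal conditioned on age group, calibrated so
# most children under 24 months fall under 8 kg (malnourished cohorts run
# 2-3 kg below healthy medians).
draw_admission_weight <- function(age_group) {
  mu <- c("6-11" = 5.4, "12-23" = 6.9, "24-35" = 8.4, "36-59" = 10.2)
  sdlog <- 0.13
  w <- stats::rlnorm(length(age_group),
                     meanlog = log(mu[age_group]) - sdlog^2 / 2, sdlog = sdlog)
  round(pmax(w, 3.0), 1)
}

#' Generate a synthetic patient-card cohort
#'
#' Each card is simulated forward from its admission state:
#' `MUAC(t+d) = MUAC(t) + v(MUAC(t)) * d/7 + noise` and
#' `weight(t+d) = weight(t) * (1 + g(MUAC(t)) * d/1000) + noise`,
#' where `v` is the mean MUAC velocity (mm/week), `g` the mean proportional
#' weight gain (g/kg/day) and `d` the realized visit interval in days.
#' Cards end at the discharge rule (status `"recovered"`), at early default
#' or at the visit cap (status `"other"`). The same seed reproduces the
#' cohort bitwise.
#'
#' @param config A [generator_config()].
#' @param seed RNG seed; defaults to `config$rng_seed`.
#' @return A `patient_cards` data frame.
#' @export
generate_cohort <- function(config, seed = config$rng_seed) {
  assert_that(inherits(config, "generator_config"),
              "config must be a generator_config")
  with_seed(seed, {
    n_c <- config$n_per_country
    country <- rep(names(n_c), times = n_c)
    n <- length(country)
    facility <- ifelse(stats::runif(n) < config$tfp_fraction[country],
                       "TFP", "SFP")
    sex <- ifelse(stats::runif(n) < config$female_fraction, "F", "M")
    groups <- c("6-11", "12-23", "24-35", "36-59")
    age_group <- sample(groups, n, replace = TRUE,
                        prob = config$age_group_probs)
    age_lo <- c("6-11" = 6, "12-23" = 12, "24-35" = 24, "36-59" = 36)
    age_hi <- c("6-11" = 11, "12-23" = 23, "24-35" = 35, "36-59" = 59)
    age_months <- age_lo[age_group] +
      floor(stats::runif(n) * (age_hi[age_group] - age_lo[age_group] + 1))
    draw_adm <- function(support, k) {
      probs <- attr(support, "probs") %||% rep(1 / length(support),
                                               length(support))
      support[sample.int(length(support), k, replace = TRUE, prob = probs)]
    }
    muac <- numeric(n)
    muac[facility == "TFP"] <- draw_adm(config$admission_muac_tfp,
                                        sum(facility == "TFP"))
    muac[facility == "SFP"] <- draw_adm(config$admission_muac_sfp,
                                        sum(facility == "SFP"))
    weight <- draw_admission_weight(age_group)
    u <- stats::runif(n)
    oedema <- rep("absent", n)
    oedema[u < config$oedema_missing_prob] <- NA_character_
    oedema[u >= config$oedema_missing_prob &
             u < config$oedema_missing_prob + config$oedema_present_prob] <- "present"
    admit_date <- as.Date("2012-01-01") + floor(stats::runif(n) * 365)
    dropout <- stats::runif(n) < config$nonresponse_fraction
    # dropouts leave after a uniformly drawn visit count >= 2
    dropout_after <- ifelse(dropout, 2L + floor(stats::runif(n) * 5), NA_integer_)

    card_id <- sprintf("%s-%05d", abbreviate(country, 3), seq_len(n))
    interval_base <- config$visit_interval_days[facility]

    rows <- vector("list", config$max_visits)
    active <- rep(TRUE, n)
    status <- rep("other", n)
    visit_no <- 1L
    date <- admit_date
    repeat {
      idx <- which(active)
      rows[[visit_no]] <- data.frame(
        card_id = card_id[idx], country = country[idx],
        facility = facility[idx], sex = sex[idx],
        age_months = as.numeric(age_months[idx]), visit_date = date[idx],
        muac_mm = muac[idx], weight_kg = weight[idx],
        height_cm = NA_real_, oedema = oedema[idx],
        discharge_status = NA_character_, stringsAsFactors = FALSE)
      discharged <- active & muac >= config$discharge_muac
      status[discharged] <- "recovered"
      active[discharged] <- FALSE
      active[active & !is.na(dropout_after) & visit_no >= dropout_after] <- FALSE
      if (visit_no >= config$max_visits || !any(active)) break
      idx <- which(active)
      d <- interval_base[idx] *
        ifelse(stats::runif(length(idx)) < config$missed_visit_prob, 2, 1)
      step_mu <- config$muac_velocity_fn(muac[idx]) * d / 7
      step_wt <- weight[idx] * config$weight_gain_fn(muac[idx]) * d / 1000
      noise_mu <- if (config$sd_muac_change > 0)
        stats::rnorm(length(idx), 0, config$sd_muac_change) else 0
      noise_wt <- if (config$sd_weight_change > 0)
        stats::rnorm(length(idx), 0, config$sd_weight_change) else 0
      muac[idx] <- pmax(muac[idx] + step_mu + noise_mu, 66)
      weight[idx] <- pmax(weight[idx] + step_wt + noise_wt, 1.0)
      date[idx] <- date[idx] + d
      visit_no <- visit_no + 1L
    }
    df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    df$discharge_status <- status[match(df$card_id, card_id)]
    first_seen <- match(df$card_id, unique(card_id))
    df <- df[order(first_seen, df$visit_date), , drop = FALSE]
    new_patient_cards(df)
  })
}

#' Inject implausible records into a cohort
#'
#' Corrupts a copy of `cards` to exercise the usability and plausibility
#' filters, and returns a manifest listing every corruption. Measurement
#' corruptions (`muac_spike`, `weight_jump`, `muac_range`) are applied to
#' the final visit of a card so each corruption implicates exactly one
#' visit record; card-level corruptions remove follow-up visits or blank
#' age, sex or a visit date.
#'
#' @param cards A `patient_cards` data frame.
#' @param rates Named list/vector of per-card corruption probabilities with
#'   any of: `muac_spike` (MUAC change > 15 mm/week), `weight_jump`
#'   (> 25 g/kg/day), `muac_range` (MUAC outside 65-200 mm), `missing_age`,
#'   `missing_sex`, `missing_date`, `no_followup`.
#' @param seed RNG seed.
#' @return The corrupted `patient_cards` with attribute `"manifest"`: a data
#'   frame with columns `card_id`, `visit_date` (`NA` for card-level
#'   corruptions) and `type`.
#' @export
inject_errors <- function(cards, rates = list(), seed = 1L) {
  types <- c("muac_spike", "weight_jump", "muac_range",
             "missing_age", "missing_sex", "missing_date", "no_followup")
  r <- stats::setNames(rep(0, length(types)), types)
  rates <- unlist(rates)
  assert_that(all(names(rates) %in% types),
              paste("unknown error type; expected one of:",
                    paste(types, collapse = ", ")))
  assert_that(all(rates >= 0 & rates <= 1), "rates must lie in [0,1]")
  r[names(rates)] <- rates
  df <- as.data.frame(cards)
  ids <- unique(df$card_id)
  manifest <- list()
  with_seed(seed, {
    draws <- matrix(stats::runif(length(ids) * length(types)) <
                      rep(r, each = length(ids)),
                    nrow = length(ids), dimnames = list(ids, types))
    keep <- rep(TRUE, nrow(df))
    for (i in seq_along(ids)) {
      id <- ids[i]
      rows <- which(df$card_id == id)
      note <- function(type, date = as.Date(NA)) {
        manifest[[length(manifest) + 1L]] <<- data.frame(
          card_id = id, visit_date = date, type = type,
          stringsAsFactors = FALSE)
      }
      truncated <- FALSE
      if (draws[i, "no_followup"] && length(rows) >= 2L) {
        keep[rows[-1L]] <- FALSE
        rows <- rows[1L]
        truncated <- TRUE
        note("no_followup")
      }
      if (draws[i, "missing_age"]) { df$age_months[rows] <- NA_real_; note("missing_age") }
      if (draws[i, "missing_sex"]) { df$sex[rows] <- NA_character_; note("missing_sex") }
      if (draws[i, "missing_date"] && !truncated && length(rows) >= 2L) {
        # blank an interior visit date; card becomes unusable
        j <- rows[1L + sample.int(length(rows) - 1L, 1L)]
        df$visit_date[j] <- as.Date(NA)
        note("missing_date")
      }
      if (!truncated && length(rows) >= 2L) {
        last <- rows[length(rows)]
        prev <- rows[length(rows) - 1L]
        days <- as.numeric(df$visit_date[last] - df$visit_date[prev])
        if (is.finite(days) && days >= 1) {
          if (draws[i, "muac_spike"]) {
            df$muac_mm[last] <- df$muac_mm[prev] +
              (16 + stats::runif(1) * 9) * days / 7
            note("muac_spike", df$visit_date[last])
          }
          if (draws[i, "weight_jump"]) {
            df$weight_kg[last] <- df$weight_kg[prev] * (1 + 30 * days / 1000)
            note("weight_jump", df$visit_date[last])
          }
          if (draws[i, "muac_range"] && !draws[i, "muac_spike"]) {
            df$muac_mm[last] <- sample(c(50, 250), 1L)
            note("muac_range", df$visit_date[last])
          }
        }
      }
    }
    df <- df[keep, , drop = FALSE]
  })
  out <- new_patient_cards(df)
  manifest <- if (length(manifest) > 0L) do.call(rbind, manifest) else
    data.frame(card_id = character(0), visit_date = as.Date(character(0)),
               type = character(0), stringsAsFactors = FALSE)
  attr(out, "manifest") <- manifest
  out
}
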