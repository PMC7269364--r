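# Usability, biological-plausibility and outcome-eligibility filters.
#
# Three layers, applied in order in the pipeline:
#   1. card usability  — at least one follow-up visit; age, sex and all
#      visit dates present;
#   2. visit plausibility — wide anthropometric bounds (z-scores, raw MUAC
#      range) and between-visit change limits that flag likely measurement
#      or recording errors;
#   3. card outcome eligibility — discharged as recovered with non-negative
#      MUAC gain and the program-specific minimum relative weight gain.
# Finally the analysis window keeps interval observations whose prior-visit
# MUAC lies in the configured range.

#' Card usability
#'
#' A card is unusable if it has no follow-up visits (fewer than two visits)
#' or is missing age, sex or any visit date.
#'
#' @param cards A `patient_cards` data frame.
#' @return Data frame with one row per card: `card_id`, `no_followup`,
#'   `missing_age_sex_date`, `usable`.
#' @export
card_usable <- function(cards) {
  df <- as.data.frame(cards)
  per_card <- function(f) vapply(split(df, factor(df$card_id,
                                                  levels = unique(df$card_id))),
                                 f, logical(1))
  no_followup <- per_card(function(d) nrow(d) < 2L)
  missing_meta <- per_card(function(d) {
    any(is.na(d$age_months)) || any(is.na(d$sex)) || any(is.na(d$visit_date))
  })
  data.frame(card_id = unique(df$card_id),
             no_followup = unname(no_followup),
             missing_age_sex_date = unname(missing_meta),
             usable = unname(!no_followup & !missing_meta),
             stringsAsFactors = FALSE)
}

#' Flag biologically implausible visit records
#'
#' Applies the plausibility bounds to per-visit measures: weight-for-height
#' z outside [-5, 5], weight-for-age z outside [-6, 5], height-for-age z
#' outside [-6, 6], MUAC outside [65, 200] mm, weight change of more than
#' 25 g/kg/day in magnitude, or MUAC change greater than 15 mm/week in
#' either direction. Range rules are outside-closed-interval (the bound
#' itself is retained); change rules are strict inequalities on the
#' magnitude. Missing values never flag.
#'
#' @param observations Data frame with any of the columns `muac_mm`, `whz`,
#'   `waz`, `haz`, `muac_change_rate` (mm/week, signed) and
#'   `weight_change_rate` (g/kg/day, signed).
#' @return Data frame of logical flag columns `whz_out`, `waz_out`,
#'   `haz_out`, `muac_out`, `weight_change_out`, `muac_change_out` and
#'   `implausible` (any flag).
#' @export
flag_implausible <- function(observations) {
  n <- nrow(observations)
  col <- function(nm) if (nm %in% names(observations)) observations[[nm]] else
    rep(NA_real_, n)
  out_of <- function(x, lo, hi) is_true(x < lo | x > hi)
  flags <- data.frame(
    whz_out = out_of(col("whz"), -5, 5),
    waz_out = out_of(col("waz"), -6, 5),
    haz_out = out_of(col("haz"), -6, 6),
    muac_out = out_of(col("muac_mm"), 65, 200),
    weight_change_out = is_true(abs(col("weight_change_rate")) > 25),
    muac_change_out = is_true(abs(col("muac_change_rate")) > 15))
  flags$implausible <- Reduce(`|`, flags)
  flags
}

#' Outcome eligibility of a treated card
#'
#' Eligible cards were discharged as recovered, experienced a non-negative
#' MUAC gain from admission to discharge, and gained at least 10% of
#' admission weight if admitted as a SAM patient (TFP) or at least 3% if
#' admitted as a MAM patient (SFP). Thresholds are inclusive.
#'
#' @param cards A `patient_cards` data frame.
#' @return Data frame with one row per card: `card_id`, `not_recovered`,
#'   `negative_muac_gain`, `insufficient_weight_gain`, `eligible`.
#' @export
outcome_eligible <- function(cards) {
  df <- as.data.frame(cards)
  sp <- split(df, factor(df$card_id, levels = unique(df$card_id)))
  res <- lapply(sp, function(d) {
    d <- d[order(d$visit_date), , drop = FALSE]
    first <- d[1L, ]; last <- d[nrow(d), ]
    not_recovered <- !is_true(first$discharge_status == "recovered")
    neg_muac <- is_true(last$muac_mm < first$muac_mm)
    min_gain <- if (is_true(first$facility == "TFP")) 0.10 else 0.03
    rel_gain <- (last$weight_kg - first$weight_kg) / first$weight_kg
    insufficient <- !is_true(rel_gain >= min_gain)
    data.frame(card_id = first$card_id, not_recovered = not_recovered,
               negative_muac_gain = neg_muac,
               insufficient_weight_gain = insufficient,
               eligible = !not_recovered & !neg_muac & !insufficient,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Restrict interval observations to the MUAC analysis window
#'
#' Keeps observations whose prior-visit MUAC lies in the closed window
#' (default [100, 140] mm); the number dropped is reported via `message()`.
#'
#' @param observations Interval observations (see [interval_changes()]).
#' @param window Closed MUAC interval in mm.
#' @return The filtered observations.
#' @export
apply_muac_window <- function(observations, window = c(100, 140)) {
  keep <- is_true(observations$prior_muac >= window[1] &
                    observations$prior_muac <= window[2])
  if (any(!keep)) {
    message(sprintf("apply_muac_window: dropped %d of %d observations outside [%g, %g] mm",
                    sum(!keep), length(keep), window[1], window[2]))
  }
  observations[keep, , drop = FALSE]
}

# Per-visit plausibility flags for a whole cohort: merges z-scores (if a
# reference is given) with between-visit change rates, attributing each
# interval's change to the later visit.
cohort_plausibility <- function(cards, reference = NULL) {
  df <- as.data.frame(cards)
  n <- nrow(df)
  obs <- data.frame(card_id = df$card_id, visit_date = df$visit_date,
                    muac_mm = df$muac_mm, stringsAsFactors = FALSE)
  obs$muac_change_rate <- NA_real_
  obs$weight_change_rate <- NA_real_
  same_card <- c(FALSE, df$card_id[-1L] == df$card_id[-n])
  prev <- seq_len(n) - 1L
  days <- as.numeric(df$visit_date - df$visit_date[pmax(prev, 1L)])
  ok <- same_card & is_true(days >= 1)
  obs$muac_change_rate[ok] <-
    (df$muac_mm[ok] - df$muac_mm[pmax(prev, 1L)][ok]) / (days[ok] / 7)
  obs$weight_change_rate[ok] <-
    (df$weight_kg[ok] - df$weight_kg[pmax(prev, 1L)][ok]) * 1000 /
    df$weight_kg[pmax(prev, 1L)][ok] / days[ok]
  if (!is.null(reference)) {
    z <- compute_zscores(cards, reference)
    obs$whz <- z$whz; obs$waz <- z$waz; obs$haz <- z$haz
  }
  cbind(obs[c("card_id", "visit_date")], flag_implausible(obs))
}
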