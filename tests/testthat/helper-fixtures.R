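# Fixtures built in code: hand-sized patient cards and a synthetic LMS
# growth reference.

# Construct a patient_cards object from per-card visit vectors.
make_card <- function(card_id = "C1", country = "Kenya", facility = "TFP",
                      sex = "F", age_months = 12,
                      dates = as.Date("2012-01-01") + seq(0, by = 7,
                                                          length.out = length(muac)),
                      muac, weight, height = NA_real_,
                      oedema = "absent", status = "recovered") {
  data.frame(card_id = card_id, country = country, facility = facility,
             sex = sex, age_months = age_months,
             visit_date = as.Date(dates), muac_mm = muac, weight_kg = weight,
             height_cm = height, oedema = oedema, discharge_status = status,
             stringsAsFactors = FALSE)
}

as_cards <- function(...) {
  df <- do.call(rbind, list(...))
  muacdose:::new_patient_cards(df)
}

# Synthetic LMS reference spanning ages 4-62 months and heights 60-125 cm.
fixture_reference <- function() {
  path <- system.file("extdata", "lms_synthetic.csv", package = "muacdose")
  read_growth_reference(path)
}

# A clean, noise-free cohort under a preset (deterministic trajectories).
noise_free_config <- function(n_per_country = 10, preset = "fig2_anchor",
                              seed = 1L, ...) {
  generator_config(n_per_country = n_per_country, preset = preset,
                   sd_muac_change = 0, sd_weight_change = 0,
                   missed_visit_prob = 0, nonresponse_fraction = 0,
                   oedema_missing_prob = 0, oedema_present_prob = 0,
                   rng_seed = seed, ...)
}

# Eligible, QC-passed interval observations from a cohort.
eligible_observations <- function(cards, window = c(100, 140)) {
  usab <- card_usable(cards)
  cards <- cards[cards$card_id %in% usab$card_id[usab$usable], , drop = FALSE]
  flags <- suppressMessages(muacdose:::cohort_plausibility(cards))
  cards <- cards[!flags$implausible, , drop = FALSE]
  elig <- outcome_eligible(cards)
  cards <- cards[cards$card_id %in% elig$card_id[elig$eligible], , drop = FALSE]
  suppressMessages(apply_muac_window(interval_changes(cards), window))
}
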