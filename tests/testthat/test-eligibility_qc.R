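test_that("card usability requires a follow-up visit and complete metadata", {
  one_visit <- as_cards(make_card("A", dates = as.Date("2012-01-01"),
                                  muac = 110, weight = 6.0))
  u <- card_usable(one_visit)
  expect_false(u$usable)
  expect_true(u$no_followup)

  complete <- as_cards(make_card("B", muac = c(108, 110, 112, 114),
                                 weight = c(6.0, 6.2, 6.4, 6.6)))
  expect_true(card_usable(complete)$usable)

  no_sex <- as_cards(make_card("C", sex = NA_character_,
                               muac = c(108, 110), weight = c(6, 6.2)))
  u <- card_usable(no_sex)
  expect_false(u$usable)
  expect_true(u$missing_age_sex_date)
})

test_that("change thresholds are strict: 15 mm/week retained, 16 excluded", {
  obs <- data.frame(muac_mm = c(110, 110, 110),
                    muac_change_rate = c(15, 16, -16),
                    weight_change_rate = 0)
  f <- flag_implausible(obs)
  expect_equal(f$muac_change_out, c(FALSE, TRUE, TRUE))
  # weight 5.0 -> 5.9 kg over 7 days: 900/5.0/7 = 25.71 g/kg/day, excluded
  obs2 <- data.frame(weight_change_rate = c(900 / 5.0 / 7, 25, -25.5))
  expect_equal(flag_implausible(obs2)$weight_change_out,
               c(TRUE, FALSE, TRUE))
})

test_that("range rules exclude outside the closed interval only", {
  f <- flag_implausible(data.frame(muac_mm = c(64, 65, 200, 201)))
  expect_equal(f$muac_out, c(TRUE, FALSE, FALSE, TRUE))
  f <- flag_implausible(data.frame(whz = c(-5, 5, -5.01, 5.2),
                                   waz = c(-6, 5, -6.1, 5.1),
                                   haz = c(-6, 6, -6.2, 6.3)))
  expect_equal(f$whz_out, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(f$waz_out, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(f$haz_out, c(FALSE, FALSE, TRUE, TRUE))
})

test_that("plausibility flags are idempotent and order-independent", {
  set.seed(8)
  obs <- data.frame(muac_mm = sample(c(60, 110, 210), 30, TRUE),
                    muac_change_rate = rnorm(30, 0, 10),
                    weight_change_rate = rnorm(30, 0, 15),
                    whz = rnorm(30, 0, 3))
  f1 <- flag_implausible(obs)
  # idempotence: flagging the retained subset flags nothing new
  f2 <- flag_implausible(obs[!f1$implausible, , drop = FALSE])
  expect_false(any(f2$implausible))
  # order independence: the exclusion set is the union of individual flags
  manual <- with(obs, (muac_mm < 65 | muac_mm > 200) |
                   abs(muac_change_rate) > 15 |
                   abs(weight_change_rate) > 25 |
                   (whz < -5 | whz > 5))
  expect_equal(f1$implausible, manual)
})

test_that("outcome eligibility applies inclusive 10%/3% thresholds by program", {
  # TFP card with exactly 10% weight gain and positive MUAC gain: eligible
  tfp <- as_cards(make_card("A", facility = "TFP",
                            muac = c(108, 110, 114), weight = c(5.0, 5.2, 5.5)))
  expect_true(outcome_eligible(tfp)$eligible)

  # SFP card with 1.7% gain: insufficient
  sfp <- as_cards(make_card("B", facility = "SFP",
                            muac = c(118, 120), weight = c(6.0, 6.1)))
  e <- outcome_eligible(sfp)
  expect_false(e$eligible)
  expect_true(e$insufficient_weight_gain)

  # SFP card with exactly 3% gain: eligible (5.0 -> 5.15 kg)
  sfp3 <- as_cards(make_card("C", facility = "SFP",
                             muac = c(118, 121), weight = c(5.0, 5.15)))
  expect_true(outcome_eligible(sfp3)$eligible)

  # recovered card with discharge MUAC below admission: negative MUAC gain
  neg <- as_cards(make_card("D", muac = c(115, 112), weight = c(6.0, 6.8)))
  e <- outcome_eligible(neg)
  expect_false(e$eligible)
  expect_true(e$negative_muac_gain)

  # non-recovered card is ineligible regardless of growth
  lost <- as_cards(make_card("E", status = "other",
                             muac = c(108, 116), weight = c(5.0, 5.9)))
  expect_true(outcome_eligible(lost)$not_recovered)
})

test_that("the MUAC window keeps the closed interval and logs the drop count", {
  obs <- data.frame(prior_muac = c(99, 100, 120, 140, 141, 105, 130, 101,
                                   139.5, 150),
                    muac_velocity = 1)
  expect_message(kept <- apply_muac_window(obs, c(100, 140)), "dropped 3 of 10")
  expect_equal(nrow(kept), 7L)
  expect_true(all(kept$prior_muac >= 100 & kept$prior_muac <= 140))
})

test_that("a clean cohort raises no flags; injected errors match the manifest", {
  cfg <- noise_free_config(n_per_country = 8)
  cards <- generate_cohort(cfg, seed = 12)
  flags <- muacdose:::cohort_plausibility(cards)
  expect_false(any(flags$implausible))

  corrupted <- inject_errors(cards,
                             rates = list(muac_spike = 0.3, weight_jump = 0.3,
                                          muac_range = 0.2, missing_age = 0.1,
                                          no_followup = 0.1),
                             seed = 13)
  man <- attr(corrupted, "manifest")
  expect_gt(nrow(man), 0L)

  # visit-level: flagged records == visit-level manifest entries
  flags <- muacdose:::cohort_plausibility(corrupted)
  flagged <- flags[flags$implausible, c("card_id", "visit_date")]
  man_visit <- unique(man[!is.na(man$visit_date),
                          c("card_id", "visit_date")])
  expect_setequal(paste(flagged$card_id, flagged$visit_date),
                  paste(man_visit$card_id, man_visit$visit_date))

  # card-level: unusable cards == card-level manifest entries
  u <- card_usable(corrupted)
  man_card <- unique(man$card_id[is.na(man$visit_date)])
  expect_setequal(u$card_id[!u$usable], man_card)
})
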