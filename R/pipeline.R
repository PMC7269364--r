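# End-to-end pipeline: cohort -> QC -> growth curves & trend test ->
# energy bands -> protocol performance, with a Fig-1-style attrition table.
#
# Exclusion reasons are attributed to the first failing rule in the order
# usability -> plausibility -> outcome eligibility -> analysis window, so
# the attrition counts are disjoint and non-increasing.

#' Run the full MUAC dosing analysis
#'
#' Executes every stage in fixed order on `cards` (or on a cohort generated
#' from `gen_config`): usability filter, per-visit plausibility filter
#' (with z-scores when `reference` is supplied), outcome-eligibility
#' filter, interval velocities, MUAC analysis window, velocity smoothing,
#' the resampled trend analysis, band-percentile energy dosage, and the
#' protocol-performance simulation. Re-running with the same configuration
#' and seed reproduces every output exactly.
#'
#' @param config A [run_config()].
#' @param cards A `patient_cards` data frame, or `NULL` to generate one.
#' @param gen_config A [generator_config()] used when `cards` is `NULL`.
#' @param reference Optional `growth_reference` enabling the z-score
#'   plausibility rules.
#' @param protocol A `protocol_spec` to evaluate (default proposed).
#' @param dir Optional directory; when given, every stage output is written
#'   there as CSV.
#' @param verbose Emit stage messages (default `FALSE`).
#' @return Object of class `muac_run`: list with `attrition`, `curves`
#'   (smoothed MUAC velocity and weight gain), `trend`
#'   (a `trend_test_result`), `energy_bands`, `subgroups`, `performance`
#'   (a `performance_summary`), `protocol_curves`, `observations`, and
#'   `provenance` (seed and config). Stages after a cohort with no usable
#'   cards are skipped, with the reason recorded in `$skipped`.
#' @export
run_pipeline <- function(config = run_config(), cards = NULL,
                         gen_config = NULL, reference = NULL,
                         protocol = get_protocol("proposed"), dir = NULL,
                         verbose = FALSE) {
  assert_that(inherits(config, "run_config"), "config must be a run_config")
  quiet <- function(expr) if (verbose) expr else suppressMessages(expr)
  if (is.null(cards)) {
    gen_config <- gen_config %||% generator_config(rng_seed = config$rng_seed)
    cards <- generate_cohort(gen_config, seed = config$rng_seed)
  }
  n_cards0 <- length(unique(cards$card_id))
  n_visits0 <- nrow(cards)

  usab <- card_usable(cards)
  usable_ids <- usab$card_id[usab$usable]
  step_rows <- list(data.frame(step = "input", unit = "cards",
                               kept = n_cards0, dropped = 0),
                    data.frame(step = "unusable (no follow-up / missing age, sex or date)",
                               unit = "cards", kept = length(usable_ids),
                               dropped = n_cards0 - length(usable_ids)))
  cards1 <- cards[cards$card_id %in% usable_ids, , drop = FALSE]

  if (length(usable_ids) == 0L) {
    attrition <- do.call(rbind, step_rows)
    return(structure(list(attrition = attrition,
                          skipped = "no usable cards; downstream stages skipped",
                          provenance = list(seed = config$rng_seed,
                                            config = config)),
                     class = "muac_run"))
  }

  plaus <- quiet(cohort_plausibility(cards1, reference))
  bad_visits <- plaus[plaus$implausible, c("card_id", "visit_date")]
  keep_visit <- !plaus$implausible
  step_rows[[3]] <- data.frame(step = "implausible visit records",
                               unit = "visits", kept = sum(keep_visit),
                               dropped = sum(!keep_visit))
  cards2 <- cards1[keep_visit, , drop = FALSE]

  elig <- outcome_eligible(cards2)
  elig_ids <- elig$card_id[elig$eligible]
  step_rows[[4]] <- data.frame(step = "ineligible outcome (not recovered / MUAC loss / low weight gain)",
                               unit = "cards", kept = length(elig_ids),
                               dropped = nrow(elig) - length(elig_ids))
  cards3 <- cards2[cards2$card_id %in% elig_ids, , drop = FALSE]

  obs_all <- interval_changes(cards3)
  obs <- quiet(apply_muac_window(obs_all, config$muac_window))
  step_rows[[5]] <- data.frame(step = "prior MUAC outside analysis window",
                               unit = "interval observations",
                               kept = nrow(obs),
                               dropped = nrow(obs_all) - nrow(obs))
  attrition <- do.call(rbind, step_rows)
  rownames(attrition) <- NULL

  if (nrow(obs) < 10L) {
    return(structure(list(attrition = attrition,
                          skipped = "fewer than 10 analyzable interval observations",
                          provenance = list(seed = config$rng_seed,
                                            config = config)),
                     class = "muac_run"))
  }

  grid <- seq(config$muac_window[1], config$muac_window[2], by = 1)
  curve_muac <- local_poly_smooth(obs$prior_muac, obs$muac_velocity,
                                  grid = grid, kernel = config$kernel,
                                  bandwidth = config$bandwidth,
                                  degree = config$degree)
  curve_weight <- local_poly_smooth(obs$prior_muac, obs$weight_gain_rate,
                                    grid = grid, kernel = config$kernel,
                                    bandwidth = config$bandwidth,
                                    degree = config$degree)

  trend <- quiet(resample_trend_analysis(
    obs, per_country = config$trend_per_country,
    replicates = config$trend_replicates,
    muac_range = c(max(config$muac_window[1], 100), 125),
    seed = config$rng_seed, level = config$sig_level,
    kernel = config$kernel, bandwidth = config$bandwidth,
    degree = config$degree, unit = config$sampling_unit))

  est <- energy_estimates(obs)
  bands <- quiet(band_percentile(est, band_width = config$band_width,
                                 level = config$percentile))
  subgroups <- lapply(c(admission_muac = "admission_muac",
                        continent = "continent", age_group = "age_group"),
                      function(s) quiet(subgroup_comparison(
                        est, scheme = s,
                        continent_map = config$continent_map,
                        band_width = config$band_width,
                        level = config$percentile)))

  performance <- quiet(simulate_trials(
    est, per_country = config$trial_per_country,
    replicates = config$trial_replicates, protocol = protocol,
    seed = config$rng_seed, unit = config$sampling_unit,
    continent_map = config$continent_map))
  protocol_curves <- mean_energy_by_muac(est)

  run <- structure(list(attrition = attrition,
                        curves = list(muac_velocity = curve_muac,
                                      weight_gain = curve_weight),
                        trend = trend, energy_bands = bands,
                        subgroups = subgroups, performance = performance,
                        protocol_curves = protocol_curves,
                        observations = obs, excluded_visits = bad_visits,
                        skipped = NULL,
                        provenance = list(seed = config$rng_seed,
                                          config = config)),
                   class = "muac_run")
  if (!is.null(dir)) write_run_outputs(run, dir)
  run
}

write_run_outputs <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_result_table(run$attrition, file.path(dir, "attrition.csv"))
  curves <- data.frame(muac = run$curves$muac_velocity$grid,
                       muac_velocity = run$curves$muac_velocity$estimate,
                       weight_gain_rate = run$curves$weight_gain$estimate)
  write_result_table(curves, file.path(dir, "curves.csv"))
  write_result_table(run$energy_bands, file.path(dir, "energy_bands.csv"))
  write_result_table(as.data.frame(run$performance),
                     file.path(dir, "performance.csv"))
  write_result_table(run$protocol_curves, file.path(dir, "protocol_curves.csv"))
  trend <- data.frame(replicate = seq_along(run$trend$slopes),
                      slope = run$trend$slopes,
                      p_value = run$trend$p_values)
  utils::write.csv(trend, file.path(dir, "trend_replicates.csv"),
                   row.names = FALSE)
  write_run_config(run$provenance$config, file.path(dir, "run_config.yaml"))
  invisible(dir)
}

#' @export
print.muac_run <- function(x, ...) {
  cat("MUAC dosing analysis run (seed ", x$provenance$seed, ")\n", sep = "")
  cat("Attrition:\n")
  print(x$attrition, row.names = FALSE)
  if (!is.null(x$skipped)) {
    cat("Downstream stages skipped: ", x$skipped, "\n", sep = "")
    return(invisible(x))
  }
  cat("\n")
  print(x$trend)
  invisible(x)
}

#' @export
summary.muac_run <- function(object, ...) {
  print(object)
  if (is.null(object$skipped)) {
    cat("\nEnergy dosage bands (", 100 * object$energy_bands$level[1],
        "th percentile):\n", sep = "")
    print(object$energy_bands, row.names = FALSE)
    cat("\nProtocol performance (total rows):\n")
    perf <- as.data.frame(object$performance)
    print(perf[perf$factor == "total", , drop = FALSE], row.names = FALSE)
  }
  invisible(object)
}
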