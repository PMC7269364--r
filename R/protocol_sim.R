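# Dosing protocols, coverage metrics and the protocol-performance
# simulation.
#
# The proposed simplified protocol doses by MUAC alone: two RUTF sachets
# (1000 kcal) per day while MUAC is 100 to <115 mm, aiming to cover 100% of
# energy needs, and one sachet (500 kcal) while MUAC is 115 to <125 mm,
# aiming to cover 50% (the remainder from home foods). Comparators dose by
# weight and/or admission program.

#' @rdname proposed_dose
#' @format NULL
#' @export
RUTF_SACHET_KCAL <- 500

#' @rdname proposed_dose
#' @format NULL
#' @export
RUTF_SACHET_G <- 92

#' Proposed MUAC-based dose
#'
#' Two 92 g RUTF sachets (1000 kcal) per day for MUAC 100 to <115 mm, one
#' sachet (500 kcal) for 115 to <125 mm. Outside [100, 125) the protocol
#' defines no dose and `NA` is returned (the caller decides exclusion).
#'
#' @param muac MUAC in mm.
#' @return kcal/day, or `NA` outside the protocol domain.
#' @export
proposed_dose <- function(muac) {
  ifelse(is_true(muac >= 100 & muac < 115), 2 * RUTF_SACHET_KCAL,
         ifelse(is_true(muac >= 115 & muac < 125), RUTF_SACHET_KCAL,
                NA_real_))
}

#' Comparator protocol doses
#'
#' Golden's minimum / intermediate / standard protocols prescribe 135, 150
#' and 170 kcal/kg/day regardless of MUAC; the Sierra Leone protocol
#' 175 kcal/kg/day below MUAC 115 mm and 75 kcal/kg/day at 115 to <125 mm;
#' the Kenya protocol 200 kcal/kg/day for children admitted to a SAM (TFP)
#' program and a flat 500 kcal/day for children admitted to a MAM (SFP)
#' program.
#'
#' @param protocol One of `"golden_min"`, `"golden_int"`, `"golden_std"`,
#'   `"sierra_leone"`, `"kenya"`.
#' @param muac MUAC in mm.
#' @param weight Weight in kg (required by the per-kg rules).
#' @param program Admission program, `"SAM"`/`"TFP"` or `"MAM"`/`"SFP"`
#'   (used by the Kenya protocol).
#' @return kcal/day.
#' @export
comparator_dose <- function(protocol, muac, weight, program = NULL) {
  per_kg <- c(golden_min = 135, golden_int = 150, golden_std = 170)
  if (protocol %in% names(per_kg)) {
    assert_that(all(is_true(weight > 0)), "weight must be positive")
    return(per_kg[[protocol]] * weight)
  }
  if (protocol == "sierra_leone") {
    assert_that(all(is_true(weight > 0)), "weight must be positive")
    return(ifelse(is_true(muac < 115), 175, 75) * weight)
  }
  if (protocol == "kenya") {
    sam <- toupper(as.character(program)) %in% c("SAM", "TFP")
    out <- ifelse(sam, 200 * weight, 500)
    if (any(sam)) assert_that(all(is_true(weight[sam] > 0)),
                              "weight must be positive")
    return(out)
  }
  stop("unknown protocol: ", protocol, call. = FALSE)
}

#' Dosing-protocol specification
#'
#' @param name Protocol name.
#' @param dose_fn Function `(muac, weight, program) -> kcal/day` (may return
#'   `NA` outside the protocol's domain).
#' @return Object of class `protocol_spec`.
#' @export
protocol_spec <- function(name, dose_fn) {
  assert_that(is.function(dose_fn), "dose_fn must be a function")
  structure(list(name = name, dose_fn = dose_fn), class = "protocol_spec")
}

#' Protocol registry
#'
#' @param name `"proposed"` or a [comparator_dose()] protocol name.
#' @return A `protocol_spec`.
#' @export
get_protocol <- function(name = c("proposed", "golden_min", "golden_int",
                                  "golden_std", "sierra_leone", "kenya")) {
  name <- match.arg(name)
  if (name == "proposed") {
    protocol_spec("proposed", function(muac, weight, program)
      proposed_dose(muac))
  } else {
    force(name)
    protocol_spec(name, function(muac, weight, program)
      comparator_dose(name, muac, weight, program))
  }
}

# MUAC stratum of a visit by prior-visit MUAC.
muac_stratum <- function(muac) {
  ifelse(is_true(muac >= 100 & muac < 115), "sam",
         ifelse(is_true(muac >= 115 & muac < 125), "mam", NA_character_))
}

# Reporting factors for Table-2-style summaries.
performance_factors <- function(df, continent_map = default_continent_map()) {
  list(total = rep("all", nrow(df)),
       sex = df$sex,
       age_group = as.character(cut(df$age_months, c(6, 12, 24, 60),
                                    labels = c("6-11", "12-23", "24-59"),
                                    right = FALSE)),
       weight_band = as.character(cut(df$prior_weight,
                                      c(3.5, 6.0, 8.0, 17.5),
                                      labels = c("3.5-5.9", "6.0-7.9",
                                                 "8.0-17.5"),
                                      right = FALSE)),
       admission = df$facility,
       continent = map_continent(df$country, continent_map))
}

#' Energy-coverage metrics of a protocol on one visit set
#'
#' Per visit, the provision ratio is dose / need. A SAM-stratum visit
#' (prior MUAC 100 to <115 mm) succeeds when the ratio reaches the SAM
#' coverage target (default 1.0, full needs); a MAM-stratum visit (115 to
#' <125 mm) when it reaches the MAM target (default 0.5, half of needs).
#' Visits with no defined dose or prior MUAC outside [100, 125) are
#' excluded and counted.
#'
#' @param estimates An `energy_estimates` data frame.
#' @param protocol A `protocol_spec` (default the proposed protocol).
#' @param targets Named coverage targets per stratum,
#'   `c(sam = 1.0, mam = 0.5)`.
#' @param continent_map Named country -> continent vector.
#' @return Data frame with one row per (stratum, factor, level):
#'   `stratum`, `factor`, `level`, `n`, `median_provision_pct`,
#'   `success_pct`; attribute `"excluded"` counts visits outside the
#'   protocol domain.
#' @export
coverage_metrics <- function(estimates, protocol = get_protocol("proposed"),
                             targets = c(sam = 1.0, mam = 0.5),
                             continent_map = default_continent_map()) {
  df <- as.data.frame(estimates)
  df$stratum <- muac_stratum(df$prior_muac)
  df$dose <- protocol$dose_fn(df$prior_muac, df$prior_weight, df$facility)
  usable <- !is.na(df$stratum) & !is.na(df$dose) & is_true(df$need_kcal > 0)
  n_excluded <- sum(!usable)
  skipped_need <- sum(!is.na(df$stratum) & !is.na(df$dose) &
                        !is_true(df$need_kcal > 0))
  if (skipped_need > 0L) {
    message(sprintf("coverage_metrics: %d visit(s) with non-positive need skipped",
                    skipped_need))
  }
  df <- df[usable, , drop = FALSE]
  ratio <- df$dose / df$need_kcal
  success <- ratio >= targets[df$stratum]
  factors <- performance_factors(df, continent_map)
  rows <- list()
  for (st in c("sam", "mam")) {
    in_st <- df$stratum == st
    for (f in names(factors)) {
      lv <- factors[[f]]
      for (l in unique(stats::na.omit(lv[in_st]))) {
        sel <- in_st & is_true(lv == l)
        rows[[length(rows) + 1L]] <- data.frame(
          stratum = st, factor = f, level = l, n = sum(sel),
          median_provision_pct = 100 * stats::median(ratio[sel]),
          success_pct = 100 * mean(success[sel]),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(stratum = character(0),
                                      factor = character(0),
                                      level = character(0), n = integer(0),
                                      median_provision_pct = numeric(0),
                                      success_pct = numeric(0))
  rownames(out) <- NULL
  attr(out, "excluded") <- n_excluded
  out
}

#' Simulated protocol-performance trials
#'
#' Repeats [coverage_metrics()] over country-stratified subsamples drawn
#' without replacement (default 200 visits per country, 100 replicates) and
#' aggregates per (stratum, factor, level): mean and min-max of the
#' per-replicate visit counts, the median across replicates of the
#' per-replicate median provision percentage, and mean/min/max of the
#' per-replicate success percentages.
#'
#' @param estimates An `energy_estimates` data frame.
#' @param per_country Visits (or cards) drawn per country.
#' @param replicates Number of replicates.
#' @param protocol A `protocol_spec`.
#' @param seed RNG seed.
#' @param targets Coverage targets per stratum.
#' @param unit Sampling unit, `"visits"` (default) or `"cards"`.
#' @param continent_map Named country -> continent vector.
#' @return Object of class `performance_summary`: a data frame with columns
#'   `stratum`, `factor`, `level`, `mean_n`, `min_n`, `max_n`,
#'   `median_provision_pct`, `mean_success_pct`, `min_success_pct`,
#'   `max_success_pct`; attributes `replicates`, `per_country`, `protocol`.
#' @export
simulate_trials <- function(estimates, per_country = 200, replicates = 100,
                            protocol = get_protocol("proposed"), seed = 1L,
                            targets = c(sam = 1.0, mam = 0.5),
                            unit = c("visits", "cards"),
                            continent_map = default_continent_map()) {
  unit <- match.arg(unit)
  counts <- table(estimates$country)
  short <- names(counts)[counts < per_country]
  if (length(short) > 0L) {
    message("simulate_trials: stratum smaller than per_country, using all available: ",
            paste(short, collapse = ", "))
  }
  reps <- with_seed(seed, {
    lapply(seq_len(replicates), function(r) {
      idx <- stratified_sample_idx(estimates, per_country, unit)
      cm <- suppressMessages(
        coverage_metrics(estimates[idx, , drop = FALSE], protocol,
                         targets = targets, continent_map = continent_map))
      cm$replicate <- r
      cm
    })
  })
  all <- do.call(rbind, reps)
  key <- interaction(all$stratum, all$factor, all$level, drop = TRUE)
  agg <- lapply(split(all, key), function(d) {
    data.frame(stratum = d$stratum[1L], factor = d$factor[1L],
               level = d$level[1L],
               mean_n = mean(d$n), min_n = min(d$n), max_n = max(d$n),
               median_provision_pct = stats::median(d$median_provision_pct),
               mean_success_pct = mean(d$success_pct),
               min_success_pct = min(d$success_pct),
               max_success_pct = max(d$success_pct),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$stratum, out$factor, out$level), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("performance_summary", "data.frame")
  attr(out, "replicates") <- replicates
  attr(out, "per_country") <- per_country
  attr(out, "protocol") <- protocol$name
  out
}

#' @export
print.performance_summary <- function(x, ...) {
  cat(sprintf("Protocol performance: %s, %d replicates of %d visits/country\n",
              attr(x, "protocol"), attr(x, "replicates"),
              attr(x, "per_country")))
  NextMethod()
}

#' Mean prescribed energy by MUAC for a set of protocols
#'
#' For each integer MUAC bin in `window` and each protocol, the mean
#' prescribed kcal/day over the observations whose prior MUAC falls in the
#' bin (per-kg rules average over the empirical weight distribution at that
#' MUAC).
#'
#' @param observations An `interval_obs` (or `energy_estimates`) data frame.
#' @param protocols List of `protocol_spec`s; defaults to the proposed
#'   protocol plus all comparators.
#' @param window Closed-open MUAC window (default `c(100, 125)`).
#' @return Data frame: `muac`, `protocol`, `mean_kcal`, `n`.
#' @export
mean_energy_by_muac <- function(observations, protocols = NULL,
                                window = c(100, 125)) {
  protocols <- protocols %||% lapply(c("proposed", "golden_min", "golden_int",
                                       "golden_std", "sierra_leone", "kenya"),
                                     get_protocol)
  df <- observations[is_true(observations$prior_muac >= window[1] &
                               observations$prior_muac < window[2]), ,
                     drop = FALSE]
  bins <- floor(df$prior_muac)
  rows <- list()
  for (p in protocols) {
    dose <- p$dose_fn(df$prior_muac, df$prior_weight, df$facility)
    for (b in sort(unique(bins))) {
      sel <- bins == b & !is.na(dose)
      if (!any(sel)) next
      rows[[length(rows) + 1L]] <- data.frame(
        muac = b, protocol = p$name, mean_kcal = mean(dose[sel]),
        n = sum(sel), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
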