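# Patient-card I/O, result tables and run configuration.
#
# The canonical interchange format is a UTF-8, comma-separated file with a
# header, one row per clinic visit, one card (treatment episode) per card_id.

#' Default column mapping for patient-card files
#'
#' Maps the internal field names onto file column names. Supply a modified
#' copy to [read_patient_cards()] when a file uses different headers.
#'
#' @return Named character vector: names are internal fields, values are the
#'   column names expected in the file.
#' @export
default_card_schema <- function() {
  fields <- c("card_id", "country", "facility", "sex", "age_months",
              "visit_date", "muac_mm", "weight_kg", "height_cm", "oedema")
  stats::setNames(fields, fields)
}

card_columns <- function() {
  c("card_id", "country", "facility", "sex", "age_months", "visit_date",
    "muac_mm", "weight_kg", "height_cm", "oedema", "discharge_status")
}

new_patient_cards <- function(df) {
  df <- df[, card_columns(), drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("patient_cards", "data.frame")
  df
}

#' Read longitudinal patient cards from a CSV file
#'
#' One row per visit; rows are grouped by `card_id` and sorted by visit date
#' within card. Cards keep their order of first appearance in the file.
#' Malformed rows (unparseable dates, non-numeric measurements, missing
#' mandatory identifiers) abort the read with their data row numbers;
#' duplicate `(card_id, visit_date)` pairs are rejected, since a card cannot
#' record two visits on the same day.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Column mapping as returned by [default_card_schema()].
#' @return A `patient_cards` data frame (one row per visit) with columns
#'   `card_id`, `country`, `facility` (`"TFP"`/`"SFP"`), `sex` (`"F"`/`"M"`),
#'   `age_months`, `visit_date` (`Date`), `muac_mm`, `weight_kg`,
#'   `height_cm`, `oedema` (`"absent"`/`"present"` or `NA`), and
#'   `discharge_status` (`"recovered"`/`"other"`/`"unknown"`).
#' @export
read_patient_cards <- function(path, schema = default_card_schema()) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  missing_cols <- setdiff(unname(schema), names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(raw)
  get_col <- function(field) {
    x <- raw[[schema[[field]]]]
    trimws(x)
  }
  bad <- character(0)
  note_bad <- function(rows, what) {
    if (length(rows) > 0L) {
      bad <<- c(bad, paste0(what, " in row(s) ", paste(rows, collapse = ", ")))
    }
  }

  card_id <- get_col("card_id")
  note_bad(which(card_id == ""), "missing card_id")

  visit_date <- as.Date(get_col("visit_date"), format = "%Y-%m-%d")
  note_bad(which(is.na(visit_date) & get_col("visit_date") != ""),
           "unparseable visit_date (ISO 8601 expected)")

  parse_num <- function(field, positive = TRUE) {
    x <- get_col(field)
    out <- suppressWarnings(as.numeric(x))
    note_bad(which(is.na(out) & x != ""), paste0("non-numeric ", field))
    if (positive) note_bad(which(is_true(out <= 0)), paste0("non-positive ", field))
    out
  }
  muac_mm <- parse_num("muac_mm")
  weight_kg <- parse_num("weight_kg")
  height_cm <- parse_num("height_cm")
  age_months <- parse_num("age_months", positive = FALSE)

  sex_raw <- toupper(substr(get_col("sex"), 1L, 1L))
  sex <- ifelse(sex_raw %in% c("F", "M"), sex_raw, NA_character_)
  note_bad(which(is.na(sex) & get_col("sex") != ""), "unrecognised sex code")

  fac <- toupper(get_col("facility"))
  note_bad(which(!fac %in% c("TFP", "SFP") & fac != ""), "unrecognised facility")
  fac[fac == ""] <- NA_character_

  oed_raw <- get_col("oedema")
  oedema <- rep(NA_character_, n)
  oedema[oed_raw == "0"] <- "absent"
  oedema[oed_raw %in% c("1", "2", "3")] <- "present"
  note_bad(which(!oed_raw %in% c("", "0", "1", "2", "3")), "unrecognised oedema code")

  if (length(bad) > 0L) {
    stop("malformed patient-card file:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  }

  dup <- duplicated(paste(card_id, visit_date))
  if (any(dup)) {
    pairs <- unique(paste0("(", card_id[dup], ", ", visit_date[dup], ")"))
    stop("duplicate (card_id, visit_date) record(s): ",
         paste(pairs, collapse = ", "), call. = FALSE)
  }

  status <- if (schema["card_id"] != "" && "discharge_status" %in% names(raw)) {
    s <- trimws(raw[["discharge_status"]])
    ifelse(s %in% c("recovered", "other"), s, "unknown")
  } else rep("unknown", n)

  df <- data.frame(card_id = card_id, country = get_col("country"),
                   facility = fac, sex = sex, age_months = age_months,
                   visit_date = visit_date, muac_mm = muac_mm,
                   weight_kg = weight_kg, height_cm = height_cm,
                   oedema = oedema, discharge_status = status,
                   stringsAsFactors = FALSE)
  # stable sort: cards in first-appearance order, visits date-ascending
  first_seen <- match(df$card_id, unique(df$card_id))
  df <- df[order(first_seen, df$visit_date), , drop = FALSE]
  new_patient_cards(df)
}

#' Write patient cards back to CSV
#'
#' Inverse of [read_patient_cards()]: `read_patient_cards(write_patient_cards(x))`
#' reproduces `x`.
#'
#' @param cards A `patient_cards` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_patient_cards <- function(cards, path) {
  out <- as.data.frame(cards)
  out$visit_date <- format(out$visit_date, "%Y-%m-%d")
  out$oedema <- ifelse(is.na(out$oedema), "",
                       ifelse(out$oedema == "present", "1", "0"))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.patient_cards <- function(x, ...) {
  cat(sprintf("Patient cards: %d cards, %d visits, countries: %s\n",
              length(unique(x$card_id)), nrow(x),
              paste(sort(unique(x$country)), collapse = ", ")))
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10L) cat("... and", nrow(x) - 10L, "more visit rows\n")
  invisible(x)
}

# Fixed numeric formatting for result tables, keyed by column name:
# kcal columns as integers, percentages to 1 dp, velocities/rates to 2 dp.
format_result_column <- function(name, x) {
  if (!is.numeric(x)) return(as.character(x))
  if (grepl("kcal", name, ignore.case = TRUE)) {
    ifelse(is.na(x), "", sprintf("%.0f", x))
  } else if (grepl("(pct|percent|_frac)", name, ignore.case = TRUE)) {
    ifelse(is.na(x), "", sprintf("%.1f", x))
  } else if (grepl("(velocity|gain|rate|slope)", name, ignore.case = TRUE)) {
    ifelse(is.na(x), "", sprintf("%.2f", x))
  } else {
    ifelse(is.na(x), "", format(x, trim = TRUE, scientific = FALSE))
  }
}

#' Write a result table as CSV with fixed numeric formatting
#'
#' Columns whose names contain `kcal` are written as integers, columns
#' containing `pct`/`percent` to one decimal place, and columns containing
#' `velocity`/`gain`/`rate`/`slope` to two decimal places.
#'
#' @param rows A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(rows, path) {
  assert_that(is.data.frame(rows), "rows must be a data frame")
  out <- rows
  for (nm in names(out)) out[[nm]] <- format_result_column(nm, out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#' @param path CSV file path.
#' @return A data frame with numeric columns re-parsed.
#' @export
read_result_table <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Analysis run configuration
#'
#' Bundles the tunable parameters of the full analysis: the MUAC analysis
#' window, dosage band width, percentile level, resampling sizes, smoother
#' settings and RNG seed.
#'
#' @param muac_window Closed MUAC analysis window in mm (default `c(100, 140)`):
#'   intervals whose prior-visit MUAC falls outside are excluded.
#' @param band_width Width in mm of the dosage reporting bands (default 5);
#'   must divide the window length.
#' @param percentile Percentile level for band dosage derivation (default 0.95).
#' @param trend_per_country,trend_replicates Visits sampled per country and
#'   number of replicates for the trend analysis (defaults 1000 and 100).
#' @param trial_per_country,trial_replicates Visits sampled per country and
#'   number of replicates for protocol-performance trials (defaults 200, 100).
#' @param rng_seed Integer seed controlling all randomness of a run.
#' @param sig_level Significance level used when counting non-significant
#'   trend replicates (default 0.05).
#' @param kernel,degree,bandwidth Smoother settings, see [local_poly_smooth()].
#' @param sampling_unit `"visits"` (default) or `"cards"`: the unit drawn in
#'   country-stratified resampling.
#' @param continent_map Named character vector country -> continent.
#' @return An object of class `run_config`.
#' @export
run_config <- function(muac_window = c(100, 140), band_width = 5,
                       percentile = 0.95,
                       trend_per_country = 1000, trend_replicates = 100,
                       trial_per_country = 200, trial_replicates = 100,
                       rng_seed = 1L, sig_level = 0.05,
                       kernel = "epanechnikov", degree = 0, bandwidth = NULL,
                       sampling_unit = c("visits", "cards"),
                       continent_map = default_continent_map()) {
  sampling_unit <- match.arg(sampling_unit)
  assert_that(length(muac_window) == 2L && muac_window[1] < muac_window[2],
              "muac_window must be an increasing length-2 interval")
  assert_that(percentile > 0 && percentile < 1,
              "percentile must lie strictly between 0 and 1")
  assert_that(band_width > 0 &&
                abs(diff(muac_window) %% band_width) < 1e-9,
              "band_width must divide the muac_window length")
  assert_that(sig_level > 0 && sig_level < 1,
              "sig_level must lie strictly between 0 and 1")
  for (nm in c("trend_per_country", "trend_replicates", "trial_per_country",
               "trial_replicates")) {
    v <- get(nm)
    assert_that(is.numeric(v) && length(v) == 1L && v >= 1,
                paste(nm, "must be a positive count"))
  }
  structure(list(muac_window = as.numeric(muac_window),
                 band_width = band_width, percentile = percentile,
                 trend_per_country = as.integer(trend_per_country),
                 trend_replicates = as.integer(trend_replicates),
                 trial_per_country = as.integer(trial_per_country),
                 trial_replicates = as.integer(trial_replicates),
                 rng_seed = as.integer(rng_seed), sig_level = sig_level,
                 kernel = kernel, degree = degree, bandwidth = bandwidth,
                 sampling_unit = sampling_unit,
                 continent_map = continent_map),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration:\n")
  cat(sprintf("  MUAC window [%g, %g] mm, bands of %g mm, percentile %.2f\n",
              x$muac_window[1], x$muac_window[2], x$band_width, x$percentile))
  cat(sprintf("  trend resampling: %d/country x %d; trials: %d/country x %d (%s)\n",
              x$trend_per_country, x$trend_replicates, x$trial_per_country,
              x$trial_replicates, x$sampling_unit))
  cat(sprintf("  smoother: %s kernel, degree %d, bandwidth %s; seed %d\n",
              x$kernel, x$degree,
              if (is.null(x$bandwidth)) "rule-of-thumb" else format(x$bandwidth),
              x$rng_seed))
  invisible(x)
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_run_config()` returns a `run_config`; `write_run_config()`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$continent_map)) vals$continent_map <- unlist(vals$continent_map)
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param config A `run_config` object.
#' @export
write_run_config <- function(config, path) {
  vals <- unclass(config)
  vals$continent_map <- as.list(vals$continent_map)
  yaml::write_yaml(vals, path)
  invisible(path)
}
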