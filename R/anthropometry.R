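# LMS growth-reference z-scores.
#
# A growth reference is a table of (indicator, sex, key) rows carrying the
# LMS parameters: L (Box-Cox power), M (median in measurement units) and
# S (coefficient of variation). Keys are age in days for weight-for-age
# (WAZ) and height-for-age (HAZ), and height in mm for weight-for-height
# (WHZ). Z-scores here feed only the wide plausibility bounds of the QC
# filters, so the raw LMS transform is used without any tail adjustment.

#' LMS z-score transform
#'
#' `z = ((x/M)^L - 1) / (L * S)`, with the continuous limit
#' `z = log(x/M) / S` used when `|L| < 1e-7`.
#'
#' @param x Measurement, in the reference's units; must be positive.
#' @param L Box-Cox power.
#' @param M Reference median; positive.
#' @param S Reference coefficient of variation; positive.
#' @return Numeric z-score(s).
#' @examples
#' lms_zscore(11, L = 1, M = 10, S = 0.1)  # 1
#' @export
lms_zscore <- function(x, L, M, S) {
  n <- max(length(x), length(L), length(M), length(S))
  x <- rep_len(x, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  if (any(is_true(x <= 0)) || any(is_true(M <= 0)) || any(is_true(S <= 0))) {
    stop("lms_zscore: x, M and S must be strictly positive", call. = FALSE)
  }
  z <- ifelse(abs(L) < 1e-7,
              log(x / M) / S,
              ((x / M)^L - 1) / (L * S))
  as.numeric(z)
}

#' Inverse LMS transform
#'
#' Reconstructs the measurement with z-score `z` under parameters (L, M, S):
#' `x = M * (1 + L*S*z)^(1/L)` (log form in the `L -> 0` limit).
#'
#' @param z Z-score(s).
#' @inheritParams lms_zscore
#' @return Measurement(s) in reference units.
#' @export
lms_inverse <- function(z, L, M, S) {
  n <- max(length(z), length(L), length(M), length(S))
  z <- rep_len(z, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  ifelse(abs(L) < 1e-7, M * exp(S * z), M * (1 + L * S * z)^(1 / L))
}

new_growth_reference <- function(df) {
  needed <- c("indicator", "sex", "key", "L", "M", "S")
  assert_that(all(needed %in% names(df)),
              paste("growth reference needs columns:",
                    paste(needed, collapse = ", ")))
  assert_that(all(df$M > 0) && all(df$S > 0),
              "growth reference must have M > 0 and S > 0 in every row")
  df <- df[order(df$indicator, df$sex, df$key), , drop = FALSE]
  split_keys <- split(df$key, paste(df$indicator, df$sex))
  if (any(vapply(split_keys, function(k) any(diff(k) <= 0), logical(1)))) {
    stop("growth reference keys must be strictly increasing per (indicator, sex)",
         call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("growth_reference", "data.frame")
  df
}

#' Read an LMS growth-reference table from CSV
#'
#' Expected columns: `indicator` (`"waz"`, `"haz"`, `"whz"`), `sex`
#' (`"F"`/`"M"`), `key` (age in days for waz/haz, height in mm for whz),
#' `L`, `M`, `S`.
#'
#' @param path CSV file path.
#' @return A `growth_reference` data frame.
#' @export
read_growth_reference <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$indicator <- tolower(df$indicator)
  df$sex <- toupper(substr(df$sex, 1L, 1L))
  new_growth_reference(df)
}

# Interpolate L, M, S at `key` for one (indicator, sex) slice.
# Returns a data.frame with columns L, M, S; NA rows where key is outside
# the reference range or missing.
lookup_lms <- function(reference, indicator, sex, key) {
  out <- data.frame(L = rep(NA_real_, length(key)), M = NA_real_, S = NA_real_)
  for (sx in unique(stats::na.omit(sex))) {
    slice <- reference[reference$indicator == indicator & reference$sex == sx, ]
    idx <- which(is_true(sex == sx) & !is.na(key))
    if (nrow(slice) < 1L || length(idx) == 0L) next
    inside <- idx[key[idx] >= min(slice$key) & key[idx] <= max(slice$key)]
    if (length(inside) < length(idx)) {
      warning(sprintf("%d %s key(s) outside the %s reference range; z-scores set missing",
                      length(idx) - length(inside), sx, indicator), call. = FALSE)
    }
    if (length(inside) == 0L) next
    for (p in c("L", "M", "S")) {
      out[[p]][inside] <- stats::approx(slice$key, slice[[p]],
                                        xout = key[inside], rule = 1)$y
    }
  }
  out
}

#' Per-visit z-scores for patient cards
#'
#' Computes WAZ at every visit, and WHZ/HAZ wherever height is recorded
#' (program cards carry height only at admission and discharge). Age at a
#' visit is the admission age in months times 30.4375 days plus the days
#' elapsed since admission. Missing measurements or reference coverage
#' yield missing z-scores (with a warning for out-of-range keys), never
#' imputation.
#'
#' @param cards A `patient_cards` data frame.
#' @param reference A `growth_reference`.
#' @return Data frame with columns `card_id`, `visit_date`, `waz`, `haz`,
#'   `whz` aligned with the visit rows of `cards`.
#' @export
compute_zscores <- function(cards, reference) {
  assert_that(inherits(reference, "growth_reference"),
              "reference must be a growth_reference")
  df <- as.data.frame(cards)
  adm_date <- stats::ave(as.numeric(df$visit_date), df$card_id,
                         FUN = function(d) min(d, na.rm = TRUE))
  age_days <- df$age_months * DAYS_PER_MONTH +
    (as.numeric(df$visit_date) - adm_date)
  height_mm <- df$height_cm * 10

  z_of <- function(indicator, key, x) {
    p <- lookup_lms(reference, indicator, df$sex, key)
    ok <- !is.na(p$M) & !is.na(x) & is_true(x > 0)
    z <- rep(NA_real_, nrow(df))
    if (any(ok)) z[ok] <- lms_zscore(x[ok], p$L[ok], p$M[ok], p$S[ok])
    z
  }
  data.frame(card_id = df$card_id, visit_date = df$visit_date,
             waz = z_of("waz", age_days, df$weight_kg),
             haz = z_of("haz", age_days, df$height_cm),
             whz = z_of("whz", height_mm, df$weight_kg),
             stringsAsFactors = FALSE)
}
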