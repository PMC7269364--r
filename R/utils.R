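# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# TRUE for NA-safe logical tests: NA counts as FALSE.
is_true <- function(x) !is.na(x) & x

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

# Countries of the five study programs and their continents.
default_continent_map <- function() {
  c("Kenya" = "Africa", "Chad" = "Africa", "South Sudan" = "Africa",
    "Pakistan" = "Asia", "Yemen" = "Asia")
}

map_continent <- function(country, continent_map = default_continent_map()) {
  unknown <- setdiff(unique(as.character(country)), names(continent_map))
  if (length(unknown) > 0L) {
    stop("no continent mapping for country: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  unname(continent_map[as.character(country)])
}

# Age groups used throughout the reporting (months at interval start).
age_group_of <- function(age_months, breaks = c(6, 12, 24, 36, 60),
                         labels = c("6-11", "12-23", "24-35", "36-59")) {
  as.character(cut(age_months, breaks = breaks, labels = labels, right = FALSE))
}

DAYS_PER_MONTH <- 30.4375
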