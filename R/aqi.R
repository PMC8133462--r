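# Air Quality Index categorisation (official MEP cut points) and the
# synthetic hourly AQI generator.

# Official category cut points: 0-50 Excellent, 51-100 Good, 101-150 Slightly
# Polluted, 151-200 Moderately Polluted, 201-300 Heavily Polluted, >300
# Severely Polluted.
.aqi_breaks <- c(0, 50, 100, 150, 200, 300, Inf)
.aqi_levels <- c(
  "Excellent", "Good", "Slightly_Polluted",
  "Moderately_Polluted", "Heavily_Polluted", "Severely_Polluted"
)

#' Map AQI readings to official air-quality categories
#'
#' Uses the six-category Chinese MEP standard: Excellent (0-50), Good
#' (51-100), Slightly Polluted (101-150), Moderately Polluted (151-200),
#' Heavily Polluted (201-300), Severely Polluted (>300).
#'
#' @param aqi numeric vector of non-negative AQI readings.
#' @return factor with the six category levels.
#' @export
aqi_level <- function(aqi) {
  if (any(!is.finite(aqi)) || any(aqi < 0)) {
    stop("AQI readings must be finite and non-negative")
  }
  idx <- findInterval(aqi, .aqi_breaks, left.open = TRUE)
  idx[aqi == 0] <- 1L
  factor(.aqi_levels[idx], levels = .aqi_levels)
}

#' Names of the AQI level dummies entering the regressions
#'
#' "Good" is the omitted benchmark category and never appears as a dummy.
#' @return character vector of the non-benchmark level names.
#' @export
aqi_dummy_levels <- function() setdiff(.aqi_levels, "Good")

#' Generate a synthetic hourly city-level AQI series
#'
#' Produces one AQI reading per city, day, and hour (0..23 labelled 1..24,
#' hour t covering the clock interval (t-1, t]). Three patterns are
#' supported:
#' \describe{
#'   \item{wave}{a single pollution episode peaking mid-period, arriving in
#'     each city with a city-specific lag (emulating a front spreading across
#'     a province) plus mild noise;}
#'   \item{flat}{a constant value (useful for degenerate tests);}
#'   \item{iid}{independent uniform draws over the configured range.}
#' }
#' Values are clamped to `range` and categories assigned with [aqi_level()].
#'
#' @param config a [world_config()] list (uses `n_cities`, `n_days`,
#'   `aqi_range`).
#' @param pattern one of "wave", "flat", "iid".
#' @param value constant used by the "flat" pattern.
#' @return data.frame with columns city, day, hour (1..24), aqi, level.
#' @export
gen_aqi <- function(config, pattern = c("wave", "flat", "iid"), value = 75) {
  pattern <- match.arg(pattern)
  rng <- config$aqi_range
  if (rng[1] < 0 || rng[2] > 500 || rng[1] >= rng[2]) {
    stop("aqi_range must lie within [0, 500] with min < max")
  }
  grid <- expand.grid(
    hour = 1:24, day = seq_len(config$n_days), city = seq_len(config$n_cities)
  )[, c("city", "day", "hour")]
  tau <- (grid$day - 1) * 24 + grid$hour  # absolute hour in the period
  n_hours <- config$n_days * 24
  aqi <- switch(pattern,
    flat = rep(value, nrow(grid)),
    iid = stats::runif(nrow(grid), rng[1], rng[2]),
    wave = {
      # episode peaks at ~70% of the period; later cities peak later
      lag <- 6 * (grid$city - 1)
      peak <- 0.7 * n_hours + lag
      width <- 0.22 * n_hours
      base <- rng[1] + 0.08 * diff(rng)
      amp <- (rng[2] - base)
      base + amp * exp(-((tau - peak) / width)^2) + stats::rnorm(nrow(grid), 0, 3)
    }
  )
  aqi <- pmin(pmax(aqi, rng[1]), rng[2])
  grid$aqi <- aqi
  grid$level <- aqi_level(aqi)
  grid
}
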