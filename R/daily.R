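# Daily aggregates and the intra-day substitution regressions: if people
# merely reschedule activities within the day, daily aggregates should not
# respond to daily pollution even though hourly shares do.

#' Build city-day aggregates from the hourly panel
#'
#' For each city-day: the average hourly share of each location over the
#' panel hours, multiplied by 1000 (the regression scaling); the average of
#' the per-hour mean distances (when the panel carries `dist_mean`); and
#' four daily AQI summaries — maximum, mean, median, and an "official"
#' daily value (implemented as the mean of the hourly AQI; the official
#' published aggregate is not reconstructable and this stand-in is
#' pluggable).
#'
#' @param panel a [build_panel()] panel.
#' @param hours hours expected per city-day (default 7:22); a missing hour
#'   is an error naming the cell.
#' @param official function summarising hourly AQI to the "official" daily
#'   value.
#' @return data.frame city, day, share1000_h/m/p/o, dist_mean, aqi_max,
#'   aqi_mean, aqi_median, aqi_official.
#' @export
build_daily <- function(panel, hours = 7:22, official = mean) {
  dt <- data.table::as.data.table(panel)
  chk <- dt[, list(nh = length(unique(hour))), by = c("city", "day")]
  if (any(chk$nh != length(hours))) {
    bad <- chk[chk$nh != length(hours)][1, ]
    stop(sprintf("city %s day %s is missing panel hours", bad$city, bad$day))
  }
  if (!"dist_mean" %in% names(dt)) dt$dist_mean <- NA_real_
  out <- dt[, list(
    share1000_h = 1000 * mean(s_h), share1000_m = 1000 * mean(s_m),
    share1000_p = 1000 * mean(s_p), share1000_o = 1000 * mean(s_o),
    dist_mean = mean(dist_mean),
    aqi_max = max(aqi), aqi_mean = mean(aqi),
    aqi_median = stats::median(aqi), aqi_official = official(aqi)
  ), by = c("city", "day")]
  data.table::setorder(out, city, day)
  as.data.frame(out)
}

#' Daily-level regression with city and day fixed effects
#'
#' Least squares of a daily outcome (a share-times-1000 column or the daily
#' mean distance) on one daily AQI summary, controlling for city and day
#' fixed effects, with classical i.i.d.-normal two-sided tests (appropriate
#' at this sample size by design).
#'
#' @param daily a [build_daily()] table.
#' @param measure which AQI summary: "max", "mean", "median", "official".
#' @param outcome outcome column name (default "share1000_h").
#' @return list: coefficient (on the AQI measure), se, t, p, ci (95%), lm
#'   fit.
#' @export
fit_daily <- function(daily, measure = c("mean", "max", "median", "official"),
                      outcome = "share1000_h") {
  measure <- match.arg(measure)
  xcol <- paste0("aqi_", measure)
  if (is.null(daily[[outcome]])) stop("unknown outcome column: ", outcome)
  nparam <- 1 + (length(unique(daily$city)) - 1) + (length(unique(daily$day)) - 1) + 1
  if (nrow(daily) - nparam < 1) {
    stop("insufficient degrees of freedom for the daily regression")
  }
  f <- stats::as.formula(paste(outcome, "~", xcol, "+ factor(city) + factor(day)"))
  m <- stats::lm(f, data = daily)
  sm <- summary(m)$coefficients
  est <- sm[xcol, "Estimate"]
  se <- sm[xcol, "Std. Error"]
  ci <- est + c(-1, 1) * stats::qt(0.975, m$df.residual) * se
  list(coefficient = est, se = se, t = sm[xcol, "t value"],
       p = sm[xcol, "Pr(>|t|)"], ci = ci, model = m,
       measure = measure, outcome = outcome)
}

#' Compare daily-level to hourly-level pollution effects
#'
#' The hourly marginal effect of a one-point AQI increase on a share,
#' expressed per mille (share x 1000), is directly comparable to the daily
#' regression coefficient: under no intra-day substitution the two agree;
#' under perfect substitution the daily coefficient is zero. A ratio inside
#' (0, 1) (by its 95% CI) is flagged as partial substitution.
#'
#' @param hourly_effect an aqi-measure [effect_continuous()] result with
#'   `delta = 1` scaling, or any `effect_result` plus the `delta` used.
#' @param daily_fit a [fit_daily()] result for the matching location share.
#' @param location location code of the compared share ("h", "m", "p", "o").
#' @param delta the AQI increase `hourly_effect` was scaled by.
#' @return list: hourly (per-mille per AQI point), daily, ratio, ratio_ci,
#'   verdict in \{"none", "partial", "full-or-more"\}.
#' @export
compare_scales <- function(hourly_effect, daily_fit, location = "h",
                           delta = 10) {
  h <- hourly_effect$d_share[hourly_effect$location == location] * 1000 / delta
  d <- daily_fit$coefficient
  ratio <- if (h == 0) NA_real_ else d / h
  ratio_ci <- if (h == 0) c(NA_real_, NA_real_) else sort(daily_fit$ci / h)
  verdict <- if (is.na(ratio)) {
    "undefined"
  } else if (ratio_ci[2] < 0 || daily_fit$p > 0.05 && abs(ratio) < 0.5) {
    "none"
  } else if (ratio_ci[1] > 0 && ratio_ci[2] < 1) {
    "partial"
  } else {
    "full-or-more"
  }
  list(hourly = h, daily = d, ratio = ratio, ratio_ci = ratio_ci,
       verdict = verdict)
}
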