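# Aggregation of labelled phone-hours into the city-day-hour panel that the
# share regressions consume.

# Shares are computed as count ratios (n_l / n_total) so that rescaling all
# counts by an exactly-representable factor leaves them bit-identical.
add_share_columns <- function(panel) {
  for (l in c("h", "m", "p", "o")) {
    panel[[paste0("s_", l)]] <- panel[[paste0("n_", l)]] / panel$n_total
  }
  lv <- aqi_dummy_levels()
  for (d in lv) panel[[d]] <- as.integer(as.character(panel$level) == d)
  panel
}

#' Build the city-day-hour panel from labelled placements
#'
#' Tallies phone-hours by label into counts `n_h, n_m, n_p, n_o` for every
#' city-day-hour cell, derives shares and AQI level dummies ("Good" is the
#' omitted benchmark), and joins the hourly AQI series and optional
#' covariates. Hours outside `hours` (default 7..22) are excluded. When the
#' placements carry distances, each cell's mean binned distance is included
#' as `dist_mean` for the daily aggregation.
#'
#' @param labeled labelled placements from [label_hours()].
#' @param aqi hourly AQI series (city, day, hour, aqi, level).
#' @param covariates optional data.frame keyed by city, day, hour.
#' @param hours panel hour labels.
#' @return data.frame with one row per (city, day, hour).
#' @export
build_panel <- function(labeled, aqi, covariates = NULL, hours = 7:22) {
  dt <- data.table::as.data.table(labeled)
  dt <- dt[dt$hour %in% hours]
  counts <- dt[, list(
    n_total = .N,
    n_h = sum(label == "h"), n_m = sum(label == "m"),
    n_p = sum(label == "p"), n_o = sum(label == "o"),
    dist_mean = if ("distance_mid" %in% names(dt)) mean(distance_mid) else NA_real_
  ), by = c("city", "day", "hour")]
  grid <- data.table::CJ(city = sort(unique(aqi$city[aqi$city %in% counts$city])),
                         day = sort(unique(counts$day)), hour = hours)
  counts <- counts[grid, on = c("city", "day", "hour")]
  if (any(is.na(counts$n_total) | counts$n_total == 0)) {
    bad <- counts[is.na(n_total) | n_total == 0][1, ]
    stop(sprintf("panel cell with no phones: city %s, day %s, hour %s",
                 bad$city, bad$day, bad$hour))
  }
  adt <- data.table::as.data.table(aqi[, c("city", "day", "hour", "aqi", "level")])
  counts <- adt[counts, on = c("city", "day", "hour")]
  if (any(is.na(counts$aqi))) stop("AQI series does not cover all panel cells")
  panel <- as.data.frame(counts)
  panel <- panel[order(panel$city, panel$day, panel$hour), ]
  rownames(panel) <- NULL
  panel <- add_share_columns(panel)
  if (!is.null(covariates)) {
    panel <- merge(panel, covariates, by = c("city", "day", "hour"),
                   all.x = TRUE, sort = FALSE)
    panel <- panel[order(panel$city, panel$day, panel$hour), ]
    extra <- setdiff(names(covariates), c("city", "day", "hour"))
    miss <- vapply(extra, function(v) any(is.na(panel[[v]])), logical(1))
    if (any(miss)) {
      warning("missing covariate values left NA: ",
              paste(extra[miss], collapse = ", "))
    }
  }
  panel
}

#' Log odds of each non-home location against home
#'
#' `ln(n_l) - ln(n_h)` for l in \{m, p, o\}, the dependent variable of the
#' aggregated logit regression. A zero count is a hard error by default;
#' alternatively a 0.5 continuity correction is added to all four counts of
#' the affected cell, or the cell's row for that location is dropped.
#'
#' @param panel a [build_panel()] panel.
#' @param zero_policy "error", "continuity" or "drop".
#' @return data.frame city, day, hour, location, log_odds.
#' @export
log_odds <- function(panel, zero_policy = c("error", "continuity", "drop")) {
  zero_policy <- match.arg(zero_policy)
  y <- log_odds_matrix(panel, zero_policy)
  out <- do.call(rbind, lapply(c("m", "p", "o"), function(l) {
    data.frame(city = panel$city, day = panel$day, hour = panel$hour,
               location = l, log_odds = y[, l], stringsAsFactors = FALSE)
  }))
  out[!is.na(out$log_odds), ]
}

# n x 3 matrix of log odds (columns m, p, o); NA marks dropped rows.
# Computed as log(n_l / n_h) so count rescaling is bit-preserving.
log_odds_matrix <- function(panel, zero_policy = "error") {
  nl <- as.matrix(panel[, c("n_m", "n_p", "n_o")])
  nh <- panel$n_h
  zero <- nh == 0 | rowSums(nl == 0) > 0
  if (any(zero)) {
    if (zero_policy == "error") {
      i <- which(zero)[1]
      stop(sprintf(paste0("zero count in panel cell city %s, day %s, hour %s; ",
                          "use zero_policy = 'continuity' or 'drop'"),
                   panel$city[i], panel$day[i], panel$hour[i]))
    } else if (zero_policy == "continuity") {
      nl[zero, ] <- nl[zero, ] + 0.5
      nh[zero] <- nh[zero] + 0.5
      message(sum(zero), " cell(s) received the 0.5 continuity correction")
    }
  }
  y <- log(nl / nh)
  colnames(y) <- c("m", "p", "o")
  if (any(zero) && zero_policy == "drop") {
    y[zero, ] <- NA
    message(sum(zero), " cell(s) dropped (zero count)")
  }
  y
}

#' Randomly thin phones for the multi-phone sensitivity analysis
#'
#' Keeps each phone independently with probability 1/k, emulating the
#' correction for users carrying k phones on average (dropping (k-1)/k of
#' the observations).
#'
#' @param placements placements or labelled placements.
#' @param k average phones per user (k = 1 returns the input).
#' @param seed optional seed.
#' @return thinned placements.
#' @export
thin_users <- function(placements, k, seed = NULL) {
  stopifnot(k >= 1)
  if (k == 1) return(placements)
  if (!is.null(seed)) set.seed(seed)
  ids <- unique(placements$phone_id)
  keep <- ids[stats::runif(length(ids)) < 1 / k]
  out <- placements[placements$phone_id %in% keep, ]
  rownames(out) <- NULL
  dw <- attr(placements, "dwell")
  if (!is.null(dw)) attr(out, "dwell") <- dw[dw$phone_id %in% keep]
  out
}
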