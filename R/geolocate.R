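# Geolocation of phones from tower connection logs: sample-selection
# filters, dwell-time accounting, night-time home inference, hourly
# positions, and distance-from-home binning.
#
# Conventions: timestamps are seconds since the period start; hour label t
# covers the half-open clock window [t-1:00, t:00), so day hours 7..22 span
# 06:00-22:00 and the night window 00:00-06:00 carries labels 1..6.

#' Apply the sample-selection filters to a record stream
#'
#' Keeps phones whose first-to-last record span is at least `min_span_hours`
#' (default 96 h, i.e. four active days) and that have at least
#' `min_records` tower records.
#'
#' @param records data.frame with phone_id, timestamp columns.
#' @param min_records minimum record count (default 20).
#' @param min_span_hours minimum first-to-last span in hours (default 96).
#' @return character vector of eligible phone ids (empty input gives an
#'   empty result).
#' @export
filter_users <- function(records, min_records = 20, min_span_hours = 96) {
  if (nrow(records) == 0) return(character(0))
  dt <- data.table::as.data.table(records)
  s <- dt[, list(n = .N, span = (max(timestamp) - min(timestamp)) / 3600),
          by = "phone_id"]
  sort(s[s$n >= min_records & s$span >= min_span_hours, ][["phone_id"]])
}

#' Per-tower dwell seconds of one phone within a time window
#'
#' Walks the phone's time-ordered records: a connect or service record makes
#' its tower current (service renews the connection), a disconnect clears
#' it; each inter-record interval is attributed to the tower current at its
#' opening. The final interval, if unterminated, is clipped at the window
#' end; all intervals are clipped to the half-open window `[start, end)`.
#'
#' @param records records of a single phone (phone_id, tower_id, timestamp,
#'   event).
#' @param window numeric length-2, `[start, end)` in seconds.
#' @return named numeric vector of seconds per tower_id.
#' @export
dwell_times <- function(records, window) {
  stopifnot(length(window) == 2, window[2] > window[1])
  if (length(unique(records$phone_id)) > 1) {
    stop("dwell_times() expects records of a single phone")
  }
  r <- records[order(records$timestamp), , drop = FALSE]
  tower <- ifelse(r$event == "disconnect", NA_character_, r$tower_id)
  start <- r$timestamp
  end <- c(r$timestamp[-1], window[2])
  s <- pmax(start, window[1])
  e <- pmin(end, window[2])
  keep <- !is.na(tower) & e > s
  if (!any(keep)) return(stats::setNames(numeric(0), character(0)))
  out <- tapply(e[keep] - s[keep], tower[keep], sum)
  stats::setNames(as.numeric(out), names(out))
}

# Vectorised per-phone-hour dwell table for a whole record stream.
# Returns a data.table: phone_id, day, hour (1..24), tower_id, city, dwell.
hourly_dwell <- function(records, towers, period_end = NULL) {
  dt <- data.table::as.data.table(records)
  unknown <- setdiff(unique(dt$tower_id), towers$tower_id)
  if (length(unknown) > 0) {
    stop("records reference unknown tower(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  if (is.null(period_end)) period_end <- max(dt$timestamp)
  data.table::setorder(dt, phone_id, timestamp)
  dt[, end := data.table::shift(timestamp, -1, fill = NA), by = "phone_id"]
  dt[is.na(end), end := pmax(timestamp, period_end)]
  dt[event == "disconnect", tower_id := NA_character_]
  dt <- dt[!is.na(tower_id) & end > timestamp]
  h0 <- floor(dt$timestamp / 3600)
  h1 <- ceiling(dt$end / 3600) - 1
  np <- as.integer(h1 - h0 + 1)
  idx <- rep(seq_len(nrow(dt)), np)
  habs <- h0[idx] + sequence(np) - 1
  ps <- pmax(dt$timestamp[idx], habs * 3600)
  pe <- pmin(dt$end[idx], (habs + 1) * 3600)
  out <- data.table::data.table(
    phone_id = dt$phone_id[idx],
    day = as.integer(habs %/% 24 + 1),
    hour = as.integer(habs %% 24 + 1),
    tower_id = dt$tower_id[idx],
    dwell = pe - ps
  )
  out <- out[dwell > 0,
             list(dwell = sum(dwell)),
             by = c("phone_id", "day", "hour", "tower_id")]
  tw <- data.table::as.data.table(towers[, c("tower_id", "city", "x", "y")])
  out <- tw[out, on = "tower_id"]
  data.table::setcolorder(out, c("phone_id", "day", "hour", "tower_id",
                                 "city", "x", "y", "dwell"))
  out[]
}

#' Dwell-weighted average tower position
#'
#' `x = sum(w_k x_k)`, `y = sum(w_k y_k)` with `w_k` the tower's share of
#' total dwell. Lies in the convex hull of the contributing towers and is
#' invariant to rescaling all dwell times.
#'
#' @param dwell named numeric vector of seconds per tower_id (as returned by
#'   [dwell_times()]).
#' @param towers tower table (tower_id, x, y).
#' @return length-2 numeric (x, y), or NULL as the "no-fix" signal when
#'   total dwell is zero.
#' @export
weighted_position <- function(dwell, towers) {
  tot <- sum(dwell)
  if (length(dwell) == 0 || tot <= 0) return(NULL)
  i <- match(names(dwell), towers$tower_id)
  if (anyNA(i)) {
    stop("dwell references unknown tower(s): ",
         paste(names(dwell)[is.na(i)], collapse = ", "))
  }
  w <- dwell / tot
  c(x = sum(w * towers$x[i]), y = sum(w * towers$y[i]))
}

#' Infer home locations from night-time records
#'
#' Pools each phone's dwell over the night window (default hour labels 1..6,
#' the clock window 00:00-06:00) across all days of the raw period, and
#' returns the dwell-weighted average of the registered towers' locations.
#'
#' @param records record stream (all phones).
#' @param towers tower table.
#' @param night_hours night hour labels (default 1:6).
#' @param period_end end of the raw observation window, seconds.
#' @return data.frame phone_id, x, y, n_night_towers, night_seconds. Phones
#'   with no night records are absent; their ids are attached as
#'   `attr(, "no_home")`.
#' @export
infer_home <- function(records, towers, night_hours = 1:6,
                       period_end = NULL) {
  hd <- hourly_dwell(records, towers, period_end)
  nd <- hd[hd$hour %in% night_hours,
           list(dwell = sum(dwell)), by = c("phone_id", "tower_id", "x", "y")]
  if (nrow(nd) == 0) {
    res <- data.frame(phone_id = character(0), x = numeric(0), y = numeric(0),
                      n_night_towers = integer(0), night_seconds = numeric(0))
  } else {
    res <- nd[, list(
      x = sum(dwell * x) / sum(dwell),
      y = sum(dwell * y) / sum(dwell),
      n_night_towers = .N,
      night_seconds = sum(dwell)
    ), by = "phone_id"]
    res <- as.data.frame(res)
  }
  no_home <- setdiff(unique(records$phone_id), res$phone_id)
  attr(res, "no_home") <- no_home
  res
}

#' Bin a distance into the 501-interval midpoint scheme
#'
#' Intervals are [0, 100], (100, 200], ..., (49900, 50000], (50000, Inf) in
#' metres; a finite-bin distance maps to its interval midpoint, and
#' distances beyond the 50 km censoring limit map to the limit with the
#' censoring flag set.
#'
#' @param d non-negative distances, metres.
#' @param width interval width (default 100 m).
#' @param censor upper censoring limit (default 50,000 m).
#' @return data.frame distance_mid, censored_upper.
#' @export
bin_distance <- function(d, width = 100, censor = 50000) {
  if (any(d < 0)) stop("negative distance passed to bin_distance()")
  censored <- d > censor
  i <- pmax(ceiling(d / width), 1)
  mid <- ifelse(censored, censor, width * i - width / 2)
  data.frame(distance_mid = mid, censored_upper = censored)
}

#' Hourly placements: position, city, and distance from home per phone-hour
#'
#' Computes each phone's dwell-weighted position in every panel hour,
#' assigns the phone-hour to the city with the largest dwell (ties broken by
#' lowest city id), and measures the Euclidean distance to the inferred
#' home, both raw and binned.
#'
#' @param records record stream.
#' @param towers tower table.
#' @param homes home table from [infer_home()] (computed if NULL).
#' @param hours panel hour labels (default 7:22).
#' @param night_hours night window used when homes must be inferred.
#' @param period_end end of the raw window, seconds.
#' @return data.frame phone_id, city, day, hour, x, y, distance,
#'   distance_mid, censored_upper. The per-phone-hour per-tower dwell table
#'   is attached as `attr(, "dwell")`; phones dropped for lack of a home are
#'   counted in `attr(, "dropped_no_home")`.
#' @export
hourly_placements <- function(records, towers, homes = NULL, hours = 7:22,
                              night_hours = 1:6, period_end = NULL) {
  hd <- hourly_dwell(records, towers, period_end)
  if (is.null(homes)) {
    homes <- infer_home(records, towers, night_hours, period_end)
  }
  dh <- hd[hd$hour %in% hours]
  pos <- dh[, list(
    x = sum(dwell * x) / sum(dwell),
    y = sum(dwell * y) / sum(dwell),
    total_dwell = sum(dwell)
  ), by = c("phone_id", "day", "hour")]
  cityd <- dh[, list(cdwell = sum(dwell)), by = c("phone_id", "day", "hour", "city")]
  data.table::setorder(cityd, phone_id, day, hour, -cdwell, city)
  citym <- cityd[, utils::head(.SD, 1), by = c("phone_id", "day", "hour")]
  pos <- citym[, c("phone_id", "day", "hour", "city")][pos, on = c("phone_id", "day", "hour")]
  hm <- data.table::as.data.table(homes[, c("phone_id", "x", "y")])
  data.table::setnames(hm, c("x", "y"), c("hx", "hy"))
  n_before <- length(unique(pos$phone_id))
  pos <- hm[pos, on = "phone_id", nomatch = NULL]
  dropped <- n_before - length(unique(pos$phone_id))
  pos[, distance := sqrt((x - hx)^2 + (y - hy)^2)]
  bins <- bin_distance(pos$distance)
  out <- data.frame(
    phone_id = pos$phone_id, city = pos$city, day = pos$day, hour = pos$hour,
    x = pos$x, y = pos$y, distance = pos$distance,
    distance_mid = bins$distance_mid, censored_upper = bins$censored_upper,
    stringsAsFactors = FALSE
  )
  attr(out, "dwell") <- dh
  attr(out, "dropped_no_home") <- dropped
  out
}
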