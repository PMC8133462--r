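# Synthetic-world generator: towers, facilities, homes, ground-truth
# parameters, logit-governed hourly location choices, and noisy tower
# connection logs. The generator's defaults mirror the study design the
# estimators target: 6 cities, 4 days, hours 7..22, an AQI episode in the
# 25-225 range, and a choice set {home, mall, park, other}.

.locations <- c("m", "p", "o")  # non-home alternatives; "h" is the base

#' Configuration of a synthetic world
#'
#' @param n_cities number of cities (spatially disjoint square extents).
#' @param n_days number of days in the study period.
#' @param hours daytime panel hours; hour `t` labels the clock interval
#'   `(t-1, t]`, so the default `7:22` covers 06:00-22:00.
#' @param n_users_per_city phones simulated per city.
#' @param towers_per_city towers per city, laid out on a jittered grid.
#' @param city_extent side of each city's square extent, metres.
#' @param n_parks,n_malls facilities per city (0 allowed).
#' @param facility_size side of the square facility polygons, metres.
#' @param tower_jitter grid jitter as a fraction of tower spacing (0 gives an
#'   exact grid, useful for geometry oracles).
#' @param aqi_range range of generated AQI values.
#' @param night_hours hour labels generated at the true home (default 1:6,
#'   i.e. the clock window 00:00-06:00 used for home inference).
#' @param seed integer seed; identical seeds give bit-identical worlds.
#' @return list of class `mobiaq_config`.
#' @export
world_config <- function(n_cities = 6, n_days = 4, hours = 7:22,
                         n_users_per_city = 5000, towers_per_city = 49,
                         city_extent = 10000, n_parks = 3, n_malls = 3,
                         facility_size = 1500, tower_jitter = 0.15,
                         aqi_range = c(25, 225), night_hours = 1:6,
                         seed = 1L) {
  cfg <- list(
    n_cities = as.integer(n_cities), n_days = as.integer(n_days),
    hours = as.integer(hours), n_users_per_city = as.integer(n_users_per_city),
    towers_per_city = as.integer(towers_per_city),
    city_extent = city_extent, n_parks = as.integer(n_parks),
    n_malls = as.integer(n_malls), facility_size = facility_size,
    tower_jitter = tower_jitter, aqi_range = aqi_range,
    night_hours = as.integer(night_hours), seed = as.integer(seed)
  )
  with(cfg, {
    if (n_cities < 1 || n_days < 1 || n_users_per_city < 1 || towers_per_city < 1)
      stop("all counts must be >= 1")
    if (n_parks < 0 || n_malls < 0) stop("facility counts must be >= 0")
    if (city_extent <= 0) stop("city_extent must be positive")
    if (any(hours < 1) || any(hours > 24)) stop("hours must lie in 1..24")
    if ((n_parks + n_malls) * facility_size^2 > 0.5 * city_extent^2)
      stop("city_extent too small to place the requested facilities")
  })
  class(cfg) <- "mobiaq_config"
  cfg
}

# x-offset separating city extents so positions never straddle cities
city_origin <- function(city, extent) (city - 1) * 2 * extent

#' Ground-truth parameters of a synthetic world
#'
#' Builds the parameter set governing choices and distances. Utility of the
#' home alternative is normalised to zero; for l in \{m, p, o\} the
#' systematic utility is
#' `gamma[j,y,l] + delta[t,l] + x(AQI) %*% beta_l + eta[j,y,t,l]`.
#' Defaults produce baseline shares of roughly (h, m, p, o) =
#' (0.55, 0.05, 0.05, 0.35) and pollution responses of the magnitude seen in
#' city-scale mobility data: air quality worsening from Good to Heavily
#' Polluted moves several percentage points of the population home.
#'
#' @param config a [world_config()].
#' @param beta_level 4 x 3 matrix of level-dummy coefficients (rows
#'   Excellent, Slightly_Polluted, Moderately_Polluted, Heavily_Polluted;
#'   columns m, p, o); effects are relative to the omitted "Good" level.
#' @param beta_aqi length-3 continuous-AQI coefficients (per AQI point).
#' @param beta_t,beta_t2 length-3 AQI-by-hour interaction coefficients (the
#'   AQI slope at hour t is `beta_aqi + beta_t*t + beta_t2*t^2`).
#' @param gamma_sd,eta_sd standard deviations of the city-day-location
#'   effects and the city-day-hour-location shocks.
#' @param beta_d_level,beta_d_aqi distance-model pollution coefficients
#'   (metres per dummy switch / per AQI point).
#' @param sigma_d individual-level distance error sd, metres.
#' @param substitution fraction of the AQI response rescheduled within the
#'   day (0 = none: utilities respond to the raw AQI; 1 = perfect: utilities
#'   respond only to within-day AQI deviations, leaving daily aggregates
#'   unmoved).
#' @return list of class `mobiaq_truth`.
#' @export
world_truth <- function(config,
                        beta_level = NULL, beta_aqi = c(-0.0015, -0.0025, -0.002),
                        beta_t = c(0, 0, 0), beta_t2 = c(0, 0, 0),
                        gamma_sd = 0.15, eta_sd = 0.05,
                        beta_d_level = c(50, -150, -350, -550),
                        beta_d_aqi = -6, sigma_d = 1500,
                        substitution = 0) {
  nh <- length(config$hours)
  if (is.null(beta_level)) {
    beta_level <- rbind(
      Excellent          = c(0.02, 0.10, 0.05),
      Slightly_Polluted  = c(-0.05, -0.15, -0.08),
      Moderately_Polluted = c(-0.10, -0.30, -0.18),
      Heavily_Polluted   = c(-0.18, -0.45, -0.30)
    )
  }
  colnames(beta_level) <- .locations
  base <- c(m = log(0.05 / 0.55), p = log(0.05 / 0.55), o = log(0.35 / 0.55))
  gamma <- array(
    rep(base, each = config$n_cities * config$n_days) +
      stats::rnorm(config$n_cities * config$n_days * 3, 0, gamma_sd),
    dim = c(config$n_cities, config$n_days, 3),
    dimnames = list(NULL, NULL, .locations)
  )
  peak <- c(m = 19, p = 11, o = 13)
  amp <- c(m = 0.5, p = 0.7, o = 0.9)
  delta <- matrix(
    vapply(.locations, function(l) {
      amp[l] * exp(-((config$hours - peak[l]) / 3.5)^2)
    }, numeric(nh)),
    nrow = nh, ncol = 3, dimnames = list(config$hours, .locations)
  )
  eta <- array(
    stats::rnorm(config$n_cities * config$n_days * nh * 3, 0, eta_sd),
    dim = c(config$n_cities, config$n_days, nh, 3),
    dimnames = list(NULL, NULL, config$hours, .locations)
  )
  names(beta_aqi) <- names(beta_t) <- names(beta_t2) <- .locations
  names(beta_d_level) <- rownames(beta_level)
  truth <- list(
    config = config,
    gamma = gamma, delta = delta, eta = eta,
    beta_level = beta_level, beta_aqi = beta_aqi,
    beta_t = beta_t, beta_t2 = beta_t2,
    eta_sd = eta_sd,
    gamma_d = matrix(1200 + stats::rnorm(config$n_cities * config$n_days, 0, 100),
                     config$n_cities, config$n_days),
    delta_d = 900 * exp(-((config$hours - 14) / 4.5)^2),
    beta_d_level = beta_d_level, beta_d_aqi = beta_d_aqi, sigma_d = sigma_d,
    substitution = substitution
  )
  names(truth$delta_d) <- config$hours
  class(truth) <- "mobiaq_truth"
  truth
}

#' Generate a synthetic world
#'
#' Lays towers on a jittered grid covering each city's extent, places
#' non-overlapping square park and mall polygons, draws home locations
#' uniformly over the extent, and populates the ground truth.
#'
#' @param config a [world_config()].
#' @param truth_args named list passed on to [world_truth()].
#' @return list of class `mobiaq_world` with elements `config`, `towers`
#'   (data.frame tower_id, city, x, y), `parks`, `malls` (facility lists),
#'   `homes` (data.frame phone_id, city, x, y) and `truth`.
#' @export
gen_world <- function(config = world_config(), truth_args = list()) {
  set.seed(config$seed)
  towers <- do.call(rbind, lapply(seq_len(config$n_cities), function(j) {
    ox <- city_origin(j, config$city_extent)
    m <- ceiling(sqrt(config$towers_per_city))
    s <- config$city_extent / m
    g <- expand.grid(ix = seq_len(m), iy = seq_len(m))
    g <- g[seq_len(config$towers_per_city), ]
    n <- nrow(g)
    data.frame(
      tower_id = sprintf("C%02dT%03d", j, seq_len(n)),
      city = j,
      x = ox + (g$ix - 0.5) * s + stats::runif(n, -1, 1) * config$tower_jitter * s,
      y = (g$iy - 0.5) * s + stats::runif(n, -1, 1) * config$tower_jitter * s,
      stringsAsFactors = FALSE
    )
  }))
  place <- function(kind, n_per_city) {
    out <- list()
    for (j in seq_len(config$n_cities)) {
      ox <- city_origin(j, config$city_extent)
      placed <- list()
      half <- config$facility_size / 2
      lo <- half; hi <- config$city_extent - half
      if (n_per_city > 0 && hi <= lo)
        stop("city_extent too small to place the requested facilities")
      for (i in seq_len(n_per_city)) {
        ok <- FALSE
        for (try in 1:200) {
          cx <- stats::runif(1, lo, hi); cy <- stats::runif(1, lo, hi)
          clash <- any(vapply(placed, function(f) {
            abs(f$cx - cx) < config$facility_size &&
              abs(f$cy - cy) < config$facility_size
          }, logical(1)))
          if (!clash) { ok <- TRUE; break }
        }
        if (!ok) stop("city_extent too small to place the requested facilities")
        placed[[i]] <- list(cx = cx, cy = cy)
        out[[length(out) + 1L]] <- list(
          id = sprintf("%s_C%02d_%02d", kind, j, i), city = j, kind = kind,
          poly = rect_poly(ox + cx - half, cy - half, ox + cx + half, cy + half),
          centroid = c(ox + cx, cy)
        )
      }
    }
    out
  }
  parks <- place("park", config$n_parks)
  malls <- place("mall", config$n_malls)
  n <- config$n_users_per_city
  homes <- do.call(rbind, lapply(seq_len(config$n_cities), function(j) {
    ox <- city_origin(j, config$city_extent)
    data.frame(
      phone_id = sprintf("P%02d%06d", j, seq_len(n)),
      city = j,
      x = ox + stats::runif(n, 0, config$city_extent),
      y = stats::runif(n, 0, config$city_extent),
      stringsAsFactors = FALSE
    )
  }))
  truth <- do.call(world_truth, c(list(config = config), truth_args))
  truth$home_coords <- homes
  structure(
    list(config = config, towers = towers, parks = parks, malls = malls,
         homes = homes, truth = truth),
    class = "mobiaq_world"
  )
}

# Systematic utilities v[, c("m","p","o")] for every (city, day, hour) cell of
# the aqi series restricted to panel hours. Returns a data.frame keyed by
# city, day, hour with utility and probability columns.
cell_utilities <- function(truth, aqi, measure = c("levels", "aqi"),
                           eta = truth$eta) {
  measure <- match.arg(measure)
  cfg <- truth$config
  cells <- aqi[aqi$hour %in% cfg$hours, c("city", "day", "hour", "aqi", "level")]
  cells <- cells[order(cells$city, cells$day, cells$hour), ]
  ti <- match(cells$hour, cfg$hours)
  x <- if (measure == "levels") {
    lv <- as.character(cells$level)
    t(vapply(lv, function(l) {
      if (l %in% rownames(truth$beta_level)) truth$beta_level[l, ] else c(m = 0, p = 0, o = 0)
    }, numeric(3)))
  } else {
    a <- cells$aqi
    if (truth$substitution > 0) {
      dm <- stats::ave(cells$aqi, cells$city, cells$day, FUN = mean)
      a <- cells$aqi - truth$substitution * dm
    }
    slope <- outer(rep(1, nrow(cells)), truth$beta_aqi) +
      outer(cells$hour, truth$beta_t) + outer(cells$hour^2, truth$beta_t2)
    slope * a
  }
  v <- matrix(
    vapply(seq_along(.locations), function(k) {
      truth$gamma[cbind(cells$city, cells$day, k)] +
        truth$delta[cbind(ti, k)] +
        x[, k] +
        if (is.null(eta)) rep(0, nrow(cells)) else
          eta[cbind(cells$city, cells$day, ti, k)]
    }, numeric(nrow(cells))),
    nrow = nrow(cells), ncol = 3, dimnames = list(NULL, .locations)
  )
  p <- logit_invert(v)
  cbind(cells, v = v, p)
}

#' Invert multinomial-logit utilities into choice shares
#'
#' Given systematic utilities of the non-home alternatives (home normalised
#' to zero), returns the implied shares: `s_h = 1 / (1 + sum(exp(v_l)))` and
#' `s_l = exp(v_l) * s_h`.
#'
#' @param v numeric matrix, one column per non-home alternative.
#' @return matrix with columns `p_h` followed by `p_<alternative>`; rows sum
#'   to one.
#' @export
logit_invert <- function(v) {
  v <- as.matrix(v)
  e <- exp(v)
  denom <- 1 + rowSums(e)
  out <- cbind(1 / denom, e / denom)
  colnames(out) <- paste0("p_", c("h", colnames(v)))
  out
}

#' Simulate hourly location choices for every user
#'
#' Draws one location in \{h, m, p, o\} per user-hour, either by sampling the
#' closed-form logit probabilities (`method = "multinomial"`) or by argmax
#' over utilities with i.i.d. standard Gumbel draws (`method = "argmax"`);
#' the two are distributionally identical. Users choosing a park or mall are
#' placed at the centroid of the facility of that kind nearest their home;
#' users choosing "other" are placed at an intended distance from home drawn
#' from the truncated-at-zero distance model, in a uniformly random direction
#' kept inside the city extent.
#'
#' @param world a [gen_world()] result.
#' @param aqi a [gen_aqi()] series covering the world's cities/days.
#' @param measure which pollution term enters utilities: level dummies or
#'   continuous AQI.
#' @param method draw mechanism (see above).
#' @param seed optional seed for this stage.
#' @return data.frame: phone_id, city, day, hour, label, x, y, d_true.
#' @export
gen_choices <- function(world, aqi, measure = c("levels", "aqi"),
                        method = c("multinomial", "argmax"), seed = NULL) {
  measure <- match.arg(measure)
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  cfg <- world$config
  truth <- world$truth
  cells <- cell_utilities(truth, aqi, measure)
  # facilities nearest each home, per kind
  nearest_fac <- function(facs, homes) {
    if (length(facs) == 0) return(rep(NA_integer_, nrow(homes)))
    idx <- rep(NA_integer_, nrow(homes))
    for (j in unique(homes$city)) {
      fj <- which(vapply(facs, function(f) f$city == j, logical(1)))
      hj <- which(homes$city == j)
      if (length(fj) == 0) next
      cen <- t(vapply(facs[fj], function(f) f$centroid, numeric(2)))
      d2 <- outer(homes$x[hj], cen[, 1], "-")^2 + outer(homes$y[hj], cen[, 2], "-")^2
      idx[hj] <- fj[max.col(-d2, ties.method = "first")]
    }
    idx
  }
  park_of <- nearest_fac(world$parks, world$homes)
  mall_of <- nearest_fac(world$malls, world$homes)
  labs <- c("h", "m", "p", "o")
  out <- vector("list", nrow(cells))
  for (r in seq_len(nrow(cells))) {
    j <- cells$city[r]; y <- cells$day[r]; t <- cells$hour[r]
    hj <- which(world$homes$city == j)
    n <- length(hj)
    pr <- c(cells$p_h[r], cells$p_m[r], cells$p_p[r], cells$p_o[r])
    if (length(world$parks) == 0) { pr[3] <- 0 }
    if (length(world$malls) == 0) { pr[2] <- 0 }
    pr <- pr / sum(pr)
    lab <- if (method == "multinomial") {
      sample(labs, n, replace = TRUE, prob = pr)
    } else {
      vv <- c(0, cells$v.m[r], cells$v.p[r], cells$v.o[r])
      if (length(world$parks) == 0) vv[3] <- -Inf
      if (length(world$malls) == 0) vv[2] <- -Inf
      g <- matrix(-log(-log(stats::runif(n * 4))), n, 4)
      labs[max.col(sweep(g, 2, vv, "+"), ties.method = "first")]
    }
    hx <- world$homes$x[hj]; hy <- world$homes$y[hj]
    x <- hx; yy <- hy
    ip <- lab == "p"; im <- lab == "m"; io <- lab == "o"
    if (any(ip)) {
      cen <- t(vapply(world$parks[park_of[hj][ip]], function(f) f$centroid, numeric(2)))
      x[ip] <- cen[, 1]; yy[ip] <- cen[, 2]
    }
    if (any(im)) {
      cen <- t(vapply(world$malls[mall_of[hj][im]], function(f) f$centroid, numeric(2)))
      x[im] <- cen[, 1]; yy[im] <- cen[, 2]
    }
    if (any(io)) {
      no <- sum(io)
      mu <- truth$gamma_d[j, y] + truth$delta_d[as.character(t)] +
        (if (measure == "levels") {
          l <- as.character(cells$level[r])
          if (l %in% names(truth$beta_d_level)) truth$beta_d_level[l] else 0
        } else truth$beta_d_aqi * cells$aqi[r])
      d <- mu + stats::rnorm(no, 0, truth$sigma_d)
      for (it in 1:20) {
        neg <- d <= 0
        if (!any(neg)) break
        d[neg] <- mu + stats::rnorm(sum(neg), 0, truth$sigma_d)
      }
      d <- pmax(d, 1)
      ox <- city_origin(j, cfg$city_extent)
      px <- rep(NA_real_, no); py <- rep(NA_real_, no)
      hox <- hx[io]; hoy <- hy[io]
      todo <- rep(TRUE, no)
      for (it in 1:20) {
        if (!any(todo)) break
        th <- stats::runif(sum(todo), 0, 2 * pi)
        cx <- hox[todo] + d[todo] * cos(th)
        cy <- hoy[todo] + d[todo] * sin(th)
        okp <- cx >= ox & cx <= ox + cfg$city_extent & cy >= 0 & cy <= cfg$city_extent
        px[todo][okp] <- cx[okp]; py[todo][okp] <- cy[okp]
        todo[todo] <- !okp
      }
      if (any(todo)) {  # clamp the rare stragglers into the extent
        th <- stats::runif(sum(todo), 0, 2 * pi)
        px[todo] <- pmin(pmax(hox[todo] + d[todo] * cos(th), ox), ox + cfg$city_extent)
        py[todo] <- pmin(pmax(hoy[todo] + d[todo] * sin(th), 0), cfg$city_extent)
      }
      x[io] <- px; yy[io] <- py
    }
    out[[r]] <- data.frame(
      phone_id = world$homes$phone_id[hj], city = j, day = y, hour = t,
      label = lab, x = x, y = yy,
      d_true = sqrt((x - hx)^2 + (yy - hy)^2),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Tower-assignment noise configuration for [gen_logs()]
#'
#' The hour is split among the `k` nearest towers with dwell fractions
#' proportional to `exp(-distance / lambda)`, perturbed by a Dirichlet draw
#' with concentration `concentration` (larger = less noise;
#' `concentration = Inf` disables the perturbation). `k = 1` with infinite
#' concentration is the noiseless limit: one connection to the nearest tower.
#'
#' @param k number of nearest towers sharing the hour.
#' @param lambda decay length of the proximity weights, metres.
#' @param concentration Dirichlet concentration of the dwell-fraction noise.
#' @param service_rate probability of emitting an extra in-call "service"
#'   record within a connection segment.
#' @export
log_noise <- function(k = 3, lambda = 1000, concentration = 60,
                      service_rate = 0) {
  stopifnot(k >= 1, lambda > 0, concentration > 0,
            service_rate >= 0, service_rate <= 1)
  list(k = as.integer(k), lambda = lambda, concentration = concentration,
       service_rate = service_rate)
}

#' Emit a noisy tower connection log from true hourly positions
#'
#' For every phone-hour the hour is split among the `k` nearest towers (see
#' [log_noise()]); each segment produces a connect and a disconnect record.
#' Night hours (the configured 00:00-06:00 window) are generated at the true
#' home as a single six-hour stay, making home inference identifiable by
#' construction. The stream is time-ordered per phone.
#'
#' @param choices output of [gen_choices()].
#' @param world the [gen_world()] world.
#' @param noise a [log_noise()] configuration.
#' @param seed optional seed for this stage.
#' @return data.frame: phone_id, tower_id, timestamp (seconds since period
#'   start), event in \{connect, disconnect, service\}.
#' @export
gen_logs <- function(choices, world, noise = log_noise(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- world$config
  nw <- cfg$night_hours
  # stays: day choices (1h windows) plus one night stay per phone-day; the
  # raw period includes the night after the last full day (so a resident's
  # first-to-last span exceeds the 96 h selection filter, as in a raw log
  # that starts before and ends after the analysed days)
  nights <- merge(
    expand.grid(phone_id = world$homes$phone_id, day = seq_len(cfg$n_days + 1L),
                stringsAsFactors = FALSE),
    world$homes, by = "phone_id"
  )
  stays <- rbind(
    data.frame(phone_id = choices$phone_id, city = choices$city,
               start = (choices$day - 1) * 86400 + (choices$hour - 1) * 3600,
               len = 3600, x = choices$x, y = choices$y,
               stringsAsFactors = FALSE),
    data.frame(phone_id = nights$phone_id, city = nights$city,
               start = (nights$day - 1) * 86400 + (min(nw) - 1) * 3600,
               len = length(nw) * 3600, x = nights$x, y = nights$y,
               stringsAsFactors = FALSE)
  )
  k <- noise$k
  recs <- vector("list", cfg$n_cities)
  for (j in seq_len(cfg$n_cities)) {
    tw <- world$towers[world$towers$city == j, ]
    sj <- stays[stays$city == j, ]
    n <- nrow(sj)
    kk <- min(k, nrow(tw))
    near <- matrix(NA_integer_, n, kk)
    ndist <- matrix(NA_real_, n, kk)
    chunk <- 20000L
    for (lo in seq(1L, n, by = chunk)) {
      hi <- min(lo + chunk - 1L, n)
      D <- outer(sj$x[lo:hi], tw$x, "-")^2 + outer(sj$y[lo:hi], tw$y, "-")^2
      for (q in seq_len(kk)) {
        idx <- max.col(-D, ties.method = "first")
        near[lo:hi, q] <- idx
        ndist[lo:hi, q] <- sqrt(D[cbind(seq_len(hi - lo + 1L), idx)])
        D[cbind(seq_len(hi - lo + 1L), idx)] <- Inf
      }
    }
    w <- exp(-ndist / noise$lambda)
    w <- w / rowSums(w)
    if (is.finite(noise$concentration) && kk > 1) {
      g <- matrix(stats::rgamma(n * kk, shape = noise$concentration * w), n, kk)
      bad <- rowSums(g) <= 0
      if (any(bad)) g[bad, ] <- w[bad, ]
      w <- g / rowSums(g)
    }
    # segment bounds within each stay (nearest tower first)
    cum <- matrix(0, n, kk + 1)
    for (q in seq_len(kk)) cum[, q + 1] <- cum[, q] + w[, q]
    cum[, kk + 1] <- 1
    seg_start <- sj$start + cum[, seq_len(kk), drop = FALSE] * sj$len
    seg_end <- sj$start + cum[, -1, drop = FALSE] * sj$len
    keep <- (seg_end - seg_start) > 1e-6
    tower <- tw$tower_id[as.vector(near)]
    con <- data.frame(phone_id = rep(sj$phone_id, kk), tower_id = tower,
                      timestamp = as.vector(seg_start), event = "connect",
                      stringsAsFactors = FALSE)[as.vector(keep), ]
    dis <- data.frame(phone_id = rep(sj$phone_id, kk), tower_id = tower,
                      timestamp = as.vector(seg_end), event = "disconnect",
                      stringsAsFactors = FALSE)[as.vector(keep), ]
    rj <- rbind(con, dis)
    if (noise$service_rate > 0) {
      mid <- (con$timestamp + dis$timestamp) / 2
      use <- stats::runif(nrow(con)) < noise$service_rate
      if (any(use)) {
        rj <- rbind(rj, data.frame(
          phone_id = con$phone_id[use], tower_id = con$tower_id[use],
          timestamp = mid[use], event = "service", stringsAsFactors = FALSE
        ))
      }
    }
    recs[[j]] <- rj
  }
  recs <- do.call(rbind, recs)
  ev_rank <- match(recs$event, c("disconnect", "service", "connect"))
  recs <- recs[order(recs$phone_id, recs$timestamp, ev_rank), ]
  rownames(recs) <- NULL
  recs
}

#' Simulate an aggregated city-day-hour panel directly from ground truth
#'
#' Shortcut for recovery experiments: instead of materialising individual
#' users, draws the cell counts `n[j,y,t,l]` from a multinomial with the
#' closed-form logit probabilities (distributionally identical to aggregating
#' [gen_choices()]), with a fresh city-day-hour shock `eta` per call. The
#' realised shocks are attached as `attr(panel, "eta")` so conditional
#' estimands can be computed.
#'
#' @param truth a [world_truth()] object.
#' @param aqi a [gen_aqi()] series.
#' @param n_per_cell users per city-hour cell.
#' @param measure pollution term entering utilities.
#' @param eta "draw" (fresh shocks, sd `truth$eta_sd`), "truth" (the stored
#'   world shocks) or "zero".
#' @param counts "multinomial" draws cell counts; "expected" uses the exact
#'   expected counts `n_per_cell * p` (no sampling noise), which makes the
#'   log-odds regression identified to machine precision.
#' @param seed optional seed.
#' @return a panel data.frame as produced by [build_panel()].
#' @export
gen_panel <- function(truth, aqi, n_per_cell = 5000,
                      measure = c("levels", "aqi"),
                      eta = c("draw", "truth", "zero"),
                      counts = c("multinomial", "expected"), seed = NULL) {
  measure <- match.arg(measure)
  eta <- match.arg(eta)
  counts_mode <- match.arg(counts)
  if (!is.null(seed)) set.seed(seed)
  cfg <- truth$config
  nh <- length(cfg$hours)
  eta_arr <- switch(eta,
    truth = truth$eta,
    zero = NULL,
    draw = array(stats::rnorm(cfg$n_cities * cfg$n_days * nh * 3, 0, truth$eta_sd),
                 dim = c(cfg$n_cities, cfg$n_days, nh, 3),
                 dimnames = list(NULL, NULL, cfg$hours, .locations))
  )
  cells <- cell_utilities(truth, aqi, measure, eta = eta_arr)
  pmat <- as.matrix(cells[, c("p_h", "p_m", "p_p", "p_o")])
  counts <- if (counts_mode == "expected") {
    n_per_cell * pmat
  } else {
    t(apply(pmat, 1, function(p) stats::rmultinom(1, n_per_cell, p)))
  }
  panel <- data.frame(
    city = cells$city, day = cells$day, hour = cells$hour,
    n_total = n_per_cell,
    n_h = counts[, 1], n_m = counts[, 2], n_p = counts[, 3], n_o = counts[, 4],
    aqi = cells$aqi, level = cells$level,
    stringsAsFactors = FALSE
  )
  panel <- add_share_columns(panel)
  emat <- as.matrix(cells[, paste0("v.", .locations)]) * 0
  if (!is.null(eta_arr)) {
    ti <- match(cells$hour, cfg$hours)
    for (q in seq_along(.locations)) {
      emat[, q] <- eta_arr[cbind(cells$city, cells$day, ti, q)]
    }
  }
  colnames(emat) <- .locations
  attr(panel, "eta") <- emat
  panel
}

#' Map ground truth into the coefficient parameterisation of a fitted model
#'
#' The log-odds regression is estimated with reference coding (first city-day
#' and first hour absorbed into the intercept). This maps the truth's
#' saturated parameters onto that coding, so fitted coefficients can be
#' compared one-to-one with truth.
#'
#' @param truth a [world_truth()] object.
#' @param fit a [fit_share_logit()] result (supplies design-column names).
#' @return matrix with the same rows/columns as `coef(fit)`.
#' @export
truth_coefficients <- function(truth, fit) {
  cfg <- truth$config
  cn <- rownames(fit$coefficients)
  out <- matrix(0, length(cn), 3, dimnames = list(cn, .locations))
  h0 <- cfg$hours[1]
  for (q in seq_along(.locations)) {
    l <- .locations[q]
    for (nm in cn) {
      out[nm, q] <-
        if (nm == "(Intercept)") truth$gamma[1, 1, q] + truth$delta[as.character(h0), q]
        else if (grepl("^cd\\d+_\\d+$", nm)) {
          ji <- as.integer(sub("cd(\\d+)_(\\d+)", "\\1", nm))
          yi <- as.integer(sub("cd(\\d+)_(\\d+)", "\\2", nm))
          truth$gamma[ji, yi, q] - truth$gamma[1, 1, q]
        } else if (grepl("^hr\\d+$", nm)) {
          ti <- sub("hr", "", nm)
          truth$delta[ti, q] - truth$delta[as.character(h0), q]
        } else if (nm %in% rownames(truth$beta_level)) truth$beta_level[nm, q]
        else if (nm == "aqi") truth$beta_aqi[q]
        else if (nm == "aqi:t") truth$beta_t[q]
        else if (nm == "aqi:t2") truth$beta_t2[q]
        else 0
    }
  }
  out
}

#' Ground-truth level-switch effect on choice shares
#'
#' Evaluates the counterfactual share difference (to-level minus from-level)
#' with the *true* parameters and the supplied cell shocks, averaged over all
#' panel cells — the estimand the fitted level-switch effect targets.
#'
#' @param truth a [world_truth()] object.
#' @param panel a panel with city/day/hour/aqi columns.
#' @param from,to level names.
#' @param eta cell shock matrix (rows = panel rows, columns m, p, o);
#'   defaults to the shocks attached to `panel` by [gen_panel()].
#' @return named vector of share changes for h, m, p, o (sums to zero).
#' @export
true_level_effect <- function(truth, panel, from = "Good",
                              to = "Heavily_Polluted",
                              eta = attr(panel, "eta")) {
  cfg <- truth$config
  if (is.null(eta)) eta <- matrix(0, nrow(panel), 3, dimnames = list(NULL, .locations))
  ti <- match(panel$hour, cfg$hours)
  base <- sapply(seq_along(.locations), function(q) {
    truth$gamma[cbind(panel$city, panel$day, q)] + truth$delta[cbind(ti, q)] + eta[, q]
  })
  shift <- function(level) {
    b <- if (level %in% rownames(truth$beta_level)) truth$beta_level[level, ] else c(0, 0, 0)
    v <- sweep(base, 2, b, "+")
    colnames(v) <- .locations
    logit_invert(v)
  }
  d <- colMeans(shift(to)) - colMeans(shift(from))
  stats::setNames(d, c("h", .locations))
}

#' Write the synthetic world's interchange files
#'
#' Emits towers.csv, facilities.geojson, aqi.csv and truth.json into `dir`.
#' The CSV schemas are the interchange contract also accepted for real data.
#'
#' @param world a [gen_world()] world.
#' @param aqi a [gen_aqi()] series.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, aqi, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(world$towers, file.path(dir, "towers.csv"), row.names = FALSE)
  utils::write.csv(aqi, file.path(dir, "aqi.csv"), row.names = FALSE)
  write_facilities_geojson(c(world$parks, world$malls),
                           file.path(dir, "facilities.geojson"))
  truth <- world$truth
  tr <- list(
    gamma = truth$gamma, delta = truth$delta,
    beta_level = truth$beta_level, beta_aqi = truth$beta_aqi,
    beta_t = truth$beta_t, beta_t2 = truth$beta_t2, eta_sd = truth$eta_sd,
    gamma_d = truth$gamma_d, delta_d = truth$delta_d,
    beta_d_level = truth$beta_d_level, beta_d_aqi = truth$beta_d_aqi,
    sigma_d = truth$sigma_d, substitution = truth$substitution,
    home_coords = truth$home_coords
  )
  jsonlite::write_json(tr, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "columnmajor")
  invisible(dir)
}
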