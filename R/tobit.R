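# Double-censored (Tobit) regression of hourly distance from home. The
# latent distance is linear in city-day and hour fixed effects plus
# pollution covariates with a normal error; the observed distance is clipped
# at 0 below and at the 50 km bin above. The censored-normal log-likelihood
# is maximised by quasi-Newton iterations from an OLS start, with sigma
# parameterised on the log scale.

#' Specification of the distance (Tobit) model
#'
#' @inheritParams choice_spec
#' @param lower,upper censoring limits in metres (defaults 0 and 50,000).
#' @return list of class `tobit_spec`.
#' @export
tobit_spec <- function(measure = c("levels", "aqi"),
                       interactions = c("none", "t2"),
                       covariates = character(0),
                       lower = 0, upper = 50000) {
  stopifnot(is.finite(lower), is.finite(upper), lower < upper)
  structure(
    list(measure = match.arg(measure),
         interactions = match.arg(interactions),
         covariates = covariates, lower = lower, upper = upper),
    class = "tobit_spec"
  )
}

# Negative log-likelihood and gradient of the double-censored normal model.
# theta = c(beta, log sigma); code: 0 interior, -1 lower-censored, 1 upper.
censnorm_negll <- function(theta, X, y, code, lower, upper) {
  p <- ncol(X)
  beta <- theta[1:p]
  sigma <- exp(theta[p + 1])
  mu <- drop(X %*% beta)
  ll <- numeric(length(y))
  i0 <- code == 0L; iu <- code == 1L; il <- code == -1L
  ll[i0] <- stats::dnorm(y[i0], mu[i0], sigma, log = TRUE)
  if (any(iu)) ll[iu] <- stats::pnorm((mu[iu] - upper) / sigma, log.p = TRUE)
  if (any(il)) ll[il] <- stats::pnorm((lower - mu[il]) / sigma, log.p = TRUE)
  -sum(ll)
}

censnorm_grad <- function(theta, X, y, code, lower, upper) {
  p <- ncol(X)
  beta <- theta[1:p]
  sigma <- exp(theta[p + 1])
  mu <- drop(X %*% beta)
  i0 <- code == 0L; iu <- code == 1L; il <- code == -1L
  gmu <- numeric(length(y))   # d loglik / d mu
  gls <- numeric(length(y))   # d loglik / d log sigma
  r <- (y[i0] - mu[i0]) / sigma
  gmu[i0] <- r / sigma
  gls[i0] <- r^2 - 1
  mills <- function(z) exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
  if (any(iu)) {
    a <- (mu[iu] - upper) / sigma
    lam <- mills(a)
    gmu[iu] <- lam / sigma
    gls[iu] <- -lam * a
  }
  if (any(il)) {
    b <- (lower - mu[il]) / sigma
    lam <- mills(b)
    gmu[il] <- -lam / sigma
    gls[il] <- -lam * b
  }
  -c(drop(crossprod(X, gmu)), sum(gls))
}

#' Maximum-likelihood fit of a double-censored normal regression
#'
#' Low-level fitter on an explicit design matrix: interior observations
#' contribute the normal density, observations at the limits contribute the
#' corresponding tail probability. Optimised by BFGS with analytic
#' gradients from an OLS start; convergence requires the gradient sup-norm
#' to fall below `1e-6 * max(1, |loglik|)`.
#'
#' @param X design matrix.
#' @param y observed outcome (clipped at the limits).
#' @param lower,upper censoring limits.
#' @param censored_lower,censored_upper logical vectors; by default an
#'   observation is treated as censored exactly when `y` sits at a limit.
#' @return list: coefficients, sigma, logLik, vcov (for c(beta, log sigma)),
#'   se, convergence record.
#' @export
censnorm_mle <- function(X, y, lower = 0, upper = 50000,
                         censored_lower = y <= lower,
                         censored_upper = y >= upper) {
  X <- as.matrix(X)
  code <- integer(length(y))
  code[censored_lower] <- -1L
  code[censored_upper] <- 1L
  if (all(code != 0L)) stop("all observations are censored; model not identified")
  ls <- stats::lm.fit(X, y)
  if (anyNA(ls$coefficients)) {
    stop("design is rank deficient; collinear column(s): ",
         paste(names(ls$coefficients)[is.na(ls$coefficients)], collapse = ", "))
  }
  start <- c(ls$coefficients, log(stats::sd(ls$residuals)))
  fn <- function(th) censnorm_negll(th, X, y, code, lower, upper)
  gr <- function(th) censnorm_grad(th, X, y, code, lower, upper)
  pscale <- pmax(abs(start), 1e-2)  # beta and log sigma live on very
  opt <- stats::optim(start, fn, gr, method = "BFGS",  # different scales
                      control = list(maxit = 500, reltol = 1e-12,
                                     parscale = pscale))
  g <- gr(opt$par)
  tol <- 1e-6 * max(1, abs(opt$value))
  if (max(abs(g)) > tol) {
    opt <- stats::optim(opt$par, fn, gr, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-14,
                                       parscale = pscale))
    g <- gr(opt$par)
    if (max(abs(g)) > tol) {
      stop("Tobit optimisation did not converge (gradient sup-norm ",
           format(max(abs(g))), ")")
    }
  }
  p <- ncol(X)
  H <- stats::optimHess(opt$par, fn, gr)
  vcov <- tryCatch(solve(H), error = function(e) matrix(NA, p + 1, p + 1))
  beta <- opt$par[1:p]
  names(beta) <- colnames(X)
  list(
    coefficients = beta, sigma = unname(exp(opt$par[p + 1])),
    logLik = -opt$value, vcov = vcov,
    se = sqrt(pmax(diag(vcov), 0)),
    gradient_norm = max(abs(g)),
    n = length(y), n_lower = sum(code == -1L), n_upper = sum(code == 1L),
    counts = opt$counts, convergence = opt$convergence
  )
}

#' Fit the Tobit distance-from-home model
#'
#' Builds the same fixed-effect + pollution design as the share regressions
#' (city-day and hour dummies, level dummies or continuous AQI, optional
#' t/t^2 interactions) on individual phone-hours and maximises the
#' double-censored normal likelihood of the binned distance.
#'
#' @param placements labelled or raw placements with `distance_mid`,
#'   `censored_upper`, city, day, hour columns and, for pollution terms, an
#'   AQI join (see `aqi`).
#' @param spec a [tobit_spec()].
#' @param aqi hourly AQI series to join on (city, day, hour); not needed if
#'   the placements already carry `aqi`/level columns.
#' @return object of class `tobit_fit`.
#' @export
fit_tobit <- function(placements, spec = tobit_spec(), aqi = NULL) {
  df <- placements
  if (!is.null(aqi)) {
    df <- merge(df, aqi[, c("city", "day", "hour", "aqi", "level")],
                by = c("city", "day", "hour"), sort = FALSE)
  }
  if (spec$measure == "levels") {
    for (d in aqi_dummy_levels()) {
      df[[d]] <- as.integer(as.character(df$level) == d)
    }
  }
  X <- choice_design(df, spec)
  y <- df$distance_mid
  fit <- censnorm_mle(X, y, spec$lower, spec$upper,
                      censored_lower = y <= spec$lower,
                      censored_upper = df$censored_upper)
  fit$spec <- spec
  fit$data <- df
  fit$X <- X
  class(fit) <- "tobit_fit"
  fit
}

# E[observed d | mu, sigma] under double censoring at [L, U].
censored_mean <- function(mu, sigma, lower, upper) {
  aL <- (lower - mu) / sigma
  aU <- (upper - mu) / sigma
  lower * stats::pnorm(aL) + upper * stats::pnorm(aU, lower.tail = FALSE) +
    mu * (stats::pnorm(aU) - stats::pnorm(aL)) +
    sigma * (stats::dnorm(aL) - stats::dnorm(aU))
}

#' Marginal effect of pollution on distance from home
#'
#' Contrasts two pollution scenarios (level switch, or an AQI increase of
#' `delta_aqi`) and reports both the latent effect (the coefficient
#' contrast, averaged over observations) and the expected-observed effect
#' (the change in the doubly-censored normal mean E[d | x], averaged over
#' observations).
#'
#' @param fit a [fit_tobit()] fit.
#' @param from,to level names for a level-switch contrast.
#' @param delta_aqi AQI increase for a continuous contrast (used when the
#'   fit's measure is "aqi").
#' @return list with `latent` and `observed` effects in metres, plus the
#'   per-row contrasts.
#' @export
tobit_effect <- function(fit, from = "Good", to = "Heavily_Polluted",
                         delta_aqi = 10) {
  X <- fit$X
  t <- fit$data$hour
  sub_design <- function(scen) {
    f2 <- list(X = X, panel = fit$data, spec = fit$spec, zero_cols = character(0))
    scenario_design(f2, scen)
  }
  if (fit$spec$measure == "levels") {
    X_from <- sub_design(list(level = from))
    X_to <- sub_design(list(level = to))
  } else {
    a <- fit$data$aqi
    if (is.null(a)) stop("continuous contrast requires an aqi column")
    X_from <- X
    X_to <- X
    X_to[, "aqi"] <- X_from[, "aqi"] + delta_aqi
    if ("aqi:t" %in% colnames(X)) {
      X_to[, "aqi:t"] <- X_to[, "aqi"] * t
      X_to[, "aqi:t2"] <- X_to[, "aqi"] * t^2
    }
  }
  mu_from <- drop(X_from %*% fit$coefficients)
  mu_to <- drop(X_to %*% fit$coefficients)
  latent <- mu_to - mu_from
  observed <- censored_mean(mu_to, fit$sigma, fit$spec$lower, fit$spec$upper) -
    censored_mean(mu_from, fit$sigma, fit$spec$lower, fit$spec$upper)
  list(latent = mean(latent), observed = mean(observed),
       latent_rows = latent, observed_rows = observed)
}

#' Hourly profile of the Tobit pollution effect
#'
#' Evaluates the [tobit_effect()] contrast within each hour stratum; with a
#' t/t^2-interaction fit this traces the time-varying distance response.
#'
#' @inheritParams tobit_effect
#' @return data.frame hour, latent, observed (metres).
#' @export
tobit_hourly <- function(fit, from = "Good", to = "Heavily_Polluted",
                         delta_aqi = 10) {
  eff <- tobit_effect(fit, from, to, delta_aqi)
  t <- fit$data$hour
  out <- do.call(rbind, lapply(sort(unique(t)), function(tt) {
    i <- t == tt
    data.frame(hour = tt, latent = mean(eff$latent_rows[i]),
               observed = mean(eff$observed_rows[i]))
  }))
  attr(out, "pooled") <- c(latent = eff$latent, observed = eff$observed)
  out
}

#' Median distance from home by city and hour
#'
#' Descriptive summary pooling days: the median binned distance per
#' (city, hour) stratum.
#'
#' @param placements placements with `distance_mid`.
#' @return data.frame city, hour, median_distance.
#' @export
summarize_distance <- function(placements) {
  dt <- data.table::as.data.table(placements)
  out <- dt[, list(median_distance = stats::median(distance_mid)),
            by = c("city", "hour")]
  data.table::setorder(out, city, hour)
  as.data.frame(out)
}
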