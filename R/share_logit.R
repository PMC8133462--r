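# Aggregated multinomial-logit share regressions: the log-odds of each
# non-home location against home is linear in city-day and hour fixed
# effects plus pollution covariates, and is fitted by one OLS regression per
# location. Counterfactual shares are obtained by inverting the logit.

#' Model specification for the share regressions
#'
#' @param measure pollution measure: "levels" (dummies for the non-Good AQI
#'   categories, "Good" omitted as the benchmark) or "aqi" (continuous).
#' @param interactions "none" or "t2" (interact the pollution terms with
#'   hour t and t^2 for time-varying effects).
#' @param covariates names of extra panel columns to include.
#' @return list of class `choice_spec`.
#' @export
choice_spec <- function(measure = c("levels", "aqi"),
                        interactions = c("none", "t2"),
                        covariates = character(0)) {
  structure(
    list(measure = match.arg(measure),
         interactions = match.arg(interactions),
         covariates = covariates),
    class = "choice_spec"
  )
}

# Design matrix with reference coding: intercept; city-day dummies cd{j}_{y}
# (first city-day omitted); hour dummies hr{t} (first hour omitted);
# pollution terms; extra covariates.
choice_design <- function(panel, spec) {
  n <- nrow(panel)
  cd <- interaction(panel$city, panel$day, drop = TRUE, lex.order = TRUE)
  cd_levels <- levels(cd)
  hours <- sort(unique(panel$hour))
  cols <- list("(Intercept)" = rep(1, n))
  for (lv in cd_levels[-1]) {
    jy <- strsplit(lv, ".", fixed = TRUE)[[1]]
    cols[[paste0("cd", jy[1], "_", jy[2])]] <- as.numeric(cd == lv)
  }
  for (t in hours[-1]) cols[[paste0("hr", t)]] <- as.numeric(panel$hour == t)
  t <- panel$hour
  if (spec$measure == "levels") {
    for (d in aqi_dummy_levels()) {
      v <- panel[[d]]
      if (is.null(v) || sum(v) == 0) next  # level unobserved in this panel
      cols[[d]] <- v
      if (spec$interactions == "t2") {
        cols[[paste0(d, ":t")]] <- v * t
        cols[[paste0(d, ":t2")]] <- v * t^2
      }
    }
  } else {
    cols[["aqi"]] <- panel$aqi
    if (spec$interactions == "t2") {
      cols[["aqi:t"]] <- panel$aqi * t
      cols[["aqi:t2"]] <- panel$aqi * t^2
    }
  }
  for (v in spec$covariates) {
    if (is.null(panel[[v]])) stop("covariate column not in panel: ", v)
    cols[[v]] <- panel[[v]]
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

# Core least-squares fit of the three log-odds equations on a shared design.
make_choice_fit <- function(X, Y, panel, spec, check_rank = TRUE) {
  p <- ncol(X)
  coefs <- matrix(NA_real_, p, 3, dimnames = list(colnames(X), c("m", "p", "o")))
  resid <- matrix(NA_real_, nrow(X), 3, dimnames = list(NULL, c("m", "p", "o")))
  sigma2 <- numeric(3)
  dfres <- numeric(3)
  zero_cols <- character(0)
  for (q in 1:3) {
    ok <- !is.na(Y[, q])
    f <- stats::lm.fit(X[ok, , drop = FALSE], Y[ok, q])
    b <- f$coefficients
    if (anyNA(b)) {
      unsupported <- colSums(abs(X[ok, , drop = FALSE])) == 0
      dead <- names(b)[is.na(b) & !unsupported]
      if (check_rank && length(dead) > 0) {
        stop("design is rank deficient; collinear column(s): ",
             paste(dead, collapse = ", "))
      }
      zero_cols <- union(zero_cols, names(b)[is.na(b)])
      b[is.na(b)] <- 0  # columns with no support in this (re)sample
    }
    coefs[, q] <- b
    resid[ok, q] <- f$residuals
    dfres[q] <- sum(ok) - f$rank
    sigma2[q] <- sum(f$residuals^2) / max(dfres[q], 1)
  }
  structure(
    list(coefficients = coefs, residuals = resid, sigma2 = sigma2,
         df_residual = dfres, X = X, panel = panel, spec = spec,
         zero_cols = zero_cols),
    class = "choice_fit"
  )
}

#' Fit the aggregated logit share regressions
#'
#' Estimates, for each location l in \{m, p, o\}, the linear regression of
#' `ln(n_l) - ln(n_h)` on city-day fixed effects, hour fixed effects, and
#' the pollution covariates of `spec`, by ordinary least squares on the
#' city-day-hour panel. The three equations share one design matrix.
#'
#' @param panel a [build_panel()] panel.
#' @param spec a [choice_spec()].
#' @param zero_policy zero-count handling passed to the log-odds computation.
#' @return object of class `choice_fit` with elements `coefficients`
#'   (columns m, p, o), `residuals`, `sigma2`, `X`, `panel`, `spec`.
#' @export
fit_share_logit <- function(panel, spec = choice_spec(),
                            zero_policy = "error") {
  X <- choice_design(panel, spec)
  if (nrow(X) < ncol(X)) stop("fewer panel rows than parameters per location")
  Y <- log_odds_matrix(panel, zero_policy)
  make_choice_fit(X, Y, panel, spec)
}

#' @export
coef.choice_fit <- function(object, ...) object$coefficients

#' Standard errors of a choice fit
#' @param fit a `choice_fit`.
#' @return matrix of standard errors matching `coef(fit)`.
#' @export
se_choice_fit <- function(fit) {
  R <- qr.R(qr(fit$X))
  XtXinv <- chol2inv(R)
  out <- sqrt(outer(diag(XtXinv), fit$sigma2))
  dimnames(out) <- dimnames(fit$coefficients)
  out
}

# Counterfactual design: copy X and overwrite the pollution columns for a
# scenario. A scenario is list(level = "<name>") or list(aqi = <value>).
scenario_design <- function(fit, scenario) {
  X <- fit$X
  t <- fit$panel$hour
  sp <- fit$spec
  pollution_cols <- if (sp$measure == "levels") {
    dl <- aqi_dummy_levels()
    intersect(c(dl, paste0(rep(dl, each = 2), c(":t", ":t2"))), colnames(X))
  } else {
    intersect(c("aqi", "aqi:t", "aqi:t2"), colnames(X))
  }
  X[, pollution_cols] <- 0
  if (!is.null(scenario$level)) {
    if (sp$measure != "levels") stop("scenario sets a level but the fit uses continuous AQI")
    lvl <- scenario$level
    if (!lvl %in% c("Good", aqi_dummy_levels())) stop("unknown AQI level: ", lvl)
    if (lvl != "Good") {
      if (!lvl %in% colnames(X)) {
        stop("level ", lvl, " has no dummy in this fit (unobserved in the panel)")
      }
      if (lvl %in% fit$zero_cols) {
        stop("level ", lvl, " has no support in this (re)sample")
      }
      X[, lvl] <- 1
      if (paste0(lvl, ":t") %in% colnames(X)) {
        X[, paste0(lvl, ":t")] <- t
        X[, paste0(lvl, ":t2")] <- t^2
      }
    }
  } else if (!is.null(scenario$aqi)) {
    if (sp$measure != "aqi") stop("scenario sets an AQI value but the fit uses level dummies")
    X[, "aqi"] <- scenario$aqi
    if ("aqi:t" %in% colnames(X)) {
      X[, "aqi:t"] <- scenario$aqi * t
      X[, "aqi:t2"] <- scenario$aqi * t^2
    }
  } else {
    stop("scenario must set either a level or an aqi value")
  }
  X
}

#' Counterfactual choice shares under a pollution scenario
#'
#' Inverts the fitted log-odds into shares for every panel row with the
#' pollution covariates set to the scenario and everything else at its
#' observed value: `s_h = 1 / (1 + sum(exp(v_l)))`, `s_l = exp(v_l) s_h`.
#' Estimated cell residuals are included in `v` by default (they sit inside
#' the exponent of the share inversion); `include_residuals = FALSE` gives
#' smooth fitted-only predictions.
#'
#' @param fit a [fit_share_logit()] fit.
#' @param scenario `list(level = "<name>")` (use "Good" for the omitted
#'   benchmark) or `list(aqi = <value>)`; NULL reproduces observed
#'   covariates.
#' @param include_residuals logical.
#' @return matrix with columns p_h, p_m, p_p, p_o; rows sum to one.
#' @export
counterfactual_shares <- function(fit, scenario = NULL,
                                  include_residuals = TRUE) {
  X <- if (is.null(scenario)) fit$X else scenario_design(fit, scenario)
  v <- X %*% fit$coefficients
  if (include_residuals) v <- v + fit$residuals
  logit_invert(v)
}

effect_table <- function(d_share, base_share) {
  data.frame(
    location = c("h", "m", "p", "o"),
    d_share = d_share,
    d_pp = 100 * d_share,
    pct_change = 100 * d_share / base_share,
    per_million = 1e6 * d_share,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Marginal effect of switching the air-quality level
#'
#' Average over all panel rows of the counterfactual share difference
#' between the `to` and `from` levels (each row evaluated with its other
#' covariates at observed values). Reported per location as share change,
#' percentage points, percent change (ratio of averaged difference to the
#' averaged from-scenario share), and persons per one million.
#'
#' @param fit a levels-measure [fit_share_logit()] fit.
#' @param from,to level names (default "Good" to "Heavily_Polluted").
#' @param include_residuals include estimated cell residuals (default TRUE).
#' @return data.frame of class `effect_result`; the four share changes sum
#'   to zero.
#' @export
effect_level_switch <- function(fit, from = "Good", to = "Heavily_Polluted",
                                include_residuals = TRUE) {
  s_from <- counterfactual_shares(fit, list(level = from), include_residuals)
  s_to <- counterfactual_shares(fit, list(level = to), include_residuals)
  keep <- stats::complete.cases(s_from)
  d <- colMeans(s_to[keep, , drop = FALSE]) - colMeans(s_from[keep, , drop = FALSE])
  out <- effect_table(unname(d), unname(colMeans(s_from[keep, , drop = FALSE])))
  class(out) <- c("effect_result", class(out))
  out
}

#' Marginal effect of a continuous AQI increase
#'
#' Analytic derivatives of the inverted logit with respect to AQI,
#' `ds_l/dAQI = s_l b_l - s_l sum(b_l' s_l')` for non-home locations and
#' `ds_h/dAQI = -s_h sum(b_l' s_l')`, scaled by `delta` (default 10 AQI
#' points). With `at = "means"` the shares are the sample means of the
#' observed panel shares (and, under a t-interaction fit, the AQI slopes are
#' evaluated at the sample-mean hour); with `at = "rows"` the derivative is
#' computed row by row at observed shares and averaged, which decomposes
#' exactly across hour strata.
#'
#' @param fit an aqi-measure [fit_share_logit()] fit.
#' @param delta AQI increase to scale by.
#' @param at "means" or "rows".
#' @return data.frame of class `effect_result`.
#' @export
effect_continuous <- function(fit, delta = 10, at = c("means", "rows")) {
  at <- match.arg(at)
  if (fit$spec$measure != "aqi") {
    stop("continuous marginal effects require a fit with measure = 'aqi'")
  }
  b <- aqi_slopes(fit)
  sh <- as.matrix(fit$panel[, c("s_h", "s_m", "s_p", "s_o")])
  if (at == "means") {
    sbar <- colMeans(sh)
    bbar <- colMeans(b)
    d <- share_derivative(sbar, bbar) * delta
    out <- effect_table(unname(d), unname(sbar))
  } else {
    dmat <- t(vapply(seq_len(nrow(sh)),
                     function(i) share_derivative(sh[i, ], b[i, ]),
                     numeric(4)))
    d <- colMeans(dmat) * delta
    out <- effect_table(unname(d), unname(colMeans(sh)))
  }
  class(out) <- c("effect_result", class(out))
  out
}

# AQI slope per row and location (n x 3), honouring t/t^2 interactions.
aqi_slopes <- function(fit) {
  t <- fit$panel$hour
  b <- matrix(rep(fit$coefficients["aqi", ], each = length(t)),
              ncol = 3, dimnames = list(NULL, c("m", "p", "o")))
  if ("aqi:t" %in% rownames(fit$coefficients)) {
    b <- b + outer(t, fit$coefficients["aqi:t", ]) +
      outer(t^2, fit$coefficients["aqi:t2", ])
  }
  b
}

# ds/dAQI at shares s = (h, m, p, o) and slopes b = (m, p, o).
share_derivative <- function(s, b) {
  sumterm <- sum(b * s[2:4])
  c(-s[1] * sumterm, s[2:4] * b - s[2:4] * sumterm)
}

#' Hourly marginal-effect profile
#'
#' Evaluates the level-switch effect (or the continuous-AQI derivative)
#' within each hour stratum of the panel. With a t/t^2-interaction fit this
#' traces the time-varying response; without interactions all hours collapse
#' to the pooled effect. Stratum effects weighted by stratum size recompose
#' the pooled row-average effect exactly.
#'
#' @param fit a [fit_share_logit()] fit.
#' @param from,to levels for a level-switch profile (levels measure).
#' @param delta AQI increase for a continuous profile (aqi measure).
#' @param include_residuals passed to the level-switch evaluation.
#' @return data.frame hour, location, d_share, d_pp, per_million.
#' @export
hourly_effects <- function(fit, from = "Good", to = "Heavily_Polluted",
                           delta = 10, include_residuals = TRUE) {
  t <- fit$panel$hour
  if (fit$spec$measure == "levels") {
    s_from <- counterfactual_shares(fit, list(level = from), include_residuals)
    s_to <- counterfactual_shares(fit, list(level = to), include_residuals)
    dmat <- s_to - s_from
  } else {
    b <- aqi_slopes(fit)
    sh <- as.matrix(fit$panel[, c("s_h", "s_m", "s_p", "s_o")])
    dmat <- t(vapply(seq_len(nrow(sh)),
                     function(i) share_derivative(sh[i, ], b[i, ]),
                     numeric(4))) * delta
  }
  colnames(dmat) <- c("h", "m", "p", "o")
  out <- do.call(rbind, lapply(sort(unique(t)), function(tt) {
    d <- colMeans(dmat[t == tt, , drop = FALSE], na.rm = TRUE)
    data.frame(hour = tt, location = names(d), d_share = unname(d),
               d_pp = 100 * unname(d), per_million = 1e6 * unname(d),
               stringsAsFactors = FALSE)
  }))
  attr(out, "pooled") <- colMeans(dmat, na.rm = TRUE)
  out
}

#' Percentile bootstrap confidence intervals for panel estimators
#'
#' Resamples the panel (rows, or city-day blocks to respect within-day
#' dependence), refits the share regressions, re-evaluates `statistic`, and
#' returns percentile intervals. Replicates in which the estimator fails
#' (e.g. a resample without support for a required level) are dropped and
#' counted; more than 10% failures is an error.
#'
#' @param panel a [build_panel()] panel.
#' @param spec a [choice_spec()].
#' @param statistic function of a `choice_fit` returning a named numeric
#'   vector.
#' @param B number of bootstrap samples (default 500).
#' @param unit resampling unit: "city-day" or "row".
#' @param level confidence level (default 0.95).
#' @param seed optional seed; identical seeds give identical intervals.
#' @param zero_policy zero-count policy for the resampled fits.
#' @return list with `ci` (2 x k matrix of percentile bounds), `estimate`,
#'   `replicates` (B_ok x k), `n_failed`.
#' @export
bootstrap_ci <- function(panel, spec, statistic, B = 500,
                         unit = c("city-day", "row"), level = 0.95,
                         seed = NULL, zero_policy = "error") {
  unit <- match.arg(unit)
  stopifnot(B >= 2)
  if (!is.null(seed)) set.seed(seed)
  X <- choice_design(panel, spec)
  Y <- log_odds_matrix(panel, zero_policy)
  est <- statistic(make_choice_fit(X, Y, panel, spec))
  n <- nrow(panel)
  blocks <- if (unit == "city-day") {
    split(seq_len(n), interaction(panel$city, panel$day, drop = TRUE))
  } else NULL
  reps <- matrix(NA_real_, B, length(est),
                 dimnames = list(NULL, names(est)))
  n_failed <- 0
  for (bi in seq_len(B)) {
    idx <- if (unit == "row") {
      sample.int(n, n, replace = TRUE)
    } else {
      unlist(blocks[sample.int(length(blocks), length(blocks), replace = TRUE)],
             use.names = FALSE)
    }
    r <- tryCatch(
      statistic(make_choice_fit(X[idx, , drop = FALSE], Y[idx, , drop = FALSE],
                                panel[idx, , drop = FALSE], spec,
                                check_rank = FALSE)),
      error = function(e) NULL
    )
    if (is.null(r) || anyNA(r)) n_failed <- n_failed + 1 else reps[bi, ] <- r
  }
  if (n_failed > 0.1 * B) {
    stop(n_failed, " of ", B, " bootstrap replicates failed")
  }
  reps <- reps[stats::complete.cases(reps), , drop = FALSE]
  alpha <- (1 - level) / 2
  ci <- apply(reps, 2, stats::quantile, probs = c(alpha, 1 - alpha))
  list(ci = ci, estimate = est, replicates = reps, n_failed = n_failed)
}

#' Convenience statistic: share change per location for a level switch
#'
#' @param from,to level names.
#' @param include_residuals passed through.
#' @return function of a `choice_fit` for use with [bootstrap_ci()].
#' @export
stat_level_switch <- function(from = "Good", to = "Heavily_Polluted",
                              include_residuals = TRUE) {
  function(fit) {
    e <- effect_level_switch(fit, from, to, include_residuals)
    stats::setNames(e$d_share, e$location)
  }
}
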