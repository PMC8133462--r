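# Aggregated logit: identification, counterfactual inversion, marginal
# effects, bootstrap, and scale invariance.

small_truth <- function(measure = "levels", seed = 51, ...) {
  cfg <- world_config(n_cities = 3, n_days = 2, n_users_per_city = 10,
                      towers_per_city = 9, seed = seed)
  set.seed(seed)
  truth <- world_truth(cfg, ...)
  aqi <- gen_aqi(cfg, "wave")
  list(cfg = cfg, truth = truth, aqi = aqi)
}

test_that("a noiseless exact-logit panel identifies every coefficient", {
  s <- small_truth()
  pan <- gen_panel(s$truth, s$aqi, n_per_cell = 1000, measure = "levels",
                   eta = "zero", counts = "expected")
  fit <- fit_share_logit(pan, choice_spec("levels"))
  expect_equal(coef(fit), truth_coefficients(s$truth, fit), tolerance = 1e-9)
  # residuals vanish and fitted + residuals reproduce the log odds exactly
  expect_lt(max(abs(fit$residuals)), 1e-10)
  # same for the continuous measure with hour interactions
  s2 <- small_truth(beta_t = c(1e-4, -2e-4, 5e-5), beta_t2 = c(-1e-5, 1e-5, 0))
  pan2 <- gen_panel(s2$truth, s2$aqi, n_per_cell = 1000, measure = "aqi",
                    eta = "zero", counts = "expected")
  fit2 <- fit_share_logit(pan2, choice_spec("aqi", "t2"))
  expect_equal(coef(fit2), truth_coefficients(s2$truth, fit2), tolerance = 1e-7)
})

test_that("estimates are invariant to row order and recover noisy truth", {
  s <- small_truth()
  pan <- gen_panel(s$truth, s$aqi, n_per_cell = 5000, measure = "levels",
                   eta = "draw", seed = 31)
  fit <- fit_share_logit(pan, choice_spec("levels"))
  perm <- sample(nrow(pan))
  fitp <- fit_share_logit(pan[perm, ], choice_spec("levels"))
  expect_equal(coef(fit), coef(fitp), tolerance = 1e-12)
  # single-replicate sanity: the pollution coefficients sit within 4
  # estimated SEs of truth (the full 3-SE coverage experiment is in the
  # acceptance suite)
  tr <- truth_coefficients(s$truth, fit)
  se <- se_choice_fit(fit)
  rows <- rownames(tr) %in% aqi_dummy_levels()
  expect_true(all(abs(coef(fit)[rows, ] - tr[rows, ]) <= 4 * se[rows, ]))
})

test_that("rank-deficient designs are rejected with the collinear column named", {
  s <- small_truth()
  pan <- gen_panel(s$truth, s$aqi, n_per_cell = 1000, seed = 3)
  pan$dup <- pan$Heavily_Polluted  # exact copy of an existing regressor
  expect_error(fit_share_logit(pan, choice_spec("levels", covariates = "dup")),
               "dup|Heavily")
})

test_that("counterfactual inversion is exact and matches hand arithmetic", {
  # hand-set utilities: v = (ln 2, 0, 0) -> shares (0.2, 0.4, 0.2, 0.2)
  sh <- logit_invert(matrix(c(log(2), 0, 0), 1, dimnames = list(NULL, c("m", "p", "o"))))
  expect_equal(drop(sh), c(p_h = 0.2, p_m = 0.4, p_p = 0.2, p_o = 0.2))
  s <- small_truth()
  pan <- gen_panel(s$truth, s$aqi, n_per_cell = 4000, seed = 9)
  fit <- fit_share_logit(pan, choice_spec("levels"))
  # observed scenario reproduces the observed shares exactly
  obs <- counterfactual_shares(fit, NULL, include_residuals = TRUE)
  expect_equal(unname(obs),
               unname(as.matrix(pan[, c("s_h", "s_m", "s_p", "s_o")])),
               tolerance = 1e-12)
  expect_equal(rowSums(counterfactual_shares(fit, list(level = "Heavily_Polluted"))),
               rep(1, nrow(pan)), tolerance = 1e-12)
  # independent arithmetic for one row under a Good -> Heavily switch
  i <- which(pan$level == "Good")[1]
  b <- coef(fit)
  Xs <- fit$X[i, , drop = FALSE]
  Xs[, aqi_dummy_levels()[aqi_dummy_levels() %in% colnames(Xs)]] <- 0
  Xs[, "Heavily_Polluted"] <- 1
  v <- drop(Xs %*% b) + fit$residuals[i, ]
  e <- exp(v)
  manual <- c(1, e) / (1 + sum(e))
  got <- counterfactual_shares(fit, list(level = "Heavily_Polluted"))[i, ]
  expect_equal(unname(got), unname(manual), tolerance = 1e-12)
  expect_error(counterfactual_shares(fit, list(level = "Apocalyptic")), "unknown")
})

test_that("level-switch effects conserve the share simplex and scale correctly", {
  s <- small_truth()
  pan <- gen_panel(s$truth, s$aqi, n_per_cell = 4000, seed = 12)
  fit <- fit_share_logit(pan, choice_spec("levels"))
  eff <- effect_level_switch(fit)
  expect_lt(abs(sum(eff$d_share)), 1e-12)
  expect_equal(eff$per_million, eff$d_pp * 1e4)
  # a zeroed pollution response produces zero effects
  fit0 <- fit
  fit0$coefficients[aqi_dummy_levels()[aqi_dummy_levels() %in%
                                         rownames(fit0$coefficients)], ] <- 0
  eff0 <- effect_level_switch(fit0)
  expect_equal(eff0$d_share, rep(0, 4), tolerance = 1e-14)
  # the generated world has a positive home response to pollution
  expect_gt(eff$d_share[eff$location == "h"], 0)
})

test_that("analytic AQI derivatives equal the finite-difference oracle", {
  s <- small_truth()
  pan <- gen_panel(s$truth, s$aqi, n_per_cell = 4000, measure = "aqi", seed = 15)
  fit <- fit_share_logit(pan, choice_spec("aqi"))
  eff <- effect_continuous(fit, delta = 1)
  expect_lt(abs(sum(eff$d_share)), 1e-12)
  # oracle: central difference of the inverted logit at the sample means
  sbar <- colMeans(pan[, c("s_h", "s_m", "s_p", "s_o")])
  b <- coef(fit)["aqi", ]
  f <- function(da) {
    v <- log(sbar[2:4] / sbar[1]) + b * da
    drop(logit_invert(matrix(v, 1, dimnames = list(NULL, c("m", "p", "o")))))
  }
  h <- 1e-3
  num <- (f(h) - f(-h)) / (2 * h)
  expect_equal(eff$d_share, unname(num), tolerance = 1e-6)
  expect_error(effect_continuous(fit_share_logit(pan, choice_spec("levels"))),
               "aqi")
})

test_that("hourly effects collapse to the pooled effect and recompose exactly", {
  s <- small_truth()
  pan <- gen_panel(s$truth, s$aqi, n_per_cell = 4000, measure = "aqi", seed = 18)
  # without interactions the latent slopes are hour-constant
  fit <- fit_share_logit(pan, choice_spec("aqi"))
  he <- hourly_effects(fit, delta = 10)
  pooled <- attr(he, "pooled")
  # stratum sizes are equal here; the weighted recomposition is exact
  for (l in c("h", "m", "p", "o")) {
    strata <- he$d_share[he$location == l]
    expect_equal(mean(strata), unname(pooled[l]), tolerance = 1e-12)
  }
  rows_eff <- effect_continuous(fit, delta = 10, at = "rows")
  expect_equal(rows_eff$d_share, unname(pooled[c("h", "m", "p", "o")]),
               tolerance = 1e-12)
  # an interaction fit with zero interaction truth stays flat within noise
  fit2 <- fit_share_logit(pan, choice_spec("aqi", "t2"))
  he2 <- hourly_effects(fit2, delta = 10)
  hprof <- he2$d_share[he2$location == "h"]
  expect_lt(diff(range(hprof)), 0.1)
})

test_that("a U-shaped hourly response is recovered by the interaction fit", {
  # truth with an AQI slope strongest at the day edges, weakest mid-day
  s <- small_truth(beta_t = c(0, 0, 6e-4), beta_t2 = c(0, 0, -2e-5))
  pan <- gen_panel(s$truth, s$aqi, n_per_cell = 50000, measure = "aqi", seed = 21)
  fit <- fit_share_logit(pan, choice_spec("aqi", "t2"))
  he <- hourly_effects(fit, delta = 10)
  est <- he$d_share[he$location == "h"]
  bo <- s$truth$beta_aqi["o"] + s$truth$beta_t["o"] * (7:22) +
    s$truth$beta_t2["o"] * (7:22)^2
  # the true home response profile mirrors -slope_o; compare shapes
  expect_gt(cor(est, -bo), 0.8)
})

test_that("bootstrap intervals are seeded, degenerate without noise, and robust", {
  s <- small_truth()
  pan <- gen_panel(s$truth, s$aqi, n_per_cell = 4000, seed = 25)
  st <- stat_level_switch()
  b1 <- bootstrap_ci(pan, choice_spec("levels"), st, B = 50, seed = 77)
  b2 <- bootstrap_ci(pan, choice_spec("levels"), st, B = 50, seed = 77)
  expect_identical(b1$ci, b2$ci)
  expect_true(all(b1$ci[1, ] <= b1$estimate & b1$estimate <= b1$ci[2, ]))
  # noiseless data: every resample refits the same coefficients exactly
  pan0 <- gen_panel(s$truth, s$aqi, n_per_cell = 1000, eta = "zero",
                    counts = "expected")
  stat_coef <- function(fit) c(bh = coef(fit)["Heavily_Polluted", "o"])
  b0 <- bootstrap_ci(pan0, choice_spec("levels"), stat_coef, B = 40,
                     unit = "row", seed = 5)
  expect_lt(diff(b0$ci[, "bh"]), 1e-9)
})

test_that("count rescaling leaves estimates and effects bit-unchanged", {
  s <- small_truth()
  pan <- gen_panel(s$truth, s$aqi, n_per_cell = 4000, seed = 29)
  fit <- fit_share_logit(pan, choice_spec("levels"))
  eff <- effect_level_switch(fit)
  for (k in c(2, 10, 0.5)) {
    pank <- pan
    for (cc in c("n_total", "n_h", "n_m", "n_p", "n_o")) pank[[cc]] <- pank[[cc]] * k
    pank <- mobiaq:::add_share_columns(pank)
    fitk <- fit_share_logit(pank, choice_spec("levels"))
    expect_identical(coef(fitk), coef(fit))
    expect_identical(effect_level_switch(fitk)$d_share, eff$d_share)
  }
})
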