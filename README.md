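# mobiaq

Air pollution changes where people go. When a city's Air Quality Index
(AQI) climbs from "Good" (51–100) to "Heavily Polluted" (201–300), do
people skip the park, shelter in malls, or simply stay home — and by how
much? **mobiaq** is an R package for answering that question from the
rawest large-scale mobility signal there is: mobile-phone tower connection
logs. It is aimed at researchers in environmental epidemiology, health
economics, and urban mobility who work with call-detail-record-style data
(or need a validated synthetic stand-in for it).

## What it does

The package implements the full measurement-and-inference chain:

1. **Geolocation** — per-phone dwell-time accounting over
   connect/disconnect/service records; hourly positions as dwell-weighted
   tower centroids; home inference from the 00:00–06:00 night window;
   sample filters (≥ 96 h span, ≥ 20 records); distances binned into 100 m
   intervals censored at 50 km.
2. **Facility classification** — Voronoi service areas per tower (built
   in-package by half-plane clipping), park/mall tower tags at a 5%
   cell-overlap threshold, and the hour labelling rule: home if within
   500 m of home, else park/mall if > 40 minutes on tagged towers, else
   other.
3. **Aggregated logit share regressions** — for each location
   *l* ∈ {mall, park, other} (home is the base), OLS on the city–day–hour
   panel:

   ln *n*<sub>jytl</sub> − ln *n*<sub>jyth</sub> =
   γ<sup>(L)</sup><sub>jyl</sub> + δ<sup>(L)</sup><sub>tl</sub> +
   *X*<sub>jyt</sub>β<sup>(L)</sup><sub>l</sub> + η<sub>jytl</sub>,

   the linearisation of an individual Gumbel-heterogeneity logit under
   large cell counts. Counterfactual shares come from inverting the logit;
   marginal effects (level switches and continuous-AQI derivatives) are
   averaged over the panel, with percentile bootstrap CIs (row or city-day
   block resampling).
4. **Censored distance regression** — a doubly censored (0 / 50 km) Tobit
   of hourly distance from home, fitted by a hand-rolled maximum-likelihood
   routine (BFGS, analytic gradients, log-σ parameterisation), reporting
   both latent and expected-observed effects, with hourly t/t² interaction
   profiles.
5. **Daily substitution analysis** — city-day aggregates (mean hourly
   share × 1000, daily AQI summaries) regressed with city and day fixed
   effects, and a scale comparison that flags partial intra-day
   rescheduling.
6. **Synthetic world with ground truth** — towers, facilities, homes, AQI
   episodes, logit-governed choices and noisy logs, so every estimator is
   validated by parameter recovery, coverage, and geometry oracles. (Real
   operator logs of this kind are proprietary; the generator reproduces the
   statistical structure the estimators assume.)

## Worked example

```r
library(mobiaq)

cfg     <- world_config(n_cities = 2, n_days = 4, n_users_per_city = 500,
                        towers_per_city = 25, seed = 42)
world   <- gen_world(cfg)
aqi     <- gen_aqi(cfg, "wave")                       # AQI episode, 25-225
choices <- gen_choices(world, aqi, seed = 1)          # true hourly locations
records <- gen_logs(choices, world, log_noise(), seed = 2)  # noisy tower logs

keep       <- filter_users(records)
placements <- hourly_placements(records[records$phone_id %in% keep, ], world$towers)
tags       <- tag_towers(voronoi_service_areas(world$towers),
                         c(world$parks, world$malls))
labeled    <- label_hours(placements, tags)
panel      <- build_panel(labeled, aqi)

fit <- fit_share_logit(panel, choice_spec("levels"))
effect_level_switch(fit)        # "Good" -> "Heavily_Polluted"
```

```
  location d_share  d_pp pct_change per_million
1        h  0.0953  9.53       17.4       95281
2        m -0.0253 -2.53      -19.9      -25263
3        p -0.0164 -1.64      -21.7      -16426
4        o -0.0536 -5.36      -21.6      -53592
```

Read: in this synthetic world, air quality worsening from Good to Heavily
Polluted puts 9.5 percentage points more of the population at home
(95,281 more people per million, a 17% increase), drawn away from malls,
parks and other out-of-home locations; the four changes sum to zero because
everyone is always somewhere. The distance model tells the same story in
metres:

```r
tob <- fit_tobit(labeled, tobit_spec("levels"), aqi = aqi)
tobit_effect(tob)[c("latent", "observed")]
```

```
distance: latent -245 m, expected-observed -191 m (sigma 1286 m)
```

`bootstrap_ci()` attaches percentile confidence intervals to any of these
effects; `hourly_effects()` and `tobit_hourly()` trace the within-day
profile under t/t² interaction fits; `build_daily()` / `fit_daily()` /
`compare_scales()` run the daily substitution analysis; `run_pipeline()`
orchestrates all stages with one seed and writes CSV/JSON artifacts plus a
manifest (see also the thin CLI in `inst/scripts/mobiaq.R`). Column
contracts of the interchange files (`towers.csv`, `records.csv`,
`aqi.csv`, `placements.csv`, `panel.csv`, facility GeoJSON) are documented
in the function help pages and are the same for synthetic and real data.

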