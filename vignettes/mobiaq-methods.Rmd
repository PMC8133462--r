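---
title: "Measuring pollution responses in mobility data: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring pollution responses in mobility data: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mobiaq estimates how hourly air pollution shifts where people are — at home,
at a park, at a shopping mall, or elsewhere — and how far from home they
are, starting from the rawest signal a mobile network produces: timestamped
connect/disconnect/service records between phones and towers. This vignette
explains the models, the measurement pipeline, the synthetic world used to
validate both, and the design decisions taken where the problem was
genuinely open.

## The measurement pipeline

**From logs to positions.** A phone's records are walked in time order: a
connect or service record makes its tower "current" (a service record renews
the connection), a disconnect clears it, and each inter-record interval is
attributed to the tower current at its opening. Intervals are clipped to
half-open hour windows `[t-1:00, t:00)`, so one second of airtime is never
counted in two hours; hour `t` labels the clock interval `(t-1, t]`. The
phone's hourly position is the dwell-weighted average of its towers'
coordinates — the working assumption being that connection time decays with
distance to the tower, so the weighted centroid tracks the phone. (The
assumption is monotone-decay, not any exact functional form; the synthetic
generator uses `exp(-distance/lambda)` weights, and any monotone decay would
do for testing the inference.)

**Homes.** A phone's home is the dwell-weighted tower centroid of all its
records in the night window 00:00–06:00, pooled across all days of the raw
period. Pooling (rather than per-day homes averaged afterwards) uses all
night dwell symmetrically and is the variant implemented; with stationary
homes the two coincide in expectation.

**Sample selection.** Phones enter the analysis only if their raw records
span at least 96 hours and number at least 20 — dropping visitors and
out-of-towners. Both thresholds are configurable.

**Facility classification.** Each tower's service area is its Voronoi cell,
built by half-plane clipping against the perpendicular bisectors to the
city's other towers and clipped to a bounding region (default: the tower
bounding box padded by one median nearest-neighbour spacing; the padding
choice only affects edge towers). A tower is a *park tower* if at least 5%
of its cell area is covered by park polygons, and likewise for malls; the
two tags are independent. A phone-hour is labelled **h** if its raw
(unbinned) distance from home is under 500 m; otherwise **p** if it spent
strictly more than 40 minutes of the hour on park towers (union over
towers); otherwise **m** by the same rule for malls; otherwise **o**. Home
takes precedence by construction — the facility rules only apply to phones
away from home — and the p-before-m order when both facility criteria are
met is configurable, with conflicts counted in the run log.

**Distances.** Distance from home is Euclidean on planar metre coordinates
(an equirectangular adapter `lonlat_to_xy()` serves real lon/lat input; at
city scale the projection error is far below tower-spacing error). Distances
are recorded as midpoints of 100 m intervals `[0,100], (100,200], ...,
(49900,50000]`, censored at 50 km: anything beyond is recorded as 50,000 m
with a censoring flag. A boundary value `100k` falls in `(100(k-1), 100k]`.
Midpoints are treated as exact values downstream, matching how such binned
data are conventionally analysed; an interval likelihood is a non-goal.

## The location-choice model

Each person in city $j$ on day $y$ at hour $t$ picks one location
$l \in \{h, m, p, o\}$ to maximise utility

$$w_{ijytl} = \gamma^{(L)}_{jyl} + \delta^{(L)}_{tl} + X_{jyt}\beta^{(L)}_l
            + \eta_{jytl} + \upsilon_{ijytl}, \qquad w_{ijyth} = \upsilon_{ijyth},$$

with i.i.d. type-I extreme-value (Gumbel) heterogeneity $\upsilon$. Home is
the normalised base alternative. $X$ carries the pollution terms: either
dummies for the official AQI categories (Excellent $\le$ 50, Good 51–100,
Slightly Polluted 101–150, Moderately Polluted 151–200, Heavily Polluted
201–300, Severely Polluted > 300) with **Good always the omitted
benchmark**, or the AQI as a continuous variable, optionally interacted with
$t$ and $t^2$ for time-varying responses.

With large cell populations the observed shares obey the logit closed form,
which linearises into one OLS regression per non-home location:

$$\ln n_{jytl} - \ln n_{jyth} = \gamma^{(L)}_{jyl} + \delta^{(L)}_{tl}
  + X_{jyt}\beta^{(L)}_l + \eta_{jytl}.$$

This aggregation is the model's engine: it turns hundreds of millions of
individual choices into a few hundred panel rows, absorbs systematic
measurement error into the fixed effects ($\gamma$ city-day, $\delta$
hour) and the cell shock $\eta$, and is estimable by least squares. The
design uses reference coding — first city-day and first hour absorbed into
the intercept; estimates of the pollution effects are invariant to that
arbitrary choice. `truth_coefficients()` maps the generator's saturated
parameters onto the same coding so recovery can be checked coefficient by
coefficient.

**Counterfactual shares and marginal effects.** Shares are recovered by
inverting the logit, $s_h = 1/(1+\sum_l e^{v_l})$, $s_l = e^{v_l}s_h$, with
$v_l$ the fitted value under a scenario (one level dummy set, or an AQI
value) and everything else at observed values. The estimated residuals
$\hat\eta$ are included in $v$ by default, because the share inversion
carries $\eta$ inside the exponent; a fitted-only mode exists for smooth
predictions. The level-switch effect is the average over all panel rows of
the scenario difference (e.g. Good → Heavily Polluted); the percent change
is the ratio of the averaged difference to the averaged baseline share (one
headline percent per location, not an average of row-wise ratios); persons
per million is the share change times $10^6$. The four effects sum to zero
by construction — a simplex-conservation identity the tests assert to
$10^{-12}$.

For continuous AQI the analytic derivatives are

$$\frac{\partial s_l}{\partial \mathrm{AQI}} = s_l\beta_{l} - s_l\sum_{l'} \beta_{l'}s_{l'},
\qquad \frac{\partial s_h}{\partial \mathrm{AQI}} = -s_h\sum_{l'} \beta_{l'}s_{l'},$$

evaluated at the sample-mean shares (`at = "means"`, the headline number) or
row by row and averaged (`at = "rows"`). The two differ by a Jensen term
when shares vary a lot over the sample; the row-average version is the exact
analog of a daily-regression slope and is what the hour-stratified profiles
and the substitution comparison use, because stratum averages then recompose
the pooled effect exactly.

**Bootstrap.** Confidence intervals are percentile bootstrap over refits
(default B = 500). The resampling unit is the city-day block by default, to
respect within-day dependence; row resampling is also provided, and is the
right choice when the cell shocks are known to be independent (as in the
synthetic world, whose $\eta$ is i.i.d. by construction — the coverage
experiment uses it). Replicates whose refit fails (e.g. a resample with no
support for a required level) are dropped and counted; more than 10%
failures aborts.

**Scale invariance.** If every user carried $k$ phones the counts scale by
$k$ and $\ln(kn_l) - \ln(kn_h)$ is unchanged — the model is immune to
multi-phone multiplicity. The package computes log odds and shares as count
*ratios* first (`log(n_l/n_h)`, `n_l/n_total`), so scaling by any factor
exactly representable in binary floating point is bit-preserving, which the
tests assert with `identical()`. `thin_users()` implements the complementary
sensitivity for the distance analysis: keep each phone with probability
$1/k$.

## The distance model

Intended distance from home is latent linear-normal,

$$d^*_{ijyt} = \gamma^{(D)}_{jy} + \delta^{(D)}_t + X_{jyt}\beta^{(D)} + \varepsilon_{ijyt},$$

observed as $d = 0$ if $d^* \le 0$, $d = d^*$ in $(0, 50000]$, and
$d = 50000$ beyond — a doubly censored Tobit. The log-likelihood sums the
normal density for interior observations and the matching tail probability
for censored ones. It is maximised by BFGS with analytic gradients from an
OLS start, with $\sigma$ parameterised on the log scale so the optimisation
is unconstrained, and `parscale` set from the start values because the
intercept (metres, $10^3$–$10^4$) and $\log\sigma$ live on very different
scales. Convergence requires the gradient sup-norm below
$10^{-6}\max(1, |\ell|)$; standard errors come from the inverse observed
information. With midpoint binning the smallest observable distance is 50 m,
so the lower limit never binds *in the data*; it still matters in the
expected-value formula, because at city-scale parameters
($\mu \sim 10^3$ m, $\sigma \sim 1.5 \times 10^3$ m) the latent distribution
puts real mass below zero.

Effects are reported twice: the **latent** effect (the coefficient
contrast, the structural "meters closer" number) and the
**expected-observed** effect, the average change in
$E[d\,|\,x]$ under the doubly-censored normal mean formula. The two
coincide when neither limit has mass and the observed one is attenuated
otherwise; both are always reported since either could be the quantity a
reader wants.

## The daily (intra-day substitution) analysis

If people merely reschedule activities within the day, daily aggregates
should not respond to daily pollution even though hourly shares do. For
each city-day the package averages the hourly shares over the 16 panel
hours (× 1000, the conventional regression scaling) and the per-hour mean
distances, summarises the day's AQI four ways (max, mean, median, and an
"official" daily value — implemented as the hourly mean, clearly a
stand-in since official daily aggregation rules are not reconstructable —
with a pluggable override), and regresses each daily outcome on one AQI
summary with city and day fixed effects and classical normal-theory tests
(appropriate to a 24-row regression by design). `compare_scales()` puts the
hourly effect on the daily coefficient's per-mille-per-AQI-point scale and
flags a ratio whose CI sits inside (0, 1) as partial substitution.

## The synthetic world

The generator exists because operator logs of this kind are never public:
it emulates the statistical structure the estimators assume, with stored
ground truth, so every stage can be validated end to end. Its defaults are
the study design the models target:

| parameter | default | meaning |
|---|---|---|
| `n_cities`, `n_days`, `hours` | 6, 4, 7:22 | panel dimensions (384 cells) |
| `n_users_per_city` | 5000 | phones per city |
| `towers_per_city` | 49 | jittered 7×7 grid over the extent |
| `city_extent` | 10,000 m | square city side |
| `n_parks`, `n_malls`, `facility_size` | 3, 3, 1500 m | square facilities, placed disjointly |
| `aqi_range` | 25–225 | AQI episode range ("wave" pattern with city-specific lags) |
| `night_hours` | 1:6 | night window generated at the true home |
| `eta_sd`, `gamma_sd` | 0.05, 0.15 | cell shock and city-day heterogeneity |
| `beta_level` (Heavily row) | (−0.18, −0.45, −0.30) | Good→Heavily log-odds shifts for m, p, o |
| `beta_d_level` (Heavily), `sigma_d` | −550 m, 1500 m | distance response and noise |

The pollution coefficients were chosen once so that baseline shares sit
near (h, m, p, o) = (0.55, 0.05, 0.05, 0.35) and a Good→Heavily switch
moves several percent of the population home with a double-digit percent
drop in park attendance — the order of magnitude reported for city-scale
exposure-avoidance behaviour. Choices are drawn either by argmax over
Gumbel-perturbed utilities or from the closed-form multinomial (the two are
distributionally identical; both are implemented and cross-checked).
`gen_panel()` bypasses individual users entirely and draws cell counts
multinomially — the aggregated shortcut used by the recovery and coverage
experiments — with an `expected` mode (counts = $n \cdot p$) that makes
identification exact to machine precision for oracle tests.

Positions: home-choosers sit at their home; park/mall visitors at the
centroid of the facility of that kind nearest home (no within-facility
movement — a non-goal); "other" visitors at a truncated-at-zero draw from
the distance model in a uniform random direction, redrawn up to 20 times to
stay inside the extent and clamped thereafter (rare, and counted). Logs
split each hour among the k = 3 nearest towers with
$\exp(-d/\lambda)$ weights perturbed by a Dirichlet draw; `k = 1` with
infinite concentration is the noiseless limit. Night stays are generated at
the true home, which is what makes home inference identifiable by
construction, and the raw period includes the night after the last full day
so that genuine residents pass the 96-hour filter.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: road networks and trip chaining;
within-facility and within-hour movement; tower capacity effects (the
distance-decay assumption failing under congestion); workplaces;
heterogeneous phone ownership correlated with behaviour; and any
correlation between measurement error and pollution, which is exactly the
threat the fixed effects are meant to absorb and which no synthetic
validation can rule out in the field.

The substitution experiment uses a dedicated knob: with `substitution = phi`
the utilities respond to $\mathrm{AQI} - \phi \cdot
\overline{\mathrm{AQI}}_{jy}$, so $\phi = 1$ leaves daily aggregates
untouched (perfect rescheduling) while the hourly regression — whose
city-day fixed effects absorb the day-mean term — still identifies the full
hourly response; $\phi = 0$ is the no-substitution regime. This experiment
sets `gamma_sd = 0` so the daily coefficient targets a single homogeneous
slope; with heterogeneous city-day baselines the 24-row daily regression
estimates a leverage-weighted average of city-day-specific responses and
the daily/hourly comparison is no longer a point identity.

## Numerical choices

- Zero counts break the log odds; the default policy is a hard error
  (panels should be sized to avoid them), with a 0.5-to-all-four-counts
  continuity correction and a drop-row policy available, each logged.
- Degenerate geometry: duplicate tower coordinates are an error naming the
  towers; fewer than three towers per city is an error; zero-area cells are
  an error. Half-plane clipping uses a relative 1e-9 slack on the inside
  test so bisector-boundary vertices are kept.
- Boundary conventions: home rule strict `<` 500 m; facility rule strict
  `>` 40 min; overlap tag inclusive `>=` 5%; all configurable.
- City assignment of a phone-hour with dwell in several cities: largest
  dwell wins, ties to the lowest city id.
- Tobit: log-σ parameterisation, BFGS `reltol` 1e-12 with a tighter second
  pass if the gradient criterion is missed, then a hard error.
- Finite-difference oracle for the derivative identity uses a central
  difference with step 1e-3 AQI points, where truncation and rounding error
  are both orders of magnitude below the 1e-6 relative tolerance.

## Experiment sizes

The validation experiments run at the study-design scale: coefficient
recovery and bootstrap coverage use the 384-cell panel with 5,000 users per
cell (200 and 100 replicates; B = 200 inside the coverage study); Tobit
recovery uses n = 100,000 with ~20% upper censoring, 200 replicates; the
geometry oracle uses a one-million-point nearest-tower sample over a
25-tower city, where the per-cell binomial error (~0.5% relative) sits well
inside the 2% acceptance band; the end-to-end geolocation check uses a
noiseless two-city world. The demonstration pipeline in
`scripts/acceptance.R` runs six cities at 1,200 users each with the Tobit
fitted on a 200,000-row subsample.

## Known limitations

- The share regressions are aggregate: individual-level covariates or
  panel linkage across hours are out of scope (and the anonymised data the
  design mirrors would not permit them anyway).
- $\xi_{jyt}$-type city-day-hour shocks in the distance model cannot be
  separated from the individual error at this fixed-effect resolution; they
  are folded into $\varepsilon$.
- The censored likelihood treats bin midpoints as exact observations.
- The "official daily AQI" is a stand-in (hourly mean).
- Voronoi cells are a coverage proxy; real propagation footprints are not
  polygons.
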