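---
title: "A Monte Carlo model of school-lunch plate waste"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Monte Carlo model of school-lunch plate waste}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(platewaste)
```

## The model in one paragraph

Plate waste — served food left uneaten — is simulated as the outcome of the
interaction between two stochastic agents: a *week menu* (five daily
portions drawn from regulated component distributions) and a *child* (an
eating rate, a competitive-food flag, a weekly vector of hated days, and a
disposition to stop eating when time runs out). Each simulated plate is
decomposed, in order, into waste caused by **competitive food** (food eaten
instead of the school lunch), **rejected food** (dislikes and hated-day
refusals), and **insufficient time**, with the remainder eaten. The model
has two scenario inputs — nominal lunch duration and the share of children
unsatisfied with school food — and is run as a Monte Carlo over many
independent (child, week-menu) pairs.

## Portion generation

A daily portion is the sum of seven components (grams):

$$p = m + s + sd + ld + b + fp + mk$$

main dish, soup, solid dessert, liquid dessert (a drink such as juice or
sweet tea — distinct from milk), bread, fresh product, milk. Components are
drawn from bounded distributions (defaults in `menu_config()`):

| component | distribution | bounds (g) |
|---|---|---|
| main dish `m` | Gumbel(225, 37.5) | [150, 430] |
| soup `s` | Normal(225, 37.5) | [150, 300] |
| solid dessert `sd` | Normal(75, 12.5) | [50, 100] |
| liquid dessert `ld` | Normal(200, 25) | [150, 250] |
| bread `b` | 20 + Exp(1.2) | [20, 35] |
| fresh product `fp` | Normal(75, 12.5) | [50, 100] |
| milk `mk` | constant 200 | — |
| MS joint (`m`, `s`) | Normal(200, 25), Normal(175, 12.5) | [150, 250], [150, 200] |
| dessert joint (`sd`, `ld`) | Normal(32.5, 8.75), Normal(150, 25) | [15, 50], [100, 200] |

The main part follows the three regulated menu types with probabilities
0.65 / 0.30 / 0.05: main dish + soup (MS, which uses the joint MS pair —
smaller servings of each, because two courses are served), main dish +
dessert (MD, marginal `m` only), soup + dessert (SD, marginal `s` only). A
dessert is generated *unconditionally*, its type uniform among solid /
liquid / both (the "both" case uses the joint dessert pair); bread appears
with probability 1/2, and exactly one of fresh product / milk / neither is
added (1/3 each). Two pseudocode-level readings were settled here once: a
dessert line that names the solid-dessert distribution for the liquid
dessert is read as a typo (the liquid dessert uses its own Normal(200, 25)
— the observed menus serve a drink daily, which supports the unconditional
dessert), and the joint MS pair applies only to MS menus while MD/SD use
the marginals.

**Bound enforcement is by rejection sampling, not clipping**: resampling
until the draw lands inside the support preserves the distribution's shape
inside the interval, whereas clipping would pile probability mass on the
endpoints. The shifted exponential for bread already starts its support at
20 g, so only its upper bound can reject.

## Intake kinetics

Cumulative food-mass intake is modelled as the integral of an eating speed
$v(t) = v_0 + a_0 t + x t^2$:

$$e(t) = v_0 t + \frac{a_0 t^2}{2} + \frac{x t^3}{3},$$

with the integration constant fixed at zero (no food eaten at $t = 0$).
Setting $x = 0$ gives the quadratic (decelerating) model, whose speed hits
zero at $t^\ast = v_0/|a_0|$ with maximal intake $v_0^2/(2|a_0|)$; setting
$a_0 = x = 0$ gives constant-speed intake. Three numerical conventions
matter:

* **Doubled deceleration.** Decelerations reported for the
  $e(t) = k t^2 + v_0 t$ parameterisation must be doubled before use as
  the speed-model coefficient ($-2.6 \to -5.2$ g/min² for girls,
  $-2.7 \to -5.4$ for boys); `doubled_deceleration()` does exactly this.
* **Clamped speed.** The polynomial is physically valid only while
  $v(t) \ge 0$: intake cannot decrease. `cumulative_intake()` therefore
  clamps the speed at zero — the quadratic model plateaus past $t^\ast$,
  and a cubic with $x > 0$ whose speed dips below zero plateaus during the
  dip and resumes after it. The implementation is closed-form (the dip is
  an interval between the two roots of a quadratic); tests verify it
  against numerical quadrature of $\max(v(t), 0)$.
* **Full precision.** Reported worked values mix rounding and truncation
  (7.778 printed as 7.7, 0.5656 as 0.56); every function returns full
  precision and leaves formatting to display code.

`solve_cubic_acceleration()` recalibrates $x$ so the model reproduces an
observed total intake: $x = 3(E - v_0 t - a_0 t^2/2)/t^3$. For boys
(42 g/min, −5.4 g/min², 289 g in 8.8 min) this yields 0.5656 g/min³. For
girls the stated inputs (34, −5.2, 258 g, 10.7 min) algebraically yield
0.470 g/min³, while the published coefficient is 0.55 — a discrepancy we
expose rather than silently correct in either direction: the package
computes 0.470 from those inputs, and accepts 0.55 wherever a coefficient
is a user input (the published downstream average speed, 27.16 g/min, is
consistent with 0.55).

The empirical linear relation between lunch intake and eating rate,
$E(v) = 6.8 v + 125$ and its inverse $v(E) = (E - 125)/6.8$, lives in
`intake_speed_relation()`; applied to the 390–540 g drink-free portion
range it implies eating rates of 39–61 g/min.

The Monte Carlo engine itself uses the *linear* compromise model — a
constant solid-food rate of 35(5) g/min, liquids at twice that rate — on
the grounds that the decelerating model approaches linearity over a
restricted lunch window and that school conditions are rarely ideal. The
kinetics module exists because the model's rate constants are derived from
it, and to let users rederive them (`kinetics_table()`).

## Child agents

`generate_population()` draws, per child:

* `vs` ~ Normal(35, 5) g/min, resampled while non-positive (the truncated
  mass is ~1e−12 at the defaults, so resampling is a formality, not a
  distortion); `vl = 2·vs` exactly.
* `ef` ~ Bernoulli(0.30): eats competitive food. Applied as a stable
  child-level flag on every school day, not redrawn daily.
* `u` ~ Bernoulli(0.27): unsatisfied with school food.
* `stops` ~ Bernoulli(0.67): stops eating when time runs out (the
  alternative is to keep eating and arrive late). Drawn once per child —
  a disposition, since it is reported as a share of children.
* a hated-day count $h$ ~ Normal(3, 0.5) for unsatisfied children,
  Normal(0, 0.5) for satisfied, clamped to $[0, 5]$ and **rounded to the
  nearest integer** (the count must be an integer; rounding is our
  choice, stated here because it is observable: a satisfied child has zero
  hated days with probability $\Phi(1) \approx 0.841$, not 1). The $h$
  hated weekdays are chosen uniformly at random without replacement —
  only the count is specified by the source model.

## The three-stage waste decomposition

For each child-day, the portion vector $\vec p$ is split so that,
componentwise and exactly,

$$\vec p = \vec e + \vec w_{ef} + \vec w_h + \vec w_t .$$

**Stage 1 — competitive food** (`competitive_impact()`). If `ef = 1`, an
impact level $k$ is drawn uniformly from $\{0.12, 0.37, 0.62, 0.87\}$ and
every component is displaced by a fraction Normal$(k, 0.06)$, clamped to
$[0,1]$. This follows the generating pseudocode literally even though the
underlying survey bins are labelled as *eaten* shares; the alternative
reading — waste $= 1 -$ eaten fraction, with the survey's bin shares as
weights — is available as
`competitive_config(semantics = "complement")`. Literal is the default
because the pseudocode is the normative artifact of the source model.
The pseudocode's component lists omit milk, but they also omit it from
the portion return line where milk plainly belongs, so we read the
omission as notational and displace all seven components.

**Stage 2 — rejected food** (`rejected_impact()`). On a hated day each
component is wasted in its category fraction: main dish Normal(0.30, 0.05),
soup Normal(0.15, 0.03), solid dessert 0.02, liquid dessert
Normal(0.35, 0.07), fresh product Normal(0.30, 0.10), bread 0.05 — all
clamped to $[0,1]$. Milk has no observed category and defaults to 0 (a
config override exists). Independently, the *stable dislikes* apply: the
whole soup is left with probability 0.5 and the whole main dish with
probability 0.08, on every day — they encode survey-reported dislikes that
are not conditioned on satisfaction. The stricter reading (skips only on
hated days) is a flag, `skips_on_hated_days_only`. The skip probability for
the main dish is 0.08: the survey reports 8% of children never eat the main
dish, and the generating pseudocode's probability pair is read in the same
order convention as its competitive-food line. Finally the rejected amount
is capped at what competitive food left on the plate,
$\vec w_h \leftarrow \min(\vec w_h,\, \vec p - \vec w_{ef})$, floored at
zero: a child already filled by competitive food cannot reject more than
remains.

**Stage 3 — insufficient time** (`time_limited_waste()`). The remainder is
consumed at `vs` (solids) and `vl` (soup, liquid dessert, milk) in eating
order — main part, then dessert, then bread / fresh product / milk; the
order is our assumption (the source specifies only the rates), and it only
matters for the per-component attribution of time waste, not its total. If
the required time exceeds the available time and the child stops, the
unconsumed remainder is wasted; a child who eats on wastes nothing at this
stage. Available time is the nominal lunch duration minus a 6-minute
walking delay (about 3 minutes each way to and from the canteen).

All three stages draw the same number of random variates whatever the
behavioural flags, which makes coupled replay possible: re-seeding and
changing only a flag or the time budget replays identical draws, so
monotonicity tests compare like with like.

## The Monte Carlo driver

One repetition is one (child, week-menu) pair — the source model counts
"repetitions" without fixing the unit, and this reading matches its
two-agent formulation while keeping repetitions i.i.d., so Monte Carlo
standard errors are valid. The default is 10,000 repetitions. The weekly
waste fraction is mass-weighted (total wasted grams over total served
grams); reporting can exclude the liquid dessert — drinks dominate wasted
mass — without changing the model. `sweep_grid()` evaluates the (duration ×
unsatisfied share) surface with per-cell seeds derived from the base seed,
so grids are bit-reproducible regardless of evaluation order.

`optimal_duration()` answers the planning question under *ideal
conditions*: competitive food, hated days and preference skips disabled, so
only the time constraint produces waste. It scans a 1-minute duration grid
(walking time excluded) at the lower recalculated rate of 27(2) g/min, so
the answer covers slower eaters, and returns the smallest duration whose
mean waste fraction falls below a threshold (default 0.02 — the adequacy
criterion is inherently a choice, so it is a parameter, and conclusions
should be read as threshold-dependent). The stop/late disposition is
*retained* in ideal mode: it is a property of the schedule interaction, not
of food preferences. All durations share one seed, so the scanned curve is
monotone by construction. At the defaults the scan places the minimal
adequate eating duration at 18 min, with the curve falling steeply before
~18 min and flat beyond ~20–22 min.

## Validation

`rmse()` and `mape()` implement the two forecast-quality metrics; MAPE
takes absolute errors (as printed, the percentage-error sum lacks
absolute-value bars, under which opposite-signed errors would cancel and
the metric would be uninterpretable). The per-school field observations
behind the published error figures are not available, so
`synthesize_observations()` generates format-identical *synthetic*
observations: for each lunch duration the simulator's mean waste fraction
is perturbed per school by multiplicative Normal(1, `noise_sd`) noise.
`validate_forecasts()` then forecasts at each observed duration
(walking-adjusted, on an independent seed stream), pairs by duration,
refuses mismatched units and unmatched duration groups, and reports RMSE,
MAPE, N and residuals. Pooling over (school × duration) cells is
unweighted. Validating the simulator against its own noise-free synthetic
observations is a self-consistency check — the RMSE must shrink to the
Monte Carlo standard error — and that is what the test suite asserts; it
says nothing about agreement with real schools.

## What the synthetic data do and do not show

The generator emulates the *structure* of the field situation: regulated
menu mixes, survey-derived behavioural rates, duration-grouped weekly
observations. It does not emulate school-level heterogeneity (every cell
shares one behavioural parameter set), menu autocorrelation across weeks,
weekday effects, or any satisfaction–competitive-food correlation, and the
satisfaction distribution is the assumed two-group mixture rather than a
possible exponential alternative. Passing tests therefore demonstrate
internal correctness — conservation, calibration of the generators,
monotone and approximately linear scenario responses, self-consistent
validation — not forecast accuracy for a particular school, which requires
local survey data.

## Problem sizes and numerical choices

The test suite runs the generators at n = 10,000 draws (4σ binomial bands),
conservation on 10,000 child-days at 1e−9, scenario monotonicity on
10,000-repetition means, self-consistency at 10,000 repetitions, the
ideal-condition scan at 5,000 repetitions, and the full default sweep (30
durations × 21 shares) at 1,000 repetitions per cell — sizes chosen to make
Monte Carlo bands a small fraction of the effects being checked. Fraction
draws are clamped to [0,1]; rejection sampling aborts with an error after
1,000 rounds (reachable only with inconsistent user configs); seeds are
propagated to grid cells as `base + 7919·cell` modulo the 32-bit integer
maximum.

## Known limitations

Competitive-food impact applies deterministically on every day for flagged
children; a per-day stochastic variant is a plausible alternative the
configuration does not currently express. Waste is tracked in grams, not
nutrients. The walking delay is a single constant, while in reality it
varies by school layout. The published headline error figures cannot be
reproduced without the unpublished per-school observations; the validation
module is exercised against synthetic data only, and is exact in its
metrics, not in its claim on reality.
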