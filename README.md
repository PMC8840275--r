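# platewaste

Monte Carlo forecasting of school-lunch plate waste.

School canteens discard a substantial share of the food they serve, but
measuring plate waste in the field is slow and intrusive, and data-hungry
forecasting methods fail exactly where monitoring is weakest. `platewaste`
implements a feature-based simulator for school food managers and
researchers: instead of fitting historical waste series, it *generates*
lunches and children from survey- and literature-derived distributions and
predicts waste from two scenario inputs a school actually controls or can
cheaply survey — **lunch duration** and the **share of children unsatisfied
with school food**.

## The model

A daily portion is the sum of seven components (grams),

```
p = m + s + sd + ld + b + fp + mk
```

(main dish, soup, solid dessert, liquid dessert, bread, fresh product,
milk), drawn from bounded distributions under the regulated menu types
MS/MD/SD (probabilities 0.65/0.30/0.05). A child agent carries a solid-food
eating rate `vs ~ N(35, 5)` g/min (liquids at `2·vs`), a competitive-food
flag (P = 0.30), an unsatisfied flag (P = 0.27), a stop-when-out-of-time
disposition (P = 0.67), and a weekly hated-day vector (≈3 days/week if
unsatisfied, ≈0 otherwise). Each plate is decomposed exactly as

```
p = e(t) + w_ef + w_h + w_t
```

— eaten mass plus waste from competitive food, rejected food, and
insufficient time, applied in that order with the rejected amount capped by
what competitive food left on the plate. Eating time is the nominal lunch
duration minus a 6-minute canteen walking delay. A closed-form kinetics
module covers the underlying cumulative-intake models
`e(t) = v0·t + a0·t²/2 + x·t³/3` and the linear intake–speed relation
`E(v) = 6.8·v + 125`, from which the simulator's rate constants derive.

See the methods vignette (`vignettes/plate-waste-model.Rmd`) for the full
model, its assumptions and design choices.

## Worked example

```r
library(platewaste)

cfg <- simulation_config(lunch_duration = 25, pr_unsatisfied = 0.27,
                         ef_prob = 0.30, repetitions = 10000, seed = 42)
run_simulation(cfg)
#> <plate_waste_sim> 10000 reps | 25 min lunch (19 min eating) | unsatisfied 0.27 | competitive 0.30
#>   mean weekly waste: 29.92% of served mass (SE 0.219%)
#>   excluding liquid dessert: 32.17%
```

Under this scenario a school wastes about 30% of served mass per week; the
Monte Carlo standard error (0.22 percentage points over 10,000 simulated
child-weeks) shows the estimate itself is tight — the uncertainty that
matters is in the scenario inputs. `tidy()` attributes the waste:
component-wise, soup loses the most (≈59% of served soup, driven by the
half of children who never eat soup), and competitive food removes a
near-uniform ≈15% across components.

The planning questions chain the same way:

```r
# waste surface over the two scenario axes (the "tomogram")
grid <- sweep_grid(cfg, durations = 10:40, shares = seq(0, 1, 0.05))
autoplot(grid)

# minimal adequate eating time under ideal conditions, slow eaters (27(2) g/min)
optimal_duration(cfg, durations = 8:32)
#> <duration_scan> minimal adequate eating duration: 18 min (waste < 2%)
```

Waste rises steeply (near-exponentially) as effective eating time drops
below ~18 minutes, and approximately linearly with the unsatisfied share —
so scheduling enough lunch time is the first lever, food acceptance the
second.

Forecast validation against per-school weekly observations (here synthetic,
with 3% observation noise):

```r
obs <- synthesize_observations(simulation_config(repetitions = 5000, seed = 7),
                               noise_sd = 0.03)
validate_forecasts(simulation_config(repetitions = 5000, seed = 7), obs)
#> <waste_validation> N = 28 observations
#>   RMSE: 0.0093 (waste-fraction units)
#>   MAPE: 2.41%
```

A thin command-line front end is in `inst/cli/platewaste.R`
(`kinetics`, `simulate`, `sweep` subcommands); scenario files are YAML, see
`inst/extdata/default-config.yaml`.

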