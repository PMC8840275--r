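# Default plate-waste simulation scenario. Every key is optional: omitted
# keys keep the package defaults shown here.
lunch_duration: 25      # nominal lunch break, minutes
pr_unsatisfied: 0.27    # share of children unsatisfied with school food
ef_prob: 0.30           # competitive-food probability
repetitions: 10000
walking_delay: 6        # minutes lost walking to/from the canteen
ideal_mode: false
# seed: 42

menu:
  menu_probs: {MS: 0.65, MD: 0.30, SD: 0.05}
  bread_prob: 0.5
  dessert_probs: {solid: 0.3333333, liquid: 0.3333333, both: 0.3333334}
  optional_probs: {fresh: 0.3333333, milk: 0.3333333, none: 0.3333334}
  components:
    m:  {family: gumbel, location: 225, scale: 37.5, bounds: [150, 430]}
    s:  {family: normal, location: 225, scale: 37.5, bounds: [150, 300]}
    sd: {family: normal, location: 75, scale: 12.5, bounds: [50, 100]}
    ld: {family: normal, location: 200, scale: 25, bounds: [150, 250]}
    b:  {family: exponential, location: 20, scale: 1.2, bounds: [20, 35]}
    fp: {family: normal, location: 75, scale: 12.5, bounds: [50, 100]}
    mk: {family: constant, location: 200, bounds: [200, 200]}
  joint_ms:
    m: {family: normal, location: 200, scale: 25, bounds: [150, 250]}
    s: {family: normal, location: 175, scale: 12.5, bounds: [150, 200]}
  joint_d:
    sd: {family: normal, location: 32.5, scale: 8.75, bounds: [15, 50]}
    ld: {family: normal, location: 150, scale: 25, bounds: [100, 200]}

population:
  rate_mean: 35         # compromise solid-food eating rate, g/min
  rate_sd: 5
  stop_prob: 0.67       # stop eating when time runs out
  hated_mean_unsat: 3   # hated days/week, unsatisfied children
  hated_mean_sat: 0
  hated_sd: 0.5

waste_fractions:
  soup_skip_prob: 0.5
  main_skip_prob: 0.08
  skips_on_hated_days_only: false
  fractions:
    m:  {family: normal, location: 0.30, scale: 0.05}
    s:  {family: normal, location: 0.15, scale: 0.03}
    sd: {family: constant, location: 0.02}
    ld: {family: normal, location: 0.35, scale: 0.07}
    b:  {family: constant, location: 0.05}
    fp: {family: normal, location: 0.30, scale: 0.10}
    mk: {family: constant, location: 0}

competitive:
  k_values: [0.12, 0.37, 0.62, 0.87]
  k_sd: 0.06
  semantics: literal
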