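# famstates

Parental marital states and child outcomes from longitudinal family
histories.

In many longitudinal village registries — the motivating setting is a
small-scale, high-fertility farming community with unstable marriages,
polygyny, and many biological fathers unknown to the record — a child's
family structure changes year by year: parents die, divorce, remarry, take
co-wives, or are simply external to the registry. `famstates` asks how
those time-varying parental states relate to four child outcomes —
survival, height, weight-for-height, and years of schooling — while
controlling for the stable traits of the parents themselves. It is written
for demographers, human-behavioural ecologists and epidemiologists working
with reconstructed family histories.

The package provides, end to end:

* a **child-year panel builder**: marriage spells and vital records are
  expanded into per-year spouse sets, and every child-year (ages 0–18,
  censored at death or last observation) is classified for each parent into
  a branching tree of states — external, deceased, unmarried, married to
  the other biological parent or to a step-parent, monogamously or
  polygynously;
* four **Bayesian hierarchical models** sharing the linear predictor

  θ<sub>it</sub> = α + γ<sub>O(i)</sub> + ε<sub>Y(t)</sub> + κ<sub>Q(i)</sub> + η<sub>J(i)</sub> + β<sub>1,a</sub> + β<sub>2,a</sub>M<sub>i</sub> + β<sub>3,a</sub>T<sub>i</sub> + Σ<sub>k</sub> β<sub>k,a</sub>x<sub>k,it</sub>

  (birth order, calendar year, mother and father identity, and age-specific
  effects of sex, twin status and each parental-state indicator), with
  outcome families: discrete-time Bernoulli survival on the logit scale,
  log-normal height, log-normal weight controlling for height with an
  age-specific coefficient, and zero-inflated Poisson schooling with two
  full predictors (never-attend probability and attained years). Age-,
  birth-order- and year-indexed effect vectors get squared-exponential
  Gaussian-process priors, so effects vary smoothly with no assumed
  functional form;
* a **Hamiltonian Monte Carlo sampler** (dynamic trajectories with a
  no-U-turn rule, compiled analytic gradients, non-centered
  parameterization) with split-Rhat/ESS diagnostics;
* **posterior contrasts**: predicted curves per parental state in natural
  units, drawwise differences against the two-living-monogamous-parents
  base case, cumulative survival curves, and 90% highest-posterior-density
  intervals;
* a **synthetic-data generator** (Markov marital dynamics, polygyny,
  external parents, survey-year observation, outcomes drawn from the exact
  likelihoods) so the whole pipeline is testable against known truth;
* a **command-line pipeline** (`inst/cli/famstates`):
  `simulate | build-panel | fit | contrast | report`, with YAML config,
  run manifests, CSV/JSON artifacts and plots.

## A worked example

```r
library(famstates)

# a synthetic village with known generating parameters
sc   <- sim_config(n_children = 500, seed = 1)
hist <- simulate_histories(sc)
tl   <- build_marriage_timeline(hist$spells, hist$vitals,
                                year_range = sc$year_range)
panel <- build_child_year_panel(hist$children, tl,
                                survey_years = sc$survey_years)
truth <- make_true_params(years = seq(sc$year_range[1], sc$year_range[2]))
truth$survival$beta["X", 1:3] <- -1.0     # maternal death penalty, ages 0-2
sim <- simulate_outcomes(panel, truth, seed = 2, records = hist$children)

# fit the mother-perspective survival model
fc <- fit_config("survival", chains = 2, warmup = 500, samples = 500,
                 seed = 3)
m  <- assemble_model(sim$panel, fc)
d  <- run_mcmc(m, fc)

# base-case curve and the mother-deceased contrast, female child
base  <- predict_curve(d, m, sex = "female")
focal <- predict_curve(d, m, sex = "female", mother_state = "DECEASED")
summarize_contrast(contrast(cumulative_survival(base),
                            cumulative_survival(focal)))
```

On this simulated village (the same computation `scripts/acceptance.R`
performs with `--seed 1`) the pipeline prints, among others:

```
first_year_death_fraction                        0.1020 (n=500)
base_female_annual_survival_age0                 0.8956 (n=5793)
base_female_cumulative_survival_age19            0.6112 (n=5793)
mother_deceased_annual_survival_contrast_age0    -0.0498 (n=5793)
recovered_mother_deceased_logit_effect_ages0to2  -0.2871 (n=5793)
base_female_height_age8_cm                       122.3086 (n=835)
```

Reading: 10.2% of the 500 simulated children died in their first year; the
fitted model predicts a base-case (two living, monogamously married
parents) first-year survival probability of 0.896 for girls and a 0.611
probability of surviving to age 19; a girl whose mother is deceased loses
about 0.05 of first-year survival probability; the injected −1.0
logit-scale maternal-death effect is recovered shrunken toward zero (the
weakly regularising priors pool an effect concentrated at three ages, as
the methods vignette discusses); and the predicted base height at age 8 is
122.3 cm against a generating truth of 124 cm.

The methods vignette (`vignettes/famstates-methods.Rmd`) documents the
panel semantics, model definitions, priors, sampler, generator defaults and
their rationale, and known limitations.

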