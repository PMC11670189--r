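---
title: "Models and methods in famstates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in famstates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

famstates studies how the year-by-year marital situation of a child's
biological parents relates to four child outcomes — survival, height,
weight-for-height, and years of schooling — in longitudinal village
registries where marriages are unstable, polygyny occurs, and many
biological fathers are unknown to the record. This vignette is the package's
own account of the methods: the panel semantics, the four hierarchical
models, the priors and sampler, the synthetic-data generator, and the design
decisions taken where more than one reasonable choice existed.

## The child-year panel

The unit of analysis is the child-year. A child contributes one row per
completed-year age from 0 to `min(18, age at death, age at last
observation)`; a child born five years before the end of data collection is
censored at age 5, and a child who died at age 2 contributes ages 0–2 with
`survived = 0` on the final row. Rows exist only while the child is at risk,
which is what makes the discrete-time survival likelihood valid.

Each child-year is classified, separately for the mother and the father,
into one leaf of a branching tree:

* `EXTERNAL` — the parent's vital and marital status is unknown to the
  registry (never lived in, or left, the community). These children are
  retained, not dropped: exclusion would remove precisely the most
  marginalised families. A single external category is used for both
  parents because external mothers are rare.
* `DECEASED` — from the calendar year of death onward.
* `UNMARRIED`, or married to the child's other biological parent
  (`BIO_MONO`/`BIO_POLY`) or to a step-parent (`STEP_MONO`/`STEP_POLY`),
  with the `_POLY` suffix marking a polygynous union.

Annual resolution forces three conventions, chosen once and applied
everywhere:

1. **Same-year transitions.** When several unions touch the same calendar
   year, the state in force at the *end* of the year wins: unions whose
   effective end (divorce or a partner's death) precedes the year's end are
   superseded by any union still open; if every union of the year has ended,
   the latest-starting one defines the state. Without this rule a divorce
   followed by a remarriage in the same year would be indistinguishable
   from polygyny.
2. **Year of death.** A parent who dies in year *y* is `DECEASED` from year
   *y* onward; the surviving spouse is still coded by the marriage in that
   year (spouse sets empty from *y + 1*).
3. **Polygyny for mothers.** A mother is in polygyny whenever her current
   husband has two or more concurrent wives, whether that husband is the
   biological father (`BIO_POLY`) or a step-father (`STEP_POLY`). The
   indicator coding uses a single polygyny flag `P` next to the step-father
   flag `Z`, so `STEP_POLY` sets both. Because the original coding of a
   mother married to the biological father in polygyny could also have been
   a distinct category, `mother_poly_coding = "split"` exposes the
   alternative with separate with/without-biological-father polygyny
   indicators; the default is the single flag.

Birth order is capped at a tenth "10+" category: a smooth prior over sparse
high parities is unstable, and parities above ten are rare.

## The four outcome models

All four models share one hierarchical linear predictor for child *i* in
year *t* at age *a*:

$$
\theta_{it} = \alpha + \gamma_{O_i} + \epsilon_{Y_t} + \kappa_{Q_i} +
\eta_{J_i} + \beta_{1,a} + \beta_{2,a} M_i + \beta_{3,a} T_i +
\sum_k \beta_{k,a} x_{k,it}
$$

with a global intercept, birth-order, calendar-year, mother-identity and
father-identity effects, an age-specific baseline, age-specific male and
twin effects, and age-specific coefficients on the parental-state
indicators (father deceased, mother deceased, mother unmarried, step-father,
polygyny, external for the mother perspective; the father perspective keeps
mother-deceased and father-deceased and adds father-unmarried, step-mother,
and polygyny with/without the biological mother). External parents
contribute zero to the identity random effects. The parent-identity terms
are the package's guard against selection: parents whose stable traits
affect both their marital trajectories and their children's outcomes.

The outcome distributions are:

* survival: `S ~ Bernoulli(logistic(theta))`, conditional on surviving the
  previous year (rows exist only while at risk);
* height: `log(H_cm) ~ Normal(theta, lambda)`;
* weight: `log(K_kg) ~ Normal(theta + b_a (log H - c_a), lambda)`, an
  age-specific control for height. The centring constants `c_a` are the
  mean log height at each age in the fitted data; centring at the age mean
  makes the intercept curve interpretable and decorrelates the height
  coefficient from the age baseline;
* education: `E ~ ZIPoisson(logistic(theta), exp(eta))` — a point mass for
  children who never attend school and a Poisson count of completed years
  for attendees, with two full, independent copies of the linear predictor.

## Gaussian-process smoothing

Each age-indexed effect row, the birth-order vector and the calendar-year
vector get a squared-exponential Gaussian-process prior over the integer
category index,

$$ k(i, j) = s^2 \exp\{-(i-j)^2 / (2\ell^2)\} + 10^{-6}\,\delta_{ij}, $$

which pools neighbouring categories without imposing a functional form. The
kernel is the minimal stationary choice with exactly the three properties
the model needs (partial pooling, no fixed shape, controlled roughness) and
is isolated behind `gp_covariance()`. Mother- and father-identity effects
are exchangeable zero-mean Normals with an estimated scale — identities
have no neighbourhood structure to smooth over.

## Priors, parameterization, inference

All hierarchical terms are non-centered: an effect row is
`amplitude * chol(corr) %*% z` with standard-Normal innovations `z`,
because sparse levels put the posterior in funnel geometry otherwise.
Default priors, declared in `fit_config()` and printed with every model:

| parameter | prior | default scale |
|---|---|---|
| intercept `alpha` | Normal(0, sd) | 1 |
| GP amplitudes | half-Normal(0, sd) | 1 |
| GP lengthscales | log-Normal(meanlog, sdlog) | log(3), 0.75 (category units) |
| identity-effect scales | half-Normal(0, sd) | 1 |
| residual scale `lambda` | half-Normal(0, sd) | 1 |

These are weakly regularising on the logit/log scales the models live on;
every scale is a single number a user can override, so any disagreement
with other implementations is visible rather than silent.

The sampler is dynamic Hamiltonian Monte Carlo written for this package: a
no-U-turn termination rule with multinomial state selection along the
trajectory, dual-averaging step-size adaptation (target acceptance 0.8),
and expanding diagonal mass-matrix windows during warmup. The joint density
and its analytic gradient — including the Cholesky-factor derivative for
the GP lengthscales — are compiled code, verified in the test suite against
numerical differentiation and against an independent R implementation of
every likelihood. Trajectories are capped at `2^max_treedepth` leapfrog
steps (default depth 5); energy errors above 1000 count as divergences and
are reported. GP lengthscales are bounded away from degenerate values
(outside about [1e-3, 1e3] the correlation matrix is numerically rank
deficient); the sampler treats those regions as zero density, which the
log-Normal prior makes irrelevant in practice. Split-Rhat and effective
sample sizes are computed for every parameter; `run_mcmc()` warns at
Rhat > 1.01 or any post-warmup divergence. With hundreds of weakly
identified hyperparameters at desk scale some GP hyperparameters mix
slowly; the age-specific state effects — the quantities the analysis is
about — mix an order of magnitude faster, and the reduced-scale
calibration suite checks their interval coverage directly.

Children of unknown sex are kept: the likelihood for such a child is a
two-component mixture over male/female weighted by the male fraction among
sexed children, applied at the child level (sex is shared across a child's
rows). Dropping these children — mostly infants who died long before the
surveys — would bias exactly the early-mortality estimates of interest.

## Predictions, contrasts, HPDIs

Predicted curves are for a population-typical child. Because the overall
level of the linear predictor is only softly identified — the intercept,
the age-baseline GP, the year GP and the parent-identity effects can trade
level against one another under their zero-mean priors — evaluating a draw
with every shared term set to exactly zero drops whatever share of the
level that draw assigned to those components and understates absolute
predictions. The default therefore evaluates each draw at its
population-typical values: the first birth-order category, the draw's mean
year effect, and the draw's mean mother and father effects
(`random_effects = "typical"`); the literal all-zero evaluation remains
available, and contrasts are identical under both because shared terms
cancel drawwise. Natural units mean the
distribution mean: `exp(theta + lambda^2/2)` for the log-Normal outcomes
(the median would understate cm and kg), the mixture mean
`(1 - p_never) * rate` for education (with the never-attend probability
also reported), and annual probabilities for survival with cumulative
survival as the running product over ages 0–18. Contrasts are drawwise
(focal minus base at matched posterior draws), against the base case of two
living, monogamously married biological parents; a state profile is
constant across ages (e.g. "mother deceased from birth"), and profiles that
violate the state logic (a death followed by remarriage of the same parent)
are rejected. Summaries report the posterior mean and the 90% highest
posterior density interval — the narrowest window containing 90% of the
draws, ties broken toward the lowest lower bound.

## The synthetic-data generator

The generator exists so that every stage — panel construction,
likelihoods, sampler, contrasts — can be exercised end to end against known
truth, without any external data. It emulates the structure the analysis
assumes: women move annually between unmarried and married by a Markov
kernel (marriage probability 0.3, dissolution 0.05 — unstable serial
monogamy; about 10% of new marriages join an already-married man, capped at
three wives); adults die at 2% per year; married women bear children at
0.25 per year (0.08 outside marriage, with the father recorded external);
28% of children have an external father and 6% an external mother, making
externals roughly 80% fathers; 7.5% of children have unrecorded sex; 1.5%
of births are twin pairs; anthropometrics and schooling are observed only
in the ten survey years 1995–2014. These defaults are the study conditions
of the package's calibration experiments and were fixed once, as plausible
values for a small high-fertility, high-mortality village registry.
Outcomes are then drawn from the exact model likelihoods: the default truth
uses a first-year survival probability of 0.92 rising toward 0.996 by late
childhood, standard growth curves for height and weight with an allometric
weight-for-height slope of 1.6, and schooling that begins around age 7.

What the generator does not emulate: measurement error in reported ages and
anthropometrics, recall bias in reconstructed histories, sub-annual event
ordering, migration in and out of the village, and any feedback from child
outcomes to parental behaviour (a child's death precipitating a divorce,
for example — the package quantifies that reverse-causation risk with the
same-year death/dissolution diagnostic instead of modelling it). Passing
tests therefore demonstrate internal correctness and statistical
calibration under the stated model, not robustness to those real-data
features.

A hand-written twelve-child fixture covers every leaf of both branching
trees plus censoring, a child death, twins, unknown sex and external
parents; its expected panel is frozen as a golden file and checked byte for
byte.

## Scales and reduced-scale experiments

Desk-scale defaults are deliberate: 2 chains x 500 warmup + 500 samples, a
500-child village for the effect-recovery study (20 replicates with a
maternal-death effect of -1.0 on the logit of annual survival at ages 0–2),
10,000 children for the generative-closure check of the 0.92 first-year
survival rate, and 25-child populations with 150 + 120 iterations for the
50-replicate prior-calibration suite. Full-scale settings are plain
arguments; nothing in the code assumes the reduced sizes.

## Known limitations

* Interval coverage for a *fixed* effect concentrated at a few ages runs
  below nominal: the half-Normal amplitude priors and the GP's pooling
  across neighbouring ages shrink such an effect toward zero, so 90%
  intervals centred on the shrunken estimate can miss a truth of larger
  magnitude more than 10% of the time. This is the ordinary behaviour of
  calibrated Bayesian intervals evaluated at a prior-atypical point — the
  prior-calibration suite (truth drawn from the prior) shows nominal
  coverage — but it is the relevant caveat when reading the effect-recovery
  study, whose replicate-level sign agreement is high while its coverage of
  the injected value falls short of nominal.

* Posterior summaries at desk scale carry Monte Carlo error; replicate
  counts in the calibration suites are sized to tolerate it, but individual
  fits should be read with their reported ESS.
* The year-effect GP interpolates reconstructed years with no events; its
  lengthscale is only weakly identified in sparse decades.
* A genuinely polygynous widower whose co-wives all die in one year falls
  back to the latest-starting union and is coded monogamous for that year —
  a deliberate simplification of an extremely rare case.
* The education model treats repeated survey measurements of the same child
  as conditionally independent ZIP draws; cumulative-schooling dynamics
  (and lagged family-structure effects generally) are out of scope.
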