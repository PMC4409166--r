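---
title: "Partitioning change in community productivity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning change in community productivity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoevopart)
```

## The question and the model

When a set of assembled microbial communities is propagated by serial
transfer in a new environment, total community productivity (biomass yield,
measured as the gain in optical density per growth period) changes over
time. Three mechanisms can drive that change:

1. **Ecological sorting** — some member species go extinct, and the
   community's yield reflects the survivors;
2. **Additive evolution** — the constituent species evolve different
   separate yields, while the interactions between them stay as they were;
3. **Interaction evolution** — the relationship between a community's yield
   and its members' separate yields changes: species use resources more (or
   less) complementarily than before.

The package separates these with a *frozen-coefficient counterfactual*
framework built on the additive expectation
$\sum_i a_i d_{ij}$ — the sum of monoculture yields $a_i$ over the species
present in community $j$ ($d_{ij} \in \{0,1\}$). At the start of the
experiment (week 0) a baseline linear model

$$A_j \;=\; \beta_{t=0}\!\left(E,\, S,\, \textstyle\sum_i a_{i}\,d_{ij}\right)$$

regresses community yields $A_j$ on the additive sum, with slopes and
intercepts allowed to vary with environment $E$ and log richness $S$
(`fit_baseline()`). Under no interaction the slope is 1 and the intercept 0;
slopes below 1 measure net negative interactions, and a slope that falls
with $\log S$ means interactions grow more negative in richer communities.
The model is simplified by backward AIC elimination (`simplify_by_aic()`),
respecting marginality, ties broken by removing the higher-order term first.

The baseline's coefficients are then *frozen* and applied to counterfactual
additive sums (`counterfactual_prediction()`):

| model | additive sum | survival mask $\varepsilon_{ij}$ | mechanism isolated |
|---|---|---|---|
| 1 | week-0 monoculture yields | yes | extinction only |
| 2 | week-5 monoculture yields | no | additive evolution (monocultures) |
| 3 | week-5 community-isolate yields | implicit | additive evolution (in-community) |
| 4 | week-5 sums, coefficients refitted by $E,S$ | no | + systematic interaction change |
| 5 | week-5 sums, coefficients refitted by $E$, composition | no | + composition-specific interaction change |

Each model's predicted week-5 yields give predicted *changes*
$\hat A_{j,5} - A_{j,0}$, which are regressed on the observed changes
(`evaluate_counterfactual()`); the regression's adjusted $R^2$ and AIC are
the comparison currency. Model 2 versus 3 is adjudicated by AIC. The
variance ledger (`decompose_variance()`) then reads:
extinction $= R^2_1$; additive evolution $= R^2_2$; systematic interaction
change $= R^2_4 - R^2_2$; composition-specific interaction change
$= R^2_5 - R^2_4$; residual $= 1 - R^2_5$. The last four sum to 100 %;
the extinction share is nested inside the others (a model-1 prediction is a
restriction of the additive models) and is therefore reported alongside,
not added. AIC is computed in the full Gaussian log-likelihood form
($n\log(\mathrm{RSS}/n) + n\log 2\pi + n + 2k$, with $k$ counting the
residual variance), i.e. `stats::AIC()` on the fitted regression.

A complementary test uses all data at once: `time_interaction_test()` fits
$A_{j,t} = \beta(E, S, t, \sum_i a_{i,5} d_{ij})$ at both weeks with a
per-microcosm random intercept (maximum likelihood, `nlme::lme`) and
compares against the fit without time terms by a likelihood-ratio test.
Because the week-5 additive sum already absorbs additive evolution, a time
effect indicates changed interaction strengths.

## The experimental design

`generate_design()` reproduces the random partitioned assembly scheme: each
of 12 species in monoculture, two independent random partitions of the pool
into communities at each intermediate richness (2, 3, 6), and the full
12-species mixture — 37 distinct compositions. Species with identical
colony morphotypes are kept apart by random swaps restricted to
conflict-free exchanges, so members can be re-identified at the end of the
experiment. Crossing 37 compositions with 3 replicates gives 111 microcosms
per environment and 333 after the three-way environmental split (beech tea,
pH 5 beech tea, spruce tea).

## The simulator: what it emulates and what it does not

`simulate_experiment()` generates the full experiment under switchable
scenarios. Its defaults *are* the study conditions:

* **Base yields** $a_{i,0}$: uniform on 0.1–0.4 absorbance per species;
  pH 5 shares the beech means (monoculture yields were comparable there),
  spruce is scaled by 0.5 (yields uniformly lower on spruce).
* **Interactions**: a single multiplicative factor
  $\theta(S,E) = \theta_1(E)\, S^{-\lambda(E)}$ on the additive sum.
  $\theta_1$ and $\lambda$ are calibrated so dicultures average 52.3 %,
  58.0 % and 75.1 % of additive in beech, pH 5 and spruce, and 12-species
  communities 13 %, 15 % and 16 % — inside the observed 9.9–16.1 % band.
  This makes $\theta_1(\mathrm{spruce}) \approx 1.37 > 1$; since $\theta$
  only applies to communities ($S \ge 2$, where it is 0.75 and below), the
  nominal $\theta(1)$ is never used. A single multiplicative factor, rather
  than pairwise coefficients, is exactly the quantity the ratio index and
  the slope-based models identify, which keeps the generator inside the
  inferential family being tested.
* **Extinction**: Bernoulli per species with probability
  $\mathrm{logit}^{-1}(\alpha_E + \gamma \log S)$, calibrated to ~1 % in
  monocultures and 74 / 84 / 86 % at 12 species (beech / pH 5 / spruce).
  Each microcosm keeps at least one survivor (an empty tube is never
  observed). This conditioning slightly deflates realised extinction at low
  richness — negligible for $S \ge 3$, and it is why monocultures are
  effectively immune; tests of the null richness slope therefore condition
  on $S \ge 3$.
* **Evolution**: per-species multiplicative drift of $a_i$ by week 5
  (drawn from Normal(1.3, 0.15) in additive-evolution scenarios, i.e. a
  30 % mean yield change) and/or a multiplicative drift of $\theta$
  (default 2, a doubling) in interaction-evolution scenarios. Intermediate
  weeks interpolate linearly.
* **Isolates**: surviving species yield a growth-assay observation
  $b = a_{i,5}(1 + \delta \log S_j)$ with $\delta = -0.05$ by default —
  isolates from richer communities grow less when returned to monoculture.
* **Noise**: measurement noise with standard deviation proportional to the
  expected yield (5 % default), plus a multiplicative per-microcosm effect
  (3 % default) shared across weeks — the random-intercept analogue.
* **Growth curves**: within-period OD series follow a normalised sigmoid
  saturating exactly at the target yield, so `compute_yield()` inverts them;
  the real study reported no within-period curves, so this shape is an
  assumption used only to exercise the growth primitives.

Not emulated: mechanistic resource competition or cross-feeding, phage,
within-experiment mutation dynamics, immigration, or abundance-based
extinction. Passing recovery tests therefore show that the *inference*
machinery attributes variance to the right generating mechanism within this
statistical family — not that real communities obey the generator.

## Numerical and design choices

* **Variance model in the all-data test.** Because noise scales with the
  signal and yields span a ~30-fold range across richness levels, an
  unweighted mixed-model likelihood-ratio test is strongly anticonservative
  (about 32 % rejection at nominal 5 % in null simulations). The default
  therefore models the residual standard deviation as proportional to the
  additive sum (`nlme::varPower` with power fixed at 1), which restores the
  nominal size (≈4 % over 100 null seeds); `variance = "constant"` retains
  the unweighted fit.
* **Model 5 is not simplified.** With an intercept and slope per
  environment × composition cell (150 parameters on 225 communities),
  term-wise elimination is neither stable nor informative; aliased cells
  (possible in degenerate replicate structures) are dropped with a warning.
* **Stepwise AIC under a null.** A k-df null term survives backward AIC
  elimination with asymptotically constant probability
  $P(\chi^2_k > 2k)$ (~13 % for k = 2), so a model with several null
  environment terms retains at least one of them in roughly half of
  realisations. This is a property of AIC itself, not of the
  implementation; the suite asserts the guarantees that do hold (the final
  AIC never exceeds the full model's, marginality is respected, true
  effects are retained).
* **Sensitivity analysis semantics.** `sensitivity_exclude_extinct()`
  masks end-extinct species out of the *week-0* additive sums and uses
  surviving richness. Note that under the package's own generator all
  members contribute fully at week 0, so this masking degrades the week-0
  baseline fit and *lowers* the extinction share; the analysis is useful
  for data where doomed species were already rare at the start — the
  assumption it was designed to probe.
* **Per-species sensitivity model.** One presence-weighted covariate per
  species (its week-0 replicate-mean monoculture yield in that
  environment), each interacting with time, a per-microcosm random
  intercept; the time-trend coefficients flag species whose community
  contribution changed.
* **Week-5 interaction indices** use community-isolate yields for the
  additive sum by default (what actually grew there); week-5 monoculture
  yields are available by option. Confidence intervals are Student-t on raw
  ratios, with log-ratio intervals by option.
* **Negative growth.** Raw yields are clamped at zero (biomass gains);
  generation counts keep negative per-period contributions by default,
  applying the doubling formula literally, with an optional floor at zero.
  Clamping introduces a bias below 0.5 % of the target at default noise,
  verified by simulation.
* **Mechanism recovery scoring.** `run_recovery_study()` scores a success
  when the generating mechanism's share is the largest of the three
  *mechanism* shares (extinction, additive, systematic interaction);
  composition-level and residual shares are descriptive remainders, not
  candidate mechanisms. Its sorting-only runs use extinction moderated to
  50 % at 12 species so that most communities keep several members and all
  five models remain fittable.

## Validation scale

The test suite validates at the full experimental scale (333 microcosms):
mechanism recovery over 100 seeds per pure scenario (each scenario's true
mechanism must win in at least 90), null calibration of the
time-interaction test over 500 seeds (5 % ± 3 %), and the extinction
calibration over 50 seeds (74 % ± 5 % at 12 species in beech). Exact
identities (design counts, the worked variance ledger, neutrality recovery
at $10^{-8}$, small-instance adjusted-$R^2$/AIC oracles) are checked
deterministically.

## A worked run

```{r example, eval = FALSE}
cfg <- simulation_config(scenario = "interaction_evolution", seed = 1)
report <- run_all(cfg, out_dir = "run1", make_figures = TRUE)
print(report)
report$partition$ledger
```

## Limitations

Adjusted $R^2$ differences between non-nested evaluation regressions are a
pragmatic, not exact, variance partition; negative increments are possible
and reported as-is with a warning. The evaluation regressions include an
intercept by default (the convention is not uniquely determined; an option
suppresses it). The composition-level share absorbs any mechanism that is
heterogeneous among compositions, including composition-specific sorting —
it should be read as "repeatable but composition-specific change", not as
interaction evolution alone.
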