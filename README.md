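# ecoevopart

Partitioning eco-evolutionary change in microbial community productivity.

## What it is for

Assembled bacterial communities propagated by serial transfer in a new
environment change their total biomass yield over tens of generations. For
experimentalists running such microcosm studies (communities of 1–12
species, optical-density yield assays, monoculture and community-isolate
growth assays), this package answers the question: **how much of the change
in community yield is ecological sorting (extinction), how much is additive
evolution of the member species' own yields, and how much is evolution of
the species interactions themselves?**

The core is a frozen-coefficient counterfactual framework. A week-0
baseline model

&nbsp;&nbsp;&nbsp;&nbsp;*A*<sub>j</sub> = β<sub>t=0</sub>(*E*, *S*, Σ<sub>i</sub> *a*<sub>i</sub> *d*<sub>ij</sub>)

regresses community yields *A*<sub>j</sub> on the additive expectation (the
sum of monoculture yields *a*<sub>i</sub> of member species,
*d*<sub>ij</sub> ∈ {0,1}), with slopes and intercepts varying by environment
*E* and log richness *S*, simplified by backward AIC elimination. Its frozen
coefficients are applied to counterfactual additive sums — week-0 yields
masked by survival ε<sub>ij</sub> (model 1: extinction only), week-5
monoculture yields (model 2) or community-isolate yields (model 3: additive
evolution) — and the coefficients are refitted at week 5 by richness
(model 4) and by composition (model 5) to quantify interaction change.
Regressing observed on predicted yield changes gives each model an adjusted
R² and AIC, and the variance ledger reads off the mechanism shares:
extinction = R²₁, additive = R²₂, systematic interaction change = R²₄ −
R²₂, composition-specific interaction change = R²₅ − R²₄, residual = 1 −
R²₅.

Around the core sit growth primitives (yield = max OD − starting OD;
generations = Σ log₂(OD.end/OD.start)), the random partitioned community
design generator, interaction indices (observed/additive, with t tests
against 1), a mixed-model test for changed interactions using all data,
extinction GLMs and isolate-yield trends, and a mechanism-switchable
simulator of the whole experiment so every inference stage can be validated
by parameter recovery.

## A worked example

Simulate an experiment in which the interaction factor doubles by week 5
(nothing else changes), then run the full pipeline:

```r
library(ecoevopart)
report <- run_all(simulation_config("interaction_evolution", seed = 1))
print(report)
```

```
Counterfactual partition of change in community yields
  additive-evolution model chosen by AIC: community-isolate yields (model 3)

 model                                              label   aic adjusted_r2       t   p_value
     1                                    Extinction only  -439     -0.0043  -0.200  8.42e-01
     2                           Monoculture changes only  -439     -0.0028  -0.621  5.35e-01
     3      Monoculture changes only (community isolates)  -483      0.1758  -6.985  3.25e-11
     4    Monoculture plus interaction changes (richness)  -819      0.8145  31.379  9.37e-84
     5 Monoculture plus interaction changes (composition) -1131      0.9538  67.972 4.79e-151

Variance decomposition of the change in community yields (%):
  extinction (ecological sorting)       -0.43  [nested, not summed]
  additive evolution of species yields  17.58
  interaction change (systematic)       63.87
  interaction change (composition)      13.92
  residual among replicates              4.62

Time-interaction test: LR = 1322 on 5 df, P = 1.27e-283
```

Reading this: extinction predicts nothing (R² ≈ 0 — none was simulated);
the additive counterfactuals explain little; refitting the slopes at week 5
explains 81 % of the variance in yield changes, so 64 percentage points are
attributed to systematic interaction change — the generating mechanism. The
time-interaction likelihood-ratio test agrees emphatically. Mechanism
attribution is validated across seeds with

```r
run_recovery_study(n_seeds = 100)   # fraction of seeds the true mechanism wins
```

## Layout

- `R/core.R` — growth computations, environment handling, CSV table I/O
- `R/design.R` — random partitioned design, morphotype conflict resolution
- `R/simulate.R` — the experiment simulator and its calibrations
- `R/interactions.R` — additive expectations, interaction indices, synergy GLM
- `R/partition.R` — baseline model, counterfactuals, ledger, mixed-model test
- `R/longitudinal.R` — richness/time trend models, extinction GLM, isolate trend
- `R/pipeline.R` — `run_all()` driver and the mechanism-recovery study
- `vignettes/partitioning-community-yield-change.Rmd` — methods and design notes
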