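---
title: "Discovering decision rules in a household farming simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering decision rules in a household farming simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emdisc)
```

## The question the package answers

Agent-based models of artificial societies encode an individual-scale
decision rule — here, how a subsistence farming household chooses its next
farm plot — and are judged by a population-scale outcome, the annual
household count matched against a historical target series. A single
hand-written rule is one hypothesis in an enormous space of plausible
decision processes, and parameter calibration alone cannot tell which
*causal factors* (soil quality, distance, social attraction, migration
pressure, ...) actually matter for fitting the data.

`emdisc` implements a model-discovery loop around such a simulation:

1. **Simulate.** An annual-step demographic model of farming households
   with a pluggable plot-selection strategy; fitness of a strategy is the
   RMSE between simulated and target household counts over the span.
2. **Search.** A strongly-typed genetic program evolves selection rules
   built from nine factor terminals and `+`/`-` operators under one of four
   social connectivity configurations, logging every evaluated rule.
3. **Rank.** A random-forest regression of fitness on the rules' signed
   factor coefficients ("presence") yields factor importance: impurity
   (gini), permutation, and decision-path joint contributions for
   interactions; Mann-Whitney comparison matrices and a designed-strategy
   robustness comparison complete the analysis.

## The simulator

Households farm one cell each, store maize, age, reproduce and die on an
annual clock. Within year $t$ the order of events is:

1. **Harvest.** Each farm yields
   $h = Y_z(t)\, q\, a\,(1 + \varepsilon)$, $\varepsilon \sim N(0, v)$,
   truncated at zero, where $Y_z(t)$ is the zone's baseline yield
   (kg/cell/year, the precomputed imprint of drought conditions), $q \in
   [0,1]$ the cell's soil quality, $a$ the harvest adjustment, and $v$ the
   harvest variance.
2. **Consumption.** Each household consumes its annual nutrition need,
   eating the oldest vintage first; maize older than two harvests spoils
   and is discarded.
3. **Mortality.** Households older than their (individually drawn) death
   age are removed.
4. **Relocation.** A household whose realized harvest fell short of its
   need estimates that the farm can no longer sustain it and invokes the
   selection strategy over the candidate plots its connectivity allows; it
   re-sites its dwelling near an active water source (within the
   `water_source_distance` parameter). A household with no admissible farm
   or dwelling leaves the population.
5. **Fission.** A household inside its fertile age window holding at least
   one year's need fissions with its drawn fertility probability; the child
   receives a fixed fraction of the parent's stock and invokes the strategy
   for its own farm.

Agent processing order is reshuffled every year from the run RNG, so no
household is systematically advantaged by its id. Corn is conserved within
each step up to harvest inflow, consumption, spoilage and the stock of
departing households; the per-year ledger is returned with every run and
asserted in the tests to 1e-9 relative.

Two design points deserve emphasis because the literature leaves them open:

* **The relocation trigger** uses the current year's realized harvest as
  the estimate of next year's — the simplest estimator consistent with
  "the farm can no longer produce enough".
* **Initialization** places the target series' first value of households on
  the highest-quality available plots (dwellings nearest to water), which
  anchors the year-zero error at zero. Initial ages are uniform on
  0–25 years and initial stores are one year's need.

### Parameters

All eleven demographic and agronomic parameters are drawn per run from the
±5% windows around the best published calibration of this model family
(`default_param_ranges()`): e.g. water source distance (10.925, 12.075)
cells, minimum death age (38, 42) years, base nutrition need (175.75,
194.25) kg/year, harvest adjustment (0.608, 0.672), harvest variance
(0.418, 0.462). Evaluating every candidate rule under freshly drawn
parameters selects for rules that are *robust* to parameter initialization
rather than tuned to one vector; `degenerate_ranges()` pins the windows for
exact replays.

## The rule language

A rule is `argmax[S_X](expression)`: the household scores every candidate
plot with the expression and takes the best, ties broken toward the lowest
`(y, x)` coordinate. The expression is a typed tree over nine factor
terminals combined with `+` and `-`; each terminal returns a desirability
sub-score min-max normalized to $[0,1]$ *within the candidate set* (an
all-equal factor returns the neutral 0.5, so degenerate normalizations
never produce NaN):

| factor | raw statistic (higher sub-score) |
|---|---|
| `F_Dist` | distance from the current farm (farther, by default) |
| `F_Dry`  | dryness of the plot's zone this year (negated baseline yield) |
| `F_Qual` | soil quality |
| `F_Yield`| last year's realized yield on the plot (0 if never farmed) |
| `F_Water`| active water sources within the social radius |
| `F_Soc`  | households dwelling within the social radius |
| `F_HAge` | age similarity to households near the plot |
| `F_HAgri`| corn-stock similarity to households near the plot |
| `F_Mig`  | 1 if the plot lies in a different zone, else 0 (not normalized) |

On the distance orientation the literature is self-contradictory: the
factor catalogue scores *closer* plots higher, while the original-rule
equation, the robustness baseline `argmax(-F_Dist)` and the discussion all
treat positive `F_Dist` as *farther*. We follow the latter, which makes
`argmax(-F_Dist)` reproduce the classical nearest-available-plot strategy
decision-for-decision (a property the acceptance suite checks against a
hard-coded oracle); `sim_options(dist_farther = FALSE)` flips the
orientation.

The homophily statistics are the negated mean absolute attribute difference
to households within the social radius; plots with no household in radius
take the worst observed raw value so the statistic is defined everywhere.
"Knowledge" of plots under the family / neighbor / best-performer
connectivities means the available plots within the neighbor radius
(default 10 cells) of the knowing household's dwelling; the social radius
(default 5 cells) and the top-`k` of `S_Perf` (default 10) are likewise
unstated in the source material and exposed in `sim_options()`.
Knowledge is current-year only; households do not remember plots from
past years.

Coefficients are *not* terminals: integer presence arises only from
repeated terminals under `+`/`-` (e.g. `2*F_Mig` is `F_Mig + F_Mig`), so
`extract_presence()` — the linear expansion of the tree — is always a
signed integer vector. Rule evaluation computes exactly this linear form,
which is mathematically identical to evaluating the tree node by node; the
test suite checks the argmax against a scalar per-candidate tree
evaluation on fuzzed contexts, with a 1e-9 score slack absorbing float
association order on exact ties.

## The genetic program

Each run evolves 50-individual generations (100 by default) of trees with
depth 4–10, initialized half-and-half (half full trees, half grow trees,
target heights uniform over the depth range). Selection is tournament of
3; variation is typed subtree crossover (probability 0.8) and typed
subtree-regrow mutation (0.2, also resampling the connectivity with
probability 0.2). The source protocol names none of these operators, so
conventional defaults are declared in `gp_config()` rather than inferred.
Offspring exceeding the depth bound are rejected in favour of their parent
(bloat control). Every individual in every generation is re-evaluated
under freshly drawn parameters — memoization would be unsound since
fitness is itself stochastic — and every evaluation is appended to the
factor-scores table, so the table row count is exactly
`population x (generations + 1) x runs`. One simulator replicate per
evaluation follows the published protocol; `gp_config(replicates = ...)`
averages several seeded replicates per evaluation for users who want a
less noisy fitness at proportional cost.
Per-evaluation RNG streams derive from (seed, run, generation, index), so
a serial execution is fully reproducible and any parallel scheduler
executing evaluations independently would produce a permutation of the
same table.

## The importance pipeline

`fit_forest()` regresses fitness on the nine presence columns, restricted
by default to `S_All` rules (full information fits best, and mirroring the
published analysis keeps the feature space homogeneous), with a 90/10
train/test split and a tree-count search over 10–1000. Three importance
views are computed:

* **Gini / impurity** (`gini_importance()`): variance-decrease shares,
  normalized to sum to one (delegated to the forest backend).
* **Permutation** (`permutation_importance()`): mean held-out MSE increase
  over independent column shuffles (default 10 repeats).
* **Joint contributions** (`joint_contributions()`): every prediction is
  decomposed along each tree's root-to-leaf path; the change in node mean
  at each split is attributed to the *set* of distinct features seen on
  the path so far. Internal node means are reconstructed exactly by
  routing the tree's in-bag training rows, so
  `bias + sum(contributions) = prediction`
  holds to numerical precision for every sample — the suite asserts 1e-9
  relative against the backend's own predictions. Aggregated absolute mass
  is normalized by the total over all subsets and reported for subsets of
  at most three factors.

`mann_whitney()` implements the one-tailed test with an exact null for
small samples (the distribution function of U when the data are tie-free,
full enumeration of group assignments otherwise) and a tie-corrected
normal approximation beyond; identical constant samples return p = 1
rather than NaN. Exactness switches at a smaller-group size of 8, with an
enumeration budget guard for pathological shapes. No multiple-testing
correction is applied by default, matching the published procedure; a Holm
option exists. `compare_strategies()` runs the robustness comparison:
n seeded simulations per strategy under freshly drawn parameters, each
designed strategy tested one-tailed against the baseline.

## The synthetic testbed

The real environment files of the historical case study are not
redistributable, so the package generates synthetic landscapes
(`generate_synthetic_environment()`) that emulate their structure: a
multi-zone grid (nearest-seed zones), a spatially autocorrelated quality
field (smoothed white noise, min-max rescaled to [0, 1]), per-zone AR(1)
baseline-yield series, sparse always-active water sources, and — crucially
— a target household series produced by one seeded simulation run under a
*planted* generating rule. By construction, re-simulating the planted rule
with the recorded seed and parameters reproduces the target exactly
(RMSE 0), giving the pipeline a ground truth.

The default spec (20x20 grid, 4 zones, 60 years, 15 initial households,
zone mean yields 550–950 kg) is a general-purpose testbed. The *recovery
experiments* in the tests and the acceptance script use a deliberately
scarcer, smaller variant — 16x16 grid, quality autocorrelation length 1,
40 years, 10 initial households, zone mean yields 330–500 kg — chosen
once, on two grounds. First, discrimination: with the nutrition need
around 185 kg and harvest adjustment around 0.64, only higher-quality
cells sustain a household, so plot choice materially drives demography
and the planted factor leaves a recoverable signature; a short
autocorrelation length disperses the initial settlement, which separates
the dynamics of clustering (`F_Soc`), quality-seeking (`F_Qual`) and
zone-hopping (`F_Mig`) rules. Second, scale: populations stay in the
20–50 range, keeping a full reduced search (5 runs x 16 generations x 20
individuals, about 1,600 simulations per planted factor) at desk scale.
The importance-recovery studies use 5,000-row synthetic presence tables
with planted effects (30, -10, 5 on quality, social presence, migration,
noise sd 5) over 40 seeds, with 60-tree forests.

What passing these tests shows — and what it does not: recovery of planted
single-factor rules demonstrates that the search and the importance
measures can identify a decision factor *when it truly generates the
target*, under parameter and demographic noise. It does not validate the
demographic model against any real settlement record, nor calibrate the
radii and thresholds to archaeology; with a single count series as
fitness, rules whose population trajectories are statistically close (a
quality-seeker and a yield-seeker, say) remain partially confounded, and
high-variance dynamics (strong social clustering on marginal land) are
intrinsically harder to recover from a single target realization. In the
shipped reduced experiments the planted quality rule is recovered in every
run, while planted migration and social-presence rules are recovered only
in a minority of runs: their targets are generic growth or stagnation
trajectories that flexible quality/yield/water mixtures can mimic, and the
per-run best rule — the minimum over 1,600 noisy single-replicate
evaluations — is selected precisely for such mimicry. The acceptance
checks report these recovery counts as they are. Spatial (2-D) pattern
fidelity is likewise out of scope.

## Numerical and degenerate-input conventions

* Min-max normalization over an all-equal candidate set returns 0.5
  everywhere; the migration factor is binary by definition.
* Argmax ties break toward the lowest `(y, x)`; cell storage is row-major
  in `(y, x)` so "first maximum" implements the tie-break for free.
* The empty population is an absorbing, valid state; an empty candidate
  set means relocation failure (removal), never an error.
* Environment CSV files carry at most 15 significant digits, making
  read/write round-trips byte-identical; coordinates are 0-based,
  x = column, y = row, origin top-left, stated in every file header.
* A planted-rule simulation that goes extinct within the first 10% of the
  span is rejected as a degenerate spec at generation time.
* The exact Mann-Whitney enumeration is capped at 5x10^5 assignments;
  beyond that the tie-corrected normal approximation is used.

## Reduced problem sizes

The shipped tests and the acceptance script run the full pipeline at the
reduced scales stated above (they recompute everything from scratch; the
published 20-run x 100-generation configuration remains the default of
`gp_config()` for real use). The one published quantity that needs no
environment is reproduced exactly: of the 20 best evolved rules shipped in
`table1_fixture()`, 15 have fitness below the literature benchmark RMSE of
733.6 (`table1_report()`).

## Known limitations

* One shared rule for the whole population; competing behavioral
  archetypes cannot be distinguished.
* Fitness is a single time series; pattern-oriented multi-criteria
  filtering and 2-D spatial validation are out of scope.
* Functional-ANOVA importance is deliberately not implemented; the
  decision-path joint contribution fills the interaction-importance role.
* The serial executor is the only one shipped; the evaluation-stream
  design admits a parallel scheduler but none is bundled.
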