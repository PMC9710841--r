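---
title: "Modelling personality-state variability from workplace contact networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling personality-state variability from workplace contact networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egostates)
```

## The problem

Personality expresses itself partly as *states*: momentary, situation-bound
levels of extraversion, agreeableness, conscientiousness, emotional stability
and openness that fluctuate around a person's stable traits. In a workplace
wearing sociometric badges, two passive data streams make that fluctuation
observable at scale: a log of face-to-face contact events between employees,
and thrice-daily ecological momentary assessment (EMA) self-reports of the
five states on a 1–7 Likert scale (each score the mean of two items, hence a
half-point grid).

`egostates` implements the full analysis chain that links the *structure* of
a person's weekly interaction network to the *volatility* of their
personality states that week, and quantifies which structural features carry
the predictive signal. The question it serves is exploratory and
hypothesis-generating: which aspects of social position — cohesion,
brokerage, centrality, community embedding — move together with week-level
personality dynamics?

## From directed detections to weekly networks

Badge detections are directed: each record says whose detector logged whom,
and detectors miss contacts independently in each direction. The package
splits records into Monday–Friday work weeks (calendar-based, inclusive at
both ends; weekend records are dropped at parse time) and reconciles the two
directions conservatively. For every unordered pair $\{a,b\}$ with directed
weekly counts $c_{ab}$ and $c_{ba}$,

$$w(a,b) = \min(c_{ab}, c_{ba}),$$

the number of contacts both badges agree on. Pairs with a zero minimum get no
edge; participants with no reconciled edge in a week get no node — and hence
no feature row — for that week. Ego features are undefined for degree-zero
nodes, so dropping the person-week (rather than imputing) is the only
internally consistent choice; it also means the modelling table generally has
fewer rows than participants × weeks.

## The 26 network features

Each person-week row holds 9 global structural features (constant within a
week), 4 global nodal features, and 13 egocentric features computed on the
ego network: the vertex-induced subgraph on the ego and its alters, with
alter–alter ties retained. The week index is appended as a 27th predictor
(numeric; tree models only exploit its ordering).

Distances use edge length $1/w$ — frequent contact means "close" — except
the diameter, which is a weight-agnostic hop count on the largest connected
component. Several definitions are deliberately literal rather than
textbook-normalized, and the choices are worth stating:

* **Degree centralization** (global and ego) is
  $\sum_i (d_{max} - d_i)/(n-1)$ with unweighted degrees. The conventional
  Freeman denominator is $(n-1)(n-2)$; the package follows the operational
  definition above, which gives e.g. centralization 1 for a three-node path
  and 3 for a five-node star. This diverges from the convention knowingly;
  rank order across networks of similar size is preserved.
* **Closeness** is $(n-1)/\sum_j d(v,j)$ over reachable $j$ under
  inverse-weight distances.
* **Betweenness** (global, and the ego's betweenness over alter–alter pairs
  within the ego network) counts fractions of geodesics and is normalized by
  the number of eligible pairs. Geodesics use inverse-weight lengths by
  default, consistent with the closeness/geodesic-distance scheme; a
  `betweenness_weights = "hop"` flag switches to unweighted geodesics, since
  the defining text is silent on this point.
* **Burt measures.** Effective size is $k - 2t/k$ ($k$ alters, $t$
  alter–alter ties). Efficiency divides effective size by the *order* of the
  ego network (ego included), following the literal operational definition;
  Burt's own convention divides by $k$, and
  `efficiency_denominator = "alters"` restores it. Constraint is the
  weight-proportional aggregate $\sum_j (p_{ij} + \sum_q p_{iq} p_{qj})^2$
  computed within the ego network; a single-alter ego has constraint 1.
* **Reach efficiency** is the fraction of the *whole* weekly network within
  two hops of the ego, divided again by the ego-network order. The double
  normalization is one defensible reading of an ambiguous definition; it is
  documented as this package's convention, with a flag for the alter-count
  denominator.
* **Subcommunities** come from weighted modularity maximization at
  resolution 1. At cohort scale this is the Louvain heuristic, restarted 10
  times from a fixed seed with the best partition kept; on graphs of at most
  10 nodes the exact integer-programming maximizer is used instead, because
  the greedy heuristic demonstrably misses the optimum on a few percent of
  tiny graphs where exact search is cheap. One partition is computed per
  weekly network and reused for every nodal row. `community_percent_size` is
  reported as a fraction of the order (the raw count is emitted as an
  auxiliary column); tree models are insensitive to this monotone choice.
* **Degenerate egos.** For single-edge egos, ego transitivity and ego
  centralization have empty or zero denominators; both fall back to 0 rather
  than missing so the person-week row survives — boosting handles
  near-constant columns, whereas missingness would silently drop subjects.

Every feature is validated against an independent brute-force oracle
(exhaustive path, triplet and set enumeration; exhaustive partition search
for modularity) on 200 random weighted graphs of up to 7 nodes at tolerance
1e-9 — see `tests/testthat/test-acceptance.R`.

## Outcomes: week-level state variability

For each participant, week and trait, the EMA responses (in chronological
order, all days of the week forming one series, no imputation across missed
prompts) reduce to the root mean square of successive differences:

$$\mathrm{RMSSD} = \sqrt{\frac{\sum_{i=1}^{N-1}(x_i - x_{i+1})^2}{N-1}}.$$

A week needs at least two responses ($N \ge 2$, one difference); constant
weeks legitimately give 0. On the 1–7 scale RMSSD is bounded by 6. Timestamp
ties keep file order, and the choice to let series run across the overnight
gap (rather than per-day) follows from the statistic being a within-week
summary.

## Modelling: LOSO gradient boosting

Five parallel gradient-boosted tree regressions (one per trait) predict the
person-week RMSSD from the 27 predictors under leave-one-subject-out (LOSO)
cross-validation: all 1–6 rows of one participant are held out, the model is
tuned and trained on everyone else, and this repeats once per participant.

Seven hyperparameters (boosting rounds, row subsample, feature subsample,
tree depth, minimum child weight, gamma, learning rate) are tuned by grid
search. The inner resampling is **participant-grouped 5-fold
cross-validation** rather than row-wise bootstrap: with up to six rows per
person, row-wise resampling would leak within-person structure into tuning.
The default grid crosses three levels per tunable where meaningful (108
points); `default_grid(reduced = TRUE)` is a 4-point rounds × depth grid for
simulation studies. Ties select the first grid row; every fold's seed is the
base seed plus a stable hash of the participant id, so results are
independent of fold execution order and the whole five-trait run is
bit-identical across repeats.

Two cohort-level performance views are reported, and the distinction
matters:

* `mean_r2` — the mean of per-fold $R^2$ values, where fold $R^2$ is the
  squared Pearson correlation of observed and predicted values (undefined
  with fewer than 3 rows or zero variance on either side; undefined folds
  are excluded). This mirrors how per-participant performance tables are
  usually presented, but with 1–6 rows per fold it is a noisy statistic:
  under a null association its expectation is roughly $1/(n-1) \approx 0.2$
  per 6-row fold.
* `pooled_r2` — the squared correlation between *all* held-out predictions
  and observations pooled across folds. Under the null this sits near zero,
  which makes it the measure used by the planted-effect recovery checks.

RMSE is reported raw and normalized by the pooled observed RMSSD range
across all five traits. A participant is flagged *consistently informative*
when their worst trait model still has $R^2 \ge 0.05$ and the mean
normalized RMSE across the five models is at most 0.25 (both bounds
inclusive; any undefined $R^2$ fails the flag). Comparator baselines — a
lasso-penalized linear model with cross-validated penalty and a k-nearest
neighbour regression with default $k = 5$ — run under the identical fold
scheme.

## Importance: permutation, scaled 0–100

Feature importance is *permutation* importance: the mean increase in RMSE
over `n_repeats = 10` shuffles of one predictor column, negative means
floored at 0, permutation RNG seeded per feature. (Gain-based importances
from the tree internals would be cheaper but conflate usage with
contribution; the permutation definition matches the error-inflation
description this pipeline follows.) Per trait, raw importances rescale
linearly to 0–100; the cross-trait profile is the row-wise mean of the five
scaled vectors, ranked descending with alphabetical tie-breaks. By default
the profile is computed on each fold's training side and averaged
(`importance_source = "folds"`); the `"pooled"` source — one tuned model on
the full table per trait — is the cheap alternative used in the simulation
studies. The aggregation arithmetic is validated against a published 27-row
reference profile shipped in `inst/extdata/`.

## The synthetic cohort generator

`simulate_cohort()` makes the whole chain testable with known ground truth.
It emulates the *structure* of a badge-plus-EMA study, not any particular
office:

* **Contacts**: a stochastic block model. The default cohort has 54
  participants in 4 equal blocks over 6 weeks starting Monday 2012-01-30,
  with 4 expected true contacts per within-block pair per workday and 0.8
  between blocks — giving weekly interaction volumes and community structure
  of the order seen in real sociometric-badge deposits. A log-normal weekly
  activity factor (log-SD 0.2) and per person-week engagement factors
  (log-SD 0.4) make networks vary across weeks and people, as real workplace
  networks visibly do; this within-person variation is also what gives LOSO
  folds something to predict.
* **Detector dropout**: each true contact is logged independently by each
  badge with probability 0.85 (thinning 0.15), generating the directional
  discrepancies the minimum rule reconciles. At thinning 0 reconciliation is
  provably lossless.
* **EMA**: 15 prompts per week (3 per workday at 11:00, 14:00, 17:00). Per
  participant, week and trait the latent state performs a first-order random
  walk around the person's trait mean with innovation scale
  $\sigma = \max(\sigma_0 + \beta z, 0.05)$, where $z$ is the within-week
  standardized value of the driver feature (default: egocentric efficiency,
  $\sigma_0 = 0.3$, $\beta = 0.5$) from the participant's *actual* simulated
  network; isolated participants fall back to $\sigma_0$. First-order
  innovations make $\sigma$ map monotonically onto expected RMSSD — the
  statistic the pipeline measures. Responses add Gaussian measurement noise
  (SD 0.1), then round to the half-point 1–7 grid. The floor at 0.05 keeps
  the scale positive when $\beta z$ is strongly negative.
* **Determinism**: one root seed feeds named substreams (cohort parameters,
  per-week contacts, per-week EMA), so identical configurations give
  byte-identical CSV logs and any week can be regenerated independently.

What the generator does **not** model: diurnal or weekday rhythm, EMA
non-response, participant dropout, demographic covariates, or any
directionality of the volatility link beyond the planted monotone one.
Passing the recovery tests therefore shows the pipeline can detect a planted
monotone network–volatility link at realistic size and noise — it does not
certify performance on real cohorts, where compliance, unmeasured outsiders
and non-monotone effects intrude.

## Validation problem sizes

The shipped checks run at sizes chosen to exercise every code path while
staying desk-scale: the feature oracle on 200 random graphs of 3–7 nodes;
RMSSD identity on 1,000 random series; LOSO partition properties on 20
random cohort shapes; planted-driver recovery on ten full-size cohorts
(54 × 6, single-point reduced grid, pooled importance) requiring pooled
$R^2 > 0.3$ and a top-3 driver rank in at least 8 of 10 seeds, with null
cohorts ($\beta = 0$) bounded below pooled $R^2 = 0.1$; and the acceptance
script runs one full cohort with the 4-point tuned grid.

## Known limitations

* The centralization, efficiency and reach-efficiency conventions are
  literal readings of operational definitions, not the field's canonical
  normalizations; flags expose the conventional variants.
* Per-fold $R^2$ on 1–6 rows is intrinsically unstable; prefer `pooled_r2`
  for cohort-level claims.
* Importance is a scalar screen: it carries no directionality and inherits
  the collinearity of the feature set (structurally related ego features
  share credit). Treat profiles as hypothesis-generating.
* The exact modularity maximizer is only feasible for small graphs; at
  cohort scale the restarted Louvain heuristic may return a local optimum,
  as the algorithm always can.
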