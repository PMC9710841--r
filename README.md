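# egostates

Links the **structure of workplace social networks** to the **week-level
variability of Big Five personality states**, for researchers in digital
phenotyping, organizational psychology and computational behavioral health
who work with passive-sensing contact logs and ecological momentary
assessment (EMA) self-reports.

The pipeline, end to end:

1. **Parse** two CSV logs: directed badge detections
   (`timestamp,logger_id,detected_id`) and EMA responses
   (`timestamp,participant_id,extra,agree,consc,stabl,open`, scores on a
   1–7 half-point Likert grid), split into Monday–Friday work weeks.
2. **Build** one undirected weighted network per week. Detectors miss
   contacts asymmetrically, so the edge weight of pair {a, b} is the
   reconciled minimum of the two directed counts,
   `w(a,b) = min(c_ab, c_ba)`.
3. **Extract 26 network features** per person-week — 9 global structural
   (order, size, ordered pairs, density, diameter, mean geodesic distance,
   transitivity, degree centralization, number of Louvain subcommunities),
   4 global nodal (degree, closeness, betweenness centralities, community
   percent size), and 13 egocentric (Burt effective size, efficiency and
   constraint, reach efficiency, dyadic redundancy, ego–alter similarity,
   ego betweenness, plus the structural formulas on the ego network) — with
   the week index as a 27th predictor.
4. **Compute outcomes**: per participant, week and trait, the root mean
   square of successive differences of the EMA scores,

   RMSSD = sqrt( Σᵢ (xᵢ − xᵢ₊₁)² / (N − 1) ),

   a moment-to-moment volatility statistic on the 1–7 scale.
5. **Model** each trait's RMSSD from the 27 predictors with gradient-boosted
   trees under leave-one-subject-out cross-validation, hyperparameters tuned
   by an inner participant-grouped 5-fold grid search; penalized-linear and
   k-nearest-neighbour comparators run under the same folds.
6. **Introspect** via permutation feature importance, scaled 0–100 per trait
   and averaged across the five traits into a ranked profile.

A synthetic cohort generator (`simulate_cohort()`) emulates both logs — a
stochastic block model of contacts with per-direction detector dropout, and
EMA random walks whose innovation scale is a planted function of a chosen
network feature — so the entire pipeline is testable with known ground
truth and no external data.

## Worked example

```r
library(egostates)

cfg    <- sim_config(n_participants = 20, n_weeks = 3, seed = 42)
cohort <- simulate_cohort(cfg)
run    <- run_pipeline(cohort$interactions, cohort$ema, cohort$weeks,
                       grid = default_grid(reduced = TRUE), seed = 42,
                       n_repeats = 5)
print(run)
```

```
egostates pipeline run
  person-week feature rows : 60
  outcome rows             : 60
  mean fold R2 by trait    : extra=0.64 agree=0.72 consc=0.74 stabl=0.67 open=0.81
  pooled R2 by trait       : extra=0.35 agree=0.61 consc=0.49 stabl=0.45 open=0.57
  top features             : transitivity_ego, closeness_centrality, geodesic_distance_ego
```

Every one of the 20 simulated participants produced a feature row in all
three weeks (60 person-weeks). `mean fold R2` is the average squared
correlation between observed and predicted RMSSD within each held-out
participant's 3 rows — informative but noisy at that fold size. `pooled R2`
correlates all held-out predictions with observations at once and is the
stabler cohort-level measure; 0.35–0.61 here reflects the planted
network–volatility link (the generator default couples volatility to
egocentric efficiency with coefficient 0.5). At this small cohort size,
credit for the planted driver spreads across structurally correlated ego
features (`transitivity_ego`, `closeness_centrality` top the profile); at
the default 54-participant scale the planted `efficiency` feature itself
ranks first.

```r
head(run$importance[c("feature", "average", "rank")], 3)
#>                 feature  average rank
#> 1      transitivity_ego 83.71939    1
#> 2  closeness_centrality 76.33705    2
#> 3 geodesic_distance_ego 53.11846    3

head(run$participant_summary, 2)
#>   participant_id    r2_min    r2_max    r2_avg  nrmse_min nrmse_max  nrmse_avg informative
#> 1            519 0.8000967 0.9990825 0.9361538 0.12292806 0.3306620 0.22187988        TRUE
#> 2            515 0.7993037 0.9982194 0.9269561 0.03499589 0.1288000 0.07833471        TRUE
```

`render_reports(run, "reports/")` writes the three tables (weekly outcome
summary, per-participant performance with the consistently-informative flag,
ranked feature importance) as CSV.

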