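# dccn — differential food co-consumption networks and dietary risk scores

`dccn` implements a network framework for finding *disease-specific dietary
structure* in prospective cohort data and turning it into an individual risk
score. It was built for the setting where food-frequency intakes are
zero-inflated, right-skewed, and dietarily homogeneous (e.g. rice-centered
Korean cohorts such as KoGES-CAVAS and KoGES-HEXA), so that conventional
pattern methods (PCA, factor analysis, Gaussian graphical models) struggle
to separate cases from non-cases. Its intended users are nutritional
epidemiologists analysing cohort FFQ data.

## The method

1. **Co-consumption networks (CCN).** For each outcome group (participants
   who develop the disease vs. those who do not), edge weights between the
   45 food groups are partial Spearman correlations of cumulative-average
   servings/day, adjusted for total energy intake and sex. Stability
   selection makes edges trustworthy: the group is subsampled to 50%,
   100 times, and an edge *a–b* is kept only if

   > | mean over iterations of r(a,b) | > 0.2 **and** p < 0.05 in every
   > iteration,

   with the signed mean correlation as the edge weight.

2. **Differential subnetworks.** Edges present in both group networks are
   the shared dietary backbone; removing them leaves the
   *disease-exclusive* and *non-disease-exclusive* edge sets, each inducing
   a differential subnetwork that isolates group-specific co-consumption.

3. **Integrated centrality.** Within each differential subnetwork, five
   node centralities — degree, strength (Σ|w|), betweenness, closeness,
   eigenvector — are z-standardized and averaged into one integrated
   centrality per food; foods are classified hierarchically as primary hub
   (rank 1, eigenvector ≥ 0.8), hub (ranks 2–3), bridge (betweenness
   ≥ 0.15), connector (degree ≥ 2) or peripheral.

4. **D_CCN score.** Intakes are binarized per food with adaptive cut-points
   (Q1 if Q1 > 0; else the median; else Q3; else any positive amount).
   For participant *i* with consumption indicators *b_if*,

   D_CCN(i) = Σ_f b_if · w_D(f) − Σ_f b_if · w_ND(f),

   where *w_D*, *w_ND* are the integrated centralities of the
   disease-specific and non-disease-specific subnetworks. Weights derived
   in one cohort can be transferred to score another cohort.

5. **Association.** Incidence rate ratios across within-cohort score
   quartiles come from modified Poisson regression — a Poisson GLM on the
   binary incident outcome with a log person-years offset and HC0 sandwich
   variance — adjusted for age, sex, education, exercise, smoking, alcohol,
   BMI and energy, with a trend test that scores each quartile by its
   median.

Because the motivating cohort data are access-restricted, the package
includes a first-class synthetic cohort simulator (`sim_config()`,
`simulate_cohort()`): a Gaussian copula with per-food zero-inflation by
latent thresholding, log-normal marginals, a shared block-correlation
backbone, planted group-exclusive hub-and-spoke edges, and an incident
outcome drawn from an exponential waiting time whose rate depends on the
planted adherence score. Every pipeline stage can therefore be validated
against known truth.

## Worked example

```r
library(dccn)
library(dplyr)

cfg <- sim_config(seed = 42)            # 45 foods, 2000 per group,
sim <- simulate_cohort(cfg)             # planted rho = 0.4 star edges
intake <- mutate(sim$intake[, c("id", "energy", cfg$foods)],
                 visit = 1L, .after = "id")
cohort <- mutate(sim$cohort,
                 incident_t2d = as.integer(sim$intake$group == "diabetic"))
run <- run_dccn(intake, cohort, config = list(seed = 42L))
run
#> <dccn pipeline run>
#>   seed 42, 40 excluded, networks: non_diabetic (35 edges), diabetic (35 edges)
#>   differential: 5 / 5 exclusive edges, 30 shared
#>   Q4 vs Q1 IRR 1.078, p-trend 0.149
```

The pipeline excluded 40 participants (energy tails), built both group
networks (35 edges each: the 30-edge shared backbone plus that group's 5
planted exclusive edges), and recovered **all 10 planted differential
edges with no false positives**. The near-null quartile IRR is expected in
this evaluation design: the two groups differ only in co-consumption
*structure*, not in marginal intake, so group membership is not predicted
by the score — the score→outcome model is validated separately (below).

```r
classify_roles(centralities(run$differential$exclusive_a)) |>
  select(food, degree, betweenness, eigenvector,
         integrated_centrality, rank, role) |> head(5)
#>   food    degree betweenness eigenvector integrated_centrality  rank role
#> 1 food_26      5           1       1                     2.04      1 primary_hub
#> 2 food_29      1           0       0.477                -0.355     2 hub_food
#> 3 food_27      1           0       0.452                -0.398     3 hub_food
#> 4 food_28      1           0       0.448                -0.406     4 peripheral
#> 5 food_30      1           0       0.433                -0.433     5 peripheral
```

The planted hub (`food_26`) is identified as the primary hub of the
disease-exclusive subnetwork, exactly as planted. On a cohort of 20,000
with a planted rate ratio of 1.5 per SD of the adherence score, the
modified Poisson stage recovers `IRR = 1.58 (n = 20,000)` at `--seed 1`
(see below), with the quartile trend p ≪ 0.001.

## Package tour

| Stage | Functions |
|---|---|
| Data model & I/O | `read_cohort()`, `apply_exclusions()`, `cumulative_average()`, `write_network()`, `write_scores()` |
| Synthetic cohorts | `sim_config()`, `generate_intake()`, `generate_outcome()`, `sim_truth()`, `simulate_cohort()` |
| Network building | `partial_spearman()`, `stability_edges()`, `threshold_sensitivity()` |
| Differential analysis | `differential()`, `ego_network()`, `graph_summary()`, `summarize_egos()` |
| Centrality & roles | `centralities()`, `classify_roles()` |
| Scoring | `adaptive_cutpoints()`, `binarize()`, `score_dccn()`, `transfer_scores()` |
| Association | `assign_quartiles()`, `modified_poisson()`, `quartile_irr()`, `trend_test()` |
| Orchestration | `validate_config()`, `run_dccn()`, `inst/cli/dccn.R` |

Results are tibbles throughout; fitted objects support `tidy()` and
`glance()`, and networks plot with `autoplot()`. The methods vignette
(`vignettes/dccn-methods.Rmd`) documents the modelling choices, simulator
design and known limitations.
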