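---
title: "Differential co-consumption networks: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential co-consumption networks: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dccn)
library(dplyr)
```

This vignette is the package's own account of the science it implements:
the statistical model at each stage, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the numerical and design choices made where the method
leaves room.

## The problem

Dietary pattern analysis usually summarises a food-frequency questionnaire
into a handful of latent factors or an a-priori adherence score. Both lose
the *pairwise structure* of eating — which foods are consumed together —
and neither is conditioned on disease status, so patterns extracted in one
population need not be the risk-relevant ones. In dietarily homogeneous
populations (the motivating setting is Korean cohorts where rice and
vegetable side dishes dominate every diet) overall intake variation is
small and these limitations bite hard. The co-consumption network (CCN)
approach keeps the food-to-food structure explicit, and the *differential*
CCN isolates the structure that distinguishes participants who develop
type 2 diabetes from those who do not.

## Stage 1: stability-selected partial Spearman networks

Edges are partial Spearman correlations between cumulative-average
servings/day of food pairs, adjusted for total energy intake and sex.
Spearman rather than Pearson because intakes are zero-inflated and heavily
right-skewed; partial because energy and sex confound essentially every
food-food relationship. `partial_spearman()` ranks all variables (average
ranks on ties — the standard convention, important because zero-inflated
foods have huge tie blocks at zero), residualizes the ranked pair on the
ranked covariates plus an intercept by least squares, and correlates the
residuals. The p-value uses the t reference with `n - 2 - k` degrees of
freedom.

`stability_edges()` draws `n_iter = 100` half-samples (`subsample_frac =
0.5`, without replacement) and retains an edge only when the correlation
is significant at `alpha = 0.05` in *every* iteration and the mean signed
correlation exceeds `r_threshold = 0.2` in magnitude. The conjunction of a
magnitude threshold with an all-iterations significance rule is what makes
the network sparse and stable: a single unlucky half-sample vetoes an
edge. Defaults mirror the reference analysis; `threshold_sensitivity()`
re-runs the grid (|r| > 0.15/0.25/0.30; 50/75/100 iterations) and reports
Jaccard overlap with the default edge set.

Three implementation choices deserve note:

* **Dataset-level subsampling.** Each iteration draws one subsample shared
  by all food pairs, then computes the full partial-correlation matrix in
  one rank + QR + correlation pass. This is the procedure's natural
  reading (the *dataset* is subsampled), is algebraically identical per
  pair to running the pairwise routine on the same rows (a test asserts
  this), and is roughly three orders of magnitude faster than per-pair
  regression loops.
* **"Exceeds 0.2" is read as |mean signed r| > 0.2.** Sign consistency
  across iterations is *not* additionally required — it is not part of the
  stated rule — but the number of positive-sign iterations is kept on
  every edge as a diagnostic (`n_positive`).
* **Subsampling without replacement** is the default; `replace = TRUE`
  gives a conventional bootstrap for users who prefer it. Degenerate foods
  (constant within a subsample) stay in the node set as isolates, with a
  warning.

## Stage 2: differential subnetworks

`differential()` splits the union of two group networks into A-exclusive,
B-exclusive and shared edges, with edge identity the unordered food pair
(weights are deliberately ignored for membership: an edge present in both
networks with different strengths is still *shared* structure). Exclusive
edges induce the differential subnetworks, carrying their source network's
weights. Invariants — antisymmetry under swapping inputs, edge-count
conservation, disjointness of the exclusive sets — are enforced by tests.

Ego networks (`ego_network()`, default 2 steps) use *unweighted* hop
distance: the visualization they serve shows direct neighbors expanded one
step, and hop-based membership keeps the subgraph interpretable. Graph
summaries use average degree 2E/N, density 2E/(N(N−1)) and global
transitivity (3 × triangles / connected triples); a single-node graph
reports density and clustering 0 with a degenerate flag.

## Stage 3: integrated centrality and roles

Five centralities are computed per differential subnetwork: degree,
strength, betweenness, closeness, eigenvector. The networks carry signed
weights (staple foods generate negative, substitution-type edges), and no
standard centrality is defined for signed graphs, so all strength and
distance computations use |w| — "interaction strength" semantics — while
the sign stays on the edges for display and interpretation. Shortest-path
distance is 1/|w| (stronger co-consumption = closer), the standard
weighted-graph convention. Betweenness is normalized by (N−1)(N−2)/2;
closeness is per-component (reachable nodes)/(Σ distances), 0 for
isolates; eigenvector centrality is the leading eigenvector of the |w|
adjacency of the largest component, by power iteration with a spectral
shift (`A + cI`, same eigenvectors, which makes the iteration converge on
bipartite graphs like stars), scaled to maximum 1, other components 0.

Published closeness values in the reference tables exceed 1, which no
common normalization reproduces; the convention here is documented and
the printed closeness columns are treated as non-checkable.

Each centrality column is z-standardized *across the subnetwork's nodes*
(a flagged alternative would standardize across all 45 foods, but the
subnetwork is the scoring universe, and the reference top-5 tables are
per-subnetwork). Zero-variance columns get z = 0 rather than being
dropped, so the integrated centrality is always the mean of exactly five
components. Rank ties break lexicographically by food name, making ranks
deterministic. `classify_roles()` applies the hierarchical role rules
(primary hub → hub → bridge → connector → peripheral) and reproduces all
ten published role labels from the published centrality columns — a test
and the acceptance script both assert this.

## Stage 4: adaptive binarization and the D_CCN score

Consumption status, not amount, is what co-consumption is about, so
intakes are binarized. A single quantile rule cannot work when some foods
are eaten by everyone (Q1 > 0) and others by almost no one (Q3 = 0), hence
the hierarchy: Q1 if positive, else median, else Q3, else any positive
amount. Quartiles use linear interpolation (R type 7); nothing in the
method fixes the estimator, so it is configurable in principle but the
choice is documented and constant everywhere in the package. **Values
exactly at the cut-point are coded 0** ("above the cut-point" is strict);
this matters because staple foods have heavy ties exactly at the median.

The score is linear: Diabetes Score = Σ b_f·w_D(f) over the diabetic
subnetwork's foods, similarly for the non-diabetic score, and
D_CCN = difference. Negative integrated centralities are used as-is —
truncating at zero would discard the information that a food is
structurally peripheral. Cut-points are computed on the cohort's combined
scoring population (not per outcome group): scoring must be possible
prospectively, before outcomes exist. For cross-cohort transfer
(`transfer_scores()`) cut-points are *recomputed in the target cohort*
while weights stay those of the source cohort; the alternative (importing
source cut-points) is a one-line change but re-deriving cut-points from
the target's own intake distribution is the choice here because cut-points
are population descriptors, not model parameters.

## Stage 5: modified Poisson association

Incidence rate ratios come from a Poisson GLM on the binary incident
indicator with offset log(person-years) — the "modified Poisson"
formulation — with HC0 sandwich variance replacing the model-based one
(the Poisson variance is wrong for binary outcomes; the sandwich is
consistent regardless). HC0 rather than HC1: intended cohort sizes are in
the tens of thousands, where the small-sample correction is irrelevant;
HC1 is available. CIs are Wald with the 1.96 normal quantile. Quartiles
use right-closed linear-interpolation cuts, Q1 as reference; the trend
test refits the model with each quartile scored by its median D_CCN value
as one continuous term and reports its robust Wald p. Smoking enters as
two indicators (former, current; never = reference). Alcohol is treated as
a unit-agnostic continuous covariate — the source material mixes g/day and
ml/day and the model is invariant to the scaling.

## The synthetic cohort generator

Real KoGES data are access-restricted, so the generator *is* the study
system, and its defaults are the package's fixed evaluation conditions:

* **45 foods, 2000 participants per outcome group** — the planted-recovery
  scenario used by the validation suite.
* **Gaussian copula with latent-threshold zero-inflation.** Food f is zero
  when its latent normal coordinate falls below `qnorm(zero_inflation[f])`,
  else mapped through a log-normal quantile. Thresholding the *shared*
  latent variable (rather than independent Bernoulli zeroing) means zeros
  carry correlation information, as real non-consumption does. Default
  zero-inflation ramps from 0.02 (a rice-like staple, low variance,
  meanlog log 2.8) to 0.8 (rarely eaten foods).
* **Shared backbone + planted differential stars.** Both groups share
  three 5-food blocks at latent ρ = 0.5 (30 edges of common dietary
  structure). Each group additionally gets a hub-and-spoke star (1 hub, 5
  spokes) at latent ρ = 0.4 on foods the other group leaves uncorrelated —
  the ground-truth differential edges, shaped like the hub-centered
  structures the method targets. Spoke-spoke marginal correlation is
  ρ² = 0.16, safely below the 0.2 retention threshold, so the stars do not
  generate spurious planted-adjacent edges. All matrices are
  eigenvalue-checked for positive semidefiniteness.
* **Outcome model.** The planted adherence score is the D_CCN score
  computed with the *truth* subnetworks' integrated centralities. Events
  follow an exponential waiting time with rate
  `baseline_rate × exp(log(1.5) × z)` (z = standardized planted score),
  censored at gamma-distributed follow-up (mean 5.8, SD 3.9 years);
  person-years run to diagnosis or censoring. Defaults
  (`baseline_rate = 0.01`/person-year) give a cumulative incidence near
  6%, matching the motivating cohort's 9.9 events per 1000 person-years.
  Because recorded person-time is time at risk, the Poisson/offset model
  is exactly well-specified and recovers the planted rate ratio without
  attenuation. A `linear` event model (p = rate × time) is available and
  errors when a probability would exceed 1.
* **Seeding.** One master seed expands into fixed-offset child seeds per
  stage (intake, outcome, subsampling), so stages are independently
  reproducible and two runs with one config are bit-identical.

What the generator does *not* emulate: FFQ measurement error, visit-level
intake drift, realistic Korean-diet marginals, food-group aggregation
artifacts, and — importantly — marginal intake differences between outcome
groups. The two groups differ only in correlation structure, so a passing
differential-recovery test demonstrates structure detection, not the
cohort-level score→outcome association, which is validated separately
through the planted outcome model. Real-data behavior, where both marginal
and structural differences coexist, is expected to be at least as
favorable for the score but cannot be demonstrated from synthetic data
alone.

## Evaluation design and problem sizes

The validation suite runs, at fixed seeds: oracle equivalence of the
partial correlation (explicit normal-equations residualization) and of
weighted betweenness (brute-force path counting) on 20-node graphs;
closed-form centralities on stars, paths and cycles; reproduction of the
ten published role labels; differential-edge recovery as the median over
20 replicates of the default scenario (sensitivity and false-exclusive
count); incidence-effect recovery on one cohort of 20,000 with planted
IRR 1.5/SD plus a quartile trend test; and robust-CI coverage of the null
over 500 cohorts of 2,000. These sizes give tight enough Monte Carlo error
for the stated bands (e.g. binomial SE of a 95% coverage estimate at 500
replicates is ≈1%) while keeping the whole suite in a few minutes.

## Exclusions and cumulative averages

`apply_exclusions()` removes prevalent disease (anti-diabetic medication
or fasting glucose ≥ 126 mg/dL), baseline energy at or beyond the
0.5th/99.5th percentile, and missing key covariates — in that order, one
recorded reason per participant, so logs are deterministic. The energy
band actually applied is attached to the returned cohort and reused when
the function is re-applied to its own output, making exclusion idempotent
(re-estimating percentiles on already-trimmed data would otherwise trim a
fresh tail on every application). Energy trimming runs after the
prevalent-disease rule in reason priority but both are evaluated on the
input cohort; the percentile band is computed on all baseline energies of
the input.

`cumulative_average()` averages dietary assessments strictly before the
diagnosis visit (`multi_visit`, for cohorts with repeated FFQs) or applies
the two-assessment rule (`baseline_plus_one`: baseline only if diagnosis
precedes the follow-up assessment, else the mean of both). Both designs
error loudly when a participant has no eligible visit.

## Known limitations

* Centrality on signed graphs is an open problem; |w| is a convention, not
  a theorem. Score signs are preserved, but a strongly negative edge and a
  strongly positive one contribute identically to structural importance.
* The all-iterations significance rule makes edge retention sensitive to
  group size: smaller groups (fewer cases) have systematically sparser
  networks, so differential edges partly reflect power differences. The
  reference analysis has the same property; interpret exclusive edges as
  "reliably detected only in this group", not "absent in the other".
* With event status drawn stochastically from the score at realistic
  incidence, incident-stratified networks in a *single* simulated cohort
  are nearly identical (the generator's groups differ structurally, not
  the random event strata); end-to-end evaluation therefore stratifies by
  the generative group. This is an evaluation-design statement, not a
  claim about real cohorts.
* Module detection (hypergeometric or community-based) is out of scope;
  homogeneous-diet networks form one large component where it adds little.
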