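---
title: "Methods: higher-order diagnosis features, disease networks and phenotype cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: higher-order diagnosis features, disease networks and phenotype cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in
`phenonet`, the assumptions behind them, the tunable parameters with their
defaults, the design of the synthetic-claims generator, and the numerical
choices and limitations a user should know about. It states no empirical
result beyond what the package's test suite and `scripts/acceptance.R`
themselves compute.

## Study design and data model

The unit of observation is a hospital stay: patient pseudonym, entry and
exit dates, one primary and any number of secondary 3-character ICD
diagnoses, region, sex, birth year, and an in-hospital death flag. The
analysis window is split by `study_periods()` into a *no-admission*
period, a *feature* period, a *target* period and a *follow-up* period
(defaults: 6 + 3 + 3 + 6 years from 1997-01-01). Patients enter the study
population iff they have no stay in the no-admission period and at least
one stay in each of the feature and target periods. These criteria select
patients without recent serious illness who are alive at least to the end
of the feature period.

A stay is attributed to the period containing its **exit date** (claims
records are keyed on discharge); `attribute = "entry"` switches the
convention. How a stay spanning a boundary at midnight is attributed is
not derivable from the data model — the exit-date rule is this package's
convention.

Diagnosis codes are role-suffixed (`E66p` primary, `E66s` secondary), so
both roles of one ICD code are distinct predictors. `build_matrices()`
produces the sparse feature-period indicator `X0` and the target matrix
`Y`. **Monotonicity assumption:** a condition once diagnosed is treated as
present ever after, so `Y` accumulates every code from the start of the
feature period through the end of the target period; consequently each
patient's `X0` support is a subset of their `Y` support. Without this
assumption the target data are far too sparse for a generative classifier
at realistic code frequencies; the cost is that "prediction" of a
prevalent diagnosis is partly bookkeeping, which is why trivial
self-associations are flagged downstream.

## Higher-order diagnosis features

**Candidate mining.** `mine_candidates()` enumerates, level by level, all
code sets of size 1 to `model_order` with co-occurrence support at least
`support_min` (default 30 patients — below that the coefficient estimates
fluctuate too much to be useful). Sets of two or more codes must
additionally pass the *minimum information difference to prior*:

minIDP(F) = min over d in F of 10·log10( P(d | F without d all present) / P(d) ) db,

with add-one/add-two (Laplace) smoothing of both estimates. The
probability estimates being smoothed keeps rare but perfectly
co-occurring sets finite in both directions. The minimum over members
means *every* diagnosis in the set must be more likely given the others
than a priori — a single independent tag-along pulls the measure to zero
and the set is rejected. Singletons bypass the filter: their conditional
equals their marginal, the measure is identically zero, and any positive
threshold would otherwise delete them all. Support is anti-monotone and
drives the level-wise extension; minIDP is not anti-monotone, so it
filters candidates only at output.

**Ordering.** Candidates are sorted by cardinality (descending), then
minIDP (descending), then support (descending), then lexicographically by
code string. The lexicographic tie-break is this package's addition for
determinism.

**Greedy assignment.** `assign_features()` walks the ordered set once.
A feature is assigned to a patient iff all its codes are present and none
has been covered by an earlier assigned feature; its codes are then marked
covered. Each diagnosis of a patient is therefore represented at most
once, by the highest-ranked feature that reaches it — the mapping from
patient-diagnoses to patient-features. Codes whose every candidate feature was
pruned stay uncovered and drop out of the representation, mirroring the
support-floor semantics.

**Pruning.** After assignment some features' *assigned* support may fall
below `support_min` (higher-ranked features capture their patients).
`prune_to_final()` removes only the **first** weakly supported feature in
the ordering and reassigns, because removing one feature remaps its
patients and can re-support features further down; removing all weak
features at once would discard some that deserve to stay. Termination is
guaranteed (each round removes exactly one feature) and the result is a
fixed point of the procedure (re-running it changes nothing).

## The multi-target naive Bayes model

For each target diagnosis `t`, patients split into classes `Y(,t) = 1`
and `Y(,t) = 0`, and `mnb_fit()` estimates class-conditional feature
probabilities with additive smoothing `alpha`:

θ_cf = (N_cf + α) / (N_c + α·N_F).

Under the default **multinomial** event model `N_c` is the total number of
feature occurrences in class `c`, so θ is a proper distribution over
features (Σ_f θ_cf = 1; the test suite asserts this). Under the
**Bernoulli** variant (`event_model = "bernoulli"`) the denominator is the
class patient count plus 2α — a per-feature presence probability. The two
estimators give identical coefficients when class sizes are balanced and
differ mildly otherwise; both are exposed because the per-feature
(Bernoulli) reading matches the coefficient's definition as
`Pr(X=1 | Y=1) / Pr(X=1 | Y=0)` most literally, while the multinomial
form is the classical MNB estimator. The coefficient and prior are

C(f, t) = 10·log10(θ_1f / θ_0f) db,  π(t) = 10·log10(n_1 / n_0) db,

weights of evidence on Jeffreys' deciban scale (5 db ≈ 3:1 odds
"substantial", 10 db = 10:1 "strong", 15 db ≈ 30:1 "very strong", 20 db =
100:1 "decisive"; `db_to_odds()`). The linear decision function
`Δ(p, t) = Σ_{f assigned to p} C(f, t) + π(t)` classifies `t` present iff
`Δ > 0`, strictly — a patient with no features receives the majority
class. Targets without both a positive and a negative patient are dropped
with a warning.

**Scoring.** Per-target precision, recall and F1 use the convention that a
ratio with zero denominator is 0. A target's *support* is its number of
true positives, and the total score is the support-weighted mean F1 —
prevalent diagnoses dominate deliberately. `select_targets()` fixes the
scored target list to those with at least `min_per_fold` (default 200)
positives in every fold, ranked by total positives and capped (default
1000), so hyperparameter comparisons are not biased by a changing target
roster.

**Cross-validation and tuning.** `cross_validate()` re-mines, re-prunes
and refits within each of `k = 5` seeded unstratified folds and scores on
the held-out patients (training scores are reported alongside: naive
Bayes is not prone to overfitting, and comparable train/test scores are a
useful sanity check). `tune_hyperparameters()` searches `alpha` (log
scale, default bounds 10^-3 to 10) and `minidp_min` (0-5 db) by grid — the
reference strategy — or by a small Gaussian-process expected-improvement
loop; both are deterministic given the seed. `support_min` is held fixed
rather than tuned.

## Interaction lift

The ordered feature set decomposes any higher-order feature `f`: walking
down the ordering from `f` and collecting every feature whose codes fit in
the not-yet-covered remainder yields a partition `G` of `f`'s codes
(`build_partition()`; the ordering guarantees disjointness). The expected
coefficient under additivity is `C̄(f, t) = Σ_{g∈G} C^(|g|)(g, t)`, each
term from the model **of that constituent's own order** — hence
`fit_order_models()` fits the family of models of orders 1..m. The lift

L(f, t) = C(f, t) − C̄(f, t)

is exactly additive by construction, positive for synergy and negative for
redundancy. Singletons have no decomposition; their lift is 0 by
convention and they are excluded from rankings. A feature whose partition
cannot be completed (a constituent code has no surviving feature) has
undefined lift, reported as missing rather than imputed. `rank_lifts()`
mirrors the headline table machinery: keep non-trivial combinations
(target not among the feature's own codes) with joint occurrence in at
least 50 patients and a coefficient of at least 8 db, group by feature,
report the median lift over qualifying targets, sort descending. No
significance testing is attached to lifts; the ranking is exploratory.

A conditional-boost generator (below) necessarily leaks some of a planted
triple-wise effect into the pairwise and singleton models — patients
carrying two of three codes sometimes carry the third — so the recovered
lift of a planted odds boost `B` is slightly below `10·log10(B)`; at the
fixture's code rate of 0.12 the population value is about 0.4-0.6 db below
the nominal 3.01 db for `B = 2`. The acceptance band (±1 db) accommodates
exactly this.

## The generalized disease network

Two features are similar when they predict similar targets. From the
all-data model's coefficient matrix, `coefficient_similarity()` computes
the Gaussian approximation to the mutual information of the rows,
`Φ = −½·ln(1 − ρ²)` (Pearson correlation ρ; natural log — only the
relative ordering of edges matters downstream and it is base-invariant).
Constant rows get ρ = 0; ρ² is clipped at 1 − 10⁻¹² so identical rows stay
finite. `discretize_weights()` bins the off-diagonal entries into 30
equal-width integer weights; exact zeros stay zero so absent similarity
adds no null-model mass (the source recipe leaves the treatment of zeros
open).

The null model is the **weighted configuration model**: the
maximum-entropy ensemble of weighted networks with the observed node
strengths `s_i = Σ_j w_ij` fixed. `fit_wcm()` solves
`Σ_{j≠i} y_i y_j / (1 − y_i y_j) = s_i` by Levenberg-Marquardt least
squares on the strength residuals. Numerical choices: the parameters are
fitted on the logit scale (the boundary y = 1 is a singular attractor of
the raw parametrization), initialized with seeded random numbers in
[0, 1); because the strength equations can be degenerate — an isolated
dyad constrains only the product y_i·y_j — a ridge-continuation schedule
(0.3 → 0 on the logit parameters) selects the minimum-norm, i.e.
symmetric, solution before a final pure polish; convergence requires every
strength residual below 10⁻⁶, with up to five random restarts. On a
two-node graph of weight w the fitted value is the closed form
`y* = sqrt(w/(1+w))`, which the tests verify.

An edge enters the backbone iff its null probability
`γ_ij = (y*_i·y*_j)^{w_ij}` is **strictly** below 0.05. This local filter
is the multiple-testing adjustment; no additional FDR layer is applied.
Note its character: a uniformly dense block is fully explained by its
strengths (a two-node weight-30 dyad has γ ≈ 0.37 and is never
significant), so the backbone retains edges that are heavy *relative to
their endpoints' overall connectivity* — transitively explainable
structure is removed.

`cluster_network()` applies seeded Louvain modularity (resolution 1,
weights Φ — the recipe does not fix whether Φ or the binned weights are
used; Φ is the default here) to the backbone. The **giant component** is
the network as presented (`disease_network$graph`); the cluster membership
of *all* connected backbone nodes is retained in `disease_network$nodes`
and is what `index_disease_view()` and cohort construction use. At desk
scale the backbone of a few dozen features is frequently disconnected —
two planted phenotype blocks have no significant between-block edge — and
restricting phenotype detection to the giant component would arbitrarily
discard whichever block it excludes; clustering happens on the backbone,
the giant-component restriction is presentational.

## Phenotype cohorts and matched comparison

For an index code (default example `E66`), the two clusters with the most
index-containing features define the candidate phenotypes. A patient joins
a cluster's cohort iff positive in at least one of that cluster's
index-containing features; controls carry the index code in no role during
the feature period. Patients qualifying for both clusters are excluded and
counted (`both_rule = "larger_feature_count"` instead assigns them to the
cohort whose index features they carry more of); the exclusion rule keeps
the labels provably exclusive, which the source material asserts but does
not operationalise.

`match_cohorts()` anchors on the smaller cohort and draws, per anchor and
without replacement, 3 patients from the larger cohort and 10 controls
with identical sex and region and birth years within ±2 — giving the
1 : 3 : 10 group-size pattern. Anchors with insufficient pools are
excluded and counted. `compare_cohorts()` then reports, per diagnosis
block (an inclusive range of bare ICD codes, both roles) and sex:
prevalence (any block code in the feature period), incidence (first-ever
block code in the target period — monotonicity makes "first-ever in the
target period" and "new disease" coincide), follow-up in-hospital
mortality, hospitalization days (a same-day stay counts one day) and
diagnosis counts. Differences are effect sizes
`ES_{i,j} = 10·(log10 n_j − log10 n_i)` db on relative frequencies
(antisymmetric, scale-invariant, undefined at zero frequency → missing),
with two-sided G-tests (`G = 2·Σ O·ln(O/E)`, df = 1, no continuity
correction, zero cells contribute zero), starred at p < 10⁻², 10⁻⁴, 10⁻⁶
and banded at 5/10/15/20 db.

## The synthetic-claims generator

`simulate_claims()` draws, per patient: a latent phenotype (mixing weights
may sum to less than 1; the rest are background-only patients),
demographics, independent Bernoulli feature-period codes (background rate,
overridden by phenotype core probabilities), and target-period codes
(background / phenotype target probabilities) whose odds are multiplied by
a planted `synergy_spec()` boost exactly when the patient carries the full
feature-code set — with three feature codes this is a strictly
beyond-pairwise dependency, and boost 1 is the null. Everything is
deterministic given the seed. Each patient gets one feature-period and one
target-period stay (never a no-admission stay, so simulated populations
pass selection by construction) plus a terminal follow-up stay for
patients who die. Within a stay the first drawn code becomes the primary
diagnosis (`role_rule = "first_primary"`), or all codes are recorded as
secondary with an administrative filler code (`Z00`) as primary
(`role_rule = "all_secondary"`). A stay always has a primary diagnosis, so
code-free periods also emit the filler.

The generator emulates: sparse binary diagnosis structure, monotone
accumulation across the timeline, latent phenotypes sharing an index code,
and controllable pairwise/triple-wise dependence (independent Bernoulli
given phenotype + noisy-OR-style odds boosts — chosen precisely because
the planted structure is analytically computable). It does **not**
emulate: realistic lengths of stay or seasonality, coding errors,
department transfers, age- or sex-specific disease rates, or the heavy
tail of real code-frequency distributions. Passing tests therefore show
the estimators recover *planted* structure at realistic sparsity; they do
not certify behaviour on real claims.

**Fixture design.** Two canned configurations freeze the study conditions
of the test and acceptance suites:

* `two_phenotype_fixture()` — n = 20,000; a metabolic phenotype (weight
  0.30; cores E66 0.85, E11 0.55, E78 0.35; cardiometabolic targets) and a
  musculoskeletal phenotype (weight 0.05; cores E66 0.85, M54 0.55,
  M17 0.35; musculoskeletal targets plus *milder* cardiometabolic target
  rates — obesity raises cardiometabolic risk in both phenotypes, and the
  shared target profile is also what ties the two feature groups together
  in the similarity network). Twelve background codes at 3%. Roles are
  all-secondary so each planted comorbidity maps to a single role-suffixed
  code: random primary/secondary splitting spawns parallel role-variant
  features that fragment a desk-scale clustering, which at the real-data
  scale is washed out by a thousand-target coefficient row. Core rates are
  deliberately graded (0.85/0.55/0.35): heterogeneous strengths are what
  lets within-block edges survive a configuration-model filter, and three
  cores per phenotype keep each block a single cohesive Louvain cluster.
  The 6:1 phenotype ratio leaves enough larger-cohort patients for 1:3
  matching within sex × region × ±2-year strata.

* `synergy_fixture()` — n = 20,000; 60 disjoint planted triples at code
  rate 0.12 and one boosted target each at background 0.30. The rate
  trades off leakage of the conditional boost into the pairwise models
  (grows with the rate) against the number of triple carriers
  (n·0.12³ ≈ 35 per triple); averaging the recovered lift over 60 triples
  brings the standard error of the mean to roughly 0.2 db. The lift
  benchmark evaluates the estimator on a *designed* feature set (the
  triples, one pair per triple, and singletons via `feature_set()`) —
  mining correctness is established separately against a brute-force
  enumerator, and full order-3 mining over 180 deliberately independent
  codes would only re-test the miner.

## Problem sizes, defaults and limitations

The test and acceptance suites run at n = 20,000 patients, model orders
1-3, a few dozen codes, and networks of under a hundred features; the
implementation is sparse-matrix based and handles these sizes in seconds
to a couple of minutes per stage. Defaults: `support_min = 30`,
`alpha = 1`, `minidp_min` 0-5 db (tunable), 5 folds, 200 positives per
fold, 1000-target cap, 30 bins, γ < 0.05, Louvain resolution 1, matching
3 + 10 with ±2 years.

Known limitations: the pipeline detects positive associations only
(frequent itemsets cannot represent protective combinations); the
monotonicity assumption blurs prediction and bookkeeping for prevalent
codes; cross-validated F1 under monotonicity is a model-comparison signal,
not a clinical prediction metric; lift carries no significance test;
backbone + Louvain results on very small networks are sensitive to the
discretization and should be read qualitatively; and the matched
comparison is a crude prevalence/incidence/mortality contrast — no
survival modelling, and no multiple-testing adjustment beyond the
backbone's own filter and the starred G-test thresholds.
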