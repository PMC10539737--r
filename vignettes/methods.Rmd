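---
title: "Dynamic Bayesian networks for longitudinal categorical cohorts: models and methods"
author: "cohortdbn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic Bayesian networks for longitudinal categorical cohorts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`cohortdbn` infers a dynamic Bayesian network (DBN) over categorical
clinical factors measured repeatedly on a cohort. The DBN has two parts:

* an **initial network** — a Bayesian network over the factors at first
  presentation (t = 0), describing the conditional dependencies with which
  subjects enter care;
* a **transition network** — a two-slice graph whose edges run from the
  factors at a timepoint t into the factors at t + 1, describing how the
  state evolves. The transition model is assumed homogeneous: the same
  conditional law links every consecutive pair of timepoints, so all
  consecutive complete pairs, from any subject and any t, are stacked into
  one dataset.

Two regimes are supported for the t + 1 slice. In the primary regime the
factors at t + 1 are conditionally independent given the factors at t
(temporal edges only); every graph is then bipartite and automatically
acyclic, and the structure posterior factorises over the t + 1 children
(`exact_transition_posterior()` exploits this as an exact oracle). The
secondary regime additionally allows contemporaneous edges among the
t + 1 factors (`transition_config(allow_contemporaneous = TRUE)`). In both
regimes the t slice is exogenous: nothing points into a `@t` node, `@t`
nodes are mutually unconnected, and only `@t1` families are scored — the
joint of the t slice is the initial network's business, which keeps the two
networks' roles disjoint.

Factors are binary or three-level. Three-level factors are diagnosis
variables (none / subthreshold / full-threshold); continuous source
measures are binarised at the reader (a social/occupational functioning
scale at > 70 = "good", age at > 18 years), so the network code only ever
sees categorical data. Timepoint indices are treated as homogeneous steps;
calendar spacing is deliberately ignored after index assignment, which is
an assumption, not a fact about attendance patterns.

## Eligibility and missing data

Both datasets are strict complete-case constructions, mirroring
eligibility filtering rather than imputation: the initial dataset keeps
exactly the subjects with a complete t = 0 record; the transition dataset
keeps one row per (subject, t) whose records at t and t + 1 are both
complete. Pairs separated by a missed visit (t and t + 2) are never used —
only genuinely consecutive indices count. This matches a
missing-at-random working assumption; the synthetic-data module includes
an optional outcome-dependent missingness mode precisely so that this
assumption can be probed (see below).

## Scoring and the structure prior

Structures are scored with the Bayesian–Dirichlet equivalent uniform
(BDeu) marginal likelihood: for a child with r states and q parent
configurations, hyperparameters are α_j = ESS/q and α_jk = ESS/(q·r). BDeu
is decomposable (per-family caching and the factorized transition oracle
both rely on this) and score-equivalent — Markov-equivalent DAGs receive
identical scores, which the CPDAG summaries downstream presuppose. The
default ESS is 1 and is configurable; the score family itself is a package
choice, made because it is the standard score-equivalent likelihood for
categorical structure learning.

The structure prior is uniform over DAGs satisfying an edge constraint:
a user-editable blacklist ("prior knowledge removes unrealistic edges",
e.g. nothing may point into a demographic node — see
`inst/extdata/example_constraint.yaml`), an optional whitelist, and a
parent-set cap (`max_parents`, default 4). The cap bounds the per-node
score tables (about 36k parent sets per node at 31 candidates) and is a
tractability choice. Parent sets are encoded as bitmasks over at most 31
candidate parents per child; the subset tests are written to stay clear of
the 32-bit NA sentinel at the full-31-candidate boundary.

## Posterior sampling: partition MCMC

The sampler runs a Metropolis–Hastings chain over ordered partitions of
the node set. Each DAG is compatible with exactly one ordered partition
(its parentless nodes, then iteratively the nodes whose parents all lie in
earlier parts with at least one in the immediately preceding part), and a
partition's score — the sum of posterior weight over its compatible DAGs —
factorises over nodes as a log-sum-exp over admissible parent sets. The
chain therefore samples partitions proportional to their total posterior
weight, and one DAG is drawn from the partition's conditional distribution
per recorded iteration (a draw, not a maximisation, so edge probabilities
are unbiased).

The move set is: single-node relocation (to another part or a new
singleton part at any position), a two-node swap, and a reversal of a
contiguous run of parts, mixed 0.75/0.10/0.15. All three are symmetric, so
the acceptance ratio is simply the partition-score ratio. The segment
reversal matters: relocation and swap alone mix poorly *between the
orientations of one Markov equivalence class* — for a chain-like class the
partitions of the differently-rooted orientations are separated by deep
posterior valleys, and without the reversal move the raw directional edge
probabilities on a 4-node chain were visibly biased even though the
partition scores themselves were verified exact against brute-force
enumeration. With the reversal move the empirical partition occupancy
matches the enumerated posterior.

Defaults are 2 chains of 20,000 iterations, 25% burn-in, thinning 20, with
chain c seeded at `seed + c - 1`. These are deliberately smaller than what
one would run on a large clinical dataset with an unknown answer: the
problems in this package's scope (≤ ~32 nodes, factorised or
near-factorised posteriors) mix quickly, and the sampler is continuously
cross-checked against two exact oracles — exhaustive enumeration up to 5
nodes, and the factorized transition posterior at any size — with
agreement required within 0.03 in maximum absolute edge probability.
Reproducibility is part of the contract: identical inputs and seed give an
identical sample, and a seed is required, not optional.

## CPDAG summaries

For reporting, every sampled DAG is converted to its completed partially
directed acyclic graph: skeleton plus v-structures, closed under the Meek
orientation-propagation rules (all four), with compelled edges directed
and reversible edges undirected. For two-slice samples the temporal
blacklist acts as background knowledge: cross-slice edges are compelled by
construction and stay directed. The converter was validated against a
brute-force oracle (enumerate all same-skeleton, same-v-structure acyclic
orientations, with and without background orientations) on random graphs.

Directional edge probabilities count an undirected edge at **full weight
in both directions** — a reversible edge genuinely supports either
orientation — so the two directional probabilities of a pair may sum to
more than 1. This is a documented convention choice (the alternative,
half-weighting, would make "probability 1 in both directions" impossible
and blur the distinction between "certainly present, direction unknown"
and "uncertain"). The MAP summary graph is the modal **CPDAG** (not modal
DAG) among converted draws, with a deterministic lexicographic tie-break
that warns when invoked; exports keep edges above a probability threshold
(default 0.1), drawn solid when in the MAP and dashed otherwise, with a
transparency attribute proportional to probability and nodes keyed by
clinical domain group.

## Interventional relative risks

The effect of factor A on factor B is quantified as the relative risk
under intervention,

RR = P(B = true | do(A = true)) / P(B = true | do(A = false)),

computed per sampled structure and summarised over the posterior by its
mean µ and 95% highest-density credible interval. Choices behind this:

* **Interventional, not observational.** The do-operator with truncated
  factorization (remove the intervened node's CPT, clamp, marginalise the
  rest exactly over the target's ancestors) follows the
  effect-from-structure-posterior lineage for clinical DAG averaging. An
  observational conditioning mode exists behind a flag
  (`mode = "observational"`) for sensitivity analysis.
* **Binary collapse first.** All factors are collapsed to binary before
  CPT fitting for effects: three-level diagnoses assign true to the sub-
  and full-threshold levels and false otherwise.
* **Parameter uncertainty is propagated by default.** Each retained
  posterior draw gets CPTs *sampled* from their Dirichlet posterior
  (`cpt_draws = "sample"`), not plugged in at the posterior mean. With a
  concentrated structure posterior a plug-in interval collapses to a
  point and could never cover a generator's true RR; sampling the CPTs
  gives intervals whose replicate coverage of planted effects is ≥ 80% in
  the validation suite while independent pairs exclude 1 in ≤ 10% of
  replicates. The plug-in is available as `cpt_draws = "mean"` and is the
  right choice when only structure uncertainty is of interest.
* **Two-slice covariate handling.** The transition model deliberately does
  not model the joint of the t slice, so for A@t → B@t1 the non-intervened
  time-t ancestors of B are integrated over their *empirical* joint in the
  transition dataset (g-computation), not over a product of marginals —
  time-t covariates are typically correlated and the product form would be
  biased. For initial-network (single-slice) effects the fitted BN itself
  supplies the joint and pure truncated factorization is used.
* **No ad-hoc zero protection.** Dirichlet smoothing makes every CPT cell
  strictly positive, so denominators are positive and every RR finite.
* **Indirect effects are total effects.** When the direct A→B edge is
  absent, the truncated factorization automatically yields the effect
  flowing through mediators; no path-decomposition is attempted. A pair
  with no directed path from A to B has RR exactly 1.

The HDI is the narrowest contiguous window of the sorted per-draw values
containing ⌈0.95·n⌉ points — deterministic given the draws, no kernel
smoothing. Effect matrices flag each cell `reportable` iff its interval
excludes 1, and the conventional export renders only reportable cells;
same-factor (x@t → x@t1) cells are computed like any other pair.

## The synthetic cohort generator

No public cohort accompanies this class of analysis, so validation runs
end-to-end on synthetic cohorts drawn from a known ground-truth DBN.
`make_default_truth()` builds 16 factors across the five clinical domains
(function, suicidality, substance use, physical health, syndromes), mostly
binary plus two three-level diagnoses. Baseline prevalences are drawn once
from the seed, uniformly in [0.05, 0.5] (the functioning factor is kept
near 0.5 so both levels are well represented). The transition network
plants a strong same-factor persistence edge for every factor
(risk-multiplier 5–9) — persistence of clinical state over consecutive
visits is the single most robust feature of longitudinal service data and
the generator treats it as such — plus a documented set of cross-domain
effects (function → ideation and self-harm, protective; ideation →
attempt and self-harm; depression → ideation; cannabis → manic-like
experiences; alcohol → cannabis), each with a contrast of at least 1.5.
CPTs use a clamped risk-multiplier parameterisation so the implied
relative risks are available analytically by brute-force joint summation
(`analytic_transition_rr()`), which is what coverage tests compare
against.

Simulation is ancestral: t = 0 from the initial network, each later slice
from the transition network given the previous one. Missingness is
whole-record (a missed visit), missing-completely-at-random at a
configurable rate, with truncation after a geometric dropout draw;
subjects can reappear after a gap, and an optional outcome-dependent
missingness mode (`informative_missingness`) deletes visits preferentially
when a chosen factor is active, to probe the complete-case assumption.
The default scale (2,663 subjects, 4 timepoints, 20% missed visits, 15%
per-step dropout) loosely mirrors a large youth mental-health cohort;
tests and the validation script use smaller cohorts (200–2,000 subjects)
chosen so the whole suite completes in minutes while leaving the
qualitative conclusions unchanged, and the analysis scripts state the
sizes they use.

What passing these tests shows — and does not show. The generator
produces categorical, stationary, MCAR-missing data whose dependencies
really are a DBN. Success on it validates the machinery (scoring,
sampling, conversion, effect estimation), not the clinical assumptions:
real cohorts have informative attendance, calendar-irregular visits,
unmeasured confounding, and possibly non-stationary dynamics, none of
which the default generator emulates.

## Numerical choices

* Exact DAG counting uses the classical alternating recurrence with a
  minimal base-10⁴ big-integer arithmetic implemented privately (counts
  exceed 2⁵³ from 10 nodes; no arbitrary-precision dependency is
  available). Verified against enumeration for n ≤ 4 and the published
  value at n = 10.
* Exhaustive posterior enumeration is guarded to 5 nodes; acyclicity over
  the ~10⁶ candidate parent-set combinations is checked by a vectorised
  Kahn peel over bitmasks.
* Interventional marginals restrict exact summation to the target's
  ancestors in the mutilated graph — equal to full-joint enumeration to
  ~10⁻¹⁶ on ≤ 15-node test networks.
* Degenerate inputs: empty datasets score 0 (empty product) and fit to
  prior-mean CPTs with a warning; a factor observed at a single level
  after binary collapse triggers a warning and relies on smoothing;
  zero-eligible-row dataset constructions raise errors advising factor
  subset reduction.
* Ties for the modal CPDAG break to the lexicographically smallest
  serialisation, with a logged warning.
* The pipeline driver fans the top-level seed out to per-stage seeds via a
  fixed Lehmer step, so any stage can be re-run in isolation and two runs
  of the same configuration are byte-identical.

## Known limitations

Only first-order (t, t + 1) dynamics are modelled; subjects contributing
several transition rows are treated as exchangeable (no within-subject
random effects); the transition network excludes static covariates by
default (a config flag adds them as exogenous time-t nodes); selection
bias is not corrected; and the blacklist shipped as an example is
illustrative, not a clinical consensus. The effect estimates inherit every
caveat of causal reading of an estimated DAG: acyclicity within a slice,
no unmeasured confounding, and faithfulness.
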