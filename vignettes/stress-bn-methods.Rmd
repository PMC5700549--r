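---
title: "Modelling occupational stress with discrete Bayesian networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling occupational stress with discrete Bayesian networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressbn)
```

## The problem and the model

Healthcare professionals report high levels of occupational stress, and the
classical occupational-health frameworks — Job Demand-Control (JDC),
Demand-Control-Support (DCS), Effort-Reward Imbalance (ERI) and Job
Demands-Resources (JD-R) — predict how demands, autonomy, social support and
recognition combine to produce it. `stressbn` operationalizes these
constructs as ten categorical variables built from 6th European Working
Conditions Survey (EWCS) question codes and models them jointly with a
discrete Bayesian network: a directed acyclic graph $G$ over variables
$x_1,\dots,x_n$ together with one conditional probability table (CPT) per
node, under the factorization

$$p(x_1,\dots,x_n) \;=\; \prod_{i=1}^{n} p(x_i \mid \pi_i),$$

where $\pi_i$ denotes the parents of $x_i$ in $G$. The stress outcome is a
binary indicator of psychosomatic complaints: a respondent reporting at
least three of seven health problems (hearing, skin, backache, muscular
pain, headache, anxiety, overall fatigue) is classified as stressed. Fitting
follows the usual two-step scheme: *structural learning* (a score-based
search for $G$) followed by *parametric learning* (CPT estimation given
$G$). Once fitted, the network answers arbitrary posterior queries
$P(\text{stress} \mid \text{evidence})$ exactly, which is what the scenario
sensitivity tables tabulate.

## Variable construction

The recoding scheme maps raw question codes to the analysis categories:

* **Stress** — at least 3 of the 7 symptom flags (Q78). The flags form a
  scale whose internal consistency can be checked with `cronbach_alpha()`
  ($\alpha = k/(k-1)\,(1-\sum_i \sigma^2_i/\sigma^2_T)$, sample-variance
  convention).
* **Gender** (Q2a) and **age group** (Q2b): under 35, 35 to under 45, 45 to
  55, over 55. Age 45 falls in the third group and age 55 also in the third
  ("over 55" is strict).
* **Emotional demand** (Q30h) and **job demand** (Q49a/b): the 7-point
  frequency scale collapses as {1,2} / {3,4,5} / {6,7}; this grouping is
  inferred from the category labels of the published frequency table
  ("Around half of the time" labels the middle category), which pins the
  three-way split the text leaves implicit. Job demand takes the rounded
  mean of its two items first.
* **Family demand** (Q45d) and **colleague support** (Q61a): the 5-point
  scale collapses as {1,2} / {3} / {4,5}, matching the published state
  labels "Always & most of the time / Sometimes / Rarely & never". (The
  descriptive prose suggests an alternative "always or sometimes / rarely /
  never" split; the table labels and their counts are authoritative here
  because they are the quantities the package reproduces.)
* **Control** (Q54a/c): yes only when both answers are yes. The source
  material says only that the two items are "summarized"; logical AND is
  the default because control in the JDC sense requires autonomy over both
  the order and the pace of work, and `derive_control(rule = "any_yes")`
  provides the alternative.
* **Boss support** (Q61b + Q63a-f): rounded mean of the seven 5-point
  items, then {1,2} / {3} / {4,5}. The high internal consistency of the
  seven items justifies a single composite.
* **Recognition** (Q89c): direct {1,2} / {3} / {4,5} collapse.

Composite means round half away from zero (so 2.5 rounds to 3);
`rounding = "half_even"` switches to banker's rounding. Published
percentages reproduce only under half-away-from-zero rounding of the
displayed digits, which is why `frequency_table()` uses it too.

"No reply" is an explicit `NR` state: frequency tables report it (computed
over all records, one decimal), while modelling drops NR records
(`complete_cases_only()`), mirroring the usual complete-case convention for
these surveys.

## Structure and parameter learning

`hill_climb()` performs greedy local search over add/delete/reverse
single-edge moves under acyclicity and optional edge constraints, with
seeded random restarts. Scores are decomposable:

* **BIC** (default): maximized multinomial log-likelihood minus
  $\tfrac{\ln N}{2}$ times the number of free parameters. Used with
  maximum-likelihood CPTs (pseudocount 0).
* **BDeu** with equivalent sample size `ess` as an alternative.

Both are score-equivalent across Markov-equivalent DAGs, so a single edge
may come out in either orientation; the tests score against an exhaustive
enumeration of all 25 three-node DAGs to confirm the search finds global
optima at that scale. Candidate moves are enumerated in a fixed
lexicographic order and ties take the first move, making every run
reproducible given its seed. The `stress-sink` constraint preset forbids
edges out of stress, reflecting its role as the analysis target; it is off
by default.

For networks used in inference, CPTs are fitted with pseudocount 1
(`fit_parameters(..., pseudocount = 1)`): with zero cells a single
contradictory evidence item would annihilate a posterior, and smoothing
keeps every evidence configuration strictly positive. Score computation
stays at pseudocount 0 (standard BIC). With pseudocount 0, parent
configurations never observed fall back to a uniform child distribution,
explicitly, rather than NaN.

## Inference

`variable_elimination()` computes exact posteriors. The elimination order
is the min-degree heuristic on the evolving interaction graph with an
alphabetical tie-break — fixed for reproducibility, though correctness
never depends on it. Evidence with zero probability raises a distinct
condition (`stressbn_zero_evidence_error`) instead of returning a uniform
or `NaN` posterior; a silent fallback would corrupt scenario tables
downstream. `enumerate_joint()` and `posterior_oracle()` provide the
brute-force enumeration oracle; the suite checks elimination against it on
hundreds of random networks to $10^{-10}$.

## Scenario sensitivity tables

A `scenario_spec()` names a target state, a grid of evidence variables
with their states (outermost varies slowest, matching the nested layout of
published sensitivity tables), and optional fixed evidence (a gender or an
age group). `sensitivity_table()` evaluates
$100 \cdot P(\text{stress}=\text{Yes} \mid \text{row evidence})$ per row,
carrying unrounded percentages; two-decimal rounding is presentation-only
(`format_scenario_table()`). `delta_report()` differences two rows on the
unrounded values — the convention that explains why published deltas can
differ from the difference of their rounded endpoints by up to 0.01 points.
Zero-mass rows are flagged, never dropped, so the table shape is always the
product of the grid sizes. Presets `table4` … `table8_favourable` rebuild
the published analyses' row structures (demands; demand-control-colleague
or boss support; demand-control-recognition; the latter split by gender or
age under fixed adverse/favourable demand-control conditions).

## Cross-validated ROC/AUC

`cross_validate()` partitions records into $k$ plain random folds (sizes
differing by at most one, seeded; stratification is deliberately not the
default since the emulated design used plain $N/10$ subsets). Per fold the
network is relearned on the training folds — structure once per fold, then
parameters; a fixed-DAG mode covers the alternative protocol, since which
of the two the original analysis used is not stated. Each held-out record
is scored with all its non-target variables as evidence, and predictions
are pooled so each record is scored exactly once. `auc()` computes the
trapezoid area under the pooled threshold-sweep ROC **and** the
pair-ranking (Mann-Whitney) statistic with ties counted one half, and
asserts their identity to $10^{-12}$; the suite also cross-checks against
the independent `pROC` implementation.

## The synthetic generator

The restricted EWCS microdata cannot ship with the package, so
`generator_config()` + `build_ground_truth()` define a fully known
stand-in calibrated to the published frequency table of the 2,211-record
healthcare subset:

* The nine explanatory variables are independent root nodes whose
  marginals are the published per-state counts renormalized over the
  non-NR states. Independence keeps the calibration exact and every
  posterior computable by a simple oracle; a correlated mode was
  considered and deliberately left out of the default because it buys
  realism at the cost of a closed-form calibration.
* Stress is the common child of all nine, with
  $P(\text{Yes}\mid\text{parents}) =
  \mathrm{logit}^{-1}(\beta_0 + \sum_v w_v[\text{level}_v])$. The per-level
  weights (log-odds scale, `default_stress_weights()`) increase with
  adversity — higher demands, no control, lower support and recognition,
  female, mid-career age — and rank recognition and boss support above
  colleague support, so the qualitative orderings reported for these
  variables hold in the ground truth by construction. Their magnitudes
  (0.25–1.05) were chosen once as plausible survey-scale effects giving a
  realistic stress gradient across scenarios; `weight_scale` multiplies
  them for simulation studies.
* $\beta_0$ is calibrated by `calibrate_intercept()`: bisection until the
  exact implied marginal $P(\text{stress}=\text{Yes})$ — enumerated over
  all $3^5 \cdot 2^2 \cdot 4 = 11{,}664$ root configurations — is within
  $10^{-6}$ of the published prevalence $814/2211 = 36.8\%$. The marginal
  is strictly increasing in $\beta_0$, so bisection always converges.
* "No reply" is injected independently per cell (MCAR) at the published NR
  rates, matching the complete-case modelling path; informative
  missingness is out of scope.
* `raw_from_recoded()` inverse-maps recoded states to representative raw
  question codes so the recoding front end can be exercised end-to-end;
  recoding the result reproduces the generator's table exactly.

What passing tests on this generator do **not** show: real survey data has
correlated explanatory variables, non-logistic interactions and
informative non-response, so recovery and AUC results here certify the
machinery, not field performance. In particular the published AUC of 0.85
and the published sensitivity-table cells are not reproduction targets —
they require the restricted microdata.

## Problem sizes and numerical choices

The test suite samples $n = 200{,}000$ records to check generator
calibration (binomial standard error $\approx 0.1$ percentage points, an
order below the $\pm 0.5$-point acceptance band), $n = 100{,}000$ for
parameter recovery, and $n = 20{,}000 \times 20$ seeds for structure
recovery. CPT normalization is enforced to $10^{-12}$, posterior
normalization to $10^{-10}$, hill-climbing move acceptance uses a
$10^{-9}$ improvement threshold, and bisection runs to $10^{-6}$ on the
implied marginal.

## Known limitations

* **A saturated 9-parent CPT is not estimable at these sample sizes.** The
  ground-truth stress CPT has 11,664 parent configurations. At
  $n = 100{,}000$ the mean count per configuration is $\approx 8.6$ and
  about a third of configurations are never observed, so per-cell
  maximum-likelihood recovery to $\pm 0.02$ is impossible — unseen
  configurations fall back to uniform and observed ones carry binomial
  noise an order of magnitude above that band. The corresponding
  acceptance-style check is retained (and fails) rather than weakened;
  root-node CPTs recover to $\le 0.003$, and on a bounded-fan-in ten-node
  network every cell recovers well within 0.02 at the same $n$.
* **BIC cannot select all nine stress parents at $n = 20{,}000$.** Adding
  the ninth parent multiplies the stress family's free parameters from
  2,916 to 11,664, a penalty increase of
  $\tfrac{\ln 20000}{2} \cdot 8748 \approx 43{,}300$ nats, while the
  likelihood gain available from *all* parents combined is bounded by
  $n \cdot H(\text{stress}) \le 20000 \ln 2 \approx 13{,}900$ nats. The
  search therefore consistently (and correctly, in the BIC sense) selects
  the five strongest parents — emotional demand, job demand, control, boss
  support, recognition. Full-parent-set recovery would need either far
  larger samples or a score without a full-table penalty (e.g. one
  exploiting the additive-logistic form of the mechanism), which is beyond
  the scope of a faithful CPT-based learner.
* Exact inference only; fine at ten nodes, not meant for large graphs.
* No survey design weights, no country structure, no latent variables.
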