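# stressbn

Discrete Bayesian networks for occupational stress in working-conditions
surveys.

Healthcare professionals are among the occupational groups with the
highest stress levels, and the classical frameworks — Job Demand-Control,
Demand-Control-Support, Effort-Reward Imbalance, Job Demands-Resources —
explain that stress through demands, autonomy, social support and
recognition. `stressbn` is for occupational-health researchers who want to
model those constructs **jointly** rather than one regression at a time: it
builds the ten study variables from raw 6th European Working Conditions
Survey (EWCS) question codes, learns a discrete Bayesian network over them,
and interrogates the fitted network with exact posterior queries.

The core object is a network over categorical variables
`x_1, ..., x_n` with one conditional probability table (CPT) per node,
factorizing the joint as

```
p(x_1, ..., x_n) = prod_i p(x_i | parents(x_i))
```

Stress is a binary outcome ("Yes" when a respondent reports at least three
of seven psychosomatic complaints). The package provides:

* **Survey recoding** (`recode_dataset()`, `derive_*()`, `cronbach_alpha()`,
  `frequency_table()`): question codes to analysis categories, "No reply"
  accounting, published-convention frequency tables.
* **Learning** (`hill_climb()`, `fit_parameters()`, `bic_score()`):
  score-based structure search (BIC default, BDeu option) and smoothed CPT
  estimation, with edge constraints such as the `stress-sink` preset.
* **Exact inference** (`variable_elimination()`, `predict_proba()`, plus an
  enumeration oracle): posteriors of stress under arbitrary evidence.
* **Scenario analysis** (`scenario_spec()`, `sensitivity_table()`,
  `delta_report()`, presets `table4`–`table8_favourable`): grids of
  `P(stress = Yes | evidence)` mirroring published sensitivity tables.
* **Validation** (`cross_validate()`, `roc_points()`, `auc()`): pooled
  k-fold ROC/AUC of the network as a stress classifier.
* **A calibrated synthetic generator** (`generator_config()`,
  `build_ground_truth()`, `ancestral_sample()`): ten-variable survey
  emulator whose root marginals match the published frequency table of the
  2,211-record healthcare subset and whose stress prevalence is calibrated
  by bisection to the published 36.8% — so the whole pipeline is testable
  without the restricted microdata.

## Worked example

Simulate a survey at a comfortable sample size, learn a network, tabulate
a demand-control-recognition scenario, and validate:

```r
library(stressbn)

gt <- build_ground_truth(generator_config(n = 20000))
d  <- complete_cases_only(inject_missing(ancestral_sample(gt, 20000, seed = 7), seed = 8))
nrow(d)
#> [1] 15950

dag <- hill_climb(d, blacklist = stress_sink_blacklist(names(d)))
dag
#> DAG with 10 nodes and 4 edges
#>   job_demand -> stress
#>   emotional_demand -> stress
#>   control -> stress
#>   recognition -> stress

bn  <- fit_parameters(dag, d, pseudocount = 1, variables = study_variables())
tab <- sensitivity_table(bn, scenario_preset("table6"))
writeLines(format_scenario_table(tab)[1:7])
#> job_demand                    control  recognition                  Stressed%
#> All & almost all of the time  Yes      Strongly & tend to agree     32.33%
#> All & almost all of the time  Yes      Neither agree or disagree    46.06%
#> All & almost all of the time  Yes      Tend to & strongly disagree  56.50%
#> All & almost all of the time  No       Strongly & tend to agree     51.32%
#> All & almost all of the time  No       Neither agree or disagree    58.27%
#> All & almost all of the time  No       Tend to & strongly disagree  68.51%

delta_report(tab, 4, 6)   # effect of losing recognition, high demand / no control
#> [1] 17.2

res <- cross_validate(d, k = 10, seed = 1, blacklist = stress_sink_blacklist(names(d)))
auc(res$score, res$label)
#> [1] 0.633
```

Reading the table: among workers with the highest job demands and no
control over their work, the modelled probability of stress rises from
51.3% to 68.5% as recognition falls from "agree" to "disagree" — a
17.2-point swing computed on the unrounded posteriors. The AUC (0.633
here) measures how well the network, trained out-of-fold, ranks stressed
above unstressed respondents; on this synthetic generator it reflects the
built-in signal strength, not field performance. At the published sample
size (2,211) the BIC search keeps a sparser graph; see the methods
vignette (`vignettes/stress-bn-methods.Rmd`) for why, and for every
modelling choice and its rationale.

File-level pipeline commands (`run_simulate()`, `run_recode()`,
`run_fit()`, `run_scenario()`, `run_validate()`) chain the same steps over
CSV/JSON/DOT files with provenance sidecars; `inst/scripts/stressbn-cli.R`
wraps them for shell use.

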