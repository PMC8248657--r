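---
title: "Mining associations between non-motor factors and weight loss in premanifest HD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining associations between non-motor factors and weight loss in premanifest HD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Unintended weight loss is an integral feature of Huntington's disease (HD)
and can begin years before motor onset, in the premanifest stage. Because it
occurs despite adequate calorie intake and does not track motor activity,
its drivers are plausibly non-motor: cognitive, psychiatric and functional.
Registry cohorts record a baseline visit and a handful of annual follow-ups
per participant, with a dozen clinical scales per visit. The question this
package operationalizes is: *which combinations of non-motor factor
severities are strongly associated with severe weight loss in premanifest
gene carriers, compared with gene-negative family controls?*

Conventional single-factor statistics answer this poorly, because the
interesting structure is combinatorial — a particular conjunction of, say,
symbol-digit performance, apathy and age may be predictive where each factor
alone is not. The package therefore combines four ingredients:

1. **Longitudinal consolidation.** Each subject is reduced to one record
   carrying the percentage weight change between baseline and last
   follow-up, `delta_w = (w_f - w_b) / w_b * 100`.
2. **Expert categorization.** Raw scores are mapped to a small ordinal
   code per clinical scale (the knowledge base), and `delta_w` to the
   weight category `wtCat` in -3 (very severe loss) … +3 (very severe
   gain).
3. **Class association rules (CARs).** An Apriori search restricted to
   rules `X => wtCat = y`, scored with six interest/validation measures and
   pruned of redundant rules.
4. **Corroborating views.** A self-organizing map (SOM) of the categorized
   records, and mutual-information / chi-square dependence statistics.

The real registry data are access-restricted, so the package ships a seeded
synthetic cohort generator that emulates the data's structure and lets every
stage be tested end to end, including recovery of dependencies planted at a
known confidence.

## Consolidation and cleaning

`remove_missing()` drops any visit row with a missing weight or factor
value. `remove_outliers()` applies the Tukey boxplot rule per screened
factor: quartiles are computed once on the input table with linear
interpolation (`stats::quantile`, type 7) and rows outside
`[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` are dropped. The screened factors default to
the strongly skewed scales (total functional capacity, independence,
irritability, motor and depression scores), where a boxplot on a
mostly-normal cohort flags the severe tail — exactly the behaviour the
filter is meant to exercise. Fences are deliberately single-pass: removing
the flagged rows tightens the quartiles, so re-filtering the output could
drop a few additional boundary rows; the pipeline never re-filters.

`compute_weight_change()` then locates, per subject, the unique baseline
row and the follow-up with maximal visit sequence number. Subjects lacking
either are excluded and counted. Duplicate baselines or non-positive
baseline weights are hard errors naming the subject. Factor values attached
to the consolidated record come from the last follow-up by default
(contemporaneous with `w_f`); `factor_visit = "baseline"` is available
because the registry analysis this mirrors does not state which visit
supplied them.

## The categorization scheme

`default_scheme()` encodes the expert breakpoints for the 12 clinical
factors. Conventions worth knowing:

* All intervals are half-open `[lo, hi)` on the raw scale, so every value
  in a factor's declared range maps to exactly one code, and a value
  jittered anywhere inside a category's interval keeps its code (the
  property the synthetic generator relies on).
* `mmsetotal` and `sdmt1` are reverse-scored (lower raw score = more
  severe). The printed sdmt band gap at raw 26 is closed by extending the
  severe band to `[0, 27)`.
* The independence scale bands overlap at 95 in their printed form; 95 is
  assigned to the mild band (code 2), normal starts above 95.
* `wtCat` is symmetric in the magnitude of `delta_w`: 0 below 5%, ±1 for
  5–10%, ±2 for 10–20%, ±3 at or beyond 20%, sign from the direction of
  change. Loss codes follow the printed scheme (a 20% loss is "very
  severe", code -3); gain codes mirror them, which is the only construction
  consistent with a seven-level -3…+3 axis.
* Ages are accepted from 18 upward; the top age band (>= 70) is uncapped.

`categorize()` errors on any value outside its factor's declared range
rather than guessing, and refuses records with missing values — cleaning is
a prerequisite, not an option.

## Class association rules and their measures

With `N` categorized records, an antecedent itemset `X` (category-coded
factor values, distinct factors) and consequent item `Y = (wtCat = y)`:

* support count `sigma(X)` = number of records containing `X`;
* support `s(X => Y) = sigma(X u Y) / N`;
* confidence `c = sigma(X u Y) / sigma(X)`;
* lift `= s(X u Y) / (s(X) s(Y))`, 1 at independence;
* conviction `= (1 - s(Y)) / (1 - c)`, 1 at independence, infinite for a
  perfect rule (serialized as the token `"inf"` in reports);
* chi-square of the 2x2 table `{X, not X} x {Y, not Y}` with 1 df, no
  continuity correction, and its upper-tail p-value;
* strength = the odds ratio `(a d) / (b c)` of that table: 0 for perfectly
  negative association, 1 at independence, infinite for perfectly positive
  (0/0 is taken as 1). The odds ratio is the standard measure with exactly
  this 0/1/infinity behaviour, which is why it stands behind the name.

`mine_class_rules()` is a from-scratch level-wise Apriori specialized to
class rules: candidate antecedents are generated by prefix joins, pruned by
the anti-monotone *joint* support with the consequent (so the search is
exact for the rule-support threshold), and scored only then. Defaults follow
the study configuration: minimum confidence 0.9, total rule length 2–5
(the consequent counts toward length, so antecedents have 1–4 items).
Minimum rule support is not part of the study configuration; the default is
0.01 of records and is exposed as an argument. Output order is
deterministic: lift descending, then confidence descending, then
lexicographic antecedent.

`eliminate_redundant()` removes every rule for which a strictly more
general rule (same consequent, antecedent a proper subset) with at least
the same confidence exists; the operation is idempotent because dominance
is transitive. `antecedent_histogram()` gives the per-item frequency view
used to summarize large rule sets.

The miner's correctness oracle in the test suite is exhaustive enumeration
of every antecedent subset with textbook metric formulas — an independent
code path compared rule-for-rule and metric-for-metric at tolerance 1e-12
across 50 seeded datasets.

## The self-organizing map

`train_som()` implements online competitive learning on a rectangular grid
(default 4x4 = 16 nodes, indexed row-major from the bottom-left): per
sample, the best matching unit is the node with the nearest codebook vector
(Euclidean; ties to the lowest index), and nodes within the current radius
move toward the sample scaled by the learning rate times a Gaussian kernel
of grid distance. None of the map hyperparameters are part of the study
configuration, so the defaults are ordinary choices, all configurable:
learning rate 0.05 -> 0.01 and radius max(grid)/2 -> 1, both linearly
decayed; 500 epochs; codebooks initialized uniformly within each input
column's observed range; sample order reshuffled each epoch from one seeded
stream. Ordinal codes are fed in as numbers without standardization — their
numeric ordering is meaningful — with an optional min-max scaling flag.
The per-epoch mean sample-to-BMU distance (quantization error) is recorded;
on every fixture the final value must not exceed the first-epoch value, and
each update moves a codebook component strictly toward the sample, so
codebooks stay within the data's componentwise range.

`node_counts()`, `node_class_distribution()`, `component_heatmap()` and
`codes_profile()` are plot-ready summaries (counts per node, per-node
`wtCat` mixture, one codebook component across the grid, full codebook
table); rendering is left to the user.

## Dependence statistics

`conditional_entropy()` and `mutual_information()` are plug-in estimators
in bits: `H(Y|X) = sum_i p(x_i) H(Y | x_i)` and `I = H(Y) - H(Y|X)`, with
`0 log 0 = 0`. The log base is a reporting convention only (the source
analysis does not state one); base 2 is used throughout. For a factor
combination, `X` is the exact composite tuple variable, not a chain-rule
approximation, so `I(Y; {X1, X2}) >= I(Y; X1)` holds identically.
`chi_square_independence()` is Pearson's test without continuity
correction, dropping all-zero rows/columns with a warning;
`dependence_report()` assembles the per-factor table (MI, chi-square, df,
p-value) plus any requested combinations.

Plug-in MI is biased upward by roughly
`(|X| - 1)(|Y| - 1) / (2 N ln 2)` even under independence. For single
factors at the cohort sizes used here the bias is negligible; for
three-factor composites it is not (about 0.1–0.2 bits at a few thousand
records), so joint-information values must be read against that baseline —
the dependence analysis script prints it alongside. Bias-corrected or
permutation-calibrated estimators are out of scope by design.

## The synthetic cohort generator

`generate_cohort()` emulates the registry structure: per subject one
baseline plus `k` annual follow-ups, `k` uniform on 3–5 by default;
baseline weight Normal(75, 12) kg truncated at 35; follow-up weights apply
i.i.d. multiplicative annual drift with standard deviation 4% per year —
over 3–5 years this yields a weight-change spread wide enough to populate
all seven `wtCat` bands at plausible frequencies. Factor categories are
drawn per subject from configurable marginals and then jittered uniformly
inside the category's raw interval, so categorization inverts the draw
exactly. The default marginals are roughly unimodal severity profiles of a
largely premanifest cohort (mostly functionally intact, modest psychiatric
tails); the source figures are qualitative, so these defaults are
illustrative rather than calibrated — a caveat that applies to every
downstream demonstration. Missingness is completely at random over factor
cells only (never identifiers, visit structure or weight), matching a
pipeline that drops incomplete records; one seeded stream drives the whole
cohort, so identical configurations are byte-identical.

**Planted dependencies.** A `planted_rule()` forces a configurable fraction
of subjects into the antecedent categories, and — the important part —
*every* subject whose drawn categories match the antecedent (forced or by
chance) receives the consequent weight category with the rule's target
confidence; otherwise an alternative category is drawn from the background
weight-category distribution. Conditioning on the match event rather than
on stratum membership makes the mined confidence an unbiased binomial
estimate of the target: a stratum-only design would be diluted toward the
base rate by chance matchers. The planted weight change is established in
the first follow-up year and sustained, with the last follow-up satisfying
the weight-change equation exactly; because cleaning can drop any
individual visit row, a target placed only on the final visit would be
silently re-pointed to an unplanted weight for a substantial fraction of
subjects, attenuating the planted confidence. Sustained loss is also the
clinically sensible shape. Intermediate visits of *non-planted* subjects
keep the i.i.d. drift model.

`inject_outliers()` displaces a seeded fraction of factor cells to
`Q3 + magnitude * IQR` of their column (magnitude > 1.5 required, default
3), giving the boxplot filter something real to remove in tests and
demonstrations.

What the generator does **not** emulate: CAG repeat length, progressive
worsening of factor scores over visits, within-subject correlation between
factors beyond the planted rules, informative missingness, or measurement
error in weights. Passing tests therefore demonstrate the correctness of
the pipeline's computations and its ability to recover planted structure —
not that the default marginals or effect sizes match the restricted
registry data, whose published rule tables and statistics cannot be
reproduced without access.

## Problem sizes and numerical choices

The test suite exercises: miner-vs-enumeration equivalence on 50 seeded
datasets of 150–400 rows and 4–6 factors (tolerance 1e-12 on all six
measures); planted-rule recovery on 100 seeded cohorts of 2000 subjects
with a 12% stratum at confidence 0.95, requiring the mined confidence
inside the 99% binomial interval in at least 95% of replicates; SOM
organization on 16 well-separated clusters (320 samples, 60 epochs) with at
least 95% of same-cluster samples on the majority node or an adjacent one;
marginal fidelity at the premanifest cohort's size (8012 subjects, ±0.02);
and the analytic identities of the measures on constructed transaction
sets. The demonstration workflow under `analysis/` runs the full pipeline
at registry scale (8012 + 4427 subjects) with 3% cell missingness and two
planted dependencies, and trains the maps for 100 epochs.

Ties in the BMU search break to the lowest node index; rule-level 2x2
tables with a degenerate margin score chi-square 0; `0/0` odds ratios are
reported as 1 (independence) and `x/0` as infinity; conviction at
confidence 1 is infinity; all counts enter metric formulas as doubles
because products of four counts overflow 32-bit integers. Quantile
computation everywhere is R's default type 7 (linear interpolation).

## Known limitations

* The expert breakpoints are taken at face value, including the closed
  sdmt gap and the mirrored gain bands; the registry's own data dictionary
  could differ in unknowable ways.
* Boxplot outlier screening on skewed ordinal scales removes genuine
  severe-tail records; that is inherent to the method being mirrored, and
  it is why planted demonstrations avoid screened factors for their
  antecedents.
* Plug-in MI bias (above) makes joint-information comparisons indicative,
  not inferential.
* The SOM is a visualization aid: no topology-preservation metric beyond
  the cluster-adjacency property is computed, and hexagonal lattices,
  batch training and U-matrix clustering are out of scope.
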