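---
title: "Identifying clinical subgroups on hierarchical clustering trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying clinical subgroups on hierarchical clustering trees}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The method

Molecular profiles — metabolomics, proteomics, copy-number data — tend to
group patients in ways that track clinical outcomes such as sex, BMI,
diabetes status or survival. `sgtree` searches for such subgroups without
fitting any model of the data: it operates purely on a sample-by-sample
distance matrix and a table of clinical variables.

The procedure has four steps.

1. **Clustering.** The samples are clustered hierarchically
   (`build_tree()`, any `hclust` object is equally accepted). The default
   is Euclidean distance with Ward linkage, but every choice of metric and
   linkage is under the user's control, and externally computed merge
   tables or distance matrices can be supplied (`tree_from_merges()`,
   `read_merge_table()`), so distances produced by methods such as
   similarity network fusion plug straight in.

2. **Valid cluster pairs.** Every internal node of the dendrogram splits a
   parent cluster into a left and a right subcluster. Tests in tiny
   clusters are hopelessly underpowered, so only branch points where
   *both* subclusters reach a minimum size are tested
   (`enumerate_valid_pairs()`). The default threshold is 5% of the sample
   size. "At least 5%" is read inclusively (≥), and a fractional threshold
   is converted with a ceiling, so 5% of 356 samples is a minimum
   subcluster size of 18. Splits are numbered top-down by decreasing merge
   height: the full cohort is cluster 1, and the k-th split labels its
   children 2k and 2k + 1 — the top split is always "clusters 2 versus 3",
   the second "4 versus 5". The subcluster containing the leftmost leaf in
   dendrogram order is "left"; the orientation is arbitrary in principle
   and fixed here only so that results and plots are reproducible.

3. **Association testing.** At every valid pair, each clinical outcome is
   compared between the left and right subcluster with a test dispatched
   automatically from the outcome's type (`run_associations()`):
   Fisher's exact test for categorical outcomes, a two-sample t-test for
   continuous outcomes, and the log-rank test for survival outcomes
   declared as (time, event) column pairs. Custom test functions can be
   attached per outcome for more complex data types.

4. **Multiple-testing correction.** The dendrogram partitions the cohort
   into cascaded, non-overlapping groups, so the tests performed at
   different splits of the tree are mutually independent. Each raw p-value
   is therefore Bonferroni-adjusted by the number *m* of valid cluster
   pairs: `p_adj = min(1, p_raw * m)`. The factor is *m* alone — p-values
   are *not* additionally corrected across outcomes, so the family-wise
   error rate is controlled per outcome, across the tree. An
   `across_outcomes = TRUE` flag multiplies in the outcome count for users
   who want the stricter family. *m* is fixed by the tree and the size
   threshold before any testing; it is not reduced when individual tests
   are skipped for missing values.

## Choices in the statistical details

* **Welch, not pooled.** For continuous outcomes the Welch
  unequal-variance t-test is the default: the two subclusters of a split
  rarely have equal sizes or variances, and Welch is the safer default in
  that regime. `pooled = TRUE` restores the classical pooled-variance
  test.
* **Fisher's test beyond 2×2.** Contingency tables are levels × {left,
  right}. Levels unobserved after missing-value removal are dropped; a
  single remaining level makes the test undefined and the result is
  reported as `skipped`, never as an error. For tables too large for the
  exact network algorithm, a Monte-Carlo p-value with a fixed seed is
  used, and the seed is recorded in the result's `test` field.
* **Log-rank.** The standard two-group statistic
  (O − E)² / V accumulated over pooled event times, with the p-value from
  a 1-df chi-squared distribution. Runs with no events, or with one side
  empty after missing-value removal, are skipped with a reason.
* **Missing values** are removed per (pair, outcome) test; the per-side
  sample sizes after removal are reported in every result row.
* **Type inference.** Character, factor and logical columns are
  categorical; numeric columns with at most 5 distinct observed values are
  treated as categorical codes (diagnosis grades, 0/1 indicators), all
  other numeric columns as continuous. An explicit declaration always
  overrides inference, and survival outcomes are always declared, never
  inferred.
* **Degenerate continuous data.** When both sides of a split are constant
  the t statistic is undefined; such tests are skipped with the reason
  `"constant data"`. This covers both the equal-mean and the
  unequal-mean constant case, since a divide-by-zero statistic is
  meaningless either way.

## Multi-omics fusion

Several omics blocks measured on the same samples are combined at the
distance level. Each block's distance matrix is normalized by its maximum
and the normalized matrices are summed:

$$D = \frac{D_1}{\max(D_1)} + \frac{D_2}{\max(D_2)} + \cdots +
      \frac{D_l}{\max(D_l)}.$$

Every block then contributes on the same scale (its normalized maximum is
exactly 1), the result is invariant to positive rescaling of any block and
to block order, and no block weights are introduced. The maximum is taken
over off-diagonal entries; blocks are aligned by sample ID, and positional
alignment of unnamed matrices must be requested explicitly
(`allow_unnamed = TRUE`). The fused matrix feeds directly into
`build_tree()`.

## Visualization

`plot_tree()` draws the dendrogram with a white circle at every branch
point and a label at every significant (split × outcome) association —
by default those with adjusted p ≤ 0.05, mirroring the testing threshold.
`plot_overview()` stacks the annotated tree, one colour track per outcome
(continuous values on a value-ordered colormap, categorical levels as
colour bands, survival as observation-time shading with event marks, red
circles at the splits where the outcome is significant) and a z-scored
heatmap of the data matrix, all sharing the leaf order, so relationships
between outcomes — including potential confounding — can be read off one
figure instead of correcting for a predefined confounder list.
`plot_association()` shows a single association as side-by-side boxplots,
stacked proportion bars, or Kaplan–Meier curves (a presentation choice for
survival outcomes; the test itself is the log-rank statistic). The plot
objects carry their annotation tables as attributes, so figures are
testable without pixel comparisons.

## The planted-subgroup generator

`planted_design()` / `generate_planted()` create fully synthetic cohorts
with known structure, used throughout the test suite in place of any real
cohort:

* The data matrix is standard Gaussian noise (SD 1); each nested binary
  partition adds a mean shift `delta_x` (in SD units) to one child group
  on a designated feature subset. Group labels reuse the heap numbering
  (splitting group g yields 2g and 2g + 1).
* Continuous outcomes are standard normal plus a `delta_y` shift for the
  affected group; categorical outcomes are two-level draws with a planted
  log-odds shift from a balanced baseline; survival times are exponential
  with a planted log hazard ratio, censored independently and uniformly
  over a window calibrated so the expected censoring fraction matches the
  design (default 20%).
* A single integer seed fixes everything.

The defaults mirror a realistic discovery setting: 200 samples, 100
features of which 20 carry a 2-SD group separation, and a 1.5-SD outcome
shift. Under these conditions the pipeline flags the planted outcome at
the top split with adjusted p ≤ 0.05 in well over 90% of seeds, and under
a global null (no planted effects) the per-outcome family-wise error rate
stays within binomial noise of the nominal 5% — both checks run in the
test suite and in `scripts/acceptance.R`.

What the generator deliberately does **not** emulate: correlated feature
blocks, heteroscedastic or heavy-tailed noise, batch structure, or
missingness in the omics matrix. Passing tests on these fixtures show the
machinery is correct, not that any particular real cohort contains
subgroups.

## Problem sizes and numerical notes

The test suite and the acceptance script use cohorts of 60–356 samples,
100 random trees of up to 50 leaves for the brute-force valid-pair
comparison, exhaustive enumeration of all 2×2 contingency tables with
total ≤ 30 against a hypergeometric oracle, 200 null simulations (n =
100, 20 features) for the family-wise error check, and 100 seeds of the
planted design (n = 200) for the recovery check.

Height ties between splits are broken by splitting the later-created
cluster first (which keeps parents ahead of children at equal heights),
then by the lower minimum leaf position. Non-monotone linkages (centroid,
median) can invert heights; the tree is then still processed, with a
warning, but parent cluster IDs cannot be resolved below an inversion and
are reported as `NA`. Symmetry of fused matrices is enforced to machine
precision and their diagonal is exactly zero.

## Limitations

* The branch-point tests are two-group comparisons; gradual (non-nested)
  structure is invisible to them.
* The independence argument behind the Bonferroni factor applies across
  splits of one tree; it says nothing about correlation across outcomes,
  which is why the default correction is per outcome.
* No covariate adjustment is performed — the joint visualization is the
  intended instrument for judging confounding.
* Cluster robustness (bootstrap/consensus) is out of scope; the tree is
  taken as given.
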