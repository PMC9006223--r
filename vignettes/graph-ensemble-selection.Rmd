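---
title: "Graph-based ensemble feature selection: model, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based ensemble feature selection: model, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfsel)
```

## The problem and the model

Feature selection on fragment-count descriptor matrices is unstable: two
bootstrap resamples of the same molecules can yield quite different
"optimal" subsets.  Ensembles of selectors repair the instability, but the
standard combiner — count how often each feature was selected, then keep
everything above a vote threshold — discards the *joint* structure of the
rounds.  Two features that are individually selected often but never
together (typical of redundant near-duplicates, where each round keeps one
or the other) are indistinguishable, in a vote vector, from a
complementary pair that is always kept together.

`gfsel` therefore accumulates the rounds in an undirected co-selection
graph.  For $M$ features, vertex $i$ carries a value $v_i$ and the
unordered pair $(i,j)$ an edge value $e(i,j)$; when round $t$ selects the
set $S_t$ with round weight $\alpha_t$, every $v_i, i \in S_t$ and every
$e(i,j), \{i,j\} \subseteq S_t$ increases by $\alpha_t$.  Two consequences
worth keeping in mind:

* $\sum_i v_i = \sum_t \alpha_t |S_t|$ and $e(i,j) \le \min(v_i, v_j)$ —
  tested as invariants;
* the vertex values *are* the classic vote vector, so the voting baseline
  T operates on a strict projection of the same information, and any
  difference between T and the graph variants isolates the combination
  step.  For the same reason T and the graph variants share one ensemble
  per fit rather than re-running the rounds.

The working assumption is that features carrying complementary,
nonredundant signal are the ones frequently selected *together*; features
frequently selected but rarely co-selected are suspected redundant
alternatives.

### Boosting rounds

Rounds follow discrete AdaBoost adapted to selection.  Instance weights
start uniform; each round draws a weight-proportional bootstrap resample
(the base selector has no instance-weight interface, so resampling is the
standard surrogate), runs the base selector on the resample, trains the
evaluator on the selected features, and measures the weighted error
$\varepsilon_t$ on the full training set.  Then
$\alpha_t = \log\frac{1-\varepsilon_t}{\varepsilon_t}$, clipped to
$[0, 10]$ to avoid infinite weights at $\varepsilon_t \to 0$; degenerate
rounds ($\varepsilon_t = 0$ or $\ge 0.5$) clamp $\alpha_t$ to the
respective bound, reset the instance weights to uniform, and the loop
continues.  `weighting = "uniform"` sets every $\alpha_t = 1$, recovering
plain bagged voting.  The number of rounds defaults to `rounds = 10`:
enough for vote values to separate signal from noise features on
desk-scale data while keeping a full fit in the low seconds.

### The base selector: FAST

FAST scores each feature's class relevance by symmetric uncertainty
$SU(X,Y) = 2 I(X;Y) / (H(X)+H(Y))$, discards weak features, builds the
survivors' complete pairwise-SU graph, reduces it to a *maximum* spanning
tree, cuts tree edges whose SU is smaller than both endpoints' class
relevance, and keeps the most class-relevant feature of each remaining
component.  Duplicated features therefore collapse to one representative —
the property the redundancy experiments rely on.

All information quantities use plug-in (maximum-likelihood) entropies in
bits.  Integer-valued columns (fragment counts) are used as observed;
non-integer columns are equal-frequency binned into 5 bins first — binning
only matters for user-supplied continuous data.  The relevance threshold
defaults to the rank heuristic of the FAST authors (the SU of the
$\lceil \sqrt{M}\log_2 M\rceil$-th ranked feature, clamped to the last
rank).  The spanning tree is computed by Kruskal's algorithm written in
the package, with equal-weight edges processed in ascending $(i,j)$ order:
the deterministic tie rule is part of the algorithm's contract, which is
why no graph-library MST is used.  The tree logic is verified against an
exhaustive spanning-tree enumeration on 6-feature instances.

### Subset extraction and the J criterion

Given thresholds $(\tau^\varphi, \tau^\epsilon)$, the **threshold
strategy** keeps $\{i : v_i \ge \tau^\varphi\}$ and then sweeps every
surviving pair once, in ascending lexicographic order: if
$e(i,j) < \tau^\epsilon$ the member with the smaller vertex value is
removed ($\varphi_j$ on ties), and a removed feature takes part in no
further checks.  The sweep order and the single pass are genuine design
decisions — the removal outcome is order-dependent and a fixed-point
iteration would be equally defensible — so the package fixes one
deterministic reading (a single left-to-right sweep) and validates it
against a straight-line oracle of exactly that rule.  The **chain
strategy** starts at the highest-valued candidate vertex and repeatedly
follows the strongest edge with $e \ge \tau^\epsilon$ to an unselected
candidate.  Thresholds are inclusive ($\ge$) on both axes for symmetry;
chain ties break toward the smallest feature index; for MmTC the vertex
threshold acts as a filter on which vertices may enter the chain at all.

Candidate thresholds are 0 plus the distinct observed values on each axis,
replaced by `max_levels = 20` equally spaced levels when there are more —
a bound that keeps the search quadratic-at-worst without materially moving
the argmax on desk-scale graphs.  Each candidate pair's subset is scored by

$$J = w\,\kappa(\Phi') + (1-w)\,r(\Phi'), \qquad w = 0.5,$$

with $r = 1 - m/M$ and $\kappa$ estimated by stratified 5-fold
cross-validation of the evaluator restricted to $\Phi'$.  The equal
convex weighting is the package's own reading of "combine performance and
reduction"; $w$ is exposed (`j_weight`) because the right trade-off is
application-dependent.  Three estimation choices make the search fair and
reproducible: the folds are fixed by the seed and shared across *all*
candidate pairs and across the T baseline; fold confusion counts are
pooled before computing $\kappa$; and distinct threshold pairs inducing
the same subset are evaluated once (a pure cache — tested to change
nothing relative to naive enumeration).  Ties in $J$ go to the larger
reduction, then the smaller $\tau^\epsilon$, then the smaller
$\tau^\varphi$.

## The benchmark harness

`double_cv()` implements repeated double cross-validation: each external
round splits the samples (stratified, default 50/50 — the split proportion
is a free choice and is exposed) into disjoint build and validation
portions; the ensemble, the variant extraction, and the classifier's
hyperparameter tuning (stratified inner 10-fold CV, model selection by
G-Mean) all see only the build portion; all reported metrics come from the
untouched validation portion.  External rounds are independent seeded
re-splits rather than a partition.  Classifier grids: decision trees vary
pruning on/off × committee size {1, 10} (a pragmatic mapping of
C4.5-style "trials with threshold softening" onto rpart — an
approximation, not an equivalence); random forest is fixed at 100 fully
grown Gini trees on bootstrap samples; SVM evaluates the 21 combinations
of a linear kernel with $C \in \{0.1, 1, 10\}$ and a Gaussian kernel with
the same $C$ crossed with $\gamma \in \{10^{-4}, \dots, 10\}$.
Within the selection search itself the evaluator defaults to a plain
decision tree regardless of the externally tuned family — it is fast, and
using one fixed internal evaluator keeps the J landscape comparable
across variants.

Multi-dataset comparison uses average Friedman ranks (ties averaged, best
= rank 1), the Iman–Davenport $F$ correction, Holm's step-down procedure
on $z = (R_i - R_j)/\sqrt{k(k+1)/(6N)}$ with two-sided normal p-values
(the standard reading; the test direction is not otherwise specified), and
the Nemenyi critical difference with the $q_\alpha$ table for
$k = 2..10$, $\alpha \in \{0.05, 0.10\}$.

## The synthetic generator

`simulate_fragments()` emulates sparse small-integer fragment-occurrence
descriptors: class-conditional Bernoulli presence for the planted relevant
features (present with probability 0.8 in the positive class, 0.2 in the
negative — rates chosen to give individually informative but imperfect
features, and exposed in the spec), noisy duplicate copies of each
relevant feature (per-entry presence flips at `flip_noise`), independent
Bernoulli(0.3) background features, optional label noise, an exact
minority fraction, and an optional counts mode where each presence carries
$1 + \mathrm{Poisson}(1)$.

What it does *not* emulate: real fragment descriptors are correlated in
blocks by substructure chemistry, their marginal frequencies are heavily
skewed, and relevance is graded rather than planted.  Passing tests on
this generator therefore demonstrate that the machinery recovers planted
relevance and collapses planted redundancy under controlled noise and
imbalance — not that any variant wins on real chemistry.

The test and script problem sizes are the package's reference regime:
$n = 300$ samples, $M = 60$ features (6 relevant + 6 duplicates + 48
irrelevant), 10 boosting rounds, 10–20 seeds — large enough for SU
estimates and CV folds to be stable, small enough that the whole suite
runs in minutes.

## Numerical conventions and degenerate inputs

* Information measures: base-2 logarithms everywhere; $0 \log 0 = 0$.
* G-Mean ratios with an absent class, SU of two constants, correlations of
  zero-variance columns: defined as 0 rather than an error.
* Cohen's kappa returns 0 when chance agreement is 1.
* AcRed uses Pearson correlation by default ("a correlation coefficient"
  admits several; Spearman is available via `method`).
* The coefficient of variation uses the population standard deviation; the
  divisor choice is immaterial to every self-consistent use in the
  package.
* The single-class resample in a boosting round is redrawn (bounded
  retries), then signalled; an all-empty candidate space in the threshold
  search is an error, not a silent empty selection.
* Graph JSON serialization writes values as full-precision decimal strings
  so a reload is bit-exact; all file writes are atomic
  (temp-then-rename).
* Every random choice flows from one user-supplied integer seed; fits,
  benchmark runs and CLI outputs are byte-reproducible given the seed.

## Known limitations

* The pair-removal sweep is one fixed order among several defensible ones;
  a different order can select a different (equally valid under the rule)
  subset.
* $\kappa$ inside J is an internal-CV estimate on the build portion; with
  very small $n$ its variance can dominate the J landscape and the chosen
  thresholds become seed-sensitive (the external validation layer of
  `double_cv()` is the guard).
* Plug-in entropies are biased upward on sparse contingency tables; with
  tens of samples and many-valued count features, SU rankings can be
  noisy.  The binning default (5) bounds this for continuous inputs only.
* Only binary labels are supported, and only FAST ships as a base
  selector; others plug in via `register_base_selector()`.
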