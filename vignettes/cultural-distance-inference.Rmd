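---
title: "Distinguishing geographic diffusion from lineage-linked selection in cultural trait data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distinguishing geographic diffusion from lineage-linked selection in cultural trait data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(culturedrift)
```

## The inference problem

Cultural traits recorded as presence/absence across a set of neighbouring
groups carry the imprint of the processes that spread them. Under neutral
transmission — innovation, stochastic loss, and between-group interaction
whose intensity falls with distance — between-group similarity should decay
with geographic distance, the cultural analogue of isolation-by-distance in
population genetics. When, instead, the details of a trait system are
filtered through inherited biases that run down lineage (language) lines,
two signatures appear: the pattern of between-group distances tracks
linguistic affinity even after geography is controlled for, and — if the
bias suppresses variants — overall between-group diversity is depressed
relative to a comparable neutrally-transmitted system (purifying
selection; the opposite excess marks diversifying selection).

`culturedrift` implements this whole inference chain for the classic
setting of nine equestrian buffalo-hunting groups of the 19th-century High
Plains, and for any comparable dataset: binary trait tables in, Jaccard
distance matrices, model matrices encoding the competing hypotheses,
permutation Mantel and partial Mantel tests, and a diversity-contrast
selection battery.

## Distances from trait tables

Trait tables hold three codes per cell: present, absent, questionable.
Jaccard similarity between two groups is $S = a/(a+b+c)$ — shared
presences over traits present in at least one of the pair — and the
distance is $D = 1 - S$. Joint absences ($d$) never enter: an absence may
be an observation gap rather than a real difference, and the Jaccard
coefficient is insensitive to that bias. Questionable codes are handled by
one of two explicit policies:

* **pairwise deletion** (default, conservative): a trait questionable in
  either member of a pair is excluded from that pair's counts only;
* **recode as present**: the sensitivity variant; re-running the whole
  chain under it checks that conclusions do not hinge on a handful of
  uncertain cells.

Matrices carry an explicit polarity (`distance` or `similarity`). This is
deliberate: Mantel correlations flip sign with polarity, and the selection
test is defined on distances only, so the package refuses to guess —
conversions go through `convert_polarity()` and are visible in code.

All statistics operate on the off-diagonal vectorization (upper triangle,
row-major, $i<j$; `offdiag_vector()`), so the $n(n-1)/2$ pair values of two
matrices over the same label order are aligned pairs. Diagonals are stored
but never enter any statistic. Label order is always input order, never
alphabetical, so deposited matrix orderings survive round trips.

## Model matrices

* **Geography**: great-circle (haversine) distances between territory
  centroids on a sphere of radius 6371.0088 km (the IUGG mean radius).
  The earth model matters little here — Mantel r is unchanged by small
  monotone-linear distortions at continental scale — but the choice is
  explicit and testable against closed forms.
* **Border sharing**: binary distance, 0 when two territories share a
  boundary, 1 otherwise — proximity as contact opportunity rather than
  centroid spacing.
* **Language**: a tiered similarity in percent, from a classification of
  each group into family and (optionally) subgroup. The primary scheme
  codes 5% across families, 50% within a family across subgroups, 80%
  within a subgroup. Two variants probe robustness: one upgrades two
  especially close subgroup pairs (Arapaho–Gros Ventre, Assiniboine–Teton)
  to 95%, the other lowers the within-family tier to 30%. Groups without a
  named subgroup never match anyone's subgroup, including each other's —
  the scheme has exactly three tiers. Overrides are applied last.
* **Scalar controls**: `euclidean_scalar_matrix()` turns any per-group
  number (e.g. collection sample sizes) into $|v_i - v_j|$, to check that
  an apparent cultural pattern is not an artifact of unequal sampling.

## Permutation inference on matrices

Matrix cells are not independent observations — each group contributes to
$n-1$ pairs — so significance comes from permuting *groups*: random
simultaneous row-and-column permutations of the first matrix, recomputing
the off-diagonal Pearson correlation each time. Conventions, all pinned
and logged in results:

* p-values use the +1/+1 convention (the identity arrangement counts in
  numerator and denominator), so $p \in (0, 1]$ always;
* the default tail is two-sided on $|r|$, with one-sided options;
* the first matrix is the one permuted; $r$ itself is symmetric in the
  arguments;
* every sampled test takes an explicit seed and is bit-reproducible;
  unseeded calls draw a seed and report it.

The partial Mantel statistic is the first-order partial correlation
$r_{AB\cdot C} = (r_{AB} - r_{AC}r_{BC}) / \sqrt{(1-r_{AC}^2)(1-r_{BC}^2)}$,
with the null built by permuting $A$ while $B$ and $C$ stay fixed and the
partial statistic recomputed each draw. Permuting the tested matrix with
the statistic recomputed (rather than permuting residual matrices) keeps
the procedure exactly reproducible and matches the construction the
statistic is named for. Collinear controls ($|r| = 1$) are an error, not a
NaN.

For matrices of up to eight groups, `mantel_exact()` enumerates all $n!$
simultaneous permutations. It exists as the in-package oracle: the sampled
test is validated against it (in the test suite) to within three binomial
standard errors, which is also the precision statement a user should
attach to any Monte Carlo p reported by the package.

## The selection battery

`diversity_selection_test()` contrasts the paired off-diagonal distance
vectors of a focal and a reference system with three conservative
nonparametric tests:

1. **Wilcoxon signed ranks, Monte Carlo** (default 99,999 sign-flip
   randomizations): zero differences dropped, midranks on tied $|d|$,
   statistic $W$ = rank sum over positive differences, two-sided
   extremeness measured from the null mean $m(m+1)/4$.
2. **Exact sign test**: count of focal-greater pairs among non-tied pairs;
   p is the doubled smaller binomial tail, capped at 1.
3. **Mann–Whitney U, Monte Carlo** (default 10,000 reassignments):
   midrank-based $U = \min(U_x, U_y)$; folding the two tails through the
   minimum makes small $U$ extreme in either direction.

The verdict requires unanimity by default (all three significant at
$\alpha$, 0.05 by default) and takes its direction from the means (medians
are reported alongside): focal below reference is `purifying`, above is
`diversifying`, anything else `not_detected`. The rule can be relaxed to
majority/any, and every run carries the caveat that paired matrix entries
are non-independent — this battery is a screen to be read jointly with the
Mantel results, not standalone evidence of selection.

The test statistics ($W$, the sign count, $U$) are functions of the data
alone; only the Monte Carlo p-values vary across seeds, within binomial
error of their exact counterparts (`wilcoxon_signed_exact()` enumerates
all $2^m$ sign patterns for $m \le 20$ as the oracle).

## What the simulators emulate — and what they don't

Both generators model transmission as independent per-trait adoption at
equilibrium, the simplest process with the covariance structure the
inference chain assumes:

* `simulate_neutral_ibd()`: each trait originates in a uniformly chosen
  group and is adopted by every other group independently with probability
  $\exp(-d/\lambda)$. The exponential kernel is the canonical
  isolation-by-distance choice; $\lambda$ (`decay_length`, default 400 km,
  about the nearest-neighbour centroid spacing of the nine-group layout)
  sets the interaction range. Limits pin the behaviour: $\lambda \to
  \infty$ gives all distances 0, $\lambda \to 0$ gives all distances 1.
* `simulate_lineage_bias()`: a `core_fraction` (default 0.6) of traits is
  retained by everyone; each remaining trait is favoured by a random
  subset of language families, whose groups retain it with probability 1
  while others retain with `lineage_retention` (default 0.1). Because
  lineages are assigned to groups independently of position, the induced
  language matrix is uncorrelated with geography in expectation — the
  configuration in which a language association is evidence of lineage
  bias rather than geography by proxy.

Both apply independent per-cell noise flips last (default 2%) and are
exactly reproducible per seed. Defaults were chosen once as a realistic
operating point for nine groups and ~200 traits — strong but not
degenerate structure — and the replicate benchmarks (analysis script 05)
record what the chain achieves there: with these settings both recovery
rates are at or near 100 of 100 replicates, so passing them demonstrates
internal consistency at a comfortable operating point, not performance at
the detection boundary.

What the generators do *not* emulate: historical migration episodes,
time-resolved contagion, trait interdependence (traits are exchangeable
and independent given the process), observation bias, or any fitting of
simulator parameters to real matrices. Passing the synthetic benchmarks
therefore shows the pipeline detects the structures it assumes, under
those assumptions — it says nothing about effect sizes in real
ethnographic data, where traits are correlated and sampling is uneven.

## Numerical and design choices

* Permutation-tail comparisons use a tiny absolute tolerance (1e-12 scale)
  so ties produced by symmetric matrices count as "at least as extreme";
  this keeps sampled and enumerated p-values consistent.
* Degenerate inputs fail loudly: constant off-diagonals (undefined r),
  pairs with no scorable presences (undefined Jaccard), collinear partial
  controls, all-tied paired samples (warned, p = 1).
* The fixture layout ships *synthetic placeholder* centroids and border
  pairs (flagged in filenames and by attribute); the language
  classification is a reconstruction from the standard references. Runs
  on the fixture exercise the machinery and the qualitative pattern;
  reproducing published statistics requires the originally deposited
  coordinate and distance tables, which `make_plains_fixture()` accepts as
  drop-in CSVs.
* The full chain is exposed as one call, `run_full_analysis()`, which
  derives every sub-test seed deterministically from the master seed, so
  a config reproduces its report byte-for-byte.

## Problem sizes used in the shipped analyses

The analysis scripts and acceptance script use 9 groups, 200 traits,
10,000 Mantel permutations, 99,999/10,000 selection randomizations for
single runs, and 100 replicates with 499/999 randomizations for the rate
benchmarks — sizes at which every stage is exact enough for 3-decimal
stability while the whole suite runs in minutes on one core.

## Limitations

Mantel-type tests have known power limitations when the candidate model
matrices are themselves strongly correlated; the pipeline reports the
model-vs-model correlations (language vs geography) precisely so that the
interpretability condition — their independence — is checked rather than
assumed. The selection battery inherits the non-independence of matrix
entries; its p-values are calibrated under pair exchangeability, not under
the matrix-generating process, and should be read as screens. Neither
limitation is corrected for, by design; both are surfaced in the output.
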