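# culturedrift

Matrix-comparison inference for cultural transmission: given
presence/absence trait inventories for a set of neighbouring groups,
`culturedrift` asks whether between-group differences look like **neutral,
geographically-mediated diffusion** (isolation-by-distance) or carry the
signature of **lineage-linked cultural selection** — association with
linguistic affinity that survives controlling for geography, plus
significantly depressed (purifying) or inflated (diversifying)
between-group diversity relative to a neutral reference system.

It is written for quantitative anthropologists and cultural-evolution
researchers working with the classic Plains-style setting — a handful of
groups, tens of binary traits, territory centroids, border adjacencies,
and a family/subgroup language classification — but every stage is generic.

## What it computes

* **Jaccard distances** from group × trait tables with `1/0/?` cells:
  `S = a/(a+b+c)`, `D = 1 − S`; questionable codes handled by pairwise
  deletion (default) or recoded as present (sensitivity variant). Joint
  absences never enter.
* **Model matrices**: great-circle centroid distances (haversine,
  R = 6371.0088 km), binary border-share distance (0 = shared boundary),
  tiered language similarity (5/50/80% by default, with 95% and 30%
  variants), and scalar controls `|v_i − v_j|` (e.g. sample sizes).
* **Permutation Mantel and partial Mantel tests**: Pearson r of
  off-diagonal vectors; null from random simultaneous row+column
  permutations of the first matrix; partial statistic
  `r_AB·C = (r_AB − r_AC r_BC)/√((1−r_AC²)(1−r_BC²))`. Two-sided on |r| by
  default, +1/+1 p-value convention, exact n! enumeration (`mantel_exact`)
  for n ≤ 8.
* **Diversity-contrast selection test**: Monte Carlo Wilcoxon signed ranks
  (99,999 randomizations), exact sign test, Monte Carlo Mann–Whitney U
  (10,000 reassignments) on the paired distance vectors; unanimous
  significance plus the direction of the mean contrast yields
  `purifying` / `diversifying` / `not_detected`.
* **Seeded simulators** of both generating processes, so the entire chain
  is testable end to end without external data.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on the
nine-group High Plains layout with simulated trait systems — `decoration`
diffused neutrally by geography, `ceremony` generated with lineage-biased
retention (`Rscript analysis/01_build_model_matrices.R` … `05_recovery_benchmark.R`).
Script 03 prints the Mantel battery:

```
                                          comparison      r      p significant
                              ceremony vs decoration  0.379 0.0383        TRUE
                               ceremony vs geography  0.377 0.0476        TRUE
                        ceremony vs language_matrix1 -0.879 0.0005        TRUE
                             decoration vs geography  0.845 0.0001        TRUE
                      decoration vs language_matrix1 -0.142 0.3877       FALSE
                       language_matrix1 vs geography -0.213 0.2010       FALSE
  ceremony vs language_matrix1 controlling geography -0.882 0.0005        TRUE
decoration vs language_matrix1 controlling geography  0.073 0.6473       FALSE
```

(abridged; 20 comparisons in the full report). Read: the neutrally
diffused system tracks geography strongly (r = 0.845) and language not at
all; the lineage-biased system tracks language similarity (r = −0.879 —
negative because a *distance* matrix is correlated against a *similarity*
matrix) even when geography is partialled out, while language and
geography are themselves uncorrelated — exactly the configuration in which
a language association is evidence of lineage-linked bias rather than
geography by proxy. Script 04 then contrasts diversity:

```
wilcoxon_signed_mc: statistic = 0, p = 1e-05 (36 pairs, 99999 randomizations)
sign_exact: statistic = 0, p = 2.91e-11 (36 pairs)
mann_whitney_mc: statistic = 0, p = 1e-04 (72 pairs, 10000 randomizations)
focal:     mean = 0.1977, median = 0.2078
reference: mean = 0.8447, median = 0.8605
call: purifying
```

All three tests agree and the focal (ceremony) distances are far below the
neutral reference, so the run is called purifying selection — the
simulated lineage bias is recovered.

Equivalent single calls: `jaccard_matrix()`, `mantel()`,
`partial_mantel()`, `diversity_selection_test()`, or the one-shot
`run_full_analysis(analysis_config(...))`.

The shipped nine-group layout uses a reconstructed language classification
and *synthetic placeholder* centroids/borders (so labelled); to analyse
real data, point `make_plains_fixture()` — or `analysis_config()` directly
— at your own CSV tables (square labelled matrices, `group,lat,lon`
coordinates, border pair lists, classifications).

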