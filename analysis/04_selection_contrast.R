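#!/usr/bin/env Rscript
# Diversity-contrast selection test: compare the intergroup Jaccard
# distances of the lineage-biased system (focal) against the neutrally
# diffused system (reference) with the three-test battery (Monte Carlo
# Wilcoxon signed ranks with 99,999 randomizations, exact sign test,
# Monte Carlo Mann-Whitney U with 10,000 reassignments) and classify the
# direction of selection.

suppressPackageStartupMessages(library(culturedrift))
dir.create("results", showWarnings = FALSE)
seed <- 1234L

focal <- read_pairwise_matrix("results/ceremony_jaccard.csv")
reference <- read_pairwise_matrix("results/decoration_jaccard.csv")

verdict <- diversity_selection_test(focal, reference, alpha = 0.05,
                                    n_rand_wilcoxon = 99999,
                                    n_rand_mw = 10000, seed = seed)
print(verdict)

row <- data.frame(
  wilcoxon_W = verdict$tests$wilcoxon$statistic,
  wilcoxon_p = verdict$tests$wilcoxon$p_value,
  sign_statistic = verdict$tests$sign$statistic,
  sign_p = verdict$tests$sign$p_value,
  mann_whitney_U = verdict$tests$mann_whitney$statistic,
  mann_whitney_p = verdict$tests$mann_whitney$p_value,
  focal_mean = verdict$focal_mean, focal_median = verdict$focal_median,
  reference_mean = verdict$reference_mean,
  reference_median = verdict$reference_median,
  call = verdict$call)
write.csv(row, "results/selection_verdict.csv", row.names = FALSE)
cat("\nwrote results/selection_verdict.csv; call:", verdict$call, "\n")
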