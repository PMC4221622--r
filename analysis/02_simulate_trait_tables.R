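#!/usr/bin/env Rscript
# Simulate the two trait systems the inference chain is designed to tell
# apart, on the same nine-group layout:
#   - "decoration": neutral isolation-by-distance diffusion (traits spread
#     between groups with probability decaying in geographic distance)
#   - "ceremony": lineage-biased retention (a shared core plus variants
#     retained preferentially within language families, independent of
#     geography)
# Writes both trait tables and their Jaccard distance matrices to results/.

suppressPackageStartupMessages(library(culturedrift))
dir.create("results", showWarnings = FALSE)
seed <- 1234L

lay <- make_plains_fixture()
neutral <- simulate_neutral_ibd(lay, sim_params(n_traits = 200, seed = seed))
lineage <- simulate_lineage_bias(
  lay, sim_params(n_traits = 200, core_fraction = 0.6,
                  lineage_retention = 0.1, seed = seed + 1L))

write_trait_table(neutral, "results/decoration_traits.csv")
write_trait_table(lineage, "results/ceremony_traits.csv")

for (nm in c("decoration", "ceremony")) {
  tt <- if (nm == "decoration") neutral else lineage
  D <- jaccard_matrix(tt, polarity = "distance")
  write_pairwise_matrix(D, paste0("results/", nm, "_jaccard.csv"))
  v <- offdiag_vector(D)
  cat(nm, ": 200 traits, mean intergroup Jaccard distance ",
      round(mean(v), 3), " (median ", round(median(v), 3), ")\n", sep = "")
}
cat("the lineage-biased system should show markedly lower distances;\n")
cat("formal tests follow in 03/04\n")
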