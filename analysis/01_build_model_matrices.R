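#!/usr/bin/env Rscript
# Build the model (hypothesis) matrices for the nine-group High Plains
# layout: great-circle geographic distances between territory centroids,
# binary border sharing, and the three tiered language-similarity variants.
# Writes each as a square labelled CSV under results/.
#
# Coordinates and borders are the package's synthetic placeholder
# reconstruction; substitute authoritative tables via make_plains_fixture()
# arguments when reproducing published statistics.

suppressPackageStartupMessages(library(culturedrift))
dir.create("results", showWarnings = FALSE)

lay <- make_plains_fixture()
cat("layout:", length(lay$groups), "groups,",
    length(unique(lay$classification$family)), "language families\n")

write_pairwise_matrix(lay$distances, "results/geographic_distances_km.csv")
cat("geographic distances: ",
    round(min(offdiag_vector(lay$distances))), "-",
    round(max(offdiag_vector(lay$distances))), "km between centroids\n")

borders <- border_matrix(lay$groups, lay$borders)
write_pairwise_matrix(borders, "results/border_share.csv")
cat("border matrix:", sum(offdiag_vector(borders) == 0),
    "of", length(offdiag_vector(borders)), "pairs share a border\n")

schemes <- default_language_schemes(lay$classification)
for (nm in names(schemes)) {
  m <- language_matrix(lay$classification, schemes[[nm]])
  write_pairwise_matrix(m, paste0("results/language_", nm, ".csv"))
  cat("language ", nm, ": off-diagonal tiers {",
      paste(sort(unique(offdiag_vector(m))), collapse = ", "), "}\n",
      sep = "")
}
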