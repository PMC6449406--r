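#!/usr/bin/env Rscript
# Sequence-based group prediction on a planted-site benchmark.
#
# Generates a synthetic structure-guided alignment on the packaged PX
# scaffold annotation, with canonical-site and secondary-site residues
# planted per protein, and measures how well the determinant rules
# recover the groups at increasing mutation noise.

suppressPackageStartupMessages(library(pxbinding))
dir.create("results", showWarnings = FALSE)

ann <- px_reference_annotation()
cat("Scaffold annotation:", length(ann$element), "columns; anchors at",
    paste(sprintf("%s=%d", names(ann$anchors), ann$anchors),
          collapse = ", "), "\n")

clean <- generate_alignment_with_planted_sites(
  synthetic_config(seed = 101, n_proteins = 39))
pred <- predict_proteome(clean$alignment, ann)
acc <- mean(pred$predicted_group == clean$truth$group)
cat(sprintf("Zero-noise benchmark: %d/%d groups recovered (%.0f%%)\n",
            sum(pred$predicted_group == clean$truth$group), nrow(pred),
            100 * acc))
write.table(pred, "results/group_predictions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# Degradation with per-site corruption of the planted determinants.
rates <- c(0, 0.05, 0.1, 0.2, 0.3)
sweep <- data.frame(mutation_rate = rates, recovery = vapply(rates,
  function(mu) {
    g <- generate_alignment_with_planted_sites(
      synthetic_config(seed = 101, n_proteins = 100, mutation_rate = mu))
    p <- predict_proteome(g$alignment, ann)
    mean(p$predicted_group == g$truth$group)
  }, numeric(1)))
cat("Recovery vs determinant corruption:\n")
print(sweep)
write.table(sweep, "results/mutation_sweep.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
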