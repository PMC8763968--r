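#!/usr/bin/env Rscript
# Morphometry of WT-like vs KO-like cells: gap profiles, the three largest
# gap measurements per neuron, the distant-glia flag, Feret diameter, area
# and circularity; then the between-condition comparisons (chi-square on
# flags, KS on gap distances, t tests on diameter/area/circularity).
# 20 cells per condition, whole-cell fields at 20 nm/px.

library(temquant)
dir.create("results", showWarnings = FALSE)

r <- experiment_morpho_recovery(n_per_group = 20, seed = 1)

write_table_csv(r$morpho, "results/morphometry.csv")
write_table_csv(r$gap_recovery, "results/gap_recovery.csv")
write_table_csv(r$flag_fractions, "results/flag_fractions.csv")

cat("Per-condition distant-glia flag fractions (threshold grid):\n")
print(r$flag_fractions)

err <- abs(r$gap_recovery$recovered_um - r$gap_recovery$injected_um)
cat(sprintf("\nInjected gap depths: %d sectors, max |recovered - injected| = %.4f um (1 px = %.3f um)\n",
            nrow(r$gap_recovery), max(err), r$nm_per_px / 1000))

cmp <- morpho_comparisons(r$morpho)
write_table_csv(cmp, "results/morphometry_comparisons.csv")
cat("\nBetween-condition comparisons:\n")
print(cmp[, c("measure", "test_name", "statistic", "p_value", "effect_summary")])

cat("\nReading the table: the conditions separate on the gap measures by\n",
    "orders of magnitude (flag proportions, gap distances). Soma size and\n",
    "shape are drawn from the same distribution for both groups, so their\n",
    "panels reflect sampling noise only; at n = 20 cells per group a\n",
    "nominally significant size difference can and does occur by chance\n",
    "for some seeds, which is worth remembering when reading morphometry\n",
    "tables of this size.\n")
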