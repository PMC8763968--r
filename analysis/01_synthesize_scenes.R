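#!/usr/bin/env Rscript
# Generate example synthetic TEM scenes for both conditions and both
# magnifications, and save images plus ground truth under results/scenes/.
# WT-like cells keep the tens-of-nm neuron-SGC separation; KO-like cells
# carry 2-4 micron-scale gap sectors (whole-cell fields) and doubled
# vesicle density (high-mag fields).

library(temquant)

out <- "results/scenes"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (grp in c("wt", "ko")) {
  for (kind in c("morpho", "vesicle")) {
    p <- scene_params(preset = sprintf("%s_%s", grp, kind), seed = 2024)
    sc <- synthesize_scene(p)
    base <- file.path(out, sprintf("%s_%s_example", grp, kind))
    write_image(sc$image, paste0(base, ".png"))
    write_scene_truth(sc$truth, paste0(base, ".json"))
    cat(sprintf("%s %s: ", toupper(grp), kind))
    print(sc$truth)
  }
}

cat("\nScenes and truth written to", out, "\n")
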