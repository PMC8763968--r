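#!/usr/bin/env Rscript
# Train the two-stage vesicle detector on the default synthetic corpus:
# stage 1, a patch classifier (mini-batch 25, max 500 epochs, +/-10% resize
# + reflection augmentation); stage 2, a per-pixel segmentation network
# (mini-batch 100, max 1,000 epochs, +/-5% resize + reflection + pixel
# shift). 20% of each dataset is held out for validation.

library(temquant)
dir.create("results", showWarnings = FALSE)

t0 <- Sys.time()
bundle <- train_default_detector(seed = 1, verbose = TRUE)
cat(sprintf("\nTraining took %.1f min\n",
            as.numeric(difftime(Sys.time(), t0, units = "mins"))))
print(bundle)

write_model_bundle(bundle, "results/model_bundle.json")
curves <- rbind(cbind(stage = 1L, bundle$training_report$stage1$per_epoch),
                cbind(stage = 2L, bundle$training_report$stage2$per_epoch))
write_table_csv(curves, "results/training_curves.csv")

cat(sprintf("stage-1 validation accuracy: %.2f%%\n",
            100 * bundle$training_report$stage1$validation_accuracy))
cat(sprintf("stage-2 validation accuracy: %.2f%%\n",
            100 * bundle$training_report$stage2$validation_accuracy))
cat("Model written to results/model_bundle.json\n")
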