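#!/usr/bin/env Rscript
# The feature-set ablation: 500-tree, depth-10 random forests trained on
# each of the 11 feature sets under 10-fold cross-validation, with
# fold-averaged accuracy, precision, sensitivity, F1 and AUC.

library(gaitrisk)

seed <- 20260921
feats <- read.csv("scratch/features.csv", check.names = FALSE)

ev <- evaluate_feature_sets(feats, k = 10, seed = seed)
write.csv(ev$table, "results/cv_metrics.csv", row.names = FALSE)
print(ev$table[c("set_id", "name", "accuracy", "precision",
                 "sensitivity", "f1", "auc")], digits = 3)

best <- ev$table[which.max(ev$table$auc), ]
cat(sprintf("\nbest feature set by AUC: #%d (%s), AUC %.3f, accuracy %.1f%%\n",
            best$set_id, best$name, best$auc, 100 * best$accuracy))
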