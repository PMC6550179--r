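#!/usr/bin/env Rscript
# Mean-decrease-impurity (entropy) feature importance, with across-tree
# SD, for forests refit to all instances of feature sets 10 and 11.

library(gaitrisk)

seed <- 20260921
feats <- read.csv("scratch/features.csv", check.names = FALSE)
sets <- build_feature_sets()

for (sid in c(10L, 11L)) {
  set <- sets[[sid]]
  ok <- complete.cases(feats[set$columns]) &
    apply(as.matrix(feats[set$columns]), 1,
          function(r) all(is.finite(r)))
  dat <- feats[ok, ]
  fo <- train_random_forest(dat[set$columns], factor(dat$label),
                            seed = seed + sid)
  imp <- feature_importance(fo, dat[set$columns], factor(dat$label))
  write.csv(imp, sprintf("results/importance_set%d.csv", sid),
            row.names = FALSE)
  cat(sprintf("\nfeature set #%d (%s), top 10 by mean decrease impurity:\n",
              sid, set$name))
  print(top_features(imp, 10), digits = 3, row.names = FALSE)
}
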