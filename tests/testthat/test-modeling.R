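test_that("the 11 feature sets have the prescribed compositions", {
  sets <- build_feature_sets()
  expect_length(sets, 11)
  sizes <- vapply(sets, function(s) length(s$columns), numeric(1))
  expect_equal(sizes, c(5, 11, 16, 11, 16, 11, 16, 11, 16, 36, 41))
  expect_true(all(unlist(lapply(sets, `[[`, "columns")) %in%
                    feature_catalog()))
  s10 <- sets[[10]]
  expect_true("XZ_CORR" %in% s10$columns)
  expect_false("CADENCE" %in% s10$columns)
  expect_true(all(sets[[1]]$columns %in% gaitrisk:::gait_feature_names()))
  expect_setequal(setdiff(sets[[11]]$columns, s10$columns),
                  c("CADENCE", "MEAN_STEP_TIME", "STD_STEP_TIME",
                    "MEAN_STRIDE_TIME", "STD_STRIDE_TIME"))
})

test_that("metrics reproduce the printed confusion-count formulas", {
  m <- compute_metrics(c(TP = 3, TN = 2, FP = 1, FN = 1))
  expect_equal(m[["accuracy"]], 5 / 7)
  expect_equal(m[["precision"]], 3 / 4)
  expect_equal(m[["sensitivity"]], 3 / 4)
  expect_equal(m[["f1"]], 6 / 8)
  perfect <- compute_metrics(c(TP = 10, TN = 5, FP = 0, FN = 0))
  expect_equal(unname(perfect[c("accuracy", "precision", "sensitivity",
                                "f1")]), rep(1, 4))
  z <- compute_metrics(c(TP = 0, TN = 5, FP = 0, FN = 0))
  expect_true(is.na(z[["precision"]]))
  expect_true("precision" %in% attr(z, "undefined"))
})

test_that("tied scores give AUC 1/2 and ranks match the pairwise oracle", {
  truth <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
  expect_equal(auc_rank(rep(0.5, 5), truth), 0.5)
  withr::with_seed(14, {
    for (i in 1:20) {
      sc <- sample(seq(0, 1, by = 0.1), 12, replace = TRUE)
      tp <- sample(c(TRUE, FALSE), 12, replace = TRUE)
      if (!any(tp) || all(tp)) next
      expect_equal(auc_rank(sc, tp), oracle_auc(sc, tp))
      # invariance under strictly monotone transforms
      expect_equal(auc_rank(exp(3 * sc) - 1, tp), auc_rank(sc, tp))
    }
  })
})

test_that("fold sizes differ by at most one and cover every instance once", {
  f <- make_folds(67, 10, seed = 2)
  expect_equal(sort(as.integer(table(f)), decreasing = TRUE),
               c(7L, 7L, 7L, 7L, 7L, 7L, 7L, 6L, 6L, 6L))
  expect_length(f, 67)
  expect_error(make_folds(5, 10), "exceeds")
  # grouped assignment keeps subjects intact
  groups <- rep(sprintf("S%02d", 1:20), each = 8)
  fg <- make_folds(160, 10, seed = 3, groups = groups)
  expect_true(all(vapply(split(fg, groups),
                         function(x) length(unique(x)) == 1, logical(1))))
  # stratified mode balances classes across folds
  lab <- rep(c("a", "b"), c(30, 70))
  fs <- make_folds(100, 10, seed = 4, stratified = TRUE, labels = lab)
  expect_true(all(table(fs, lab)[, "a"] == 3))
})

test_that("forests are deterministic, depth-bounded, and fit separable data", {
  df <- separable_features(seed = 21)
  x <- df[c("F1", "N1", "N2")]
  y <- factor(df$label)
  f1 <- train_random_forest(x, y, n_trees = 100, seed = 5)
  f2 <- train_random_forest(x, y, n_trees = 100, seed = 5)
  s1 <- predict_risk_scores(f1, x, method = "vote")
  expect_identical(s1, predict_risk_scores(f2, x, method = "vote"))
  expect_equal(f1$num.trees, 100)
  acc <- mean((s1 >= 0.5) == (df$label == "low"))
  expect_equal(acc, 1.0)
  # depth bound: no tree path longer than max_depth
  ti <- ranger::treeInfo(f1, 1)
  depth <- function(id, d) {
    if (ti$terminal[id + 1]) return(d)
    max(depth(ti$leftChild[id + 1], d + 1),
        depth(ti$rightChild[id + 1], d + 1))
  }
  expect_lte(depth(0L, 0L), 10)
  expect_error(train_random_forest(x, factor(rep("low", nrow(x)))),
               "2 classes")
})

test_that("leaf-probability scores agree with vote shares in rank order", {
  df <- separable_features(seed = 31, gap = 0.5)
  x <- df[c("F1", "N1", "N2", "N3")]
  y <- factor(df$label)
  fo <- train_random_forest(x, y, n_trees = 200, seed = 9)
  lp <- predict_risk_scores(fo, x, method = "leaf_prob",
                            train_x = x, train_y = y)
  vt <- predict_risk_scores(fo, x, method = "vote")
  expect_true(all(lp >= 0 & lp <= 1))
  expect_gt(cor(lp, vt, method = "spearman"), 0.9)
})

test_that("cross-validation is perfect on separable data and null on noise", {
  df <- separable_features(n_per_class = 50, seed = 41)
  cols <- c("F1", "N1", "N2")
  set <- list(set_id = 1L, name = "test", columns = cols)
  rep1 <- cross_validate(df, set, k = 10, seed = 1, n_trees = 100)
  expect_equal(unname(rep1$mean["accuracy"]), 1.0)
  expect_equal(unname(rep1$mean["auc"]), 1.0)
  expect_equal(sum(rep1$counts), rep1$n_used)
  # label permutation: accuracy near the majority-class rate
  withr::with_seed(77, {
    null_acc <- replicate(3, {
      df2 <- df
      df2$label <- sample(df2$label)
      cross_validate(df2, set, k = 10, seed = 1,
                     n_trees = 100)$mean[["accuracy"]]
    })
  })
  expect_lt(abs(mean(null_acc) - 0.5), 0.15)
})

test_that("each instance is tested exactly once and folds never overlap", {
  df <- separable_features(n_per_class = 40, seed = 51)
  set <- list(set_id = 1L, name = "t", columns = c("F1", "N1"))
  rep1 <- cross_validate(df, set, k = 10, seed = 3, n_trees = 50)
  expect_equal(sum(rep1$per_fold$TP + rep1$per_fold$TN +
                     rep1$per_fold$FP + rep1$per_fold$FN), 80)
  expect_equal(rep1$n_used, 80)
})

test_that("rows with non-finite values are dropped only for affected sets", {
  df <- separable_features(n_per_class = 30, seed = 61)
  df$CADENCE <- rnorm(60, 120, 5)
  df$CADENCE[1:10] <- NA
  set_gait <- list(set_id = 1L, name = "g", columns = c("F1", "CADENCE"))
  set_sig <- list(set_id = 2L, name = "s", columns = c("F1", "N1"))
  rg <- cross_validate(df, set_gait, k = 5, seed = 1, n_trees = 50)
  rs <- cross_validate(df, set_sig, k = 5, seed = 1, n_trees = 50)
  expect_equal(rg$n_used, 50)
  expect_equal(rg$n_dropped, 10)
  expect_equal(rs$n_used, 60)
})

test_that("spot-check compares tree, forest and SVM under one split", {
  df <- separable_features(n_per_class = 40, seed = 71)
  tab <- spot_check_models(df, columns = c("F1", "N1", "N2"), k = 5,
                           seed = 2)
  expect_equal(tab$model, c("decision_tree", "random_forest", "svm"))
  expect_true(all(c("accuracy", "precision", "sensitivity", "f1", "auc")
                  %in% names(tab)))
  expect_true(all(tab$accuracy == 1))
  expect_error(spot_check_models(within(df, label <- "low"),
                                 columns = c("F1", "N1")), "both classes")
})

test_that("impurity importance isolates the informative feature", {
  withr::with_seed(81, {
    n <- 120
    x <- data.frame(INFORMATIVE = c(rnorm(n / 2, -2), rnorm(n / 2, 2)),
                    FLAT1 = rep(1, n), FLAT2 = rep(0.5, n))
    y <- factor(rep(c("high", "low"), each = n / 2))
    fo <- train_random_forest(x, y, n_trees = 100, seed = 3)
    imp <- feature_importance(fo, x, y)
    expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
    expect_equal(imp$importance[imp$feature == "INFORMATIVE"], 1,
                 tolerance = 1e-9)
    expect_equal(imp$importance[imp$feature == "FLAT1"], 0)
    expect_equal(top_features(imp, 1)$feature, "INFORMATIVE")
  })
})

test_that("entropy importance ranks agree with ranger's Gini importance", {
  withr::with_seed(91, {
    n <- 200
    x <- data.frame(STRONG = c(rnorm(n / 2, -1.5), rnorm(n / 2, 1.5)),
                    WEAK = c(rnorm(n / 2, -0.5), rnorm(n / 2, 0.5)),
                    NOISE1 = rnorm(n), NOISE2 = rnorm(n),
                    NOISE3 = rnorm(n))
    y <- factor(rep(c("high", "low"), each = n / 2))
    fo <- train_random_forest(x, y, n_trees = 200, seed = 4)
    mine <- feature_importance(fo, x, y)
    ref <- ranger::ranger(x = x, y = y, num.trees = 200, max.depth = 10,
                          importance = "impurity", seed = 4,
                          num.threads = 1)$variable.importance
    expect_gt(cor(mine$importance, ref[mine$feature],
                  method = "spearman"), 0.8)
    expect_equal(top_features(mine, 2)$feature, c("STRONG", "WEAK"))
    expect_true(all(mine$sd >= 0))
  })
})

test_that("importance ranking breaks ties lexicographically and caps k", {
  rep0 <- structure(data.frame(feature = c("B", "A", "C"),
                               importance = c(0.4, 0.4, 0.2),
                               sd = c(0, 0, 0)),
                    class = c("importance_report", "data.frame"))
  expect_equal(top_features(rep0, 2)$feature, c("A", "B"))
  expect_equal(nrow(top_features(rep0, 10)), 3)
})

test_that("duplicating a feature does not inflate cross-validated AUC", {
  df <- separable_features(n_per_class = 100, seed = 95, gap = 0.5)
  set_a <- list(set_id = 1L, name = "a", columns = c("F1", "N1"))
  df$F1_COPY <- df$F1
  set_b <- list(set_id = 2L, name = "b",
                columns = c("F1", "F1_COPY", "N1"))
  auc_a <- cross_validate(df, set_a, k = 5, seed = 6,
                          n_trees = 200)$mean[["auc"]]
  auc_b <- cross_validate(df, set_b, k = 5, seed = 6,
                          n_trees = 200)$mean[["auc"]]
  expect_lt(auc_b - auc_a, 0.05)
})
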