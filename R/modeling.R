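#' The 11 feature-set specifications
#'
#' The ablation grid used to compare feature families: gait measures
#' alone; each single axis with and without gait; vector magnitude with
#' and without gait; and the triaxial sets with cross-correlations,
#' without (36 columns) and with (41 columns) gait.
#'
#' @return List of 11 specs, each a list with `set_id`, `name`,
#'   `columns`.
#' @export
build_feature_sets <- function() {
  sig <- c("MEAN", "STD", "RMS", "ACC", "COV", "MCR", "SMA", "P2P",
           "PFREQ", "ENERGY", "MAD")
  axis_cols <- function(ax) paste(ax, sig, sep = "_")
  gait <- gait_feature_names()
  corr <- c("XY_CORR", "YZ_CORR", "XZ_CORR")
  xyz <- c(axis_cols("X"), axis_cols("Y"), axis_cols("Z"))
  defs <- list(
    list(1L, "Gait", gait),
    list(2L, "X-axis", axis_cols("X")),
    list(3L, "X-axis, gait", c(axis_cols("X"), gait)),
    list(4L, "Y-axis", axis_cols("Y")),
    list(5L, "Y-axis, gait", c(axis_cols("Y"), gait)),
    list(6L, "Z-axis", axis_cols("Z")),
    list(7L, "Z-axis, gait", c(axis_cols("Z"), gait)),
    list(8L, "Vector magnitude", axis_cols("MAG")),
    list(9L, "Vector magnitude, gait", c(axis_cols("MAG"), gait)),
    list(10L, "XYZ, cross-correlations", c(xyz, corr)),
    list(11L, "XYZ, cross-correlations, gait", c(xyz, corr, gait))
  )
  lapply(defs, function(d) {
    list(set_id = d[[1]], name = d[[2]], columns = d[[3]])
  })
}

#' Classification metrics from confusion counts and scores
#'
#' Exact ratios: accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision
#' `TP/(TP+FP)`, sensitivity `TP/(TP+FN)`, F1 `2TP/(2TP+FP+FN)`; AUC by
#' the rank (Mann-Whitney) formulation with midranks, so tied scores
#' contribute 1/2. A zero denominator makes the metric `NA` and is
#' recorded in the `undefined` attribute.
#'
#' @param counts Named vector or list with `TP`, `TN`, `FP`, `FN`.
#' @param scores Optional numeric scores for the positive class.
#' @param truth Optional logical (or factor) truth, `TRUE`/positive for
#'   the positive class, parallel to `scores`.
#' @param positive Positive-class label used when `truth` is a factor.
#' @return Named numeric vector `accuracy`, `precision`, `sensitivity`,
#'   `f1`, `auc`.
#' @export
compute_metrics <- function(counts, scores = NULL, truth = NULL,
                            positive = "low") {
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  stopifnot(all(c(tp, tn, fp, fn) >= 0))
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- c(
    accuracy = ratio(tp + tn, tp + tn + fp + fn),
    precision = ratio(tp, tp + fp),
    sensitivity = ratio(tp, tp + fn),
    f1 = ratio(2 * tp, 2 * tp + fp + fn),
    auc = NA_real_
  )
  if (!is.null(scores)) {
    stopifnot(!is.null(truth), length(scores) == length(truth))
    is_pos <- if (is.logical(truth)) truth else truth == positive
    out["auc"] <- auc_rank(scores, is_pos)
  }
  attr(out, "undefined") <- names(out)[is.na(out)]
  out
}

#' Rank-based AUC (Mann-Whitney)
#'
#' @param scores Numeric scores, larger = more positive.
#' @param is_pos Logical, `TRUE` for positive instances.
#' @return AUC in `[0, 1]`, `NA` if either class is empty.
#' @export
auc_rank <- function(scores, is_pos) {
  np <- sum(is_pos); nn <- sum(!is_pos)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[is_pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Train a fall-risk random forest
#'
#' A forest of `n_trees` trees with maximum depth `max_depth`,
#' deterministic for a fixed seed, trained single-threaded via
#' \pkg{ranger} with in-bag bookkeeping retained so that
#' [feature_importance()] can recompute per-tree impurity decreases.
#'
#' @param x Data frame or matrix of features (finite values only).
#' @param y Factor of class labels (2 levels).
#' @param n_trees Number of trees.
#' @param max_depth Maximum tree depth.
#' @param seed Integer seed.
#' @return A fitted `ranger` object.
#' @export
train_random_forest <- function(x, y, n_trees = 500, max_depth = 10,
                                seed = 1) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop_input("need >= 2 classes, got %d", nlevels(y))
  if (NCOL(x) == 0 || NROW(x) == 0) stop_input("empty feature matrix")
  ranger::ranger(
    x = as.data.frame(x), y = y,
    num.trees = n_trees, max.depth = max_depth,
    keep.inbag = TRUE, seed = seed, num.threads = 1
  )
}

#' Per-instance scores for the positive class
#'
#' Class-probability scores from a classification forest. The default
#' `"leaf_prob"` method averages, over trees, the in-bag class fraction
#' of the terminal leaf each instance falls into — the same averaging
#' of per-tree leaf probabilities that scikit-learn's forests report —
#' and needs the training data the forest was fit on. `"vote"` is the
#' coarser fraction of trees voting for the positive class.
#'
#' @param forest A fitted `ranger` object (with `keep.inbag = TRUE` for
#'   `"leaf_prob"`).
#' @param newdata Data frame of features.
#' @param positive Positive-class label.
#' @param method `"leaf_prob"` or `"vote"`.
#' @param train_x,train_y Training data, required for `"leaf_prob"`.
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
predict_risk_scores <- function(forest, newdata, positive = "low",
                                method = c("leaf_prob", "vote"),
                                train_x = NULL, train_y = NULL) {
  method <- match.arg(method)
  lev <- forest$forest$levels
  stopifnot(positive %in% lev)
  newdata <- as.data.frame(newdata)
  if (method == "vote") {
    pred <- stats::predict(forest, data = newdata,
                           predict.all = TRUE, num.threads = 1)$predictions
    return(rowMeans(pred == match(positive, lev)))
  }
  if (is.null(train_x) || is.null(train_y) ||
      is.null(forest$inbag.counts)) {
    stop_input("leaf_prob scores need train_x, train_y and keep.inbag")
  }
  ntree <- forest$num.trees
  pos <- as.factor(train_y) == positive
  tn_tr <- stats::predict(forest, data = as.data.frame(train_x),
                          type = "terminalNodes",
                          num.threads = 1)$predictions
  tn_te <- stats::predict(forest, data = newdata,
                          type = "terminalNodes",
                          num.threads = 1)$predictions
  scores <- numeric(nrow(newdata))
  for (b in seq_len(ntree)) {
    w <- forest$inbag.counts[[b]]
    npos <- rowsum(w * pos, tn_tr[, b])
    ntot <- rowsum(w, tn_tr[, b])
    p <- npos / pmax(ntot, 1)
    scores <- scores + p[match(tn_te[, b], as.integer(rownames(ntot)))]
  }
  as.numeric(scores / ntree)
}

#' Fold assignment for k-fold cross-validation
#'
#' Plain mode shuffles instances into k folds whose sizes differ by at
#' most one. `groups` keeps all instances of a group (e.g. a subject) in
#' one fold, greedily balancing fold sizes. `stratified` deals each
#' class round-robin.
#'
#' @param n Number of instances.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @param groups Optional group id per instance.
#' @param stratified Logical; stratify by `labels`.
#' @param labels Class labels (required when `stratified`).
#' @return Integer vector of fold ids in `1..k`.
#' @export
make_folds <- function(n, k = 10, seed = 1, groups = NULL,
                       stratified = FALSE, labels = NULL) {
  if (k > n) stop_input("k = %d exceeds n = %d", k, n)
  with_seed(seed, {
    fold <- integer(n)
    if (!is.null(groups)) {
      gs <- sample(unique(groups))
      sizes <- numeric(k)
      cls_sizes <- NULL
      if (!is.null(labels)) {
        cls <- vapply(gs, function(g) {
          names(which.max(table(labels[groups == g])))
        }, character(1))
        cls_sizes <- matrix(0, length(unique(cls)), k,
                            dimnames = list(unique(cls), NULL))
      }
      for (gi in seq_along(gs)) {
        idx <- which(groups == gs[gi])
        if (!is.null(cls_sizes)) {
          # balance each class's instance count across folds, then
          # total fold size (stratified group assignment)
          cand <- which(cls_sizes[cls[gi], ] ==
                          min(cls_sizes[cls[gi], ]))
          tgt <- cand[which.min(sizes[cand])]
          cls_sizes[cls[gi], tgt] <- cls_sizes[cls[gi], tgt] + length(idx)
        } else {
          tgt <- which.min(sizes)
        }
        fold[idx] <- tgt
        sizes[tgt] <- sizes[tgt] + length(idx)
      }
    } else if (stratified) {
      stopifnot(!is.null(labels))
      for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      sizes <- rep(floor(n / k), k) + (seq_len(k) <= n %% k)
      fold[sample.int(n)] <- rep(seq_len(k), sizes)
    }
    fold
  })
}

#' k-fold cross-validation of a random-forest feature set
#'
#' Trains one forest per fold on the remaining folds and evaluates on
#' the held-out fold; metrics are computed per fold and averaged, and
#' pooled confusion counts and a pooled AUC are reported for
#' diagnostics. Instances are windows; `group_by_subject = TRUE`
#' assigns whole subjects to folds to prevent within-subject leakage.
#' Rows with missing or non-finite values in the set's columns (e.g.
#' windows with too few detected steps, for sets that include gait
#' columns) are dropped first.
#'
#' @param features Feature data frame with `label` (and `subject_id` if
#'   grouping) plus feature columns.
#' @param set A spec from [build_feature_sets()], or `NULL` for all 52
#'   catalog columns.
#' @param k Number of folds.
#' @param seed Integer seed (fold shuffling and per-fold forests).
#' @param group_by_subject Assign whole subjects to folds.
#' @param stratified Stratify folds by class.
#' @param positive Positive-class label for precision/sensitivity/AUC.
#' @param n_trees,max_depth Forest parameters.
#' @return A `cv_report`: list with `set_id`, `name`, `per_fold` data
#'   frame, `mean` metrics, pooled `counts`, `auc_pooled`, `n_used`,
#'   `n_dropped`.
#' @export
cross_validate <- function(features, set = NULL, k = 10, seed = 1,
                           group_by_subject = FALSE, stratified = FALSE,
                           positive = "low", n_trees = 500,
                           max_depth = 10) {
  cols <- if (is.null(set)) feature_catalog() else set$columns
  stopifnot(all(cols %in% names(features)), "label" %in% names(features))
  ok <- stats::complete.cases(features[cols]) &
    apply(as.matrix(features[cols]), 1, function(r) all(is.finite(r)))
  data <- features[ok, , drop = FALSE]
  n <- nrow(data)
  if (k > n) stop_input("k = %d exceeds usable n = %d", k, n)
  y <- factor(data$label)
  if (nlevels(y) < 2) stop_input("need both classes present")
  fold <- make_folds(
    n, k, seed,
    groups = if (group_by_subject) data$subject_id else NULL,
    stratified = stratified, labels = data$label
  )
  score_method <- "leaf_prob"
  per_fold <- vector("list", k)
  pooled <- c(TP = 0, TN = 0, FP = 0, FN = 0)
  all_scores <- numeric(n)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- fold == f
    forest <- train_random_forest(data[tr, cols, drop = FALSE], y[tr],
                                  n_trees = n_trees,
                                  max_depth = max_depth,
                                  seed = seed + f)
    sc <- predict_risk_scores(forest, data[te, cols, drop = FALSE],
                              positive = positive,
                              method = score_method,
                              train_x = data[tr, cols, drop = FALSE],
                              train_y = y[tr])
    all_scores[te] <- sc
    truth_pos <- data$label[te] == positive
    pred_pos <- sc >= 0.5
    cnt <- c(TP = sum(pred_pos & truth_pos),
             TN = sum(!pred_pos & !truth_pos),
             FP = sum(pred_pos & !truth_pos),
             FN = sum(!pred_pos & truth_pos))
    pooled <- pooled + cnt
    m <- compute_metrics(cnt, scores = sc, truth = truth_pos)
    per_fold[[f]] <- data.frame(fold = f, t(m), t(cnt))
  }
  per_fold <- do.call(rbind, per_fold)
  means <- colMeans(per_fold[c("accuracy", "precision", "sensitivity",
                               "f1", "auc")], na.rm = TRUE)
  structure(list(
    set_id = if (is.null(set)) NA_integer_ else set$set_id,
    name = if (is.null(set)) "all features" else set$name,
    per_fold = per_fold,
    mean = means,
    counts = pooled,
    auc_pooled = auc_rank(all_scores, data$label == positive),
    n_used = n,
    n_dropped = sum(!ok),
    seed = seed,
    positive = positive
  ), class = "cv_report")
}

#' Cross-validate every feature set
#'
#' Runs [cross_validate()] for each of the 11 feature sets and returns
#' the comparison table (one row per set, fold-averaged metrics), the
#' analogue of a feature-set ablation table.
#'
#' @inheritParams cross_validate
#' @param sets Feature sets; default [build_feature_sets()].
#' @return List with `table` (data frame) and `reports` (list of
#'   `cv_report`s).
#' @export
evaluate_feature_sets <- function(features, sets = build_feature_sets(),
                                  k = 10, seed = 1,
                                  group_by_subject = FALSE,
                                  stratified = FALSE, positive = "low",
                                  n_trees = 500, max_depth = 10) {
  reports <- lapply(sets, function(s) {
    cross_validate(features, s, k = k, seed = seed,
                   group_by_subject = group_by_subject,
                   stratified = stratified, positive = positive,
                   n_trees = n_trees, max_depth = max_depth)
  })
  tab <- do.call(rbind, lapply(reports, function(r) {
    data.frame(set_id = r$set_id, name = r$name, t(r$mean),
               auc_pooled = r$auc_pooled, n_used = r$n_used,
               n_dropped = r$n_dropped, stringsAsFactors = FALSE)
  }))
  list(table = tab, reports = reports)
}

#' Spot-check candidate classifiers with default parameters
#'
#' Evaluates a default-parameter decision tree (\pkg{rpart}), random
#' forest (\pkg{ranger}) and support-vector classifier (\pkg{e1071})
#' under the same k-fold split, reporting fold-averaged metrics for each
#' — a comparison table only, no automatic selection.
#'
#' @param features Feature data frame with `label` and feature columns.
#' @param columns Feature columns to use; default all catalog columns
#'   present.
#' @param k,seed,positive As in [cross_validate()].
#' @return Data frame: one row per model, five metric columns.
#' @export
spot_check_models <- function(features, columns = NULL, k = 10, seed = 1,
                              positive = "low") {
  cols <- columns %||% intersect(feature_catalog(), names(features))
  ok <- stats::complete.cases(features[cols]) &
    apply(as.matrix(features[cols]), 1, function(r) all(is.finite(r)))
  data <- features[ok, , drop = FALSE]
  y <- factor(data$label)
  if (nlevels(y) < 2) stop_input("need both classes present")
  n <- nrow(data)
  fold <- make_folds(n, k, seed)
  fit_score <- list(
    decision_tree = function(xtr, ytr, xte, s) {
      fit <- rpart::rpart(y ~ ., data = data.frame(xtr, y = ytr))
      stats::predict(fit, data.frame(xte))[, positive]
    },
    random_forest = function(xtr, ytr, xte, s) {
      fit <- ranger::ranger(x = xtr, y = ytr, probability = TRUE,
                            seed = s, num.threads = 1)
      stats::predict(fit, data = xte, num.threads = 1)$predictions[, positive]
    },
    svm = function(xtr, ytr, xte, s) {
      fit <- with_seed(s, e1071::svm(x = as.matrix(xtr), y = ytr,
                                     probability = TRUE))
      attr(stats::predict(fit, as.matrix(xte), probability = TRUE),
           "probabilities")[, positive]
    }
  )
  rows <- lapply(names(fit_score), function(model) {
    ms <- matrix(NA_real_, k, 5)
    for (f in seq_len(k)) {
      tr <- fold != f; te <- fold == f
      sc <- fit_score[[model]](data[tr, cols, drop = FALSE], y[tr],
                               data[te, cols, drop = FALSE], seed + f)
      truth_pos <- data$label[te] == positive
      pred_pos <- sc >= 0.5
      cnt <- c(TP = sum(pred_pos & truth_pos),
               TN = sum(!pred_pos & !truth_pos),
               FP = sum(pred_pos & !truth_pos),
               FN = sum(!pred_pos & truth_pos))
      ms[f, ] <- compute_metrics(cnt, scores = sc, truth = truth_pos)
    }
    data.frame(model = model,
               accuracy = mean(ms[, 1], na.rm = TRUE),
               precision = mean(ms[, 2], na.rm = TRUE),
               sensitivity = mean(ms[, 3], na.rm = TRUE),
               f1 = mean(ms[, 4], na.rm = TRUE),
               auc = mean(ms[, 5], na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mean-decrease-impurity feature importance with across-tree spread
#'
#' Recomputes, for every tree in the forest, the weighted reduction of
#' sample entropy achieved by each split, attributes it to the split
#' feature, and sums over the tree's splits (each tree's profile is
#' normalized to sum to one). Reported importance is the across-tree
#' mean, renormalized to sum to one, with the across-tree standard
#' deviation as the spread. The in-bag sample weights retained by
#' [train_random_forest()] reproduce each tree's own training sample.
#'
#' @param forest A `ranger` forest trained with `keep.inbag = TRUE`.
#' @param x,y The training features and labels the forest was fit on.
#' @return An `importance_report`: data frame with `feature`,
#'   `importance` (mean decrease impurity, sums to 1) and `sd`
#'   (across-tree SD), in training-column order.
#' @export
feature_importance <- function(forest, x, y) {
  stopifnot(inherits(forest, "ranger"))
  if (is.null(forest$inbag.counts)) {
    stop_input("forest must be trained with keep.inbag = TRUE")
  }
  x <- as.data.frame(x)
  vars <- forest$forest$independent.variable.names
  stopifnot(all(vars %in% names(x)))
  xm <- as.matrix(x[vars])
  y <- as.factor(y)
  ncls <- nlevels(y)
  ycode <- as.integer(y)
  ntree <- forest$num.trees
  imp <- matrix(0, ntree, length(vars),
                dimnames = list(NULL, vars))
  for (b in seq_len(ntree)) {
    ti <- ranger::treeInfo(forest, b)
    w <- forest$inbag.counts[[b]]
    used <- which(w > 0)
    nnodes <- nrow(ti)
    # route each in-bag sample to its terminal node (0-based ids)
    node <- rep(0L, length(used))
    repeat {
      isterm <- ti$terminal[node + 1L]
      if (all(isterm)) break
      act <- which(!isterm)
      nd <- node[act] + 1L
      goleft <- xm[cbind(used[act], ti$splitvarID[nd] + 1L)] <=
        ti$splitval[nd]
      node[act] <- ifelse(goleft, ti$leftChild[nd], ti$rightChild[nd])
    }
    # weighted class counts at terminals, then aggregated up the tree
    cnt <- matrix(0, nnodes, ncls)
    for (cl in seq_len(ncls)) {
      sel <- ycode[used] == cl
      if (any(sel)) {
        agg <- tapply(w[used[sel]], node[sel], sum)
        cnt[as.integer(names(agg)) + 1L, cl] <- agg
      }
    }
    for (id in rev(seq_len(nnodes))) {
      if (!ti$terminal[id]) {
        cnt[id, ] <- cnt[ti$leftChild[id] + 1L, ] +
          cnt[ti$rightChild[id] + 1L, ]
      }
    }
    tot <- sum(cnt[1, ])
    internal <- which(!ti$terminal)
    for (id in internal) {
      nl <- ti$leftChild[id] + 1L; nr <- ti$rightChild[id] + 1L
      wn <- sum(cnt[id, ]); wl <- sum(cnt[nl, ]); wr <- sum(cnt[nr, ])
      if (wn == 0) next
      dI <- (wn * entropy_bits(cnt[id, ] / wn) -
               wl * entropy_bits(cnt[nl, ] / max(wl, 1)) -
               wr * entropy_bits(cnt[nr, ] / max(wr, 1))) / tot
      v <- ti$splitvarName[id]
      imp[b, v] <- imp[b, v] + dI
    }
    s <- sum(imp[b, ])
    if (s > 0) imp[b, ] <- imp[b, ] / s
  }
  mean_imp <- colMeans(imp)
  if (sum(mean_imp) > 0) mean_imp <- mean_imp / sum(mean_imp)
  structure(data.frame(
    feature = vars,
    importance = as.numeric(mean_imp),
    sd = apply(imp, 2, stats::sd),
    stringsAsFactors = FALSE
  ), class = c("importance_report", "data.frame"))
}

#' Top-k features by mean decrease impurity
#'
#' @param report An `importance_report` from [feature_importance()].
#' @param k How many features to return; if larger than the catalog, the
#'   full ranking is returned.
#' @return The top rows, ordered by descending importance, ties broken
#'   by feature name for determinism.
#' @export
top_features <- function(report, k = 10) {
  ord <- order(-report$importance, report$feature)
  report[ord[seq_len(min(k, nrow(report)))], , drop = FALSE]
}
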