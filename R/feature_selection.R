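#' Tree-ensemble feature-importance ranking
#'
#' Fits a random forest to the labeled feature matrix and returns the mean
#' impurity-decrease (Gini) importance per feature, averaged over trees and
#' normalized to sum 1. Ties in score are broken lexicographically by
#' feature name so the rank order is always total.
#'
#' @param features Numeric data.frame/matrix (no missing values).
#' @param labels Factor (or coercible) class vector, at least 2 classes.
#' @param n_trees Number of trees (default 500).
#' @param seed Integer RNG seed.
#' @return An object of class `importance_ranking`: data.frame with
#'   `feature`, `importance` (sums to 1) and `rank`, ordered by rank.
#' @export
forest_importance <- function(features, labels, n_trees = 500, seed = 1) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stopf("labels must contain at least 2 classes")
  features <- as.data.frame(features)
  if (any(!vapply(features, is.numeric, logical(1)))) {
    stopf("all feature columns must be numeric")
  }
  if (anyNA(features)) stopf("features must not contain missing values")
  fit <- with_seed(seed, {
    randomForest::randomForest(x = features, y = labels, ntree = n_trees,
                               importance = FALSE)
  })
  imp <- fit$importance[, "MeanDecreaseGini"]
  tot <- sum(imp)
  score <- if (tot > 0) imp / tot else rep(1 / length(imp), length(imp))
  ord <- order(-score, names(score))
  out <- data.frame(feature = names(score)[ord],
                    importance = unname(score[ord]),
                    rank = seq_along(score))
  structure(out, class = c("importance_ranking", "data.frame"))
}

#' Correlation-redundancy pruning of a ranked feature list
#'
#' Greedy scan in rank order: a feature is kept iff its absolute Pearson
#' correlation with every already-kept feature is below `r_max`. Constant
#' (zero-variance) features have undefined correlation and are excluded
#' with a warning. Lowering `r_max` can only shrink the selected set.
#'
#' @param ranking An [forest_importance()] ranking covering all columns of
#'   `features`.
#' @param features The feature matrix the ranking was computed on.
#' @param r_max Absolute-correlation threshold (default 0.9).
#' @return Character vector of selected feature names, in rank order.
#' @export
correlation_prune <- function(ranking, features, r_max = 0.9) {
  features <- as.data.frame(features)
  if (!all(ranking$feature %in% names(features))) {
    stopf("ranking refers to features absent from the matrix")
  }
  kept <- character(0)
  for (f in ranking$feature) {
    v <- features[[f]]
    if (stats::sd(v) == 0) {
      warning(sprintf("feature '%s' is constant; excluded", f))
      next
    }
    ok <- all(vapply(kept, function(k) {
      abs(stats::cor(v, features[[k]])) < r_max
    }, logical(1)))
    if (ok) kept <- c(kept, f)
  }
  kept
}

#' Two-stage feature selection (importance ranking + correlation filter)
#'
#' @param instances Labeled instance data.frame containing the feature
#'   columns and the task labels.
#' @param task Classification task (see [task_labels()]).
#' @param feature_cols Candidate features (default [feature_columns()]).
#' @param r_max,n_trees,seed Passed to the two stages.
#' @return List with `ranking` and `selected`.
#' @export
select_features <- function(instances, task = "states",
                            feature_cols = feature_columns(),
                            r_max = 0.9, n_trees = 500, seed = 1) {
  tl <- task_labels(instances, task)
  X <- instances[tl$rows, feature_cols, drop = FALSE]
  ranking <- forest_importance(X, tl$labels, n_trees = n_trees, seed = seed)
  list(ranking = ranking,
       selected = correlation_prune(ranking, X, r_max = r_max))
}
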