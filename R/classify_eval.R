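MODEL_FAMILIES <- c("perceptron", "logistic", "svm", "knn",
                    "random_forest", "gradient_boosted_trees")

default_hyperparameters <- function(family) {
  switch(family,
    perceptron = list(max_epochs = 1000, learning_rate = 1),
    logistic = list(maxit = 200),
    svm = list(kernel = "radial", cost = 1),
    knn = list(k = 5),
    random_forest = list(n_trees = 500),
    gradient_boosted_trees = list(nrounds = 200, eta = 0.06, max_depth = 4,
                                  colsample_bytree = 0.5,
                                  min_child_weight = 0.5, subsample = 0.8)
  )
}

#' Specification of one classifier
#'
#' The six supported families are `perceptron`, `logistic`, `svm`, `knn`,
#' `random_forest` and `gradient_boosted_trees`. Unstated hyperparameters
#' take the family defaults; the boosted-tree default is the tuned setting
#' (200 rounds, eta 0.06, max depth 4, colsample_bytree and
#' min_child_weight 0.5, subsample 0.8). Margin/distance families
#' (perceptron, logistic, svm, knn) are fitted on train-set z-scored
#' features; tree families on raw features.
#'
#' @param family One of the six family names.
#' @param hyperparameters Named list overriding the family defaults.
#' @param seed Integer seed used for every stochastic element of the fit.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family, hyperparameters = list(), seed = 1) {
  family <- match.arg(family, MODEL_FAMILIES)
  hp <- utils::modifyList(default_hyperparameters(family), hyperparameters)
  structure(list(family = family, hyperparameters = hp, seed = seed),
            class = "model_spec")
}

#' Specification of a data-partition scheme
#'
#' @param scheme `"RTS"` (random train-test split) or `"CV"` (k-fold
#'   cross-validation).
#' @param train_fraction RTS train share (default 0.7).
#' @param k Number of CV folds (default 5).
#' @param stratified Preserve class proportions in every part (default TRUE).
#' @param seed Integer seed for the random assignment.
#' @return An object of class `partition_spec`.
#' @export
partition_spec <- function(scheme = c("RTS", "CV"), train_fraction = 0.7,
                           k = 5, stratified = TRUE, seed = 1) {
  scheme <- match.arg(scheme)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stopf("`train_fraction` must be in (0, 1)")
  }
  if (k < 2) stopf("`k` must be >= 2")
  structure(list(scheme = scheme, train_fraction = train_fraction,
                 k = as.integer(k), stratified = stratified, seed = seed),
            class = "partition_spec")
}

# Largest-remainder apportionment of `total` over quotas `q`.
apportion <- function(q, total) {
  base <- floor(q)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(-(q - base))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Build train/test indices or cross-validation folds
#'
#' RTS returns disjoint train/test index sets whose train size equals
#' `round(train_fraction * n)`; with stratification each class contributes
#' within one instance of its proportional quota. CV returns `k` disjoint
#' folds covering all instances with sizes within 1 of each other, again
#' class-stratified by default (per-class round-robin with a carried
#' pointer, so both the global and per-class fold sizes are balanced).
#'
#' @param labels Class vector (factor or character) of all instances.
#' @param spec A [partition_spec()].
#' @return For RTS a list with `train` and `test` integer indices; for CV a
#'   list of `k` integer index vectors (the held-out folds).
#' @export
make_partitions <- function(labels, spec) {
  labels <- as.factor(labels)
  n <- length(labels)
  with_seed(spec$seed, {
    if (spec$scheme == "RTS") {
      n_train <- round(spec$train_fraction * n)
      if (spec$stratified) {
        cls <- levels(droplevels(labels))
        counts <- table(droplevels(labels))
        quota <- apportion(spec$train_fraction * as.numeric(counts), n_train)
        train <- integer(0)
        for (i in seq_along(cls)) {
          idx <- sample(which(labels == cls[i]))
          train <- c(train, idx[seq_len(quota[i])])
        }
      } else {
        train <- sample(n, n_train)
      }
      list(train = sort(train), test = sort(setdiff(seq_len(n), train)))
    } else {
      k <- spec$k
      folds <- vector("list", k)
      if (spec$stratified) {
        counts <- table(droplevels(labels))
        small <- names(counts)[counts < k]
        if (length(small) > 0) {
          stopf("class(es) with fewer than k=%d members under stratified CV: %s",
                k, paste(small, collapse = ", "))
        }
        ptr <- 0
        for (cl in levels(droplevels(labels))) {
          idx <- sample(which(labels == cl))
          for (j in seq_along(idx)) {
            f <- (ptr %% k) + 1
            folds[[f]] <- c(folds[[f]], idx[j])
            ptr <- ptr + 1
          }
        }
      } else {
        idx <- sample(n)
        for (j in seq_len(n)) {
          f <- ((j - 1) %% k) + 1
          folds[[f]] <- c(folds[[f]], idx[j])
        }
      }
      lapply(folds, sort)
    }
  })
}

# ---- model fitting ------------------------------------------------------

fit_perceptron <- function(X, y, hp, seed) {
  K <- nlevels(y); p <- ncol(X)
  Xb <- cbind(1, as.matrix(X))
  W <- matrix(0, K, p + 1)
  yi <- as.integer(y)
  with_seed(seed, {
    for (epoch in seq_len(hp$max_epochs)) {
      mistakes <- 0
      for (i in sample(nrow(Xb))) {
        s <- W %*% Xb[i, ]
        pred <- which.max(s)
        if (pred != yi[i]) {
          W[yi[i], ] <- W[yi[i], ] + hp$learning_rate * Xb[i, ]
          W[pred, ] <- W[pred, ] - hp$learning_rate * Xb[i, ]
          mistakes <- mistakes + 1
        }
      }
      if (mistakes == 0) break
    }
  })
  W
}

#' Fit one classifier to a training set
#'
#' Returns a fitted handle supporting class and class-probability
#' prediction via [predict.collar_model()]. Fitting is deterministic given
#' the [model_spec()] seed: every internal source of randomness (epoch shuffling,
#' bootstrap resampling, subsampling) is run under a seed derived from it.
#' Families without native probabilities (perceptron) expose a softmax
#' calibration of their decision values.
#'
#' @param spec A [model_spec()].
#' @param X Numeric feature data.frame (training rows).
#' @param y Class labels (factor or coercible), at least 2 classes.
#' @return An object of class `collar_model`.
#' @export
train_model <- function(spec, X, y) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stopf("training labels contain a single class")
  if (nrow(X) == 0) stopf("empty training set")
  X <- as.data.frame(X)

  scaled <- spec$family %in% c("perceptron", "logistic", "svm", "knn")
  center <- scale <- NULL
  Xs <- X
  if (scaled) {
    center <- vapply(X, mean, numeric(1))
    scale <- vapply(X, stats::sd, numeric(1))
    scale[scale == 0] <- 1
    Xs <- as.data.frame(sweep(sweep(as.matrix(X), 2, center), 2, scale, "/"))
  }

  hp <- spec$hyperparameters
  fit <- switch(spec$family,
    perceptron = fit_perceptron(Xs, y, hp, spec$seed),
    logistic = with_seed(spec$seed, {
      d <- cbind(Xs, .y = y)
      nnet::multinom(.y ~ ., data = d, trace = FALSE, maxit = hp$maxit,
                     MaxNWts = 10000)
    }),
    svm = with_seed(spec$seed, {
      e1071::svm(x = as.matrix(Xs), y = y, kernel = hp$kernel,
                 cost = hp$cost, probability = TRUE, scale = FALSE)
    }),
    knn = caret::knn3(x = as.matrix(Xs), y = y, k = hp$k),
    random_forest = with_seed(spec$seed, {
      randomForest::randomForest(x = Xs, y = y, ntree = hp$n_trees)
    }),
    gradient_boosted_trees = with_seed(spec$seed, {
      K <- nlevels(y)
      params <- list(eta = hp$eta, max_depth = hp$max_depth,
                     colsample_bytree = hp$colsample_bytree,
                     min_child_weight = hp$min_child_weight,
                     subsample = hp$subsample, nthread = 1,
                     seed = spec$seed)
      if (K > 2) {
        params$objective <- "multi:softprob"
        params$num_class <- K
      } else {
        params$objective <- "binary:logistic"
      }
      dtrain <- xgboost::xgb.DMatrix(as.matrix(Xs),
                                     label = as.integer(y) - 1)
      xgboost::xgb.train(params = params, data = dtrain,
                         nrounds = hp$nrounds, verbose = 0)
    })
  )
  structure(list(spec = spec, fit = fit, levels = levels(y),
                 features = names(X), center = center, scale = scale),
            class = "collar_model")
}

#' Predict classes or class probabilities from a fitted handle
#'
#' @param object A `collar_model` from [train_model()].
#' @param newdata Feature data.frame with the training columns.
#' @param type `"class"` (default) or `"prob"` (matrix, one column per
#'   class in training-level order).
#' @param ... Unused.
#' @return Factor of classes, or a numeric probability matrix.
#' @export
predict.collar_model <- function(object, newdata,
                                 type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- as.data.frame(newdata)[, object$features, drop = FALSE]
  if (!is.null(object$center)) {
    X <- as.data.frame(sweep(sweep(as.matrix(X), 2, object$center),
                             2, object$scale, "/"))
  }
  lv <- object$levels
  K <- length(lv)
  prob <- switch(object$spec$family,
    perceptron = {
      s <- cbind(1, as.matrix(X)) %*% t(object$fit)
      s <- s - apply(s, 1, max)
      e <- exp(s)
      e / rowSums(e)
    },
    logistic = {
      p <- stats::predict(object$fit, newdata = X, type = "probs")
      if (K == 2) p <- cbind(1 - p, p)
      if (is.null(dim(p))) p <- matrix(p, nrow = 1)
      p
    },
    svm = {
      pr <- stats::predict(object$fit, as.matrix(X), probability = TRUE)
      attr(pr, "probabilities")[, lv, drop = FALSE]
    },
    knn = stats::predict(object$fit, as.matrix(X), type = "prob")[, lv,
                                                                  drop = FALSE],
    random_forest = stats::predict(object$fit, X, type = "prob")[, lv,
                                                                 drop = FALSE],
    gradient_boosted_trees = {
      p <- stats::predict(object$fit, xgboost::xgb.DMatrix(as.matrix(X)))
      if (K > 2) {
        if (is.null(dim(p))) p <- matrix(p, ncol = K, byrow = TRUE)
        p
      } else cbind(1 - p, p)
    }
  )
  colnames(prob) <- lv
  if (type == "prob") return(prob)
  if (object$spec$family == "svm") {
    # native decision-boundary prediction (deterministic, unlike the
    # internally cross-validated probability calibration)
    factor(as.character(stats::predict(object$fit, as.matrix(X))),
           levels = lv)
  } else {
    factor(lv[max.col(prob, ties.method = "first")], levels = lv)
  }
}

# ---- metrics ------------------------------------------------------------

#' Confusion matrix and per-class metrics from truth/prediction pairs
#'
#' Builds the true-by-predicted count matrix over the full class set and
#' computes overall accuracy plus one-vs-rest precision, recall and F1 per
#' class, all in percent. A class never predicted gets precision 0 by
#' convention; F1 is 0 when precision + recall is 0.
#'
#' @param truth,predicted Vectors of true and predicted classes (equal
#'   length).
#' @param levels Optional class set (default: union of observed levels).
#' @return An object of class `classification_report`: list with
#'   `confusion`, `accuracy` (percent), and `per_class` (data.frame with
#'   `class`, `precision`, `recall`, `f1`, `support`).
#' @export
classification_metrics <- function(truth, predicted, levels = NULL) {
  if (is.null(levels)) {
    levels <- union(levels(as.factor(truth)), levels(as.factor(predicted)))
  }
  truth <- factor(truth, levels = levels)
  predicted <- factor(predicted, levels = levels)
  cm <- table(truth = truth, predicted = predicted)
  total <- sum(cm)
  acc <- 100 * sum(diag(cm)) / total
  per <- do.call(rbind, lapply(levels, function(cl) {
    tp <- cm[cl, cl]
    fp <- sum(cm[, cl]) - tp
    fn <- sum(cm[cl, ]) - tp
    prec <- if (tp + fp == 0) 0 else 100 * tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else 100 * tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    data.frame(class = cl, precision = prec, recall = rec, f1 = f1,
               support = tp + fn)
  }))
  rownames(per) <- NULL
  structure(list(confusion = cm, accuracy = acc, per_class = per),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, digits = 1, ...) {
  cat(sprintf("<classification_report> accuracy %.*f%%\n", digits,
              x$accuracy))
  per <- x$per_class
  per$precision <- round(per$precision, digits)
  per$recall <- round(per$recall, digits)
  per$f1 <- round(per$f1, digits)
  print(per, row.names = FALSE)
  invisible(x)
}

#' Evaluate a fitted model on held-out instances
#'
#' @param model A `collar_model`.
#' @param X_test,y_test Held-out features and true labels.
#' @return A `classification_report` (classes fixed to the model's training
#'   levels union the observed truth).
#' @export
evaluate <- function(model, X_test, y_test) {
  if (nrow(X_test) == 0) stopf("test set is empty")
  pred <- predict(model, X_test, type = "class")
  rep <- classification_metrics(y_test, pred,
                                levels = union(model$levels,
                                               levels(as.factor(y_test))))
  rep$model <- model$spec$family
  rep
}

#' Random train-test split evaluation
#'
#' @param mspec A [model_spec()].
#' @param X,y Full feature matrix and labels.
#' @param pspec A [partition_spec()] with scheme "RTS".
#' @return A `classification_report` with a `partition` field and the
#'   fitted model attached as `model_handle`.
#' @export
rts_evaluate <- function(mspec, X, y, pspec = partition_spec("RTS")) {
  parts <- make_partitions(y, pspec)
  model <- train_model(mspec, X[parts$train, , drop = FALSE],
                       y[parts$train])
  rep <- evaluate(model, X[parts$test, , drop = FALSE], y[parts$test])
  rep$partition <- "RTS"
  rep$model_handle <- model
  rep
}

#' k-fold cross-validation evaluation
#'
#' Each instance is predicted exactly once, by the model trained on the
#' other k-1 folds; the pooled predictions form one confusion matrix (the
#' headline report), and per-fold metrics are retained in `per_fold`.
#'
#' @param mspec A [model_spec()].
#' @param X,y Full feature matrix and labels.
#' @param pspec A [partition_spec()] with scheme "CV".
#' @return A `classification_report` with `per_fold` (list of fold
#'   reports) and `partition = "CV"`.
#' @export
cv_evaluate <- function(mspec, X, y, pspec = partition_spec("CV")) {
  y <- droplevels(as.factor(y))
  folds <- make_partitions(y, pspec)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  per_fold <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    test <- folds[[f]]
    train <- setdiff(seq_along(y), test)
    ms <- mspec
    ms$seed <- child_seed(mspec$seed, f)
    model <- train_model(ms, X[train, , drop = FALSE], y[train])
    pf <- predict(model, X[test, , drop = FALSE], type = "class")
    pred[test] <- as.character(pf)
    per_fold[[f]] <- classification_metrics(y[test], pf,
                                            levels = levels(y))
  }
  rep <- classification_metrics(y, pred, levels = levels(y))
  rep$model <- mspec$family
  rep$partition <- "CV"
  rep$per_fold <- per_fold
  rep
}

#' Partial-dependence curve of a fitted model
#'
#' The standard partial-dependence estimator, computed directly: the grid
#' is `n_grid` equally spaced quantiles between the 1st and 99th percentile
#' of the feature; at each grid value the feature column is set to that
#' value for every instance and the predicted class probabilities are
#' averaged.
#'
#' @param model A `collar_model`.
#' @param X Instance feature data.frame over which to average.
#' @param feature Feature name.
#' @param n_grid Number of grid points (default 50).
#' @return An object of class `pdp_curve`: list with `feature`, `grid`
#'   (strictly increasing) and `prob` (length(grid) x classes matrix).
#' @export
pdp <- function(model, X, feature, n_grid = 50) {
  if (!feature %in% names(X)) stopf("feature '%s' not present", feature)
  v <- X[[feature]]
  qs <- stats::quantile(v, probs = seq(0.01, 0.99, length.out = n_grid),
                        names = FALSE)
  grid <- unique(qs)
  if (length(grid) == 1) {
    warning(sprintf("feature '%s' is (nearly) constant; single-point curve",
                    feature))
  }
  prob <- matrix(NA_real_, length(grid), length(model$levels),
                 dimnames = list(NULL, model$levels))
  for (i in seq_along(grid)) {
    X2 <- X
    X2[[feature]] <- grid[i]
    prob[i, ] <- colMeans(predict(model, X2, type = "prob"))
  }
  structure(list(feature = feature, grid = grid, prob = prob),
            class = "pdp_curve")
}

#' @export
print.pdp_curve <- function(x, ...) {
  cat(sprintf("<pdp_curve> feature '%s', %d grid points, classes: %s\n",
              x$feature, length(x$grid),
              paste(colnames(x$prob), collapse = " ")))
  invisible(x)
}

#' Run the full task x model x partition experiment matrix
#'
#' For every requested combination of task, model family and partition
#' scheme, fits and evaluates a classifier on the given labeled instances
#' and collects the reports (plus optional partial-dependence curves for
#' the RTS-fitted models).
#'
#' @param instances Labeled instance data.frame (features + label columns).
#' @param tasks Character vector of task names (see [task_labels()]).
#' @param models Character vector of model families (default all six).
#' @param partitions Character vector over \{"RTS", "CV"\} (default both).
#' @param feature_cols Feature columns to use (default [feature_columns()]).
#' @param pdp_features Optional feature names for PDP curves (RTS models).
#' @param seed Base seed; every combination gets a derived child seed.
#' @param train_fraction,k Partition parameters.
#' @return Nested list `bundle[[task]][[model]][[partition]]` of
#'   `classification_report`s, with `pdp` curves attached where requested,
#'   plus a `config` echo element.
#' @export
run_experiment <- function(instances,
                           tasks = c("states", "general", "fine", "posture",
                                     "behavior_by_posture"),
                           models = MODEL_FAMILIES,
                           partitions = c("RTS", "CV"),
                           feature_cols = feature_columns(),
                           pdp_features = NULL,
                           seed = 1, train_fraction = 0.7, k = 5) {
  bad <- setdiff(tasks, c("states", "general", "fine", "posture",
                          "behavior_by_posture"))
  if (length(bad) > 0) stopf("unknown task(s): %s", paste(bad, collapse = ", "))
  bundle <- list()
  comb <- 0
  for (task in tasks) {
    tl <- task_labels(instances, task)
    X <- instances[tl$rows, feature_cols, drop = FALSE]
    y <- tl$labels
    for (fam in models) {
      for (part in partitions) {
        comb <- comb + 1
        ms <- model_spec(fam, seed = child_seed(seed, comb))
        if (part == "RTS") {
          ps <- partition_spec("RTS", train_fraction = train_fraction,
                               seed = child_seed(seed, comb + 50000))
          rep <- rts_evaluate(ms, X, y, ps)
          if (!is.null(pdp_features)) {
            rep$pdp <- lapply(stats::setNames(pdp_features, pdp_features),
                              function(f) pdp(rep$model_handle, X, f))
          }
        } else {
          ps <- partition_spec("CV", k = k,
                               seed = child_seed(seed, comb + 50000))
          rep <- cv_evaluate(ms, X, y, ps)
        }
        rep$task <- task
        bundle[[task]][[fam]][[part]] <- rep
      }
    }
  }
  bundle$config <- list(tasks = tasks, models = models,
                        partitions = partitions, seed = seed,
                        feature_cols = feature_cols,
                        train_fraction = train_fraction, k = k)
  bundle
}
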