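test_that("RTS partitions have the right sizes and stratification", {
  y <- factor(rep(c("A", "B"), c(6, 4)))
  p <- make_partitions(y, partition_spec("RTS", seed = 1))
  expect_length(p$train, 7)
  expect_length(p$test, 3)
  expect_length(intersect(p$train, p$test), 0)

  # 60/40 mix: test-set class counts within 1 of the proportional quota
  y2 <- factor(rep(c("A", "B"), c(60, 40)))
  p2 <- make_partitions(y2, partition_spec("RTS", seed = 2))
  test_mix <- table(y2[p2$test])
  expect_lte(abs(test_mix[["A"]] - 18), 1)
  expect_lte(abs(test_mix[["B"]] - 12), 1)
})

test_that("CV folds partition the data into near-equal stratified parts", {
  y <- factor(rep(c("A", "B", "C"), c(50, 30, 20)))
  folds <- make_partitions(y, partition_spec("CV", k = 5, seed = 3))
  expect_length(folds, 5)
  expect_equal(sort(unlist(folds)), 1:100)
  expect_true(all(vapply(folds, length, numeric(1)) == 20))
  # per-class balance within 1 across folds
  for (cl in levels(y)) {
    per <- vapply(folds, function(f) sum(y[f] == cl), numeric(1))
    expect_lte(max(per) - min(per), 1)
  }
  # uneven n: fold sizes within 1
  y2 <- factor(rep(c("A", "B"), c(13, 7)))
  f2 <- make_partitions(y2, partition_spec("CV", k = 5, seed = 4))
  sz <- vapply(f2, length, numeric(1))
  expect_lte(max(sz) - min(sz), 1)
})

test_that("stratified CV names the class that is too small", {
  y <- factor(rep(c("A", "B"), c(30, 3)))
  expect_error(make_partitions(y, partition_spec("CV", k = 5, seed = 1)),
               "B")
})

test_that("partitions are deterministic given the seed", {
  y <- factor(rep(c("A", "B"), 50))
  p1 <- make_partitions(y, partition_spec("RTS", seed = 9))
  p2 <- make_partitions(y, partition_spec("RTS", seed = 9))
  expect_identical(p1, p2)
  p3 <- make_partitions(y, partition_spec("RTS", seed = 10))
  expect_false(identical(p1, p3))
})

test_that("a perceptron separates a linearly separable toy set perfectly", {
  set.seed(81)
  X <- data.frame(u = c(rnorm(40, -3), rnorm(40, 3)), v = rnorm(80))
  y <- factor(rep(c("L", "R"), each = 40))
  m <- train_model(model_spec("perceptron", seed = 1), X, y)
  expect_equal(mean(predict(m, X) == y), 1)
})

test_that("all six families fit deterministically and expose probabilities", {
  toy <- toy_classification()
  for (fam in c("perceptron", "logistic", "svm", "knn", "random_forest",
                "gradient_boosted_trees")) {
    m1 <- train_model(model_spec(fam, seed = 7), toy$X, toy$y)
    m2 <- train_model(model_spec(fam, seed = 7), toy$X, toy$y)
    expect_identical(predict(m1, toy$X), predict(m2, toy$X))
    pr <- predict(m1, toy$X, type = "prob")
    expect_equal(dim(pr), c(nrow(toy$X), 2))
    expect_true(all(pr >= 0 & pr <= 1))
    expect_equal(unname(rowSums(pr)), rep(1, nrow(pr)), tolerance = 1e-6)
  }
  expect_error(train_model(model_spec("logistic"), toy$X,
                           rep("A", nrow(toy$X))), "single class")
})

test_that("boosted trees with the tuned defaults run end-to-end", {
  set.seed(82)
  n <- 500
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- factor(ifelse(X$a + X$b + rnorm(n) > 0, "AC", "ST"))
  spec <- model_spec("gradient_boosted_trees", seed = 1)
  expect_equal(spec$hyperparameters$nrounds, 200)
  expect_equal(spec$hyperparameters$eta, 0.06)
  expect_equal(spec$hyperparameters$max_depth, 4)
  m <- train_model(spec, X, y)
  acc_train <- mean(predict(m, X) == y)
  expect_gte(acc_train, max(prop.table(table(y))))  # beats majority class
})

test_that("metric identities hold and match hand-worked confusions", {
  # perfect predictions
  perfect <- classification_metrics(c("A", "B", "A"), c("A", "B", "A"))
  expect_equal(perfect$accuracy, 100)
  expect_true(all(perfect$per_class[, c("precision", "recall", "f1")] == 100))

  # binary TP=8 FP=2 FN=2 TN=8 -> everything 80%
  truth <- rep(c("P", "N"), each = 10)
  pred <- c(rep("P", 8), rep("N", 2), rep("P", 2), rep("N", 8))
  r <- classification_metrics(truth, pred)
  expect_equal(r$accuracy, 80)
  prow <- r$per_class[r$per_class$class == "P", ]
  expect_equal(prow$precision, 80)
  expect_equal(prow$recall, 80)
  expect_equal(prow$f1, 80)

  # a class never predicted gets precision 0
  r2 <- classification_metrics(c("A", "B"), c("A", "A"))
  expect_equal(r2$per_class$precision[r2$per_class$class == "B"], 0)
  expect_equal(r2$per_class$f1[r2$per_class$class == "B"], 0)
})

test_that("metrics equal a brute-force recount on random prediction sets", {
  set.seed(83)
  for (i in 1:30) {
    k <- sample(2:5, 1)
    n <- sample(20:60, 1)
    cls <- LETTERS[1:k]
    truth <- sample(cls, n, replace = TRUE)
    pred <- sample(cls, n, replace = TRUE)
    r <- classification_metrics(truth, pred, levels = cls)
    expect_equal(r$accuracy, 100 * mean(truth == pred))
    for (cl in cls) {
      tp <- sum(truth == cl & pred == cl)
      fp <- sum(truth != cl & pred == cl)
      fn <- sum(truth == cl & pred != cl)
      row <- r$per_class[r$per_class$class == cl, ]
      expect_equal(row$precision, if (tp + fp == 0) 0 else 100 * tp / (tp + fp))
      expect_equal(row$recall, if (tp + fn == 0) 0 else 100 * tp / (tp + fn))
      if (row$precision + row$recall > 0) {
        expect_equal(row$f1, 2 * row$precision * row$recall /
                       (row$precision + row$recall))
      }
    }
    expect_equal(sum(r$confusion), n)
    expect_equal(as.numeric(rowSums(r$confusion)),
                 as.numeric(table(factor(truth, levels = cls))[cls]))
  }
})

test_that("CV pools each instance exactly once and keeps fold reports", {
  toy <- toy_classification(n = 150, seed = 84)
  rep <- cv_evaluate(model_spec("knn", seed = 1), toy$X, toy$y,
                     partition_spec("CV", k = 5, seed = 2))
  expect_equal(sum(rep$confusion), 150)
  expect_length(rep$per_fold, 5)
  expect_equal(sum(vapply(rep$per_fold, function(f) sum(f$confusion),
                          numeric(1))), 150)
  expect_equal(rep$partition, "CV")
})

test_that("PDP is flat for an ignored feature and sums to one", {
  toy <- toy_classification(n = 200, seed = 85)
  toy$X$ignored <- rnorm(200)  # independent of the labels
  m <- train_model(model_spec("random_forest", list(n_trees = 200),
                              seed = 3), toy$X, toy$y)
  curve <- pdp(m, toy$X, "ignored", n_grid = 20)
  expect_true(all(abs(rowSums(curve$prob) - 1) < 1e-9))
  expect_lt(diff(range(curve$prob[, "AC"])), 0.1)  # flat within MC noise
  expect_true(all(diff(curve$grid) > 0))

  informative <- pdp(m, toy$X, "a", n_grid = 20)
  expect_gt(diff(range(informative$prob[, "AC"])), 0.5)

  toy$X$flat <- 1
  m2 <- train_model(model_spec("knn", seed = 1), toy$X, toy$y)
  expect_warning(single <- pdp(m2, toy$X, "flat"), "constant")
  expect_length(single$grid, 1)
  expect_error(pdp(m, toy$X, "absent"), "not present")
})

test_that("the full task x model x partition matrix runs and reproduces", {
  inst <- sep_instances()
  # stratified subsample keeps the run quick while every class stays viable
  set.seed(86)
  idx <- unlist(lapply(split(seq_len(nrow(inst)),
                             inst$behavior_by_posture),
                       function(i) sample(i, min(length(i), 120))))
  sub <- inst[sort(idx), ]
  sub <- sub[sub$behavior != "DW", ]  # drinking too rare at this scale

  bundle <- run_experiment(sub, models = c("perceptron", "logistic", "svm",
                                           "knn", "random_forest",
                                           "gradient_boosted_trees"),
                           seed = 5)
  for (task in c("states", "general", "fine", "posture",
                 "behavior_by_posture")) {
    for (fam in names(bundle[[task]])) {
      for (part in c("RTS", "CV")) {
        r <- bundle[[task]][[fam]][[part]]
        expect_s3_class(r, "classification_report")
        expect_equal(r$accuracy, 100 * sum(diag(r$confusion)) /
                       sum(r$confusion))
      }
    }
  }
  expect_error(run_experiment(sub, tasks = "nonsense"), "unknown task")
  expect_equal(run_experiment(sub, models = character(0),
                              tasks = "states")$states, NULL)

  # determinism of the bundle under a repeated seed (light slice)
  b1 <- run_experiment(sub, tasks = "states", models = "knn", seed = 6)
  b2 <- run_experiment(sub, tasks = "states", models = "knn", seed = 6)
  expect_identical(b1$states$knn$RTS$confusion, b2$states$knn$RTS$confusion)
  expect_identical(b1$states$knn$CV$confusion, b2$states$knn$CV$confusion)
})
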