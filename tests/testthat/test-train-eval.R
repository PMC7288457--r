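test_that("fold sizes differ by at most one and stratify by label", {
  labels <- rep(c(1L, 0L), each = 1307L)
  fold <- make_folds(labels, k = 10L, seed = 4L)
  sizes <- tabulate(fold, 10L)
  expect_equal(sort(sizes, decreasing = TRUE),
               c(rep(262L, 4), rep(261L, 6)))
  expect_equal(sum(sizes), 2614L)
  # stratification: per-fold positives within one of balance
  pos_per_fold <- tabulate(fold[labels == 1L], 10L)
  expect_lte(diff(range(pos_per_fold)), 1L)
})

test_that("fold assignment is deterministic in the seed", {
  labels <- rep(c(0L, 1L), 50L)
  expect_identical(make_folds(labels, seed = 7L), make_folds(labels, seed = 7L))
  expect_false(identical(make_folds(labels, seed = 7L),
                         make_folds(labels, seed = 8L)))
  expect_error(make_folds(labels[1:5], k = 10L), "exceeds dataset size")
  expect_error(make_folds(labels, k = 1L), "at least 2")
  # plain (unstratified) shuffling still partitions evenly
  f <- make_folds(labels, k = 7L, seed = 1L, stratify = FALSE)
  expect_lte(diff(range(tabulate(f, 7L))), 1L)
})

test_that("the rotation schedule partitions and covers", {
  labels <- rep(c(0L, 1L), 60L)
  fold <- make_folds(labels, k = 10L, seed = 2L)
  tested <- integer(0)
  for (t in 1:10) {
    rot <- fold_rotation(fold, t, 10L)
    expect_length(intersect(rot$train, rot$validation), 0L)
    expect_length(intersect(rot$train, rot$test), 0L)
    expect_length(intersect(rot$validation, rot$test), 0L)
    expect_setequal(c(rot$train, rot$validation, rot$test),
                    seq_along(labels))
    tested <- c(tested, rot$test)
  }
  expect_setequal(tested, seq_along(labels))
  expect_equal(anyDuplicated(tested), 0L)
})

test_that("confusion tallies match a brute-force count", {
  expect_equal(unclass(confusion_from_scores(c(1, 1, 0, 0), c(1, 1, 0, 0))),
               list(TP = 2L, TN = 2L, FP = 0L, FN = 0L),
               ignore_attr = TRUE)
  cm0 <- confusion_from_scores(rep(0, 10), rep(c(1, 0), 5))
  expect_equal(cm0$TN, 5L)
  expect_equal(cm0$FN, 5L)
  set.seed(21)
  scores <- runif(1000)
  labels <- rbinom(1000, 1, 0.4)
  cm <- confusion_from_scores(scores, labels, threshold = 0.3)
  tally <- c(TP = 0L, TN = 0L, FP = 0L, FN = 0L)
  for (i in 1:1000) {
    pred <- scores[i] >= 0.3
    truth <- labels[i] == 1
    key <- if (pred && truth) "TP" else if (!pred && !truth) "TN"
           else if (pred) "FP" else "FN"
    tally[key] <- tally[key] + 1L
  }
  expect_equal(unlist(unclass(cm))[names(tally)], tally)
  expect_error(confusion_from_scores(c(0.2, 1.4), c(1, 0)), "0, 1")
})

test_that("metric formulas match the literal oracle to 1e-12", {
  expect_equal(compute_metrics(list(TP = 25, TN = 25, FP = 25, FN = 25)),
               list(ACC = 0.5, Sn = 0.5, Sp = 0.5, MCC = 0))
  perfect <- compute_metrics(list(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_equal(perfect$ACC, 1)
  expect_equal(perfect$MCC, 1)
  set.seed(5)
  for (i in 1:300) {
    cm <- as.list(setNames(rpois(4, 20), c("TP", "TN", "FP", "FN")))
    got <- compute_metrics(cm)
    want <- metrics_oracle(cm$TP, cm$TN, cm$FP, cm$FN)
    for (nm in c("ACC", "Sn", "Sp", "MCC"))
      expect_equal(got[[nm]], want[[nm]], tolerance = 1e-12)
    expect_gte(got$MCC, -1)
    expect_lte(got$MCC, 1)
    # label flip (swap classes) negates MCC
    flip <- compute_metrics(list(TP = cm$FN, TN = cm$FP,
                                 FP = cm$TN, FN = cm$TP))
    expect_equal(flip$MCC, -got$MCC, tolerance = 1e-12)
  }
  expect_equal(compute_metrics(list(TP = 0, TN = 0, FP = 3, FN = 0))$MCC, 0)
  expect_error(compute_metrics(list(TP = 0, TN = 0, FP = 0, FN = 0)), "empty")
})

test_that("trapezoidal AUC equals pairwise concordance", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.4, 8), rep(c(1, 0), 4))$auc, 0.5)
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
  set.seed(31)
  for (i in 1:50) {
    n <- 50L
    labels <- c(rep(1L, 20L), rep(0L, 30L))
    scores <- round(runif(n), 2)  # force ties
    got <- roc_auc(scores, labels)
    expect_equal(got$auc, concordance_oracle(scores, labels),
                 tolerance = 1e-12)
    expect_equal(got$roc$fpr[1], 0)
    expect_equal(got$roc$tpr[nrow(got$roc)], 1)
  }
})

test_that("AUC of label-independent scores centers on one half", {
  set.seed(44)
  aucs <- vapply(1:50, function(i) {
    roc_auc(runif(10000), rep(c(0L, 1L), 5000L))$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("early stopping halts after patience epochs without improvement", {
  ds <- simulate_dataset(40L, 40L, seed = 3L)
  enc <- encode_dataset(ds)
  tr <- list(x = enc$x[1:60, , , drop = FALSE], y = enc$y[1:60])
  va <- list(x = enc$x[61:80, , , drop = FALSE], y = enc$y[61:80])
  # a vanishing learning rate freezes the model, so the validation metric
  # never improves after epoch 1 and training must stop at epoch 1 + patience
  cfg <- training_config(learning_rate = 1e-12, epochs = 100L,
                         patience = 30L, seed = 1L)
  fit <- train_fold(tiny_spec(c(51L, 4L)), cfg, tr, va)
  expect_equal(fit$best_epoch, 1L)
  expect_equal(nrow(fit$history), 31L)
})

test_that("checkpointed weights reproduce the logged best validation accuracy", {
  ds <- simulate_dataset(60L, 60L, seed = 5L)
  enc <- encode_dataset(ds)
  tr <- list(x = enc$x[1:100, , , drop = FALSE], y = enc$y[1:100])
  va <- list(x = enc$x[101:120, , , drop = FALSE], y = enc$y[101:120])
  fit <- train_fold(default_model_spec(), quick_config(seed = 2L), tr, va)
  re <- mean((predict(fit, va$x) >= 0.5) == (va$y == 1))
  expect_equal(re, fit$best_val_acc)
  expect_equal(fit$best_val_acc, max(fit$history$val_acc))
  expect_error(train_fold(default_model_spec(), quick_config(),
                          list(x = NULL, y = integer(0)), va),
               "empty training set")
})

test_that("training learns a strongly separable planted motif", {
  ds <- simulate_dataset(150L, 150L, seed = 0L)
  enc <- encode_dataset(ds)
  fold <- make_folds(ds$label, k = 5L, seed = 0L)
  rot <- fold_rotation(fold, 1L, 5L)
  fit <- train_fold(default_model_spec(), quick_config(seed = 0L, epochs = 25L,
                                                       patience = 25L),
                    list(x = enc$x[rot$train, , , drop = FALSE],
                         y = enc$y[rot$train]),
                    list(x = enc$x[rot$validation, , , drop = FALSE],
                         y = enc$y[rot$validation]))
  expect_gte(fit$best_val_acc, 0.95)
})

test_that("cross-validation bookkeeping and determinism hold", {
  ds <- simulate_dataset(60L, 60L, seed = 8L)
  cfg <- quick_config(seed = 8L, epochs = 5L, patience = 5L)
  res <- cross_validate(ds, default_model_spec(), cfg, k = 5L)
  expect_s3_class(res, "m6a_cv_result")
  expect_equal(nrow(res$per_fold), 5L)
  expect_equal(unname(res$mean["ACC"]), mean(res$per_fold$ACC))
  expect_equal(unname(res$mean["MCC"]), mean(res$per_fold$MCC))
  expect_false(anyNA(res$scores))  # every record scored out-of-fold once
  res2 <- cross_validate(ds, default_model_spec(), cfg, k = 5L)
  expect_identical(res$per_fold, res2$per_fold)  # bit-for-bit reproducible
  expect_identical(res$scores, res2$scores)
})

test_that("cross-validation artifacts are written and consistent", {
  ds <- simulate_dataset(40L, 40L, seed = 9L)
  res <- cross_validate(ds, default_model_spec(),
                        quick_config(seed = 9L, epochs = 3L, patience = 3L),
                        k = 4L)
  dir <- tempfile()
  paths <- write_cv_result(res, dir)
  expect_true(all(file.exists(paths)))
  tab <- read.delim(paths[["metrics"]])
  expect_equal(nrow(tab), 5L)  # 4 folds + mean
  expect_equal(as.numeric(tab$ACC[5]), unname(res$mean["ACC"]),
               tolerance = 1e-4)
  cms <- read.delim(paths[["confusion"]])
  expect_equal(sum(cms[, c("TP", "FN", "FP", "TN")]), nrow(ds))
  rec <- jsonlite::read_json(paths[["record"]], simplifyVector = TRUE)
  expect_equal(rec$k, 4L)
  expect_length(rec$fold_assignment, nrow(ds))
})
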