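#' Confusion matrix from probability scores
#'
#' Thresholds scores at `threshold` (score >= threshold predicts the
#' positive class) and tallies TP, TN, FP, FN against the 0/1 labels.
#'
#' @param scores Numeric vector of probabilities in `[0, 1]`.
#' @param labels Binary vector (1 = positive).
#' @param threshold Decision threshold (default 0.5).
#' @return An `m6a_confusion` list with fields `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_from_scores <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  if (any(scores < 0 | scores > 1))
    stop("scores must lie in [0, 1]", call. = FALSE)
  if (!all(labels %in% c(0, 1)))
    stop("labels must be 0 or 1", call. = FALSE)
  pred <- scores >= threshold
  pos <- labels == 1
  structure(list(TP = sum(pred & pos), TN = sum(!pred & !pos),
                 FP = sum(pred & !pos), FN = sum(!pred & pos)),
            class = "m6a_confusion")
}

#' @export
print.m6a_confusion <- function(x, ...) {
  cat("confusion matrix (rows = truth, cols = prediction)\n")
  m <- rbind(positive = c(pred_pos = x$TP, pred_neg = x$FN),
             negative = c(pred_pos = x$FP, pred_neg = x$TN))
  print(m)
  invisible(x)
}

#' Threshold-based classification metrics
#'
#' Computes accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)` and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. MCC is defined
#' as 0 when its denominator vanishes; Sn (Sp) is `NaN` only when no
#' positives (negatives) were evaluated.
#'
#' @param cm An `m6a_confusion` (or list with `TP`, `TN`, `FP`, `FN`).
#' @return Named list `ACC`, `Sn`, `Sp`, `MCC`.
#' @export
compute_metrics <- function(cm) {
  tp <- as.numeric(cm$TP); tn <- as.numeric(cm$TN)
  fp <- as.numeric(cm$FP); fn <- as.numeric(cm$FN)
  total <- tp + tn + fp + fn
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  list(ACC = (tp + tn) / total,
       Sn = tp / (tp + fn),
       Sp = tn / (tn + fp),
       MCC = if (den == 0) 0 else (tp * tn - fp * fn) / den)
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over every distinct score and integrates
#' the resulting (FPR, TPR) curve with the trapezoidal rule. This AUC
#' equals the Mann-Whitney concordance probability that a random positive
#' scores above a random negative, with ties counted one half.
#'
#' @param scores Numeric score vector (any real scale).
#' @param labels Binary vector; both classes must be present.
#' @return List with `roc` (data frame `threshold`, `fpr`, `tpr`, ordered
#'   from (0,0) to (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (!all(labels %in% c(0, 1)))
    stop("labels must be 0 or 1", call. = FALSE)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0)
    stop("ROC requires both classes present", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # cumulative counts at each distinct-threshold boundary
  dup <- rev(duplicated(rev(s)))  # TRUE where the next score is identical
  tps <- cumsum(y == 1)[!dup]
  fps <- cumsum(y == 0)[!dup]
  roc <- data.frame(threshold = c(Inf, s[!dup]),
                    fpr = c(0, fps / nn),
                    tpr = c(0, tps / np))
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
  list(roc = roc, auc = auc)
}

metric_names <- c("ACC", "Sn", "Sp", "MCC", "AUC")

#' Stratified (or plain) k-fold assignment
#'
#' Shuffles the records and deals them into `k` folds of sizes differing
#' by at most one. With `stratify = TRUE` (default) the dealing is done
#' within each label class, keeping per-fold class counts within one of
#' balance. Deterministic given `seed`.
#'
#' @param labels Binary label vector (or an `m6a_dataset`).
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @param stratify Balance labels across folds.
#' @return Integer vector of fold indices in `1..k`, one per record.
#' @export
make_folds <- function(labels, k = 10L, seed = 1L, stratify = TRUE) {
  if (inherits(labels, "m6a_dataset")) labels <- labels$label
  n <- length(labels)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (k > n) stop(sprintf("k = %d exceeds dataset size %d", k, n), call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  fold <- integer(n)
  if (stratify) {
    # deal round-robin, continuing the rotation across classes so overall
    # fold sizes also stay within one of each other
    start <- 0L
    for (cls in sort(unique(labels))) {
      idx <- which(labels == cls)
      fold[idx[sample.int(length(idx))]] <-
        (start + seq_along(idx) - 1L) %% k + 1L
      start <- (start + length(idx)) %% k
    }
  } else {
    fold[sample.int(n)] <- rep_len(seq_len(k), n)
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  fold
}

#' The 10-fold train/validation/test rotation
#'
#' For repetition `t` (1-based), the test set is fold `t`, the validation
#' set fold `t %% k + 1`, and the training set the remaining `k - 2`
#' folds. Over the `k` repetitions every record is tested exactly once.
#'
#' @param fold Integer fold assignment from [make_folds()].
#' @param t Repetition index in `1..k`.
#' @param k Number of folds.
#' @return List of integer index vectors `train`, `validation`, `test`.
#' @export
fold_rotation <- function(fold, t, k = max(fold)) {
  stopifnot(t >= 1L, t <= k)
  test_f <- t
  val_f <- t %% k + 1L
  list(train = which(!(fold %in% c(test_f, val_f))),
       validation = which(fold == val_f),
       test = which(fold == test_f))
}

#' k-fold cross-validation of the convolutional classifier
#'
#' Runs `k` independent train/evaluate repetitions under the 8/1/1
#' rotation ([fold_rotation()]): each repetition trains with early
#' stopping on its validation fold ([train_fold()]) and is scored on its
#' test fold only. Per-fold sensitivity, specificity, accuracy, MCC and
#' AUC are reported together with their arithmetic means; a pooled ROC is
#' computed from the out-of-fold scores of all records (each record is
#' scored exactly once, by the repetition that held it out).
#'
#' @param dataset An `m6a_dataset`.
#' @param spec An `m6a_model_spec` (default [default_model_spec()]).
#' @param config A [training_config()]; per-repetition training seeds are
#'   derived from `config$seed`.
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold assignment (defaults to `config$seed`).
#' @param stratify Stratify folds by label (default TRUE).
#' @param threshold Classification threshold (default 0.5).
#' @param verbose Report per-fold progress.
#' @return An `m6a_cv_result`: `per_fold` data frame (one row per
#'   repetition), `mean` (named means of the per-fold metrics),
#'   `confusions`, pooled `scores`/`labels`/`pooled_auc`/`roc`, the fold
#'   assignment, and a config snapshot.
#' @export
cross_validate <- function(dataset, spec = default_model_spec(),
                           config = training_config(), k = 10L,
                           seed = config$seed, stratify = TRUE,
                           threshold = 0.5, verbose = FALSE) {
  stopifnot(inherits(dataset, "m6a_dataset"))
  enc <- encode_dataset(dataset)
  fold <- make_folds(dataset$label, k = k, seed = seed, stratify = stratify)
  n <- nrow(dataset)
  pooled_scores <- rep(NA_real_, n)
  per_fold <- vector("list", k)
  confusions <- vector("list", k)
  for (t in seq_len(k)) {
    rot <- fold_rotation(fold, t, k)
    cfg_t <- config
    cfg_t$seed <- (config$seed + 7919L * t) %% .Machine$integer.max
    sub <- function(i) list(x = enc$x[i, , , drop = FALSE], y = enc$y[i])
    fit <- train_fold(spec, cfg_t, sub(rot$train), sub(rot$validation))
    sc <- predict(fit, enc$x[rot$test, , , drop = FALSE])
    pooled_scores[rot$test] <- sc
    cm <- confusion_from_scores(sc, enc$y[rot$test], threshold = threshold)
    confusions[[t]] <- cm
    mets <- compute_metrics(cm)
    mets$AUC <- roc_auc(sc, enc$y[rot$test])$auc
    per_fold[[t]] <- data.frame(fold = t, Sp = mets$Sp, Sn = mets$Sn,
                                ACC = mets$ACC, MCC = mets$MCC,
                                AUC = mets$AUC,
                                best_epoch = fit$best_epoch,
                                best_val_acc = fit$best_val_acc,
                                seed = cfg_t$seed)
    if (verbose)
      message(sprintf("fold %2d: ACC %.4f  MCC %.4f  AUC %.4f (best epoch %d)",
                      t, mets$ACC, mets$MCC, mets$AUC, fit$best_epoch))
  }
  per_fold <- do.call(rbind, per_fold)
  roc_pooled <- roc_auc(pooled_scores, enc$y)
  structure(list(
    per_fold = per_fold,
    mean = colMeans(per_fold[, c("Sp", "Sn", "ACC", "MCC", "AUC")]),
    confusions = confusions,
    scores = pooled_scores, labels = enc$y,
    pooled_auc = roc_pooled$auc, roc = roc_pooled$roc,
    fold = fold, k = k, seed = seed, stratify = stratify,
    threshold = threshold, config = config),
    class = "m6a_cv_result")
}

#' @export
print.m6a_cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (n = %d, fold seed %d)\n",
              x$k, length(x$labels), x$seed))
  print(round(x$per_fold[, c("fold", "Sp", "Sn", "ACC", "MCC", "AUC")], 4),
        row.names = FALSE)
  cat("mean:  ", paste(sprintf("%s %.4f", names(x$mean), x$mean),
                       collapse = "  "), "\n")
  cat(sprintf("pooled AUC: %.4f\n", x$pooled_auc))
  invisible(x)
}

#' Write cross-validation artifacts
#'
#' Emits the per-fold + mean metric table, pooled ROC points, per-fold
#' 2x2 confusion matrices (all TSV) and a JSON run record holding the
#' configuration, seeds and fold assignment.
#'
#' @param result An `m6a_cv_result`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cv_result <- function(result, dir) {
  stopifnot(inherits(result, "m6a_cv_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- result$per_fold[, c("fold", "Sp", "Sn", "ACC", "MCC", "AUC")]
  mean_row <- data.frame(fold = "mean", t(result$mean))
  tab$fold <- as.character(tab$fold)
  tab <- rbind(tab, mean_row)
  # percentages to two decimals, MCC/AUC to three, matching the reporting style
  paths <- c(metrics = file.path(dir, "metrics.tsv"),
             roc = file.path(dir, "roc.tsv"),
             confusion = file.path(dir, "confusion.tsv"),
             record = file.path(dir, "run_record.json"))
  write.table(format(tab, digits = 6), paths[["metrics"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(result$roc, paths[["roc"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  cms <- do.call(rbind, lapply(seq_along(result$confusions), function(t) {
    cm <- result$confusions[[t]]
    data.frame(fold = t, TP = cm$TP, FN = cm$FN, FP = cm$FP, TN = cm$TN)
  }))
  write.table(cms, paths[["confusion"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(
    k = result$k, seed = result$seed, stratify = result$stratify,
    threshold = result$threshold, config = unclass(result$config),
    mean = as.list(result$mean), pooled_auc = result$pooled_auc,
    fold_assignment = result$fold,
    per_fold_seeds = result$per_fold$seed),
    paths[["record"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
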