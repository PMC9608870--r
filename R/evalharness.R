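#' Leave-one-subject-out folds
#'
#' One fold per subject: the held-out subject's trials form the test set and
#' all other subjects' trials the training pool. Subjects with zero trials
#' are excluded with a warning.
#'
#' @param subject per-trial subject identifiers.
#' @return list of folds, each `list(test_subject, train_subjects,
#'   train_idx, test_idx)`.
#' @export
loocv_folds <- function(subject) {
  subjects <- unique(subject)
  counts <- table(subject)
  empty <- setdiff(subjects, names(counts)[counts > 0])
  if (length(empty)) {
    warn_("excluding subjects with zero trials: ", paste(empty, collapse = ", "))
    subjects <- setdiff(subjects, empty)
  }
  if (length(subjects) < 2L) stop_("need at least 2 subjects for LOOCV")
  lapply(subjects, function(s) {
    list(test_subject = s,
         train_subjects = setdiff(subjects, s),
         train_idx = which(subject != s),
         test_idx = which(subject == s))
  })
}

#' Subsample the majority class to balance a training set
#'
#' The majority class is subsampled without replacement (seeded) down to the
#' minority class count; the minority class is untouched.
#'
#' @param labels 0/1 (or two-level) class labels of the training trials.
#' @param seed integer seed for the subsample.
#' @return integer indices (sorted) of the retained balanced subset.
#' @export
balance_classes <- function(labels, seed = 1L) {
  lv <- unique(labels)
  if (length(lv) != 2L) stop_("both classes must be present to balance")
  idx1 <- which(labels == lv[1])
  idx2 <- which(labels == lv[2])
  if (length(idx1) == length(idx2)) return(sort(c(idx1, idx2)))
  if (length(idx1) < length(idx2)) { minor <- idx1; major <- idx2 }
  else { minor <- idx2; major <- idx1 }
  kept <- with_seed(seed, sample(major, length(minor)))
  sort(c(minor, kept))
}

#' Stratified train/validation split
#'
#' Splits trials into training and validation sets at the trial level,
#' stratified by class. The total validation size is `round(fraction * N)`,
#' apportioned to the classes by largest remainder so that a balanced input
#' yields a validation class ratio within one trial of 1:1.
#'
#' @param ids trial indices (or any vector to split).
#' @param labels class labels parallel to `ids`.
#' @param fraction validation fraction in (0, 1) (default 1/11).
#' @param seed integer seed.
#' @return list with `train` and `val`, each a subset of `ids`.
#' @export
split_validation <- function(ids, labels, fraction = 1 / 11, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop_("fraction must be in (0, 1)")
  stopifnot(length(ids) == length(labels))
  n <- length(ids)
  n_val <- round(fraction * n)
  if (n_val < 1L || n_val >= n) stop_("split would produce an empty set")
  classes <- unique(labels)
  quota <- fraction * as.numeric(table(labels)[as.character(classes)])
  take <- floor(quota)
  rem <- n_val - sum(take)
  if (rem > 0) {
    extra <- order(quota - take, decreasing = TRUE)[seq_len(rem)]
    take[extra] <- take[extra] + 1L
  }
  val <- with_seed(seed, {
    unlist(lapply(seq_along(classes), function(k) {
      pool <- which(labels == classes[k])
      sample(pool, take[k])
    }))
  })
  val <- sort(val)
  list(train = ids[-val], val = ids[val])
}

#' Evaluate a trained model on one held-out subject
#'
#' Probabilities are thresholded at 0.5 (ties to the patient class);
#' confusion counts treat patient (label 1) as positive.
#'
#' @param model a trained `cnn_model` (or any object with a `predict`
#'   method returning probabilities).
#' @param x_test,y_test held-out images and 0/1 labels.
#' @param subject held-out subject id (recorded in the result).
#' @return object of class `fold_result`: list with `subject`, `prob`,
#'   `label`, `pred`, `tp`, `fp`, `tn`, `fn`, `accuracy`, `n`.
#' @export
evaluate_fold <- function(model, x_test, y_test, subject = NA) {
  prob <- if (is.numeric(model)) model else predict(model, x_test)
  pred <- as.numeric(prob >= 0.5)
  tp <- sum(pred == 1 & y_test == 1)
  fp <- sum(pred == 1 & y_test == 0)
  tn <- sum(pred == 0 & y_test == 0)
  fn <- sum(pred == 0 & y_test == 1)
  structure(
    list(subject = subject, prob = prob, label = y_test, pred = pred,
         tp = tp, fp = fp, tn = tn, fn = fn,
         accuracy = (tp + tn) / length(y_test), n = length(y_test)),
    class = "fold_result"
  )
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("Fold %s: n=%d acc=%.3f (TP=%d FP=%d TN=%d FN=%d)\n",
              x$subject, x$n, x$accuracy, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the unique predicted probabilities as thresholds, computing the
#' true- and false-positive rates, and integrates the curve by the
#' trapezoidal rule. Tied scores are collapsed into a single sweep point,
#' which makes the AUC equal to the pairwise concordance probability
#' (the Mann-Whitney statistic with ties counted 1/2).
#'
#' @param prob predicted probabilities (or any monotone scores).
#' @param label 0/1 labels; both classes must be present.
#' @return object of class `roc_curve`: list with `fpr`, `tpr`,
#'   `thresholds`, `auc`.
#' @export
roc_curve <- function(prob, label) {
  stopifnot(length(prob) == length(label))
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  if (n1 == 0L || n0 == 0L) stop_("ROC requires both classes present")
  ord <- order(prob, decreasing = TRUE)
  p <- prob[ord]; y <- label[ord]
  grp <- cumsum(!duplicated(p))            # tie groups of equal score
  tp_g <- rowsum(as.numeric(y == 1), grp)[, 1]
  fp_g <- rowsum(as.numeric(y == 0), grp)[, 1]
  tpr <- c(0, cumsum(tp_g) / n1)
  fpr <- c(0, cumsum(fp_g) / n0)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(
    list(fpr = fpr, tpr = tpr,
         thresholds = c(Inf, p[!duplicated(p)]), auc = auc),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d sweep points, AUC = %.4f\n",
              length(x$fpr), x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(x$fpr, x$tpr, type = "l", xlab = "False positive rate",
       ylab = "True positive rate",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  abline(0, 1, lty = 3)
  invisible(x)
}

#' Leave-one-subject-out cross-validation of the CNN classifier
#'
#' For each fold: the held-out subject's trials are the test set; the
#' remaining trials are class-balanced by majority subsampling, split into
#' training and validation sets (stratified, default 1/11), and a freshly
#' initialized CNN is trained with early stopping. Balancing, splitting,
#' initialization and training use fold-indexed seeds derived from `seed`,
#' so reruns are bit-reproducible. An optional learning-rate grid is searched
#' per fold.
#'
#' @param images a `trial_images` object (or matrix n x pixels).
#' @param subject,group per-trial subject ids and `"control"`/`"patient"`
#'   labels; taken from `images` when it is a `trial_images` object.
#' @param channels,hidden architecture plan passed to [build_cnn()].
#' @param lr learning rate, or a numeric vector to grid-search per fold.
#' @param val_fraction validation fraction (default 1/11).
#' @param batch_size,max_epochs,patience training controls; see [train_cnn()].
#' @param seed master seed.
#' @param verbose print fold progress.
#' @return object of class `loocv_result`: list with `folds`
#'   (list of `fold_result`), `per_subject` (data frame), `accuracy_mean`,
#'   `accuracy_sd`, `confusion` (pooled TP/FP/TN/FN), `roc`
#'   (pooled `roc_curve`), `predictions` (pooled data frame).
#' @export
crossval_cnn <- function(images, subject = NULL, group = NULL,
                         channels = c(64, 128), hidden = c(256, 64),
                         lr = 1e-3, val_fraction = 1 / 11,
                         batch_size = 64L, max_epochs = 300L, patience = 20L,
                         seed = 1L, verbose = FALSE) {
  if (inherits(images, "trial_images")) {
    subject <- subject %||% images$subject
    group <- group %||% images$group
    dims <- images$image_dim
    x <- images$images
  } else {
    x <- as.matrix(images)
    if (is.null(subject) || is.null(group)) {
      stop_("subject and group are required when images is a plain matrix")
    }
    dims <- NULL
  }
  y <- as.numeric(group == "patient")
  folds <- loocv_folds(subject)

  results <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    fseed <- derive_seed(seed, f)
    tr_idx <- fold$train_idx
    bal <- balance_classes(y[tr_idx], seed = fseed)
    tr_idx <- tr_idx[bal]
    sp <- split_validation(tr_idx, y[tr_idx], fraction = val_fraction,
                           seed = fseed + 1L)
    input_shape <- dims %||% c(1L, ncol(x))
    builder <- function() build_cnn(input_shape, channels, hidden,
                                    seed = fseed + 2L)
    if (length(lr) > 1L) {
      gs <- grid_search_lr(builder, x[tr_idx, , drop = FALSE], y[tr_idx],
                           grid = lr, val_fraction = val_fraction,
                           seed = fseed + 3L, batch_size = batch_size,
                           max_epochs = max_epochs, patience = patience)
      lr_f <- gs$lr
    } else {
      lr_f <- lr
    }
    fit <- train_cnn(builder(), x[sp$train, , drop = FALSE], y[sp$train],
                     x[sp$val, , drop = FALSE], y[sp$val],
                     lr = lr_f, batch_size = batch_size,
                     max_epochs = max_epochs, patience = patience,
                     seed = fseed + 4L)
    res <- evaluate_fold(fit$model, x[fold$test_idx, , drop = FALSE],
                         y[fold$test_idx], subject = fold$test_subject)
    res$model <- fit$model
    res$lr <- lr_f
    res$best_epoch <- fit$best_epoch
    res$test_idx <- fold$test_idx
    results[[f]] <- res
    if (verbose) {
      message(sprintf("fold %2d (%s): acc %.3f (lr %g, best epoch %d)",
                      f, fold$test_subject, res$accuracy, lr_f,
                      fit$best_epoch))
    }
  }

  per_subject <- data.frame(
    subject = vapply(results, function(r) as.character(r$subject), character(1)),
    n_trials = vapply(results, `[[`, numeric(1), "n"),
    accuracy = vapply(results, `[[`, numeric(1), "accuracy"),
    tp = vapply(results, `[[`, numeric(1), "tp"),
    fp = vapply(results, `[[`, numeric(1), "fp"),
    tn = vapply(results, `[[`, numeric(1), "tn"),
    fn = vapply(results, `[[`, numeric(1), "fn"),
    stringsAsFactors = FALSE
  )
  prob_all <- unlist(lapply(results, `[[`, "prob"))
  label_all <- unlist(lapply(results, `[[`, "label"))
  idx_all <- unlist(lapply(results, `[[`, "test_idx"))
  predictions <- data.frame(trial = idx_all, prob = prob_all,
                            label = label_all)[order(idx_all), ]

  structure(
    list(folds = results, per_subject = per_subject,
         accuracy_mean = mean(per_subject$accuracy),
         accuracy_sd = sd(per_subject$accuracy),
         confusion = c(tp = sum(per_subject$tp), fp = sum(per_subject$fp),
                       tn = sum(per_subject$tn), fn = sum(per_subject$fn)),
         roc = roc_curve(prob_all, label_all),
         predictions = predictions, seed = seed),
    class = "loocv_result"
  )
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("LOOCV over %d subjects: mean accuracy %.3f +/- %.3f, AUC %.3f\n",
              nrow(x$per_subject), x$accuracy_mean, x$accuracy_sd, x$roc$auc))
  cat("Pooled confusion: ",
      sprintf("TP=%d FP=%d TN=%d FN=%d\n", x$confusion["tp"], x$confusion["fp"],
              x$confusion["tn"], x$confusion["fn"]))
  invisible(x)
}
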