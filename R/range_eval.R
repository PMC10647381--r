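#' Median-of-halves quartiles
#'
#' Quartiles by the median-of-halves rule: Q2 is the median of the
#' rank-ordered values; Q1 and Q3 are the medians ("middle values") of the
#' lower and upper halves, with the overall median excluded from both halves
#' when n is odd. This differs from interpolation-based quantile definitions
#' (e.g. `quantile()` type 7), so it is implemented explicitly.
#'
#' @param x Numeric vector, length >= 4.
#' @return Named numeric vector `c(q1, q2, q3)`.
#' @examples
#' quartiles_moh(1:8)  # 2.5 4.5 6.5
#' quartiles_moh(1:5)  # 1.5 3.0 4.5
#' @export
quartiles_moh <- function(x) {
  if (length(x) < 4) stop("need at least 4 values for quartiles")
  x <- sort(x)
  n <- length(x)
  half <- n %/% 2
  lower <- x[1:half]
  upper <- x[(n - half + 1):n]
  c(q1 = median(lower), q2 = median(x), q3 = median(upper))
}

#' Per-group quartile normal ranges
#'
#' Estimates the quartile normal range of an HRV parameter in each age-group
#' x gender cell. With only 12 discrete input combinations, per-group
#' quantile estimation is the deterministic equivalent of any regression model
#' trained on (age group, gender) inputs, so the lookup itself is the
#' predictor. Groups with fewer than 4 values are omitted.
#'
#' @param data A data frame of per-subject values with columns `age`,
#'   `gender`, and the parameter column.
#' @param param Name of the parameter column (string or tidy-eval column).
#' @return A tibble with `age_group`, `gender`, `parameter`, `n`, `q1`, `q2`,
#'   `q3`, `mean`.
#' @export
group_quartiles <- function(data, param) {
  pname <- if (is.character(substitute(param))) param else rlang::as_name(rlang::enquo(param))
  vals <- data[[pname]]
  d <- tibble(age_group = age_group(data$age), gender = data$gender, value = vals)
  d <- d[complete.cases(d), ]
  d <- d |>
    group_by(.data$age_group, .data$gender) |>
    filter(n() >= 4) |>
    ungroup()
  if (nrow(d) == 0) {
    return(tibble(age_group = factor(levels = AGE_GROUP_LEVELS)[0],
                  gender = character(), parameter = character(),
                  n = integer(), q1 = double(), q2 = double(), q3 = double(),
                  mean = double()))
  }
  d |>
    group_by(.data$age_group, .data$gender) |>
    summarise(
      parameter = pname, n = n(),
      q1 = quartiles_moh(.data$value)[["q1"]],
      q2 = quartiles_moh(.data$value)[["q2"]],
      q3 = quartiles_moh(.data$value)[["q3"]],
      mean = mean(.data$value),
      .groups = "drop"
    )
}

#' Rank bins induced by reference quartiles
#'
#' The reference quartiles split the value axis into 4 rank bins:
#' 1 = (-Inf, q1], 2 = (q1, q2], 3 = (q2, q3], 4 = (q3, Inf) (right-closed at
#' each quartile).
#'
#' @param value Numeric vector of measured values.
#' @param reference Named vector or one-row data frame with `q1`, `q2`, `q3`.
#' @return Integer bin indices in 1..4.
#' @export
rank_bin <- function(value, reference) {
  q <- ref_quartiles(reference)
  1L + (value > q[1]) + (value > q[2]) + (value > q[3])
}

ref_quartiles <- function(reference) {
  if (is.data.frame(reference)) reference <- unlist(reference[1, c("q1", "q2", "q3")])
  q <- as.numeric(reference[c("q1", "q2", "q3")])
  if (any(is.na(q)) || is.unsorted(q)) stop("reference must supply sorted q1 <= q2 <= q3")
  q
}

#' Rank-based evaluation of a predicted range
#'
#' Scores one measured value against a predicted set of rank bins, in the
#' 4-bin universe defined by the reference quartiles: TP = 1 if the measured
#' bin was predicted; FP counts predicted bins that were not measured; FN = 1
#' if the measured bin was not predicted; TN the bins neither predicted nor
#' measured. Each sample therefore contributes tp + fp + fn + tn = 4, and
#' counts aggregate by summation.
#'
#' The predicted bins may be given explicitly (integer subset of 1..4) or as a
#' predicted quartile range, in which case the bins covered by the predicted
#' `[q1, q3]` interval (inclusive sweep from the bin of `q1` to the bin of
#' `q3`) are used.
#'
#' @param measured_value A single measured value.
#' @param reference The reference [group_quartiles()] row defining the bins.
#' @param predicted Either an integer vector of predicted bins (possibly
#'   empty) or a predicted quartile range (`q1`, `q2`, `q3`).
#' @return A one-row tibble: `tp`, `fp`, `fn`, `tn`.
#' @export
rank_eval <- function(measured_value, reference, predicted) {
  if (is.numeric(predicted) && is.null(names(predicted)) &&
      !is.data.frame(predicted) && all(predicted == round(predicted)) &&
      (length(predicted) == 0 || all(predicted %in% 1:4))) {
    bins <- unique(as.integer(predicted))
  } else {
    pq <- ref_quartiles(predicted)
    bins <- seq(rank_bin(pq[1], reference), rank_bin(pq[3], reference))
  }
  measured <- rank_bin(measured_value, reference)
  tp <- as.integer(measured %in% bins)
  fp <- length(bins) - tp
  fn <- 1L - tp
  tn <- 4L - tp - fp - fn
  tibble(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Rates from aggregated rank-evaluation counts
#'
#' @param counts A data frame with columns `tp`, `fp`, `fn`, `tn` (rows are
#'   summed first).
#' @return A one-row tibble with the summed counts plus `tpr`, `fpr`, `ppv`,
#'   `f1` (`NA` where the denominator is 0).
#' @export
eval_rates <- function(counts) {
  tp <- sum(counts$tp); fp <- sum(counts$fp)
  fn <- sum(counts$fn); tn <- sum(counts$tn)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  fpr <- if (fp + tn > 0) fp / (fp + tn) else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(tpr) && !is.na(ppv)) f1_from_rates(tpr, ppv) else NA_real_
  tibble(tp = tp, fp = fp, fn = fn, tn = tn,
         tpr = tpr, fpr = fpr, ppv = ppv, f1 = f1)
}

#' F1 score from TPR and PPV
#'
#' The harmonic mean of sensitivity (TPR, recall) and precision (PPV). By
#' convention, returns 0 when both rates are 0.
#'
#' @param tpr,ppv Rates in [0, 1].
#' @return `2 * tpr * ppv / (tpr + ppv)`.
#' @export
f1_from_rates <- function(tpr, ppv) {
  stopifnot(tpr >= 0, tpr <= 1, ppv >= 0, ppv <= 1)
  ifelse(tpr + ppv == 0, 0, 2 * tpr * ppv / (tpr + ppv))
}

#' Metrics from a confusion matrix
#'
#' @param confusion A K x K non-negative count matrix, rows = true classes,
#'   columns = predicted classes.
#' @return A list with `accuracy`, a per-class tibble (`class`, `recall`,
#'   `precision`, `f1`), and macro averages (`macro_recall`,
#'   `macro_precision`, `macro_f1`). Classes with a zero row (recall) or zero
#'   column (precision) are undefined there and excluded from the macro
#'   average with a warning.
#' @export
classification_metrics <- function(confusion) {
  m <- as.matrix(confusion)
  stopifnot(nrow(m) == ncol(m), all(m >= 0))
  classes <- rownames(m) %||% as.character(seq_len(nrow(m)))
  total <- sum(m)
  if (total == 0) stop("empty confusion matrix")
  recall <- diag(m) / rowSums(m)
  precision <- diag(m) / colSums(m)
  f1 <- 2 * recall * precision / (recall + precision)
  f1[is.nan(f1)] <- NA_real_
  recall[rowSums(m) == 0] <- NA_real_
  precision[colSums(m) == 0] <- NA_real_
  if (anyNA(c(recall, precision))) {
    warning("class with empty row/column excluded from macro averages")
  }
  list(
    accuracy = sum(diag(m)) / total,
    per_class = tibble(class = classes, recall = unname(recall),
                       precision = unname(precision), f1 = unname(f1)),
    macro_recall = mean(recall, na.rm = TRUE),
    macro_precision = mean(precision, na.rm = TRUE),
    macro_f1 = mean(f1, na.rm = TRUE)
  )
}

#' Area under the ROC curve
#'
#' Rank-based AUC: the probability that a randomly chosen positive outscores a
#' randomly chosen negative, with ties counted one half (the Mann-Whitney
#' identity). For a multiclass problem, pass a score matrix with one column
#' per class; the result is the unweighted (macro) mean of the one-vs-rest
#' AUCs.
#'
#' @param scores Numeric vector (binary) or matrix/data frame with one column
#'   per class (multiclass, columns named by class).
#' @param labels Vector of 0/1 (binary) or class labels matching the score
#'   columns.
#' @return A single AUC value.
#' @export
roc_auc <- function(scores, labels) {
  if (is.matrix(scores) || is.data.frame(scores)) {
    scores <- as.matrix(scores)
    classes <- colnames(scores)
    present <- intersect(classes, unique(as.character(labels)))
    if (length(present) < 2) stop("need at least 2 classes present")
    aucs <- vapply(present, function(cl) {
      auc_binary(scores[, cl], as.integer(as.character(labels) == cl))
    }, 0)
    mean(aucs)
  } else {
    auc_binary(scores, labels)
  }
}

auc_binary <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Regression error metrics
#'
#' @param y,yhat Observed and predicted values (equal length, n >= 1).
#' @return A one-row tibble with `mse`, `rmse`, `mae`.
#' @export
regression_metrics <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  if (length(y) == 0) stop("need at least one pair")
  mse <- mean((y - yhat)^2)
  tibble(mse = mse, rmse = sqrt(mse), mae = mean(abs(y - yhat)))
}

#' Cross-validated glucose-regulation classification harness
#'
#' Stratified k-fold cross-validation of a classifier predicting the
#' ND/GD/BD glucose-regulation class from the four HRV features the detector
#' uses (Average/Combined SDNN and RMSSD). The learner is pluggable; the
#' default is a random forest. Macro F1 is the headline metric, appropriate
#' under the strong class imbalance of such cohorts; the pooled (summed over
#' folds) confusion matrix is reported alongside per-fold metrics.
#'
#' @param features A data frame of numeric feature columns (typically
#'   `a_sdnn`, `a_rmssd`, `c_sdnn`, `c_rmssd`).
#' @param labels Class labels (factor or character), one per row.
#' @param folds Number of CV folds (default 10); reduced with a warning if
#'   the rarest class has fewer samples.
#' @param learner A list with `fit(x, y)` returning a model and
#'   `predict(model, x)` returning a list with `class` (labels) and `prob`
#'   (matrix with one column per class). Default [learner_random_forest()].
#' @param seed Seed controlling fold assignment (and the default learner).
#' @return A list: `confusion` (pooled K x K matrix), `metrics`
#'   ([classification_metrics()] of the pooled matrix), `auc` (macro
#'   one-vs-rest on pooled out-of-fold scores), `per_fold` (tibble of
#'   per-fold accuracy and macro F1), `folds`.
#' @export
gluco_classify <- function(features, labels, folds = 10,
                           learner = learner_random_forest(), seed = 1L) {
  x <- as.data.frame(features)
  y <- factor(labels)
  stopifnot(nrow(x) == length(y))
  if (nlevels(droplevels(y)) < 2) stop("need at least 2 classes")
  y <- droplevels(y)
  min_class <- min(table(y))
  if (min_class < folds) {
    warning("rarest class has ", min_class, " samples; reducing folds")
    folds <- max(2L, min_class)
  }
  set.seed(seed)
  fold_id <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  classes <- levels(y)
  confusion <- matrix(0L, nlevels(y), nlevels(y), dimnames = list(classes, classes))
  prob_all <- matrix(NA_real_, length(y), nlevels(y), dimnames = list(NULL, classes))
  pred_all <- factor(rep(NA_character_, length(y)), levels = classes)
  per_fold <- vector("list", folds)
  for (k in seq_len(folds)) {
    test <- fold_id == k
    model <- learner$fit(x[!test, , drop = FALSE], y[!test])
    out <- learner$predict(model, x[test, , drop = FALSE])
    pred <- factor(as.character(out$class), levels = classes)
    pred_all[test] <- pred
    prob_all[test, ] <- as.matrix(out$prob)[, classes]
    tab <- table(true = y[test], pred = pred)
    confusion <- confusion + as.matrix(tab)
    mk <- classification_metrics(as.matrix(tab))
    per_fold[[k]] <- tibble(fold = k, accuracy = mk$accuracy,
                            macro_f1 = mk$macro_f1)
  }
  list(
    confusion = confusion,
    metrics = classification_metrics(confusion),
    auc = roc_auc(prob_all, y),
    per_fold = dplyr::bind_rows(per_fold),
    folds = folds
  )
}

#' Random-forest reference learner
#'
#' The default pluggable learner for [gluco_classify()]: a bagged
#' randomized-tree ensemble, the family of model that performs best on this
#' task.
#'
#' @param ntree Number of trees (default 200).
#' @return A learner list with `fit` and `predict`.
#' @export
learner_random_forest <- function(ntree = 200) {
  list(
    fit = function(x, y) randomForest::randomForest(x, y, ntree = ntree),
    predict = function(model, x) {
      list(class = predict(model, x, type = "response"),
           prob = predict(model, x, type = "prob"))
    }
  )
}
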