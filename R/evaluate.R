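# Evaluation suite: confusion matrices, accuracy/precision/recall/F1 with
# one-vs-rest reductions, ROC by threshold sweep, repeated-run statistics, an
# exact-binomial McNemar test, and bootstrap confidence intervals for paired
# metric differences.

#' Confusion matrix of predicted against true labels
#'
#' @param true_labels,pred_labels Equal-length label vectors.
#' @param class_order Fixed class ordering for rows (true) and columns
#'   (predicted).
#' @return Integer matrix of counts.
#' @export
confusion <- function(true_labels, pred_labels, class_order) {
  if (length(true_labels) != length(pred_labels)) stop("label vectors differ in length")
  bad <- setdiff(unique(c(true_labels, pred_labels)), class_order)
  if (length(bad) > 0) stop("unknown label(s): ", paste(bad, collapse = ", "))
  tt <- table(factor(true_labels, levels = class_order),
              factor(pred_labels, levels = class_order))
  m <- matrix(as.integer(tt), length(class_order), length(class_order),
              dimnames = list(true = class_order, predicted = class_order))
  m
}

#' Accuracy, precision, recall and F1 from a confusion matrix
#'
#' One-vs-rest reduction against `positive_class`:
#' accuracy (TP+TN)/(TP+FP+TN+FN), precision TP/(TP+FP), recall TP/(TP+FN),
#' F1 the harmonic mean of precision and recall. Ratios with zero denominator
#' are returned as `NA` with a warning, never silently coerced to 0.
#'
#' @param cm Confusion matrix from [confusion()].
#' @param positive_class The class treated as positive.
#' @return Named list `accuracy`, `precision`, `recall`, `f1`.
#' @export
metrics <- function(cm, positive_class) {
  stopifnot(positive_class %in% rownames(cm))
  i <- match(positive_class, rownames(cm))
  tp <- cm[i, i]
  fp <- sum(cm[-i, i])
  fn <- sum(cm[i, -i])
  tn <- sum(cm[-i, -i])
  total <- tp + fp + tn + fn
  safe_ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator) for class '", positive_class, "'")
      return(NA_real_)
    }
    num / den
  }
  acc <- safe_ratio(tp + tn, total, "accuracy")
  prec <- safe_ratio(tp, tp + fp, "precision")
  rec <- safe_ratio(tp, tp + fn, "recall")
  f1 <- if (is.na(prec) || is.na(rec) || (prec + rec) == 0) {
    if (!is.na(prec) && !is.na(rec)) warning("F1 undefined for class '", positive_class, "'")
    NA_real_
  } else {
    2 * prec * rec / (prec + rec)
  }
  list(accuracy = acc, precision = prec, recall = rec, f1 = f1)
}

#' Overall (micro) accuracy of a confusion matrix
#'
#' @param cm Confusion matrix.
#' @return Trace divided by total count.
#' @export
overall_accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) return(NA_real_)
  sum(diag(cm)) / total
}

#' ROC curve and area by threshold sweep
#'
#' Sweeps every distinct score as a threshold (predict positive when
#' `score >= threshold`), returns ordered (FPR, TPR) points including (0,0)
#' and (1,1), and the area under the curve by the trapezoid rule.
#'
#' @param scores Positive-class probabilities in `[0, 1]`.
#' @param true_labels Binary labels.
#' @param positive_class Which label counts as positive.
#' @return List with `points` (data frame `fpr`, `tpr`) and `auc`.
#' @export
roc <- function(scores, true_labels, positive_class = "abnormal") {
  stopifnot(length(scores) == length(true_labels))
  pos <- true_labels == positive_class
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) stop("ROC needs both classes present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & pos) / n_pos, numeric(1L))
  fpr <- vapply(thr, function(t) sum(scores >= t & !pos) / n_neg, numeric(1L))
  fpr <- c(0, fpr, 1)
  tpr <- c(0, tpr, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Mean, standard deviation and normal-approximation confidence interval
#'
#' Sample mean, sample sd (n-1 denominator) and CI
#' `mean +/- z * sd / sqrt(R)` over repeated-run metric values.
#'
#' @param values Numeric vector of per-run metric values.
#' @param confidence Confidence level.
#' @return List `mean`, `sd`, `ci` (length-2) — `sd`/`ci` are `NA` with a
#'   warning when fewer than two values are supplied.
#' @export
run_stats <- function(values, confidence = 0.95) {
  m <- mean(values)
  if (length(values) < 2L) {
    warning("need at least two runs for sd and CI")
    return(list(mean = m, sd = NA_real_, ci = c(NA_real_, NA_real_)))
  }
  s <- stats::sd(values)
  z <- stats::qnorm((1 + confidence) / 2)
  half <- z * s / sqrt(length(values))
  list(mean = m, sd = s, ci = c(m - half, m + half))
}

#' Exact McNemar test on paired classifier predictions
#'
#' Counts discordant pairs — `b` rows where A is correct and B wrong, `c` the
#' converse — and computes the exact two-sided binomial p-value
#' `min(1, 2 * P(X <= min(b, c)))` with `X ~ Binomial(b + c, 1/2)`.
#'
#' @param pred_a,pred_b Predictions of the two classifiers.
#' @param true_labels True labels.
#' @return List `b`, `c`, `p_value`.
#' @export
mcnemar_exact <- function(pred_a, pred_b, true_labels) {
  n <- length(true_labels)
  stopifnot(length(pred_a) == n, length(pred_b) == n)
  ok_a <- pred_a == true_labels
  ok_b <- pred_b == true_labels
  b <- sum(ok_a & !ok_b)
  cc <- sum(!ok_a & ok_b)
  if (b + cc == 0) {
    warning("no discordant pairs; p-value set to 1")
    return(list(b = b, c = cc, p_value = 1))
  }
  p <- min(1, 2 * stats::pbinom(min(b, cc), b + cc, 0.5))
  list(b = b, c = cc, p_value = p)
}

#' Bootstrap confidence interval of a paired metric difference
#'
#' Percentile CI of `metric(A) - metric(B)` over paired row resampling with
#' replacement. Resamples on which the metric is undefined (`NA`) are redrawn;
#' the redraw count is attached as an attribute.
#'
#' @param metric_fn Function `(pred, truth) -> scalar` (e.g. accuracy).
#' @param pred_a,pred_b Predictions of the two classifiers.
#' @param true_labels True labels.
#' @param resamples Number of bootstrap resamples.
#' @param confidence Confidence level.
#' @param seed Integer seed.
#' @return Length-2 CI vector with attributes `resamples` and `redraws`.
#' @export
bootstrap_diff_ci <- function(metric_fn, pred_a, pred_b, true_labels,
                              resamples = 10000L, confidence = 0.95,
                              seed = 1L) {
  n <- length(true_labels)
  stopifnot(length(pred_a) == n, length(pred_b) == n, n > 0)
  set.seed(as.integer(seed))
  diffs <- numeric(resamples)
  redraws <- 0L
  for (i in seq_len(resamples)) {
    repeat {
      ix <- sample.int(n, n, replace = TRUE)
      da <- metric_fn(pred_a[ix], true_labels[ix])
      db <- metric_fn(pred_b[ix], true_labels[ix])
      if (!is.na(da) && !is.na(db)) break
      redraws <- redraws + 1L
      if (redraws > 100L * resamples) stop("metric undefined on nearly all resamples")
    }
    diffs[i] <- da - db
  }
  alpha <- (1 - confidence) / 2
  ci <- unname(stats::quantile(diffs, c(alpha, 1 - alpha), type = 7))
  attr(ci, "resamples") <- resamples
  attr(ci, "redraws") <- redraws
  ci
}

#' Single-run evaluation report
#'
#' Confusion matrix, overall accuracy, per-class one-vs-rest metrics, and —
#' when probabilities are supplied and the task has an abnormal/positive
#' class — the ROC area.
#'
#' @param true_labels,pred_labels Label vectors.
#' @param prob Optional probability matrix (columns named by class).
#' @param class_order Class ordering.
#' @return An `eval_report` list.
#' @export
eval_report <- function(true_labels, pred_labels, prob = NULL, class_order) {
  cm <- confusion(true_labels, pred_labels, class_order)
  per_class <- lapply(stats::setNames(class_order, class_order), function(cls) {
    suppressWarnings(metrics(cm, cls))
  })
  auc <- NA_real_
  if (!is.null(prob) && "abnormal" %in% class_order &&
      length(unique(true_labels)) == 2L) {
    auc <- roc(prob[, "abnormal"], true_labels, "abnormal")$auc
  }
  structure(list(confusion = cm, accuracy = overall_accuracy(cm),
                 per_class = per_class, auc = auc, n = length(true_labels)),
            class = "eval_report")
}

# Aggregate R single-run reports into best-run + statistics (selection on
# overall test accuracy, mirroring the best-detection-rate protocol).
summarize_runs <- function(runs, tag, family, head, task, confidence = 0.95) {
  acc <- vapply(runs, `[[`, numeric(1L), "accuracy")
  best_i <- which.max(acc)
  per_metric <- function(extract) {
    vals <- vapply(runs, extract, numeric(1L))
    vals <- vals[!is.na(vals)]  # undefined metrics (e.g. no predicted positives) drop out
    if (length(vals) == 0L) {
      list(mean = NA_real_, sd = NA_real_, ci = c(NA_real_, NA_real_))
    } else if (length(vals) >= 2L) {
      run_stats(vals, confidence)
    } else {
      list(mean = vals, sd = NA_real_, ci = c(NA_real_, NA_real_))
    }
  }
  stats_list <- list(accuracy = per_metric(function(r) r$accuracy))
  classes <- names(runs[[1L]]$per_class)
  for (cls in classes) {
    for (m in c("precision", "recall", "f1")) {
      stats_list[[paste(cls, m, sep = "_")]] <-
        per_metric(function(r) r$per_class[[cls]][[m]])
    }
  }
  list(tag = tag, family = family, head = head, task = task,
       n_runs = length(runs), best = runs[[best_i]], best_run = best_i,
       stats = stats_list)
}

#' Compare two models' predictions statistically
#'
#' McNemar's exact test on correctness plus a bootstrap CI of the accuracy
#' difference.
#'
#' @param pred_a,pred_b Predictions.
#' @param true_labels True labels.
#' @param resamples Bootstrap resamples.
#' @param seed Integer seed.
#' @return List with `mcnemar` and `accuracy_diff_ci`.
#' @export
compare_models <- function(pred_a, pred_b, true_labels, resamples = 10000L,
                           seed = 1L) {
  acc_fn <- function(pred, truth) mean(pred == truth)
  list(
    mcnemar = mcnemar_exact(pred_a, pred_b, true_labels),
    accuracy_diff_ci = bootstrap_diff_ci(acc_fn, pred_a, pred_b, true_labels,
                                         resamples = resamples, seed = seed)
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d, accuracy = %.3f", x$n, x$accuracy))
  if (!is.na(x$auc)) cat(sprintf(", AUC = %.3f", x$auc))
  cat("\n")
  for (cls in names(x$per_class)) {
    pc <- x$per_class[[cls]]
    cat(sprintf("  %-12s P=%.3f R=%.3f F1=%.3f\n", cls,
                pc$precision, pc$recall, pc$f1))
  }
  invisible(x)
}
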