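# FHR signal cleaning and feature conditioning: outlier trimming,
# prefix-median imputation of missing segments, decentralization
# D(t) = S0(t) - B(t), clinical mean-imputation and zero-mean standardization,
# and CTG/clinical feature fusion into a model-ready matrix.

#' Trim out-of-range samples from a trace
#'
#' Removes maximal leading and trailing runs of out-of-range FHR samples and
#' converts interior out-of-range samples to missing values.
#'
#' @param trace A `ctg_trace` (see [generate_trace()]).
#' @param valid_range Two-element numeric interval of trustworthy FHR values
#'   in bpm.
#' @return The trimmed `ctg_trace`.
#' @export
trim_outliers <- function(trace, valid_range = c(50, 210)) {
  stopifnot(inherits(trace, "ctg_trace"), length(valid_range) == 2L,
            valid_range[1] < valid_range[2])
  ok <- !is.na(trace$s0) & trace$s0 >= valid_range[1] & trace$s0 <= valid_range[2]
  first <- which(ok)[1L]
  last <- rev(which(ok))[1L]
  if (is.na(first)) stop("entire trace out of range")
  idx <- first:last
  s0 <- trace$s0[idx]
  bad <- !is.na(s0) & (s0 < valid_range[1] | s0 > valid_range[2])
  s0[bad] <- NA_real_
  trace$s0 <- s0
  trace$baseline <- trace$baseline[idx]
  trace$t <- trace$t[idx]
  trace
}

#' Prefix-median imputation of missing segments
#'
#' Missing segments are processed left to right; every sample of a segment
#' starting at index `st` is replaced by the median of the values before `st`
#' (which include values imputed for earlier segments). Observed samples are
#' never modified, so the operation is idempotent.
#'
#' @param x Numeric vector with `NA` marking missing samples; the first sample
#'   must be observed.
#' @return `x` with no missing values.
#' @export
impute_median <- function(x) {
  if (length(x) == 0L) return(x)
  if (is.na(x[1L])) stop("signal must not start with a missing value")
  i <- 1L
  n <- length(x)
  while (i <= n) {
    if (is.na(x[i])) {
      j <- i
      while (j < n && is.na(x[j + 1L])) j <- j + 1L
      x[i:j] <- stats::median(x[seq_len(i - 1L)])
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  x
}

#' Decentralize an FHR signal against its baseline
#'
#' `D(t) = S0(t) - B(t)` elementwise.
#'
#' @param s0 Observed FHR samples (no missing values).
#' @param baseline Baseline samples of equal length.
#' @return The decentralized signal.
#' @export
decentralize <- function(s0, baseline) {
  if (length(s0) != length(baseline)) stop("signal and baseline lengths differ")
  if (anyNA(s0) || anyNA(baseline)) stop("decentralize requires imputed inputs")
  s0 - baseline
}

#' Estimate a baseline by rolling median
#'
#' Used when a trace carries no baseline channel; window defaults to 10
#' minutes.
#'
#' @param s0 FHR samples without missing values.
#' @param sampling_rate Hz.
#' @param window_s Window length in seconds.
#' @return Baseline estimate of equal length.
#' @export
rolling_median_baseline <- function(s0, sampling_rate, window_s = 600) {
  w <- max(1L, as.integer(window_s * sampling_rate))
  half <- w %/% 2L
  n <- length(s0)
  vapply(seq_len(n), function(i) {
    stats::median(s0[max(1L, i - half):min(n, i + half)])
  }, numeric(1L))
}

#' Impute missing clinical cells by training-column means
#'
#' Column means are computed on the training partition only and applied to all
#' partitions, preventing information leakage from validation/test rows.
#'
#' @param table Data frame of numeric clinical columns, `NA` for missing.
#' @param train_mask Logical vector marking training rows (defaults to all).
#' @return List with `table` (no missing values) and `means` (named vector of
#'   the training means used).
#' @export
impute_clinical_mean <- function(table, train_mask = rep(TRUE, nrow(table))) {
  stopifnot(is.data.frame(table), length(train_mask) == nrow(table))
  means <- vapply(names(table), function(cn) {
    v <- table[[cn]][train_mask]
    m <- mean(v, na.rm = TRUE)
    if (!is.finite(m)) stop("clinical column '", cn, "' has no observed training value")
    m
  }, numeric(1L))
  for (cn in names(table)) {
    miss <- is.na(table[[cn]])
    if (any(miss)) table[[cn]][miss] <- means[[cn]]
  }
  list(table = table, means = means)
}

#' Zero-mean standardization of clinical columns
#'
#' Shifts each column by its training-partition mean (no variance scaling).
#' The returned means allow the inverse transform and application to new
#' partitions.
#'
#' @param table Data frame of numeric columns with no missing values.
#' @param train_mask Logical vector marking training rows.
#' @param means Optional previously stored means to apply instead of fitting.
#' @return List with `table` (centered) and `means`.
#' @export
standardize_clinical <- function(table, train_mask = rep(TRUE, nrow(table)),
                                 means = NULL) {
  stopifnot(is.data.frame(table))
  if (anyNA(table)) stop("standardize_clinical requires imputed input")
  if (is.null(means)) {
    means <- vapply(table, function(v) mean(v[train_mask]), numeric(1L))
    names(means) <- names(table)
  }
  for (cn in names(table)) table[[cn]] <- table[[cn]] - means[[cn]]
  list(table = table, means = means)
}

run_lengths <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values],
             length = r$lengths[r$values])
}

#' Summarize a trace into the four CTG features
#'
#' Baseline is the windowed median of the signal; variability the 90th minus
#' 10th percentile of the baseline-removed signal outside embedded events;
#' accelerations are excursions of at least +15 bpm lasting at least 15 s.
#' Deceleration excursions (-15 bpm or more) are categorized by a documented
#' heuristic: repeated dips are regular, dips of `prolonged_s` or longer
#' prolonged, single short dips variable when onset is abrupt and early/late
#' otherwise by duration.
#'
#' @param trace Imputed, trimmed `ctg_trace`.
#' @param min_window_s Minimum trace length in seconds.
#' @param excursion_bpm Excursion threshold in bpm.
#' @param min_event_s Minimum event duration in seconds.
#' @param prolonged_s Duration at or beyond which a deceleration is prolonged.
#' @param abrupt_onset_s Time-to-nadir at or below which onset counts as
#'   abrupt.
#' @param late_s Duration at or beyond which a gradual deceleration is late.
#' @return One-row data frame `fhr_baseline`, `baseline_variability`,
#'   `accelerations`, `deceleration`.
#' @export
summarize_trace <- function(trace, min_window_s = 1200, excursion_bpm = 15,
                            min_event_s = 15, prolonged_s = 120,
                            abrupt_onset_s = 10, late_s = 50) {
  stopifnot(inherits(trace, "ctg_trace"))
  s0 <- trace$s0
  if (anyNA(s0)) stop("summarize_trace requires an imputed trace")
  fs <- trace$sampling_rate
  if (length(s0) < min_window_s * fs) stop("trace shorter than minimum window")
  base <- stats::median(s0)
  d <- s0 - base
  min_len <- as.integer(min_event_s * fs)

  acc_runs <- run_lengths(d >= excursion_bpm)
  acc_runs <- acc_runs[acc_runs$length >= min_len, , drop = FALSE]
  dec_runs <- run_lengths(d <= -excursion_bpm)
  dec_runs <- dec_runs[dec_runs$length >= min_len, , drop = FALSE]

  in_event <- rep(FALSE, length(d))
  for (r in seq_len(nrow(acc_runs))) in_event[acc_runs$start[r]:acc_runs$end[r]] <- TRUE
  for (r in seq_len(nrow(dec_runs))) in_event[dec_runs$start[r]:dec_runs$end[r]] <- TRUE
  quiet <- d[!in_event]
  if (length(quiet) < 2L) quiet <- d
  bv <- unname(diff(stats::quantile(quiet, c(0.1, 0.9))))

  decel <- if (nrow(dec_runs) == 0L) {
    "none"
  } else if (nrow(dec_runs) >= 2L) {
    "regular"
  } else {
    dur_s <- dec_runs$length[1L] / fs
    seg <- d[dec_runs$start[1L]:dec_runs$end[1L]]
    onset_s <- (which.min(seg) - 1L) / fs
    if (dur_s >= prolonged_s) "prolonged"
    else if (onset_s <= abrupt_onset_s) "variable"
    else if (dur_s >= late_s) "late"
    else "early"
  }
  data.frame(fhr_baseline = base, baseline_variability = bv,
             accelerations = nrow(acc_runs), deceleration = decel,
             stringsAsFactors = FALSE)
}

#' Fuse CTG summary features with clinical features
#'
#' Column-wise concatenation with one-hot encoding of the deceleration
#' category; stable column order (numeric CTG, deceleration indicators,
#' clinical).
#'
#' @param ctg Data frame with `fhr_baseline`, `baseline_variability`,
#'   `accelerations`, `deceleration`.
#' @param clinical Data frame of numeric clinical columns with equal row
#'   count.
#' @return Numeric matrix with named columns (a `feature_matrix`).
#' @export
fuse_features <- function(ctg, clinical) {
  if (nrow(ctg) != nrow(clinical)) stop("CTG and clinical row counts differ")
  decel <- as.character(ctg$deceleration)
  if (!all(decel %in% DECEL_LEVELS)) {
    stop("unknown deceleration category: ",
         paste(setdiff(decel, DECEL_LEVELS), collapse = ", "))
  }
  onehot <- vapply(DECEL_LEVELS, function(l) as.numeric(decel == l),
                   numeric(nrow(ctg)))
  if (nrow(ctg) == 1L) onehot <- matrix(onehot, nrow = 1L, dimnames = list(NULL, DECEL_LEVELS))
  if (nrow(ctg) == 0L) onehot <- matrix(0, 0L, length(DECEL_LEVELS), dimnames = list(NULL, DECEL_LEVELS))
  num <- as.matrix(ctg[, c("fhr_baseline", "baseline_variability", "accelerations")])
  colnames(onehot) <- paste0("deceleration_", DECEL_LEVELS)
  cli <- as.matrix(clinical)
  out <- cbind(num, onehot, cli)
  storage.mode(out) <- "double"
  rownames(out) <- NULL
  out
}

# Encode a labeled dataset (generate_dataset output) into the model feature
# space: fused matrix with numeric columns centered on training means.
encode_dataset <- function(dataset, means = NULL) {
  clinical_cols <- c("bp_systolic", "bp_diastolic", "maternal_hr", "spo2", "temperature")
  X <- fuse_features(dataset[, c("fhr_baseline", "baseline_variability",
                                 "accelerations", "deceleration")],
                     dataset[, clinical_cols])
  numeric_cols <- c("fhr_baseline", "baseline_variability", "accelerations", clinical_cols)
  train_mask <- dataset$split %in% c("train", "validation")
  if (!any(train_mask)) train_mask <- rep(TRUE, nrow(dataset))
  if (is.null(means)) {
    means <- colMeans(X[train_mask, numeric_cols, drop = FALSE])
  }
  X[, numeric_cols] <- sweep(X[, numeric_cols, drop = FALSE], 2L, means)
  list(X = X, means = means, labels = dataset$label, split = dataset$split)
}
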