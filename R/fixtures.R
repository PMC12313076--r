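# Synthetic CTG + maternal-clinical dataset generator. Class labels follow the
# clinical reassuring/non-reassuring rule: a case is suspicious when exactly one
# of the four CTG features is non-reassuring and pathological when two or more
# are; the clinical (maternal) features never influence the label.

CTG_FEATURES <- c("fhr_baseline", "baseline_variability", "accelerations", "deceleration")
DECEL_LEVELS <- c("none", "early", "variable", "regular", "late", "prolonged")
DECEL_REASSURING <- c("none", "early", "variable")
CLASS_LEVELS <- c("normal", "suspicious", "pathological")
SPLIT_LEVELS <- c("train", "validation", "test")

DATASET_COLUMNS <- c("bp_systolic", "bp_diastolic", "maternal_hr", "spo2",
                     "temperature", "fhr_baseline", "baseline_variability",
                     "accelerations", "deceleration", "label", "split")

#' Configuration for the synthetic CTG dataset generator
#'
#' Defaults reproduce the study conditions of the emulated hospital dataset:
#' 42,000 records split 7:3 into train/test with per-class counts
#' 27,930/970/500 (train) and 12,222/265/113 (test), a 0.2 validation fraction
#' carved from the training block, reassuring CTG ranges (fetal heart rate
#' 110-160 bpm, baseline variability 5-25 bpm, accelerations >= 2 per 20 min,
#' deceleration in none/early/variable) and physiologic bounds on the
#' non-reassuring complements.
#'
#' @param train_counts Named integer vector of per-class training counts
#'   (includes the rows later carved out as validation).
#' @param test_counts Named integer vector of per-class test counts.
#' @param validation_fraction Fraction of each class's training rows marked as
#'   the validation split.
#' @param ranges Feature range table; see [default_feature_ranges()].
#' @param seed Integer seed making generation reproducible.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(train_counts = c(normal = 27930, suspicious = 970, pathological = 500),
                           test_counts = c(normal = 12222, suspicious = 265, pathological = 113),
                           validation_fraction = 0.2,
                           ranges = default_feature_ranges(),
                           seed = 42L) {
  stopifnot(all(CLASS_LEVELS %in% names(train_counts)),
            all(CLASS_LEVELS %in% names(test_counts)))
  if (any(train_counts < 0) || any(test_counts < 0)) {
    stop("per-class counts must be non-negative")
  }
  if (validation_fraction < 0 || validation_fraction >= 1) {
    stop("validation_fraction must be in [0, 1)")
  }
  validate_ranges(ranges)
  structure(list(
    train_counts = stats::setNames(as.integer(train_counts[CLASS_LEVELS]), CLASS_LEVELS),
    test_counts = stats::setNames(as.integer(test_counts[CLASS_LEVELS]), CLASS_LEVELS),
    validation_fraction = validation_fraction,
    ranges = ranges,
    seed = as.integer(seed)
  ), class = "fixture_config")
}

#' Default reassuring / non-reassuring and clinical feature ranges
#'
#' Numeric CTG features carry an inclusive reassuring interval and bounded
#' non-reassuring complements (the clinical table's open-ended inequalities,
#' clipped to physiologic limits). Clinical features carry only a normal range:
#' they are sampled from it for every class because the labeling rule uses CTG
#' features alone.
#'
#' @return A nested list of per-feature ranges.
#' @export
default_feature_ranges <- function() {
  list(
    fhr_baseline = list(reassuring = c(110, 160),
                        non_reassuring = list(c(60, 109), c(161, 210))),
    baseline_variability = list(reassuring = c(5, 25),
                                non_reassuring = list(c(0, 4), c(26, 40))),
    accelerations = list(reassuring = c(2L, 6L),        # integer counts per 20 min
                         non_reassuring = list(c(0L, 1L))),
    deceleration = list(reassuring = DECEL_REASSURING,
                        non_reassuring = setdiff(DECEL_LEVELS, DECEL_REASSURING)),
    clinical = list(
      bp_systolic = c(100, 139),
      bp_diastolic = c(60, 89),
      maternal_hr = c(60, 89),
      spo2 = c(90, 100),
      temperature = c(97, 99)
    )
  )
}

validate_ranges <- function(ranges) {
  for (f in c("fhr_baseline", "baseline_variability", "accelerations")) {
    r <- ranges[[f]]
    if (is.null(r$reassuring) || length(r$non_reassuring) == 0) {
      stop("feature '", f, "' needs reassuring and non_reassuring ranges")
    }
    for (nr in r$non_reassuring) {
      if (nr[1] > nr[2]) stop("empty non-reassuring interval for '", f, "'")
      if (nr[1] <= r$reassuring[2] && nr[2] >= r$reassuring[1]) {
        stop("reassuring and non-reassuring intervals overlap for '", f, "'")
      }
    }
  }
  d <- ranges$deceleration
  if (length(intersect(d$reassuring, d$non_reassuring)) > 0) {
    stop("deceleration reassuring/non-reassuring sets overlap")
  }
  if (length(d$non_reassuring) == 0) stop("empty non-reassuring set for 'deceleration'")
  invisible(TRUE)
}

#' Is a CTG feature value reassuring?
#'
#' Reassuring criteria: fetal heart rate baseline within 110-160 bpm (inclusive),
#' baseline variability within 5-25 bpm, at least 2 accelerations per 20 minutes,
#' and deceleration of category none, early or variable.
#'
#' @param feature One of `"fhr_baseline"`, `"baseline_variability"`,
#'   `"accelerations"`, `"deceleration"`.
#' @param value Numeric value, or deceleration category name.
#' @param ranges Feature range table (defaults to [default_feature_ranges()]).
#' @return `TRUE` if the value is reassuring.
#' @export
is_reassuring <- function(feature, value, ranges = default_feature_ranges()) {
  if (length(feature) != 1L || !feature %in% CTG_FEATURES) {
    stop("unknown CTG feature: ", paste(feature, collapse = ", "))
  }
  if (feature == "deceleration") {
    value <- as.character(value)
    if (!all(value %in% DECEL_LEVELS)) stop("unknown deceleration category: ", value)
    return(value %in% ranges$deceleration$reassuring)
  }
  if (!is.numeric(value) || anyNA(value)) stop("missing or non-numeric value for ", feature)
  r <- ranges[[feature]]$reassuring
  if (feature == "accelerations") value >= r[1] else value >= r[1] & value <= r[2]
}

#' Label a case from its four CTG features
#'
#' Counts non-reassuring CTG features: 0 is normal, exactly 1 suspicious, 2 or
#' more pathological (the pathological rule takes precedence).
#'
#' @param fhr_baseline,baseline_variability,accelerations,deceleration The four
#'   CTG feature values.
#' @param ranges Feature range table.
#' @return `"normal"`, `"suspicious"` or `"pathological"`.
#' @export
label_case <- function(fhr_baseline, baseline_variability, accelerations,
                       deceleration, ranges = default_feature_ranges()) {
  vals <- list(fhr_baseline = fhr_baseline,
               baseline_variability = baseline_variability,
               accelerations = accelerations,
               deceleration = deceleration)
  for (nm in names(vals)) {
    if (length(vals[[nm]]) != 1L || is.na(vals[[nm]])) {
      stop("missing CTG feature: ", nm)
    }
  }
  n_bad <- sum(!vapply(names(vals), function(nm) {
    is_reassuring(nm, vals[[nm]], ranges)
  }, logical(1L)))
  if (n_bad >= 2L) "pathological" else if (n_bad == 1L) "suspicious" else "normal"
}

runif_in <- function(n, interval) stats::runif(n, interval[1], interval[2])

sample_int_in <- function(n, interval) {
  vals <- seq(interval[1], interval[2])
  vals[sample.int(length(vals), n, replace = TRUE)]
}

# vectorized draw of one CTG feature; bad[i] selects the non-reassuring set
sample_ctg_feature <- function(feature, bad, ranges) {
  n <- length(bad)
  if (feature == "deceleration") {
    rs <- ranges$deceleration$reassuring
    nr <- ranges$deceleration$non_reassuring
    out <- rs[sample.int(length(rs), n, replace = TRUE)]
    if (any(bad)) out[bad] <- nr[sample.int(length(nr), sum(bad), replace = TRUE)]
    return(out)
  }
  r <- ranges[[feature]]
  draw <- function(m, iv) {
    if (feature == "accelerations") sample_int_in(m, iv) else runif_in(m, iv)
  }
  out <- draw(n, r$reassuring)
  if (any(bad)) {
    nb <- sum(bad)
    which_iv <- sample.int(length(r$non_reassuring), nb, replace = TRUE)
    bad_vals <- numeric(nb)
    for (k in seq_along(r$non_reassuring)) {
      sel <- which_iv == k
      if (any(sel)) bad_vals[sel] <- draw(sum(sel), r$non_reassuring[[k]])
    }
    out[bad] <- bad_vals
  }
  out
}

# all subsets of the four CTG features with size >= 2 (11 of them)
ctg_subsets_ge2 <- function() {
  out <- list()
  for (m in 0:15) {
    members <- CTG_FEATURES[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0]
    if (length(members) >= 2L) out[[length(out) + 1L]] <- members
  }
  out
}

#' Sample one labeled case record
#'
#' Draws clinical features from their normal ranges and CTG features so the
#' record's label, recomputed by [label_case()], equals `label`: suspicious
#' records get exactly one uniformly chosen non-reassuring CTG feature,
#' pathological records a uniformly chosen subset of two or more.
#'
#' Uses R's global RNG stream; seed with `set.seed()` for reproducibility.
#'
#' @param label Target class.
#' @param config A [fixture_config()].
#' @return One-row data frame with the dataset columns minus `split`.
#' @export
sample_case <- function(label, config = fixture_config()) {
  sample_cases(label, 1L, config)
}

# vectorized block of n records of one class
sample_cases <- function(label, n, config) {
  if (n == 0L) return(NULL)
  label <- match.arg(label, CLASS_LEVELS)
  ranges <- config$ranges
  # per-row logical matrix: which CTG features are non-reassuring
  bad <- matrix(FALSE, n, 4L, dimnames = list(NULL, CTG_FEATURES))
  if (label == "suspicious") {
    bad[cbind(seq_len(n), sample.int(4L, n, replace = TRUE))] <- TRUE
  } else if (label == "pathological") {
    subsets <- ctg_subsets_ge2()
    pick <- sample.int(length(subsets), n, replace = TRUE)
    for (k in seq_along(subsets)) {
      sel <- pick == k
      if (any(sel)) bad[sel, subsets[[k]]] <- TRUE
    }
  }
  cl <- ranges$clinical
  data.frame(
    bp_systolic = runif_in(n, cl$bp_systolic),
    bp_diastolic = runif_in(n, cl$bp_diastolic),
    maternal_hr = runif_in(n, cl$maternal_hr),
    spo2 = runif_in(n, cl$spo2),
    temperature = runif_in(n, cl$temperature),
    fhr_baseline = sample_ctg_feature("fhr_baseline", bad[, 1L], ranges),
    baseline_variability = sample_ctg_feature("baseline_variability", bad[, 2L], ranges),
    accelerations = sample_ctg_feature("accelerations", bad[, 3L], ranges),
    deceleration = sample_ctg_feature("deceleration", bad[, 4L], ranges),
    label = rep(label, n),
    stringsAsFactors = FALSE
  )
}

#' Generate the full labeled dataset
#'
#' Emits exactly the configured per-class train/test counts; the validation
#' split is carved per class from the training block at the configured
#' fraction, so `split == "train"` plus `split == "validation"` rows total the
#' configured training counts. Deterministic given `config$seed`.
#'
#' @param config A [fixture_config()].
#' @return Data frame with the dataset columns including `split`.
#' @export
generate_dataset <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  set.seed(config$seed)
  blocks <- list()
  for (ci in seq_along(CLASS_LEVELS)) {
    cls <- CLASS_LEVELS[ci]
    n_train <- config$train_counts[ci]
    tr <- sample_cases(cls, n_train, config)
    if (!is.null(tr)) {
      n_valid <- floor(config$validation_fraction * n_train)
      tr$split <- rep(c("train", "validation"),
                      c(n_train - n_valid, n_valid))
      blocks[[length(blocks) + 1L]] <- tr
    }
    te <- sample_cases(cls, config$test_counts[ci], config)
    if (!is.null(te)) {
      te$split <- "test"
      blocks[[length(blocks) + 1L]] <- te
    }
  }
  if (length(blocks) == 0L) {
    out <- empty_dataset()
  } else {
    out <- do.call(rbind, blocks)
    rownames(out) <- NULL
  }
  out
}

empty_dataset <- function() {
  out <- data.frame(
    bp_systolic = numeric(0), bp_diastolic = numeric(0), maternal_hr = numeric(0),
    spo2 = numeric(0), temperature = numeric(0), fhr_baseline = numeric(0),
    baseline_variability = numeric(0), accelerations = integer(0),
    deceleration = character(0), label = character(0), split = character(0),
    stringsAsFactors = FALSE
  )
  out
}

#' Synthesize an FHR trace for a case record
#'
#' Builds a piecewise-constant baseline near the record's FHR baseline, adds
#' uniform variability of the requested amplitude, embeds the record's
#' accelerations (+20 bpm, 20 s plateaus) and its deceleration category as
#' transient excursions, then blanks random interior segments at
#' `missing_rate`. Sample 1 is never blanked (the imputation rule needs an
#' observed first value).
#'
#' @param case One-row data frame with at least `fhr_baseline`,
#'   `accelerations`, `deceleration`.
#' @param duration Trace duration in seconds.
#' @param sampling_rate Samples per second (Hz).
#' @param missing_rate Fraction of interior samples blanked to missing.
#' @param variability_amplitude Half-range of the additive variability in bpm
#'   (0 gives a noise-free trace); defaults to half the record's baseline
#'   variability.
#' @return A `ctg_trace` list with `t`, `s0`, `baseline`, `sampling_rate`.
#' @export
generate_trace <- function(case, duration = 1200, sampling_rate = 4,
                           missing_rate = 0,
                           variability_amplitude = NULL) {
  stopifnot(duration > 0, missing_rate >= 0, missing_rate < 1)
  n <- as.integer(round(duration * sampling_rate))
  base_bpm <- case$fhr_baseline[1L]
  if (is.null(variability_amplitude)) {
    variability_amplitude <- case$baseline_variability[1L] / 2
  }
  baseline <- rep(base_bpm, n)
  s0 <- baseline + stats::runif(n, -variability_amplitude, variability_amplitude)

  embed <- function(sig, start_s, dur_s, delta, ramp_s = 5) {
    i0 <- max(1L, as.integer(start_s * sampling_rate))
    i1 <- min(n, as.integer((start_s + dur_s) * sampling_rate))
    if (i1 <= i0) return(sig)
    len <- i1 - i0 + 1L
    ramp <- min(as.integer(ramp_s * sampling_rate), len %/% 2L)
    shape <- rep(1, len)
    if (ramp > 0) {
      shape[seq_len(ramp)] <- seq(0, 1, length.out = ramp)
      shape[(len - ramp + 1L):len] <- seq(1, 0, length.out = ramp)
    }
    sig[i0:i1] <- sig[i0:i1] + delta * shape
    sig
  }

  n_acc <- as.integer(case$accelerations[1L])
  if (n_acc > 0) {
    starts <- seq(60, duration * 0.45, length.out = max(n_acc, 1L))[seq_len(n_acc)]
    # 30 s at +20 bpm with 5 s ramps keeps the excursion above the 15 bpm
    # detection criterion for >= 15 s (the ramps eat 3.75 s per side)
    for (st in starts) s0 <- embed(s0, st, 30, +20)
  }
  decel <- as.character(case$deceleration[1L])
  half <- duration * 0.55
  s0 <- switch(decel,
    none = s0,
    early = embed(s0, half, 40, -25, ramp_s = 15),
    variable = embed(s0, half, 30, -30, ramp_s = 2),
    late = embed(s0, half, 60, -25, ramp_s = 20),
    regular = {
      for (st in seq(half, duration - 60, by = 90)) s0 <- embed(s0, st, 30, -25, ramp_s = 10)
      s0
    },
    prolonged = embed(s0, half, 180, -30, ramp_s = 15),
    stop("unknown deceleration category: ", decel)
  )

  if (missing_rate > 0 && n > 1L) {
    n_miss <- as.integer(round(missing_rate * (n - 1L)))
    if (n_miss > 0) s0[1L + sample.int(n - 1L, n_miss)] <- NA_real_
  }
  structure(list(
    t = seq(0, by = 1 / sampling_rate, length.out = n),
    s0 = s0,
    baseline = baseline,
    sampling_rate = sampling_rate
  ), class = "ctg_trace")
}

#' @export
print.ctg_trace <- function(x, ...) {
  cat(sprintf("<ctg_trace> %d samples @ %g Hz (%.1f min), %d missing\n",
              length(x$s0), x$sampling_rate,
              length(x$s0) / x$sampling_rate / 60, sum(is.na(x$s0))))
  invisible(x)
}

#' @export
print.fixture_config <- function(x, ...) {
  cat("<fixture_config>\n")
  cat("  train:", paste(sprintf("%s=%d", CLASS_LEVELS, x$train_counts), collapse = " "), "\n")
  cat("  test: ", paste(sprintf("%s=%d", CLASS_LEVELS, x$test_counts), collapse = " "), "\n")
  cat(sprintf("  validation fraction %.2f, seed %d\n", x$validation_fraction, x$seed))
  invisible(x)
}
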