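# Signal cleaning and feature conditioning.

mk_trace <- function(s0, baseline = rep(140, length(s0)), fs = 4) {
  structure(list(t = seq(0, by = 1 / fs, length.out = length(s0)),
                 s0 = s0, baseline = baseline, sampling_rate = fs),
            class = "ctg_trace")
}

test_that("trim_outliers removes edge runs and masks interior outliers", {
  tr <- mk_trace(c(250, 140, 141, 250))
  out <- trim_outliers(tr, c(50, 210))
  expect_identical(out$s0, c(140, 141))

  tr2 <- mk_trace(c(140, 141, 142))
  expect_identical(trim_outliers(tr2)$s0, c(140, 141, 142))

  tr3 <- mk_trace(c(140, 250, 141))
  expect_identical(trim_outliers(tr3)$s0, c(140, NA, 141))

  expect_error(trim_outliers(mk_trace(c(300, 300))), "entire trace out of range")
})

test_that("impute_median fills segments with the observed-prefix median", {
  expect_identical(impute_median(c(120, 118, 122, NA, NA, 119)),
                   c(120, 118, 122, 120, 120, 119))
  x <- c(130, 128, 131)
  expect_identical(impute_median(x), x)
  expect_identical(impute_median(c(130, NA, NA)), c(130, 130, 130))
  expect_error(impute_median(c(NA, 120)), "must not start with a missing value")
})

test_that("impute_median is idempotent, never alters observed samples, and uses updated prefixes", {
  x <- c(120, NA, 124, NA, NA, 118, NA)
  once <- impute_median(x)
  expect_identical(impute_median(once), once)
  expect_identical(once[!is.na(x)], x[!is.na(x)])
  # second segment's prefix includes the first segment's imputed value
  y <- impute_median(c(100, NA, 200, NA))
  expect_identical(y[2], 100)               # median{100}
  expect_identical(y[4], stats::median(c(100, 100, 200)))
})

test_that("decentralize subtracts the baseline and conserves the signal", {
  expect_identical(decentralize(c(140, 145, 150), c(140, 140, 140)), c(0, 5, 10))
  s <- c(120, 121, 119)
  expect_identical(decentralize(s, s), c(0, 0, 0))
  b <- c(118, 120, 122)
  expect_identical(decentralize(s, b) + b, s)
  expect_error(decentralize(1:3, 1:2), "lengths differ")
})

test_that("clinical mean imputation uses training means only", {
  tab <- data.frame(a = c(90, NA, 110), b = c(1, 2, 3))
  out <- impute_clinical_mean(tab)
  expect_identical(out$table$a, c(90, 100, 110))
  expect_identical(out$table$b, tab$b)

  # missing test cell filled with the train mean, not the test mean
  tab2 <- data.frame(a = c(10, 20, NA, 1000))
  out2 <- impute_clinical_mean(tab2, train_mask = c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(out2$table$a[3], 15)
  expect_identical(out2$means[["a"]], 15)

  expect_error(impute_clinical_mean(data.frame(a = c(NA_real_, NA_real_))),
               "no observed training value")
})

test_that("zero-mean standardization centers on training means and inverts", {
  out <- standardize_clinical(data.frame(a = c(1, 2, 3)))
  expect_identical(out$table$a, c(-1, 0, 1))
  expect_lt(abs(mean(out$table$a)), 1e-9)

  const <- standardize_clinical(data.frame(a = rep(7, 4)))
  expect_identical(const$table$a, rep(0, 4))

  # stored means apply to new partitions, preserving offsets
  fit <- standardize_clinical(data.frame(a = c(10, 20)))
  new <- standardize_clinical(data.frame(a = c(30, 40)), means = fit$means)
  expect_identical(new$table$a, c(15, 25))
  expect_identical(new$table$a + fit$means[["a"]], c(30, 40))
})

test_that("summarize_trace recovers embedded events from noise-free traces", {
  # constant trace
  const <- mk_trace(rep(140, 4800))
  s <- summarize_trace(const)
  expect_identical(s$fhr_baseline, 140)
  expect_identical(s$baseline_variability, 0)
  expect_identical(s$accelerations, 0L)
  expect_identical(s$deceleration, "none")

  rec <- data.frame(fhr_baseline = 140, baseline_variability = 10,
                    accelerations = 2L, deceleration = "none")
  tr <- generate_trace(rec, duration = 1200, sampling_rate = 4,
                       variability_amplitude = 0)
  s2 <- summarize_trace(tr)
  expect_identical(s2$accelerations, 2L)
  expect_identical(s2$deceleration, "none")

  rec3 <- data.frame(fhr_baseline = 140, baseline_variability = 10,
                     accelerations = 0L, deceleration = "prolonged")
  tr3 <- generate_trace(rec3, duration = 1200, sampling_rate = 4,
                        variability_amplitude = 0)
  expect_identical(summarize_trace(tr3)$deceleration, "prolonged")

  expect_error(summarize_trace(mk_trace(rep(140, 100))), "shorter than minimum window")
})

test_that("fuse_features one-hot encodes deceleration with stable columns", {
  ctg <- data.frame(fhr_baseline = c(140, 100),
                    baseline_variability = c(10, 3),
                    accelerations = c(2L, 0L),
                    deceleration = c("none", "late"))
  cli <- data.frame(bp_systolic = c(120, 125), bp_diastolic = c(80, 82),
                    maternal_hr = c(70, 75), spo2 = c(98, 97),
                    temperature = c(98, 98.2))
  X <- fuse_features(ctg, cli)
  expect_identical(dim(X), c(2L, 14L))
  expect_identical(colnames(X)[4:9], paste0("deceleration_", ctgaug:::DECEL_LEVELS))
  expect_identical(unname(X[1, "deceleration_none"]), 1)
  expect_identical(unname(X[2, "deceleration_late"]), 1)
  expect_identical(sum(X[1, 4:9]), 1)

  expect_identical(dim(fuse_features(ctg[0, ], cli[0, ])), c(0L, 14L))
  expect_error(fuse_features(ctg, cli[1, , drop = FALSE]), "row counts differ")

  # CSV round-trip is identity
  f <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(X), f, row.names = FALSE)
  back <- as.matrix(utils::read.csv(f))
  expect_equal(unname(back), unname(X), tolerance = 1e-12)
})

test_that("rolling median baseline tracks a slowly varying signal", {
  s <- c(rep(120, 1000), rep(150, 1000))
  b <- rolling_median_baseline(s, sampling_rate = 1, window_s = 101)
  expect_identical(b[500], 120)
  expect_identical(b[1500], 150)
})
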