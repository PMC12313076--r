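# Metrics, ROC, run statistics, exact McNemar, bootstrap comparison.

test_that("confusion counts by (true, predicted) with fixed class order", {
  cls <- c("a", "b")
  cm <- confusion(c("a", "a", "b"), c("a", "a", "b"), cls)
  expect_identical(unname(diag(cm)), c(2L, 1L))
  expect_identical(sum(cm) - sum(diag(cm)), 0L)

  empty <- confusion(character(0), character(0), cls)
  expect_true(all(empty == 0L))

  truth <- c("a", "a", "a", "b", "b", "b")
  pred <- c("a", "b", "a", "b", "a", "b")
  cm2 <- confusion(truth, pred, cls)
  expect_identical(unname(cm2), matrix(c(2L, 1L, 1L, 2L), 2, 2))
  expect_identical(sum(cm2), 6L)  # total conservation

  expect_error(confusion("c", "a", cls), "unknown label")
})

test_that("metrics implement Eqs 3-6 and never coerce undefined ratios to 0", {
  cm <- matrix(c(8L, 2L, 2L, 88L), 2, 2,
               dimnames = list(c("pos", "neg"), c("pos", "neg")))
  m <- metrics(cm, "pos")
  expect_equal(m$accuracy, 0.96)
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 0.8)
  expect_equal(m$f1, 0.8)
  # F1 is the harmonic mean of the reported P and R
  expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall),
               tolerance = 1e-12)

  perfect <- matrix(c(5L, 0L, 0L, 5L), 2, 2,
                    dimnames = list(c("pos", "neg"), c("pos", "neg")))
  mp <- metrics(perfect, "pos")
  expect_identical(unlist(mp), c(accuracy = 1, precision = 1, recall = 1, f1 = 1))

  # TP = FP = 0: precision undefined, warned, NA
  none <- matrix(c(0L, 0L, 3L, 7L), 2, 2,
                 dimnames = list(c("pos", "neg"), c("pos", "neg")))
  expect_warning(mn <- metrics(none, "pos"), "undefined")
  expect_true(is.na(mn$precision))
  expect_false(identical(mn$precision, 0))
})

test_that("overall accuracy is trace over total", {
  cm <- matrix(c(5L, 1L, 2L, 12L), 2, 2)
  expect_equal(overall_accuracy(cm), 17 / 20)
})

test_that("roc sweeps thresholds and integrates by trapezoid", {
  truth <- rep(c("abnormal", "normal"), each = 5)
  perfect <- roc(c(rep(0.9, 5), rep(0.1, 5)), truth)
  expect_equal(perfect$auc, 1)

  flat <- roc(rep(0.5, 10), truth)
  expect_equal(flat$auc, 0.5)

  set.seed(1)
  n <- 10000
  rnd <- roc(runif(n), sample(rep(c("abnormal", "normal"), n / 2)))
  expect_lt(abs(rnd$auc - 0.5), 0.02)

  expect_error(roc(c(0.1, 0.9), c("normal", "normal")), "both classes")
})

test_that("run_stats reports mean, sample sd and the normal-approximation CI", {
  s <- run_stats(rep(91.4, 100))
  expect_equal(s$mean, 91.4)
  expect_equal(s$sd, 0)
  expect_equal(s$ci, c(91.4, 91.4))

  s2 <- run_stats(c(90, 92))
  expect_equal(s2$mean, 91)
  expect_equal(s2$sd, sqrt(2))

  expect_warning(s1 <- run_stats(5), "at least two runs")
  expect_true(is.na(s1$sd))

  # CI width shrinks like 1/sqrt(R)
  set.seed(2)
  vals <- rnorm(400)
  w25 <- diff(run_stats(vals[1:25])$ci)
  w400 <- diff(run_stats(vals)$ci)
  expect_lt(w400, w25)
})

test_that("mcnemar_exact matches the binomial oracle", {
  truth <- rep("x", 4)
  expect_warning(same <- mcnemar_exact(truth, truth, truth), "no discordant")
  expect_identical(same$p_value, 1)

  # b = 2, c = 10 -> p = 2 * P(X <= 2 | n = 12) = 158/4096
  pa <- c(rep("x", 2), rep("y", 10), rep("x", 3))
  pb <- c(rep("y", 2), rep("x", 10), rep("x", 3))
  tr <- rep("x", 15)
  m <- mcnemar_exact(pa, pb, tr)
  expect_identical(c(m$b, m$c), c(2L, 10L))
  expect_equal(m$p_value, 158 / 4096, tolerance = 1e-12)

  # symmetry: swapping A and B swaps b and c, p unchanged
  m2 <- mcnemar_exact(pb, pa, tr)
  expect_identical(c(m2$b, m2$c), c(10L, 2L))
  expect_identical(m2$p_value, m$p_value)
})

test_that("mcnemar_exact agrees with the binomial CDF for all b + c <= 20", {
  make_preds <- function(b, cc) {
    n <- b + cc + 1L
    truth <- rep("x", n)
    pa <- c(rep("x", b), rep("y", cc), "x")
    pb <- c(rep("y", b), rep("x", cc), "x")
    mcnemar_exact(pa, pb, truth)
  }
  for (n in 1:20) {
    for (b in 0:n) {
      cc <- n - b
      got <- make_preds(b, cc)$p_value
      want <- min(1, 2 * pbinom(min(b, cc), n, 0.5))
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("bootstrap_diff_ci is seeded and sound", {
  truth <- rep(c("x", "y"), 50)
  pred <- truth
  acc <- function(p, t) mean(p == t)
  ci <- bootstrap_diff_ci(acc, pred, pred, truth, resamples = 200L, seed = 1L)
  expect_identical(as.numeric(ci), c(0, 0))  # self-comparison

  ci2 <- bootstrap_diff_ci(acc, pred, pred, truth, resamples = 200L, seed = 1L)
  expect_identical(as.numeric(ci), as.numeric(ci2))

  # A strictly better on 30% of rows: CI excludes 0
  set.seed(3)
  n <- 1000
  truth2 <- sample(c("x", "y"), n, replace = TRUE)
  pa <- truth2
  pb <- truth2
  flip <- seq_len(0.3 * n)
  pb[flip] <- ifelse(truth2[flip] == "x", "y", "x")
  ci3 <- bootstrap_diff_ci(acc, pa, pb, truth2, resamples = 500L, seed = 2L)
  expect_gt(ci3[1], 0)
})

test_that("eval_report assembles the confusion matrix and per-class metrics", {
  truth <- c("normal", "abnormal", "abnormal", "normal")
  pred <- c("normal", "abnormal", "normal", "normal")
  prob <- cbind(normal = c(0.9, 0.2, 0.6, 0.8), abnormal = c(0.1, 0.8, 0.4, 0.2))
  rp <- eval_report(truth, pred, prob, c("normal", "abnormal"))
  expect_identical(sum(rp$confusion), 4L)
  expect_equal(rp$accuracy, 0.75)
  expect_equal(rp$per_class$abnormal$recall, 0.5)
  expect_false(is.na(rp$auc))
  expect_true(rp$auc >= 0 && rp$auc <= 1)
})

test_that("compare_models bundles McNemar and the bootstrap CI", {
  truth <- rep(c("x", "y"), 20)
  pa <- truth
  pb <- truth
  pb[1:4] <- ifelse(truth[1:4] == "x", "y", "x")
  cmp <- compare_models(pa, pb, truth, resamples = 200L, seed = 1L)
  expect_identical(cmp$mcnemar$b, 4L)
  expect_identical(cmp$mcnemar$c, 0L)
  expect_length(cmp$accuracy_diff_ci, 2L)
  expect_lte(cmp$accuracy_diff_ci[1], cmp$accuracy_diff_ci[2])
})
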