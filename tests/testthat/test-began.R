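# BEGAN training, Eq-2 convergence measure, stopping rules, synthetic
# generation and the augmentation plan.

test_that("reconstruction_error is the mean absolute reconstruction gap", {
  X <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_identical(reconstruction_error(X, identity), 0)
  expect_identical(reconstruction_error(matrix(c(1, 1), 1, 2),
                                        function(b) matrix(0, 1, 2)), 1)
  # invariant to row order
  f <- function(b) b * 0.5
  expect_identical(reconstruction_error(X, f),
                   reconstruction_error(X[2:1, ], f))
  expect_error(reconstruction_error(X[0, , drop = FALSE], identity), "non-empty")
  expect_error(reconstruction_error(X, function(b) b[, 1, drop = FALSE]),
               "dimension mismatch")
})

test_that("convergence_measure matches Eq 2 on a grid and is bounded below", {
  expect_identical(convergence_measure(0, 0, 0.5), 0)
  expect_identical(convergence_measure(0.5, 0.25, 0.5), 0.5)
  expect_identical(convergence_measure(0.4, 0.1, 0.5), 0.5)
  grid <- expand.grid(lr = c(0, 0.1, 0.5, 1, 3), lf = c(0, 0.05, 0.2, 1, 2),
                      a = c(0.25, 0.5, 0.75, 1))
  for (i in seq_len(nrow(grid))) {
    m <- convergence_measure(grid$lr[i], grid$lf[i], grid$a[i])
    expect_equal(m, grid$lr[i] + abs(grid$a[i] * grid$lr[i] - grid$lf[i]))
    expect_gte(m, grid$lr[i])
  }
  # equality exactly at equilibrium
  expect_identical(convergence_measure(0.8, 0.4, 0.5), 0.8)
  expect_error(convergence_measure(-0.1, 0, 0.5), "non-negative")
})

test_that("train_began is deterministic and honors the stopping rules", {
  set.seed(1)
  X <- matrix(rnorm(200, 5), 100, 2)
  cfg <- began_config(latent_dim = 4L, hidden_width = 16L, max_epochs = 8L, seed = 2L)
  a <- train_began(X, cfg)
  b <- train_began(X, cfg)
  expect_identical(a$history, b$history)
  expect_identical(length(a$history), a$epochs_run)
  expect_lte(a$epochs_run, cfg$max_epochs)

  # threshold 0 can never be met: always runs to the cap
  cap <- train_began(X, began_config(latent_dim = 4L, hidden_width = 16L,
                                     max_epochs = 5L, convergence_threshold = 0,
                                     seed = 2L))
  expect_identical(cap$stop_reason, "epoch_cap")
  expect_identical(cap$epochs_run, 5L)

  # huge threshold: stops at the first epoch with stop_reason "threshold"
  thr <- train_began(X, began_config(latent_dim = 4L, hidden_width = 16L,
                                     max_epochs = 50L, convergence_threshold = 100,
                                     seed = 2L))
  expect_identical(thr$stop_reason, "threshold")
  expect_identical(thr$epochs_run, 1L)
  expect_lt(thr$history[length(thr$history)], 100)
})

test_that("stop_reason threshold implies the final M is below the threshold", {
  set.seed(2)
  X <- matrix(rnorm(400), 200, 2)
  m <- train_began(X, began_config(latent_dim = 2L, hidden_width = 8L,
                                   max_epochs = 100L, seed = 1L))
  if (m$stop_reason == "threshold") {
    expect_lt(m$history[length(m$history)], m$config$convergence_threshold)
  } else {
    expect_identical(m$epochs_run, 100L)
  }
  expect_true(all(m$diagnostics$m == m$history))
})

test_that("generate_synthetic yields exact, reproducible counts", {
  set.seed(3)
  X <- matrix(rnorm(100, 3), 50, 2)
  m <- train_began(X, began_config(latent_dim = 2L, hidden_width = 8L,
                                   max_epochs = 3L, seed = 1L))
  expect_identical(nrow(generate_synthetic(m, 0)), 0L)
  s <- generate_synthetic(m, 6000, seed = 4L)
  expect_identical(nrow(s), 6000L)
  expect_true(all(is.finite(s)))
  expect_identical(s, generate_synthetic(m, 6000, seed = 4L))
  expect_error(generate_synthetic(structure(list(), class = "began_model"), 5),
               "not a trained")
})

test_that("synthetic means match a toy Gaussian cloud within half a standard deviation", {
  set.seed(11)
  X <- cbind(rnorm(500, 2, 1), rnorm(500, -1, 0.5))
  m <- train_began(X, began_config(max_epochs = 100L, seed = 1L))
  expect_lte(m$epochs_run, 100L)
  syn <- generate_synthetic(m, 1000, seed = 9L)
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  expect_true(all(abs(colMeans(syn) - mu) / sdv < 0.5))
})

test_that("reconstruction_error accepts a trained model and reports data-unit error", {
  set.seed(4)
  X <- matrix(rnorm(100, 100, 10), 50, 2)  # far from the origin
  m <- train_began(X, began_config(latent_dim = 2L, hidden_width = 8L,
                                   max_epochs = 20L, seed = 1L))
  err <- reconstruction_error(X, m)
  expect_gte(err, 0)
  expect_lt(err, 50)  # reconstructions live near the data, not near zero
})

test_that("make_plan implements both augmentation policies", {
  bin <- make_plan(c(normal = 27930, abnormal = 1470), mode = "binary")
  expect_identical(as.integer(bin), c(6000L, 6000L))
  expect_identical(attr(bin, "mode"), "binary")

  mc <- make_plan(c(normal = 27930, suspicious = 970, pathological = 500),
                  mode = "multiclass")
  expect_identical(as.integer(mc[c("normal", "suspicious", "pathological")]),
                   c(0L, 10000L, 10000L))

  none <- make_plan(c(a = 40, b = 30, c = 30), mode = "multiclass")
  expect_identical(as.integer(none), c(0L, 0L, 0L))

  expect_error(make_plan(c(a = 0, b = 10), mode = "binary"), "positive")
})

test_that("began_config validates its fields", {
  expect_error(began_config(alpha = 0), "alpha")
  expect_error(began_config(alpha = 1.5), "alpha")
  expect_error(began_config(convergence_threshold = -1), "convergence_threshold")
  expect_error(began_config(max_epochs = 0), "max_epochs")
  expect_error(began_config(equilibrium_gain = 0), "equilibrium_gain")
  expect_error(began_config(bottleneck_dim = 0), "bottleneck_dim")
  expect_identical(began_config()$max_epochs, 280L)
  expect_identical(began_config()$convergence_threshold, 0.058)
})
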