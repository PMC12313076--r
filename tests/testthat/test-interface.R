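# Seed fan-out, lineage hashing, dataset I/O, config round-trip, CLI and
# pipeline determinism.

small_fixture <- function(seed = 3L) {
  fixture_config(train_counts = c(normal = 40, suspicious = 15, pathological = 15),
                 test_counts = c(normal = 15, suspicious = 8, pathological = 8),
                 seed = seed)
}

tiny_experiment <- function(runs = 1L, families = "naive", heads = "dnn") {
  experiment_config(task = "multiclass", runs = runs, families = families,
                    heads = heads, classifier_epochs = 3L,
                    began = began_config(latent_dim = 4L, hidden_width = 8L,
                                         max_epochs = 3L),
                    ae = ae_config(hidden_width = 8L, code_dim = 5L, epochs = 3L),
                    plan_args = list(multiclass_count = 10L), seed = 2L)
}

test_that("derive_seed fans the global seed out per stage deterministically", {
  expect_identical(derive_seed(1L, "began-normal"), derive_seed(1L, "began-normal"))
  expect_false(derive_seed(1L, "began-normal") == derive_seed(1L, "began-suspicious"))
  expect_false(derive_seed(1L, "ae") == derive_seed(2L, "ae"))
  s <- derive_seed(123456L, "clf-run99")
  expect_true(s >= 1 && s <= 2147483047)
})

test_that("config_hash is stable and discriminates objects", {
  a <- list(x = 1, y = "z")
  expect_identical(config_hash(a), config_hash(a))
  expect_false(config_hash(a) == config_hash(list(x = 2, y = "z")))
  expect_match(config_hash(a), "^[0-9a-f]{8}$")
})

test_that("dataset CSV round-trips and schema violations name the row", {
  ds <- generate_dataset(small_fixture())
  f <- tempfile(fileext = ".csv")
  write_dataset(ds, f)
  back <- read_dataset(f)
  expect_equal(back, ds, tolerance = 1e-12)

  bad <- ds
  bad$label[3] <- "ambiguous"
  fb <- tempfile(fileext = ".csv")
  write_dataset(bad, fb)
  expect_error(read_dataset(fb), "invalid label 'ambiguous' at row 3")

  # header-only file: empty dataset, no error
  fe <- tempfile(fileext = ".csv")
  write_dataset(ds[0, ], fe)
  expect_identical(nrow(read_dataset(fe)), 0L)

  # unknown columns rejected
  odd <- cbind(ds, extra = 1)
  fo <- tempfile(fileext = ".csv")
  utils::write.csv(odd, fo, row.names = FALSE)
  expect_error(read_dataset(fo), "columns must be exactly")

  expect_error(read_dataset(tempfile()), "not found")
})

test_that("run_config round-trips through YAML", {
  cfg <- run_config(fixture = small_fixture(), experiment = tiny_experiment(),
                    seed = 9L)
  f <- tempfile(fileext = ".yaml")
  write_run_config(cfg, f)
  back <- read_run_config(f)
  expect_identical(back$seed, 9L)
  expect_identical(back$fixture$train_counts, cfg$fixture$train_counts)
  expect_identical(back$fixture$ranges, cfg$fixture$ranges)
  expect_identical(back$experiment$task, cfg$experiment$task)
  expect_identical(back$experiment$began_config$max_epochs,
                   cfg$experiment$began_config$max_epochs)
  expect_identical(back$experiment$plan_args, cfg$experiment$plan_args)
})

test_that("run_pipeline is deterministic and carries lineage hashes", {
  cfg <- run_config(fixture = small_fixture(), experiment = tiny_experiment(),
                    seed = 4L)
  r1 <- run_pipeline(cfg)
  r2 <- run_pipeline(cfg)
  expect_identical(r1$reports$dnn$best$confusion, r2$reports$dnn$best$confusion)
  expect_identical(r1$reports$dnn$stats, r2$reports$dnn$stats)
  expect_identical(attr(r1, "config_hash"), attr(r2, "config_hash"))
  expect_identical(attr(r1, "test_hash"), attr(r2, "test_hash"))
  expect_match(attr(r1, "config_hash"), "^[0-9a-f]{8}$")
})

test_that("the CLI rejects bad invocations with usage status 2", {
  expect_identical(ctg_cli(character()), 2L)
  expect_identical(ctg_cli("frobnicate"), 2L)
  expect_identical(ctg_cli(c("generate-data", "--nonsense")), 2L)
  expect_identical(ctg_cli(c("generate-data")), 2L)  # missing required --out
})

test_that("the CLI generates data and reports input errors with status 1", {
  dir <- tempfile(); dir.create(dir)
  cfgf <- file.path(dir, "run.yaml")
  write_run_config(run_config(fixture = small_fixture(),
                              experiment = tiny_experiment(), seed = 5L), cfgf)
  out <- file.path(dir, "data.csv")
  expect_identical(suppressMessages(
    ctg_cli(c("generate-data", "--out", out, "--config", cfgf))), 0L)
  ds <- read_dataset(out)
  expect_identical(nrow(ds), 101L)

  expect_identical(suppressMessages(
    ctg_cli(c("preprocess", "--in", tempfile(), "--out", out))), 1L)
})

test_that("train-clf requires the encoder artifact for encoder families", {
  dir <- tempfile(); dir.create(dir)
  dataf <- file.path(dir, "data.csv")
  write_dataset(generate_dataset(small_fixture()), dataf)
  st <- suppressMessages(ctg_cli(c(
    "train-clf", "--in", dataf, "--out", file.path(dir, "m.rds"),
    "--family", "proposed", "--head", "cnn1d", "--epochs", "2")))
  expect_identical(st, 1L)
  msgs <- capture.output(ctg_cli(c(
    "train-clf", "--in", dataf, "--out", file.path(dir, "m.rds"),
    "--family", "proposed", "--head", "cnn1d", "--epochs", "2")),
    type = "message")
  expect_true(any(grepl("missing encoder artifact", msgs)))
})

test_that("run-all produces byte-identical metrics for the same seed", {
  dir1 <- tempfile(); dir2 <- tempfile()
  cfgf <- tempfile(fileext = ".yaml")
  write_run_config(run_config(fixture = small_fixture(),
                              experiment = tiny_experiment(), seed = 1L), cfgf)
  expect_identical(suppressMessages(ctg_cli(
    c("run-all", "--outdir", dir1, "--config", cfgf, "--seed", "6"))), 0L)
  expect_identical(suppressMessages(ctg_cli(
    c("run-all", "--outdir", dir2, "--config", cfgf, "--seed", "6"))), 0L)
  f1 <- file.path(dir1, "metrics.json")
  f2 <- file.path(dir2, "metrics.json")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("compare refuses results with mismatched test-partition hashes", {
  dir <- tempfile(); dir.create(dir)
  d1 <- file.path(dir, "d1.csv"); d2 <- file.path(dir, "d2.csv")
  write_dataset(generate_dataset(small_fixture(seed = 3L)), d1)
  write_dataset(generate_dataset(small_fixture(seed = 4L)), d2)
  r1 <- file.path(dir, "r1.rds"); r2 <- file.path(dir, "r2.rds")
  expect_identical(suppressMessages(ctg_cli(c(
    "train-clf", "--in", d1, "--out", r1, "--family", "naive", "--head", "dnn",
    "--epochs", "2", "--seed", "1"))), 0L)
  expect_identical(suppressMessages(ctg_cli(c(
    "train-clf", "--in", d2, "--out", r2, "--family", "naive", "--head", "dnn",
    "--epochs", "2", "--seed", "1"))), 0L)
  # same test partition: comparison succeeds
  okf <- file.path(dir, "ok.json")
  # identical predictions: the exact McNemar test warns about zero discordance
  expect_identical(suppressWarnings(suppressMessages(ctg_cli(c(
    "compare", "--result-a", r1, "--result-b", r1,
    "--tag-a", "dnn", "--tag-b", "dnn", "--out", okf,
    "--resamples", "100")))), 0L)
  expect_true(file.exists(okf))
  # different test partitions: refused
  expect_identical(suppressMessages(ctg_cli(c(
    "compare", "--result-a", r1, "--result-b", r2,
    "--tag-a", "dnn", "--tag-b", "dnn", "--out", file.path(dir, "no.json"),
    "--resamples", "100"))), 1L)
})
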