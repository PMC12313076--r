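# Configuration, dataset/model I/O, seed fan-out, artifact lineage and the
# command-line entry points tying the stages into a reproducible pipeline.

#' Derive a stage seed from the global seed
#'
#' A single global seed fans out to per-stage seeds through a fixed hash of
#' the stage name, so stages can be re-run independently yet reproducibly.
#'
#' @param global_seed Integer global seed.
#' @param stage Stage name.
#' @return Integer seed below 2^31.
#' @export
derive_seed <- function(global_seed, stage) {
  h <- fnv1a32(charToRaw(stage))
  as.integer((as.numeric(global_seed) * 7919 + h) %% 2147483047) + 1L
}

# FNV-1a 32-bit hash over raw bytes (doubles stay exact below 2^53)
fnv1a32 <- function(bytes) {
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- bitwXor_dbl(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

bitwXor_dbl <- function(a, b) {
  # xor of doubles holding 32-bit values
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  hi * 65536 + lo
}

#' Hash an R object for artifact lineage
#'
#' @param x Any serializable object.
#' @return Hex string of the 32-bit FNV-1a hash of its serialization.
#' @export
config_hash <- function(x) {
  h <- fnv1a32(serialize(x, NULL, version = 2))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Read a labeled dataset CSV
#'
#' Validates the schema (exact column set), the label and deceleration
#' vocabularies and the split values; schema violations name the offending
#' row.
#'
#' @param path CSV path.
#' @return Dataset data frame.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(sort(names(df)), sort(DATASET_COLUMNS))) {
    stop("dataset columns must be exactly: ", paste(DATASET_COLUMNS, collapse = ", "))
  }
  df <- df[, DATASET_COLUMNS]
  check_vocab <- function(col, allowed) {
    bad <- which(!df[[col]] %in% allowed)
    if (length(bad) > 0) {
      stop("invalid ", col, " '", df[[col]][bad[1L]], "' at row ", bad[1L])
    }
  }
  if (nrow(df) > 0) {
    check_vocab("label", CLASS_LEVELS)
    check_vocab("deceleration", DECEL_LEVELS)
    check_vocab("split", SPLIT_LEVELS)
    num_cols <- setdiff(DATASET_COLUMNS, c("deceleration", "label", "split"))
    for (cn in num_cols) {
      bad <- which(!is.finite(df[[cn]]))
      if (length(bad) > 0) stop("non-finite ", cn, " at row ", bad[1L])
    }
  }
  df
}

#' Write a labeled dataset CSV
#'
#' @param dataset Dataset data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(all(DATASET_COLUMNS %in% names(dataset)))
  utils::write.csv(dataset[, DATASET_COLUMNS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Bundles the stage configurations; every stage consumes its sub-config plus
#' a seed derived from `seed`. Serializes losslessly to YAML via
#' [write_run_config()] / [read_run_config()].
#'
#' @param fixture A [fixture_config()].
#' @param experiment An [experiment_config()].
#' @param seed Global seed.
#' @return A `run_config` list.
#' @export
run_config <- function(fixture = fixture_config(), experiment = experiment_config(),
                       seed = 1L) {
  structure(list(fixture = fixture, experiment = experiment,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  lst <- rapply(unclass(config),
                function(x) if (is.null(names(x))) x else as.list(x),
                how = "list")
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lst <- yaml::read_yaml(path)
  fx <- lst$fixture
  ranges <- fx$ranges
  ranges$fhr_baseline$non_reassuring <- lapply(ranges$fhr_baseline$non_reassuring, unlist)
  ranges$baseline_variability$non_reassuring <- lapply(ranges$baseline_variability$non_reassuring, unlist)
  ranges$accelerations$non_reassuring <- lapply(ranges$accelerations$non_reassuring, unlist)
  ranges$reassuring <- NULL
  for (f in c("fhr_baseline", "baseline_variability", "accelerations")) {
    ranges[[f]]$reassuring <- unlist(ranges[[f]]$reassuring)
  }
  ranges$deceleration <- lapply(ranges$deceleration, unlist)
  ranges$clinical <- lapply(ranges$clinical, unlist)
  fixture <- fixture_config(
    train_counts = unlist(fx$train_counts), test_counts = unlist(fx$test_counts),
    validation_fraction = fx$validation_fraction, ranges = ranges, seed = fx$seed
  )
  ex <- lst$experiment
  experiment <- experiment_config(
    task = ex$task, runs = ex$runs, families = unlist(ex$families),
    heads = unlist(ex$heads), classifier_epochs = ex$classifier_epochs,
    classifier_patience = ex$classifier_patience,
    began = do.call(began_config, ex$began_config),
    ae = do.call(ae_config, ex$ae_config),
    plan_args = ex$plan_args %||% list(), seed = ex$seed
  )
  run_config(fixture = fixture, experiment = experiment, seed = lst$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline
#'
#' Generates (or loads) the dataset, trains per-class generators and the
#' autoencoders, trains the classifier families and evaluates them on the
#' real test partition — the end-to-end augmentation-plus-classification
#' procedure.
#'
#' @param config A [run_config()].
#' @param dataset Optional pre-loaded dataset (skips generation).
#' @return An `experiment_result` with `config_hash` and `test_hash`
#'   attributes for lineage.
#' @export
run_pipeline <- function(config = run_config(), dataset = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(dataset)) {
    fx <- config$fixture
    fx$seed <- derive_seed(config$seed, "fixtures")
    dataset <- generate_dataset(fx)
  }
  ex <- config$experiment
  ex$seed <- derive_seed(config$seed, "experiment")
  res <- run_experiment(dataset, ex)
  attr(res, "config_hash") <- config_hash(unclass(config))
  attr(res, "test_hash") <- config_hash(dataset[dataset$split == "test", ])
  res
}

result_to_json <- function(res, path) {
  out <- list(
    task = res$task, n_test = res$n_test,
    config_hash = attr(res, "config_hash"),
    test_hash = attr(res, "test_hash"),
    plan = as.list(unclass(res$plan)),
    models = lapply(res$reports, function(rp) {
      list(tag = rp$tag, family = rp$family, head = rp$head, runs = rp$n_runs,
           best = list(accuracy = rp$best$accuracy,
                       confusion = as.data.frame.matrix(rp$best$confusion),
                       per_class = rp$best$per_class, auc = rp$best$auc),
           stats = rp$stats)
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

## ---- command-line interface ----

cli_usage <- function() {
  paste(
    "usage: ctgaug <command> [options]",
    "commands:",
    "  generate-data --out FILE [--config FILE] [--seed N]",
    "  preprocess    --in FILE --out FILE [--meta FILE]",
    "  train-gan     --in FILE --outdir DIR [--task binary|multiclass] [--seed N] [--epochs N]",
    "  augment       --in FILE --modeldir DIR --out FILE [--task binary|multiclass] [--seed N]",
    "  train-ae      --in FILE --out FILE [--epochs N] [--seed N]",
    "  train-clf     --in FILE --out FILE --family FAM --head HEAD [--encoder FILE]",
    "                [--task binary|multiclass] [--runs N] [--epochs N] [--seed N]",
    "  evaluate      --model FILE --in FILE --out FILE",
    "  compare       --result-a FILE [--result-b FILE] --tag-a TAG --tag-b TAG --out FILE [--seed N] [--resamples N]",
    "  run-all       --outdir DIR [--config FILE] [--seed N] [--runs N] [--epochs N]",
    sep = "\n")
}

parse_flags <- function(argv) {
  flags <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stop("usage: unexpected argument '", a, "'")
    if (i == length(argv) || startsWith(argv[i + 1L], "--")) {
      stop("usage: flag ", a, " needs a value")
    }
    flags[[substring(a, 3L)]] <- argv[i + 1L]
    i <- i + 2L
  }
  flags
}

flag_or <- function(flags, name, default = NULL, required = FALSE) {
  v <- flags[[name]]
  if (is.null(v)) {
    if (required) stop("usage: missing required flag --", name)
    return(default)
  }
  v
}

cli_log <- function(...) message(format(Sys.time(), "%H:%M:%S"), " [ctgaug] ", ...)

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands (see the package CLI script in
#' `inst/cli/ctgaug.R`). Returns the exit status instead of quitting so it is
#' testable: 0 on success, 1 on validation/input errors, 2 on usage errors.
#'
#' @param argv Character vector of arguments (excluding the program name).
#' @return Integer exit status, invisibly.
#' @export
ctg_cli <- function(argv = character()) {
  status <- tryCatch({
    ctg_cli_run(argv)
    0L
  },
  ctgaug_usage = function(e) {
    message(conditionMessage(e))
    message(cli_usage())
    2L
  },
  error = function(e) {
    msg <- conditionMessage(e)
    if (startsWith(msg, "usage:")) {
      message(msg)
      message(cli_usage())
      return(2L)
    }
    message("error: ", msg)
    1L
  })
  invisible(status)
}

ctg_cli_run <- function(argv) {
  if (length(argv) == 0L) stop("usage: no command given")
  cmd <- argv[1L]
  flags <- parse_flags(argv[-1L])
  seed <- as.integer(flag_or(flags, "seed", "1"))

  load_config <- function() {
    cfg_path <- flag_or(flags, "config")
    if (is.null(cfg_path)) run_config(seed = seed) else read_run_config(cfg_path)
  }

  switch(cmd,
    "generate-data" = {
      out <- flag_or(flags, "out", required = TRUE)
      cfg <- load_config()
      fx <- cfg$fixture
      if (!is.null(flags$seed)) fx$seed <- seed
      ds <- generate_dataset(fx)
      write_dataset(ds, out)
      cli_log("wrote ", nrow(ds), " records to ", out,
              " (config ", config_hash(unclass(fx)), ", seed ", fx$seed, ")")
    },
    "preprocess" = {
      ds <- read_dataset(flag_or(flags, "in", required = TRUE))
      out <- flag_or(flags, "out", required = TRUE)
      enc <- encode_dataset(ds)
      df <- as.data.frame(enc$X)
      df$label <- enc$labels
      df$split <- enc$split
      utils::write.csv(df, out, row.names = FALSE, quote = FALSE)
      meta <- flag_or(flags, "meta", paste0(out, ".meta.json"))
      jsonlite::write_json(as.list(enc$means), meta, auto_unbox = TRUE, digits = NA)
      cli_log("wrote feature matrix (", nrow(df), " x ", ncol(enc$X), ") to ", out)
    },
    "train-gan" = {
      ds <- read_dataset(flag_or(flags, "in", required = TRUE))
      outdir <- flag_or(flags, "outdir", required = TRUE)
      task <- flag_or(flags, "task", "multiclass")
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      enc <- encode_dataset(ds)
      tr <- enc$split %in% c("train", "validation")
      y <- enc$labels[tr]
      if (task == "binary") y <- merge_binary_labels(y)
      counts <- table(y)
      plan <- make_plan(stats::setNames(as.vector(counts), names(counts)), mode = task)
      bc <- began_config(seed = seed)
      if (!is.null(flags$epochs)) bc$max_epochs <- as.integer(flags$epochs)
      for (cls in names(plan)) {
        if (plan[[cls]] == 0L) next
        bc$seed <- derive_seed(seed, paste0("began-", cls))
        model <- train_began(enc$X[tr, , drop = FALSE][y == cls, , drop = FALSE], bc)
        saveRDS(model, file.path(outdir, paste0(cls, ".rds")))
        jsonlite::write_json(
          list(class = cls, epochs_run = model$epochs_run,
               stop_reason = model$stop_reason, M_history = model$history,
               seed = bc$seed, config_hash = config_hash(unclass(bc))),
          file.path(outdir, paste0(cls, ".json")), auto_unbox = TRUE, digits = NA)
        cli_log("trained generator for ", cls, ": ", model$epochs_run,
                " epochs (", model$stop_reason, ")")
      }
    },
    "augment" = {
      ds <- read_dataset(flag_or(flags, "in", required = TRUE))
      modeldir <- flag_or(flags, "modeldir", required = TRUE)
      out <- flag_or(flags, "out", required = TRUE)
      task <- flag_or(flags, "task", "multiclass")
      enc <- encode_dataset(ds)
      tr <- enc$split %in% c("train", "validation")
      y <- enc$labels[tr]
      if (task == "binary") y <- merge_binary_labels(y)
      counts <- table(y)
      plan <- make_plan(stats::setNames(as.vector(counts), names(counts)), mode = task)
      gens <- list()
      for (cls in names(plan)) {
        if (plan[[cls]] == 0L) next
        f <- file.path(modeldir, paste0(cls, ".rds"))
        if (!file.exists(f)) stop("missing trained generator artifact: ", f)
        gens[[cls]] <- readRDS(f)
      }
      ed <- expand_dataset(enc$X[tr, , drop = FALSE], y, gens, plan, seed = seed)
      df <- as.data.frame(ed$X)
      df$label <- ed$labels
      df$source <- ed$source
      utils::write.csv(df, out, row.names = FALSE, quote = FALSE)
      cli_log("wrote expanded dataset (", nrow(df), " rows, ",
              sum(ed$source == "synthetic"), " synthetic) to ", out)
    },
    "train-ae" = {
      inp <- flag_or(flags, "in", required = TRUE)
      if (!file.exists(inp)) stop("missing input file: ", inp)
      df <- utils::read.csv(inp, stringsAsFactors = FALSE)
      X <- as.matrix(df[, setdiff(names(df), c("label", "source", "split"))])
      ac <- ae_config(seed = derive_seed(seed, "ae"))
      if (!is.null(flags$epochs)) ac$epochs <- as.integer(flags$epochs)
      model <- train_autoencoder(X, ac)
      saveRDS(model, flag_or(flags, "out", required = TRUE))
      cli_log("autoencoder trained: reconstruction error ",
              sprintf("%.4g -> %.4g", model$record$initial_error,
                      model$record$final_error))
    },
    "train-clf" = {
      ds <- read_dataset(flag_or(flags, "in", required = TRUE))
      out <- flag_or(flags, "out", required = TRUE)
      family <- flag_or(flags, "family", required = TRUE)
      head_kind <- flag_or(flags, "head", required = TRUE)
      task <- flag_or(flags, "task", "multiclass")
      n_runs <- as.integer(flag_or(flags, "runs", "1"))
      epochs <- as.integer(flag_or(flags, "epochs", "100"))
      if (!family %in% names(MODEL_FAMILIES)) stop("usage: unknown family '", family, "'")
      if (!head_kind %in% MODEL_FAMILIES[[family]]$heads) {
        stop("usage: head '", head_kind, "' is not part of the ", family, " family")
      }
      enc <- encode_dataset(ds)
      is_tr <- enc$split %in% c("train", "validation")
      is_va <- enc$split == "validation"
      is_te <- enc$split == "test"
      encoder <- NULL
      if (family != "naive") {
        encf <- flag_or(flags, "encoder")
        if (is.null(encf) || !file.exists(encf)) {
          stop("missing encoder artifact (run train-ae first): ",
               if (is.null(encf)) "--encoder not given" else encf)
        }
        encoder <- extract_encoder(readRDS(encf))
      }
      if (family == "proposed") {
        expf <- flag_or(flags, "expanded")
        if (is.null(expf) || !file.exists(expf)) {
          stop("missing expanded-dataset artifact (run augment first): ",
               if (is.null(expf)) "--expanded not given" else expf)
        }
        edf <- utils::read.csv(expf, stringsAsFactors = FALSE)
        X_tr <- as.matrix(edf[, setdiff(names(edf), c("label", "source"))])
        y_tr <- edf$label
      } else {
        X_tr <- enc$X[is_tr, , drop = FALSE]
        y_tr <- enc$labels[is_tr]
      }
      task_classes <- if (task == "binary") BINARY_LEVELS else CLASS_LEVELS
      y_te <- enc$labels[is_te]
      if (task == "binary") y_te <- merge_binary_labels(y_te)
      runs <- vector("list", n_runs)
      preds <- vector("list", n_runs)
      for (r in seq_len(n_runs)) {
        input_dim <- if (is.null(encoder)) ncol(X_tr) else encoder$code_dim
        model <- build_head(head_kind, input_dim, task)
        if (!is.null(encoder)) model <- concat_model(encoder, model)
        model <- train_classifier(
          model, X_tr, y_tr, epochs = epochs,
          X_valid = if (any(is_va)) enc$X[is_va, , drop = FALSE],
          labels_valid = if (any(is_va)) enc$labels[is_va],
          seed = derive_seed(seed, sprintf("clf-%s-%s-run%d", family, head_kind, r)))
        pr <- predict(model, enc$X[is_te, , drop = FALSE])
        runs[[r]] <- eval_report(y_te, pr$label, pr$prob, task_classes)
        preds[[r]] <- pr$label
      }
      rp <- summarize_runs(runs, tag = model_tag(family, head_kind),
                           family = family, head = head_kind, task = task)
      rp$best_pred <- preds[[rp$best_run]]
      res <- structure(list(reports = stats::setNames(list(rp), rp$tag),
                            task = task, n_test = sum(is_te), truth = y_te),
                       class = "experiment_result")
      attr(res, "test_hash") <- config_hash(ds[ds$split == "test", ])
      saveRDS(res, out)
      cli_log(rp$tag, ": best accuracy ", sprintf("%.4f", rp$best$accuracy),
              " over ", rp$n_runs, " run(s)")
    },
    "evaluate" = {
      res <- readRDS(flag_or(flags, "model", required = TRUE))
      out <- flag_or(flags, "out", required = TRUE)
      result_to_json(res, out)
      cli_log("wrote evaluation report to ", out)
    },
    "compare" = {
      res_a <- readRDS(flag_or(flags, "result-a", required = TRUE))
      res_b_path <- flag_or(flags, "result-b")
      res_b <- if (is.null(res_b_path)) res_a else readRDS(res_b_path)
      tag_a <- flag_or(flags, "tag-a", required = TRUE)
      tag_b <- flag_or(flags, "tag-b", required = TRUE)
      out <- flag_or(flags, "out", required = TRUE)
      ha <- attr(res_a, "test_hash")
      hb <- attr(res_b, "test_hash")
      if (!is.null(ha) && !is.null(hb) && !identical(ha, hb)) {
        stop("test-partition hashes differ (", ha, " vs ", hb,
             "); refusing to compare results from different test sets")
      }
      rp_a <- res_a$reports[[tag_a]]
      rp_b <- res_b$reports[[tag_b]]
      if (is.null(rp_a) || is.null(rp_b)) stop("unknown model tag")
      cmp <- compare_models(rp_a$best_pred, rp_b$best_pred, res_a$truth,
                            resamples = as.integer(flag_or(flags, "resamples", "10000")),
                            seed = seed)
      jsonlite::write_json(
        list(a = tag_a, b = tag_b,
             mcnemar = cmp$mcnemar,
             accuracy_diff_ci = as.numeric(cmp$accuracy_diff_ci),
             test_hash = ha),
        out, auto_unbox = TRUE, digits = NA)
      cli_log("wrote comparison (", tag_a, " vs ", tag_b, ") to ", out)
    },
    "run-all" = {
      outdir <- flag_or(flags, "outdir", required = TRUE)
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      cfg <- load_config()
      cfg$seed <- seed
      if (!is.null(flags$runs)) cfg$experiment$runs <- as.integer(flags$runs)
      if (!is.null(flags$epochs)) cfg$experiment$classifier_epochs <- as.integer(flags$epochs)
      res <- run_pipeline(cfg)
      result_to_json(res, file.path(outdir, "metrics.json"))
      cli_log("pipeline complete; metrics at ", file.path(outdir, "metrics.json"),
              " (config ", attr(res, "config_hash"), ", seed ", cfg$seed, ")")
    },
    stop("usage: unknown command '", cmd, "'")
  )
  invisible(NULL)
}
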