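# Classifier heads (dense, 1-D convolutional, LSTM), composition with the
# frozen encoder, supervised training on the (possibly GAN-expanded) training
# set, and the repeated-run experiment protocol comparing the naive, advanced
# and proposed model families.

BINARY_LEVELS <- c("normal", "abnormal")

#' Build an untrained classifier head
#'
#' `dnn`: dense 32 -> 16 -> output. `cnn1d`: 1-D convolution with 32 filters
#' (kernel 3, the row treated as a single-channel sequence) -> dense 16 ->
#' output. `lstm`: two recurrent layers of 64 cells -> dense 32 -> output.
#' Rectifier activations throughout and a softmax output of dimension 2
#' (binary) or 3 (multiclass).
#'
#' @param kind `"dnn"`, `"cnn1d"` or `"lstm"`.
#' @param input_dim Feature dimension consumed by the head.
#' @param task `"binary"` or `"multiclass"`.
#' @return An untrained `ctg_classifier`.
#' @export
build_head <- function(kind = c("dnn", "cnn1d", "lstm"), input_dim,
                       task = c("multiclass", "binary")) {
  kind <- match.arg(kind)
  task <- match.arg(task)
  out_dim <- if (task == "binary") 2L else 3L
  structure(list(
    head = head_new(kind, as.integer(input_dim), out_dim),
    kind = kind, task = task, out_dim = out_dim,
    encoder = NULL, frozen = FALSE, trained = FALSE,
    classes = if (task == "binary") BINARY_LEVELS else CLASS_LEVELS
  ), class = "ctg_classifier")
}

#' Compose a frozen encoder with a classifier head
#'
#' The composite consumes raw fused feature rows, passes them through the
#' encoder — whose parameters are frozen and never updated by training — and
#' feeds the codes to the head.
#'
#' @param encoder A `ctg_encoder` from [extract_encoder()].
#' @param head An untrained `ctg_classifier` whose input dimension equals the
#'   encoder code dimension.
#' @return The composite `ctg_classifier`.
#' @export
concat_model <- function(encoder, head) {
  stopifnot(inherits(encoder, "ctg_encoder"), inherits(head, "ctg_classifier"))
  if (head$head$input_dim != encoder$code_dim) {
    stop("head input dimension (", head$head$input_dim,
         ") != encoder code dimension (", encoder$code_dim, ")")
  }
  head$encoder <- encoder
  head$frozen <- TRUE
  head
}

#' Merge three-class labels for the binary task
#'
#' Suspicious and pathological collapse into a single abnormal class.
#'
#' @param labels Character vector of class labels.
#' @return Labels over `normal`/`abnormal`.
#' @export
merge_binary_labels <- function(labels) {
  bad <- setdiff(unique(labels), c(CLASS_LEVELS, BINARY_LEVELS))
  if (length(bad) > 0) stop("unknown label(s): ", paste(bad, collapse = ", "))
  ifelse(labels == "normal", "normal", "abnormal")
}

#' Train a classifier
#'
#' Cross-entropy training with Adam; for the binary task suspicious and
#' pathological labels are merged into abnormal first. When a composite model
#' carries a frozen encoder, inputs are passed through it (its parameters are
#' untouched). Optional validation data triggers early stopping on validation
#' loss.
#'
#' @param model A `ctg_classifier`.
#' @param X Numeric matrix of feature rows (raw fused features for composite
#'   models, head-space features otherwise).
#' @param labels Class label per row.
#' @param epochs,batch_size,learning_rate,patience Training control parameters.
#' @param X_valid,labels_valid Optional validation data for early stopping.
#' @param seed Integer seed.
#' @return The trained `ctg_classifier`.
#' @export
train_classifier <- function(model, X, labels, epochs = 100L, batch_size = 64L,
                             learning_rate = 1e-3, patience = 10L,
                             X_valid = NULL, labels_valid = NULL, seed = 1L) {
  stopifnot(inherits(model, "ctg_classifier"))
  X <- as.matrix(X)
  labels <- as.character(labels)
  if (model$task == "binary") labels <- merge_binary_labels(labels)
  present <- intersect(model$classes, unique(labels))
  if (length(present) < 2L) stop("training set must contain at least two classes")
  set.seed(as.integer(seed))
  if (!is.null(model$encoder)) X <- encode(model$encoder, X)
  Y <- one_hot(labels, model$classes)
  Xv <- NULL
  Yv <- NULL
  if (!is.null(X_valid)) {
    Xv <- as.matrix(X_valid)
    lv <- as.character(labels_valid)
    if (model$task == "binary") lv <- merge_binary_labels(lv)
    if (!is.null(model$encoder)) Xv <- encode(model$encoder, Xv)
    Yv <- one_hot(lv, model$classes)
  }
  model$head <- head_train(model$head, X, Y, epochs = epochs,
                           batch_size = batch_size, lr = learning_rate,
                           X_valid = Xv, Y_valid = Yv, patience = patience)
  model$trained <- TRUE
  model
}

#' Predict class probabilities and labels
#'
#' Softmax probabilities per row plus argmax labels; exact probability ties
#' resolve to the lowest class index.
#'
#' @param object A trained `ctg_classifier`.
#' @param newdata Numeric matrix of feature rows.
#' @param ... Unused.
#' @return List with `prob` (matrix, one column per class) and `label`.
#' @export
predict.ctg_classifier <- function(object, newdata, ...) {
  if (!object$trained) stop("model is not trained")
  X <- as.matrix(newdata)
  if (nrow(X) == 0L) {
    prob <- matrix(numeric(0), 0L, object$out_dim,
                   dimnames = list(NULL, object$classes))
    return(list(prob = prob, label = character(0)))
  }
  expected <- if (is.null(object$encoder)) object$head$input_dim else object$encoder$input_dim
  if (ncol(X) != expected) stop("feature dimension mismatch: got ", ncol(X),
                                ", expected ", expected)
  if (!is.null(object$encoder)) X <- encode(object$encoder, X)
  logits <- head_forward(object$head, X)$out
  prob <- softmax_rows(logits)
  colnames(prob) <- object$classes
  label <- object$classes[max.col(prob, ties.method = "first")]
  list(prob = prob, label = label)
}

#' @export
print.ctg_classifier <- function(x, ...) {
  cat(sprintf("<ctg_classifier> %s head, %s task%s%s\n", x$kind, x$task,
              if (x$frozen) ", frozen encoder attached" else "",
              if (x$trained) ", trained" else ""))
  invisible(x)
}

MODEL_FAMILIES <- list(
  naive = list(heads = c("dnn", "cnn1d", "lstm"), encoder = "none", gan = FALSE),
  advanced = list(heads = c("dnn", "cnn1d"), encoder = "plain", gan = FALSE),
  proposed = list(heads = c("dnn", "cnn1d", "lstm"), encoder = "gan", gan = TRUE)
)

model_tag <- function(family, head) {
  short <- c(dnn = "dnn", cnn1d = "cnn", lstm = "lstm")[[head]]
  switch(family,
    naive = short,
    advanced = paste0(short, "_ae"),
    proposed = if (head == "lstm") "g_lstm" else paste0("g_", short, "_ae")
  )
}

#' Experiment configuration for the family comparison
#'
#' @param task `"binary"` or `"multiclass"`.
#' @param runs Independent training runs per model (the study protocol uses
#'   100).
#' @param families Subset of `"naive"`, `"advanced"`, `"proposed"`.
#' @param heads Subset of head kinds to run within each family.
#' @param classifier_epochs,classifier_patience Classifier training controls.
#' @param began A [began_config()] for the per-class generators.
#' @param ae An [ae_config()] for the feature-extracting autoencoder.
#' @param plan_args Extra arguments passed to [make_plan()].
#' @param seed Global experiment seed.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(task = c("multiclass", "binary"), runs = 5L,
                              families = names(MODEL_FAMILIES),
                              heads = c("dnn", "cnn1d", "lstm"),
                              classifier_epochs = 100L,
                              classifier_patience = 10L,
                              began = began_config(),
                              ae = ae_config(),
                              plan_args = list(), seed = 1L) {
  task <- match.arg(task)
  families <- match.arg(families, names(MODEL_FAMILIES), several.ok = TRUE)
  structure(list(task = task, runs = as.integer(runs), families = families,
                 heads = heads, classifier_epochs = as.integer(classifier_epochs),
                 classifier_patience = as.integer(classifier_patience),
                 began_config = began, ae_config = ae,
                 plan_args = plan_args, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run the repeated-training experiment over model families
#'
#' For every requested family/head pair, trains the model `runs` times with
#' run-derived seeds and evaluates each run on the untouched real test
#' partition (synthetic rows never enter it). Per model it reports the run
#' with the best test accuracy plus mean/sd/CI statistics over runs. The
#' per-class BEGANs and the autoencoders are trained once per experiment:
#' the plain autoencoder (advanced family) on the real training rows, the
#' GAN-expanded autoencoder (proposed family) on real plus synthetic rows.
#'
#' @param dataset A labeled dataset from [generate_dataset()] (or
#'   [read_dataset()]).
#' @param config An [experiment_config()].
#' @return An `experiment_result`: list of per-model reports (see
#'   [eval_report()]) keyed by model tag, plus the encoded data and plan.
#' @export
run_experiment <- function(dataset, config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  enc <- encode_dataset(dataset)
  is_train <- enc$split %in% c("train", "validation")
  is_valid <- enc$split == "validation"
  is_test <- enc$split == "test"
  X_tr <- enc$X[is_train, , drop = FALSE]
  y_tr <- enc$labels[is_train]
  X_va <- enc$X[is_valid, , drop = FALSE]
  y_va <- enc$labels[is_valid]
  X_te <- enc$X[is_test, , drop = FALSE]
  y_te <- enc$labels[is_test]
  if (nrow(X_te) == 0L) stop("dataset has no test partition")

  task_classes <- if (config$task == "binary") BINARY_LEVELS else CLASS_LEVELS
  y_te_task <- if (config$task == "binary") merge_binary_labels(y_te) else y_te

  plan_counts <- table(factor(
    if (config$task == "binary") merge_binary_labels(y_tr) else y_tr,
    levels = task_classes))
  plan <- do.call(make_plan, c(list(class_counts = as.vector(plan_counts) |>
                                      stats::setNames(task_classes),
                                    mode = config$task),
                               config$plan_args))

  need_gan <- "proposed" %in% config$families
  gens <- NULL
  ed <- NULL
  if (need_gan) {
    gens <- list()
    y_plan <- if (config$task == "binary") merge_binary_labels(y_tr) else y_tr
    for (cls in names(plan)) {
      if (plan[[cls]] == 0L) next
      rows <- X_tr[y_plan == cls, , drop = FALSE]
      bc <- config$began_config
      bc$seed <- derive_seed(config$seed, paste0("began-", cls))
      gens[[cls]] <- train_began(rows, bc)
    }
    ed <- expand_dataset(X_tr, y_plan, gens, plan,
                         seed = derive_seed(config$seed, "augment"))
  }

  encoders <- list()
  if ("advanced" %in% config$families) {
    ac <- config$ae_config
    ac$seed <- derive_seed(config$seed, "ae-plain")
    encoders$plain <- extract_encoder(train_autoencoder(X_tr, ac))
  }
  if ("proposed" %in% config$families) {
    ac <- config$ae_config
    ac$seed <- derive_seed(config$seed, "ae-gan")
    encoders$gan <- extract_encoder(train_autoencoder(ed$X, ac))
  }

  reports <- list()
  for (family in config$families) {
    fam <- MODEL_FAMILIES[[family]]
    for (head_kind in intersect(fam$heads, config$heads)) {
      tag <- model_tag(family, head_kind)
      use_encoder <- fam$encoder != "none"
      input_dim <- if (use_encoder) config$ae_config$code_dim else ncol(X_tr)
      Xf <- if (fam$gan) ed$X else X_tr
      yf <- if (fam$gan) ed$labels else y_tr
      runs <- vector("list", config$runs)
      preds <- vector("list", config$runs)
      for (r in seq_len(config$runs)) {
        model <- build_head(head_kind, input_dim, config$task)
        if (use_encoder) {
          model <- concat_model(encoders[[fam$encoder]], model)
        }
        model <- train_classifier(
          model, Xf, yf,
          epochs = config$classifier_epochs,
          patience = config$classifier_patience,
          X_valid = if (nrow(X_va) > 0L) X_va else NULL,
          labels_valid = if (nrow(X_va) > 0L) y_va else NULL,
          seed = derive_seed(config$seed, sprintf("clf-%s-run%d", tag, r))
        )
        pr <- predict(model, X_te)
        runs[[r]] <- eval_report(y_te_task, pr$label, pr$prob, task_classes)
        preds[[r]] <- pr$label
      }
      rp <- summarize_runs(runs, tag = tag, family = family,
                           head = head_kind, task = config$task)
      rp$best_pred <- preds[[rp$best_run]]
      reports[[tag]] <- rp
    }
  }
  structure(list(reports = reports, plan = plan, task = config$task,
                 n_test = nrow(X_te), truth = y_te_task, config = config),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> task = %s, %d test rows\n", x$task, x$n_test))
  for (tag in names(x$reports)) {
    rp <- x$reports[[tag]]
    cat(sprintf("  %-10s best accuracy %.3f (mean %.3f over %d runs)\n",
                tag, rp$best$accuracy, rp$stats$accuracy$mean, rp$n_runs))
  }
  invisible(x)
}
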