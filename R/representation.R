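# Autoencoder training on the GAN-expanded dataset and extraction of the
# encoder half used downstream as a frozen feature extractor.

#' Autoencoder configuration
#'
#' Architecture input -> 80 -> 50 -> 80 -> input with rectifier hidden
#' activations and a linear output; 300 training epochs by default.
#'
#' @param hidden_width Width of the two hidden layers.
#' @param code_dim Code (bottleneck) dimension.
#' @param epochs Training epochs.
#' @param batch_size,learning_rate Mini-batch size and Adam learning rate.
#' @param seed Integer seed.
#' @return An `ae_config` list.
#' @export
ae_config <- function(hidden_width = 80L, code_dim = 50L, epochs = 300L,
                      batch_size = 64L, learning_rate = 1e-3, seed = 1L) {
  stopifnot(epochs >= 1, hidden_width >= 1, code_dim >= 1)
  structure(list(hidden_width = as.integer(hidden_width),
                 code_dim = as.integer(code_dim), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "ae_config")
}

#' Expand a training set with per-class synthetic rows
#'
#' Implements the expanded-dataset union: real training rows plus every
#' class's synthetic set, tagged with provenance. `|ED| = |TD| + sum(plan)`
#' exactly.
#'
#' @param td_train Numeric matrix of real training feature rows.
#' @param td_labels Class label per real row.
#' @param generators Named list of trained [train_began()] models, one per
#'   class with a positive plan count.
#' @param plan An [make_plan()] augmentation plan.
#' @param seed Integer seed for synthetic sampling.
#' @return List `X` (matrix), `labels`, `source` (`"real"`/`"synthetic"`).
#' @export
expand_dataset <- function(td_train, td_labels, generators, plan, seed = 1L) {
  td_train <- as.matrix(td_train)
  stopifnot(length(td_labels) == nrow(td_train))
  X <- td_train
  labels <- as.character(td_labels)
  source <- rep("real", nrow(td_train))
  for (cls in names(plan)) {
    m <- plan[[cls]]
    if (m == 0L) next
    if (is.null(generators[[cls]])) {
      stop("no trained generator for planned class '", cls, "'")
    }
    syn <- generate_synthetic(generators[[cls]], m,
                              seed = as.integer(seed) + match(cls, names(plan)))
    X <- rbind(X, syn)
    labels <- c(labels, rep(cls, m))
    source <- c(source, rep("synthetic", m))
  }
  rownames(X) <- NULL
  list(X = X, labels = labels, source = source)
}

#' Train the autoencoder on an expanded dataset
#'
#' Unsupervised mean-squared-error reconstruction training for exactly
#' `config$epochs` epochs; labels are not used. Deterministic given
#' `config$seed`.
#'
#' @param ed Numeric matrix of feature rows (real plus synthetic).
#' @param config An [ae_config()].
#' @return An `encoder_model` holding the full autoencoder, its training
#'   record (epochs, initial and final reconstruction error) and the encoder
#'   layer indices.
#' @export
train_autoencoder <- function(ed, config = ae_config()) {
  ed <- as.matrix(ed)
  if (nrow(ed) == 0L) stop("expanded dataset must be non-empty")
  if (!all(is.finite(ed))) stop("expanded dataset must be finite numeric")
  stopifnot(inherits(config, "ae_config"))
  set.seed(config$seed)
  d <- ncol(ed)
  # internal per-feature standardization so no feature's units dominate the
  # squared-error objective; the scaler travels with the extracted encoder
  sc_mu <- colMeans(ed)
  sc_sd <- apply(ed, 2L, stats::sd)
  sc_sd[!is.finite(sc_sd) | sc_sd < 1e-8] <- 1
  ed <- sweep(sweep(ed, 2L, sc_mu), 2L, sc_sd, "/")
  # the code layer is linear: a rectified 1-to-50-unit bottleneck can die
  # wholesale and freeze training, and linear codes lose no capacity here
  net <- mlp_new(c(d, config$hidden_width, config$code_dim, config$hidden_width, d),
                 linear = 2L)
  params <- mlp_params(net)
  opt <- adam_new(params)
  initial_error <- mean((ed - mlp_forward(net, ed)$out)^2)
  final_loss <- NA_real_
  for (ep in seq_len(config$epochs)) {
    ep_loss <- 0
    nb <- 0L
    for (ix in minibatches(nrow(ed), config$batch_size)) {
      net <- mlp_set_params(net, params)
      batch <- ed[ix, , drop = FALSE]
      fw <- mlp_forward(net, batch, want_cache = TRUE)
      ls <- mse_grad(fw$out, batch)
      if (!is.finite(ls$loss)) stop("autoencoder training diverged at epoch ", ep)
      gr <- mlp_backward(net, fw, ls$dZ)
      st <- adam_step(params, list(W = gr$gW, b = gr$gb), opt, config$learning_rate)
      params <- st$params
      opt <- st$state
      ep_loss <- ep_loss + ls$loss
      nb <- nb + 1L
    }
    final_loss <- ep_loss / nb
  }
  net <- mlp_set_params(net, params)
  final_error <- mean((ed - mlp_forward(net, ed)$out)^2)
  structure(list(
    autoencoder = net,
    encoder_layers = 1:2,  # input -> hidden -> code
    code_dim = config$code_dim,
    input_dim = d,
    scale_mean = sc_mu, scale_sd = sc_sd,
    record = list(epochs = config$epochs, initial_error = initial_error,
                  final_error = final_error, final_epoch_loss = final_loss,
                  seed = config$seed)
  ), class = "encoder_model")
}

#' Extract the frozen encoder from a trained autoencoder
#'
#' The returned encoder shares the autoencoder's first-half parameters
#' exactly (same objects, bit for bit).
#'
#' @param model An `encoder_model` from [train_autoencoder()].
#' @return A `ctg_encoder` usable with [encode()].
#' @export
extract_encoder <- function(model) {
  if (!inherits(model, "encoder_model") || is.null(model$autoencoder)) {
    stop("model is not a trained encoder_model")
  }
  li <- model$encoder_layers
  net <- list(W = model$autoencoder$W[li], b = model$autoencoder$b[li],
              sizes = model$autoencoder$sizes[c(li, max(li) + 1L)],
              linear = intersect(model$autoencoder$linear, li))
  structure(list(net = net, code_dim = model$code_dim,
                 input_dim = model$input_dim,
                 scale_mean = model$scale_mean, scale_sd = model$scale_sd),
            class = "ctg_encoder")
}

#' Map feature rows to their encoder codes
#'
#' @param encoder A `ctg_encoder` from [extract_encoder()].
#' @param X Numeric matrix of feature rows.
#' @return `nrow(X)` x code-dimension matrix.
#' @export
encode <- function(encoder, X) {
  stopifnot(inherits(encoder, "ctg_encoder"))
  X <- as.matrix(X)
  if (ncol(X) != encoder$input_dim) stop("feature dimension mismatch")
  H <- sweep(sweep(X, 2L, encoder$scale_mean), 2L, encoder$scale_sd, "/")
  L <- length(encoder$net$W)
  for (i in seq_len(L)) {
    Z <- add_bias(H %*% encoder$net$W[[i]], encoder$net$b[[i]])
    # mirror the autoencoder's activations exactly, incl. the linear code
    H <- if (i %in% encoder$net$linear) Z else relu(Z)
  }
  H
}

#' @export
print.encoder_model <- function(x, ...) {
  cat(sprintf("<encoder_model> %d -> %d code, %d epochs, reconstruction error %.4g -> %.4g\n",
              x$input_dim, x$code_dim, x$record$epochs,
              x$record$initial_error, x$record$final_error))
  invisible(x)
}

#' @export
print.ctg_encoder <- function(x, ...) {
  cat(sprintf("<ctg_encoder> %d -> %d (frozen feature extractor)\n",
              x$input_dim, x$code_dim))
  invisible(x)
}
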