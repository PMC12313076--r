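# Per-class boundary-equilibrium GANs (BEGAN) over the fused feature space.
# The discriminator is autoencoder-shaped; training balances real and generated
# reconstruction losses through a proportional control variable k, and stops
# when the convergence measure
#   M = lambda(real) + |alpha * lambda(real) - lambda(generated)|
# falls below a threshold (0.058 by default) or the epoch cap is reached.

#' BEGAN training configuration
#'
#' Defaults follow the study conditions: 50 latent dimensions, 80 hidden
#' neurons, rectifier activations, convergence threshold 0.058 and epoch cap
#' 280. The diversity ratio `alpha` balances sample diversity against quality;
#' it is the equilibrium target for the ratio of generated-sample to
#' real-sample reconstruction loss.
#'
#' @param latent_dim Generator input (latent) dimension.
#' @param bottleneck_dim Code width of the autoencoder-shaped discriminator.
#'   `NULL` (default) uses half the feature dimension (at least 1, at most
#'   `latent_dim`), chosen at training time. The discriminator must not be
#'   able to represent the identity map, otherwise it reconstructs generated
#'   samples as well as real ones and the equilibrium control never engages.
#' @param hidden_width Hidden layer width of generator and discriminator.
#' @param alpha Diversity ratio in (0, 1].
#' @param convergence_threshold Stop when the convergence measure drops below
#'   this value.
#' @param max_epochs Epoch cap.
#' @param equilibrium_gain Proportional gain of the control variable update.
#' @param batch_size,learning_rate Mini-batch size and Adam learning rate.
#' @param eval_batch_size Size of the fixed batch on which the per-epoch
#'   convergence measure is computed.
#' @param seed Integer seed.
#' @return A `began_config` list.
#' @export
began_config <- function(latent_dim = 50L, bottleneck_dim = NULL,
                         hidden_width = 80L, alpha = 0.5,
                         convergence_threshold = 0.058, max_epochs = 280L,
                         equilibrium_gain = 0.001, batch_size = 64L,
                         learning_rate = 1e-3, eval_batch_size = 128L,
                         seed = 1L) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (convergence_threshold < 0) stop("convergence_threshold must be >= 0")
  if (max_epochs < 1) stop("max_epochs must be >= 1")
  if (equilibrium_gain <= 0) stop("equilibrium_gain must be positive")
  # zero-length means "use the default" (a NULL becomes an empty node in YAML)
  if (length(bottleneck_dim) == 0L) bottleneck_dim <- NULL
  if (!is.null(bottleneck_dim) && bottleneck_dim < 1) {
    stop("bottleneck_dim must be >= 1")
  }
  structure(list(
    latent_dim = as.integer(latent_dim),
    bottleneck_dim = if (is.null(bottleneck_dim)) NULL else as.integer(bottleneck_dim),
    hidden_width = as.integer(hidden_width),
    alpha = alpha, convergence_threshold = convergence_threshold,
    max_epochs = as.integer(max_epochs), equilibrium_gain = equilibrium_gain,
    batch_size = as.integer(batch_size), learning_rate = learning_rate,
    eval_batch_size = as.integer(eval_batch_size), seed = as.integer(seed)
  ), class = "began_config")
}

#' Mean absolute reconstruction error of a batch
#'
#' `lambda(x) = mean |x - D(x)|` where `D` is the discriminator's autoencoding
#' map.
#'
#' @param batch Numeric matrix, one row per record.
#' @param discriminator Either a function mapping a batch to its
#'   reconstruction, or a trained `began_model` (its discriminator is used).
#' @return Non-negative scalar.
#' @export
reconstruction_error <- function(batch, discriminator) {
  batch <- as.matrix(batch)
  if (nrow(batch) == 0L) stop("batch must be non-empty")
  rec <- if (is.function(discriminator)) {
    discriminator(batch)
  } else if (inherits(discriminator, "began_model")) {
    # a trained model reconstructs in its internal standardized space; map the
    # batch in and the reconstruction back out so the error is in data units
    bs <- sweep(sweep(batch, 2L, discriminator$scale_mean), 2L,
                discriminator$scale_sd, "/")
    rs <- mlp_forward(discriminator$discriminator, bs)$out
    sweep(sweep(rs, 2L, discriminator$scale_sd, "*"), 2L,
          discriminator$scale_mean, "+")
  } else {
    stop("discriminator must be a function or a began_model")
  }
  rec <- as.matrix(rec)
  if (!all(dim(rec) == dim(batch))) stop("reconstruction dimension mismatch")
  mean(abs(batch - rec))
}

#' BEGAN convergence measure
#'
#' `M = lambda_real + |alpha * lambda_real - lambda_fake|`. `M` is bounded
#' below by `lambda_real` and equals it exactly at equilibrium
#' (`lambda_fake == alpha * lambda_real`).
#'
#' @param lambda_real Reconstruction error of a real batch (>= 0).
#' @param lambda_fake Reconstruction error of a generated batch (>= 0).
#' @param alpha Diversity ratio.
#' @return The convergence measure `M`.
#' @export
convergence_measure <- function(lambda_real, lambda_fake, alpha) {
  if (any(c(lambda_real, lambda_fake) < 0)) {
    stop("reconstruction errors must be non-negative")
  }
  lambda_real + abs(alpha * lambda_real - lambda_fake)
}

sample_latent <- function(n, dim) matrix(stats::runif(n * dim, -1, 1), n, dim)

#' Train a BEGAN on the records of one class
#'
#' Generator: latent -> hidden -> feature space (rectifier hidden, linear
#' output). Discriminator: autoencoder-shaped feature -> hidden -> latent ->
#' hidden -> feature. Each epoch alternates discriminator and generator Adam
#' updates with the proportional control
#' `k <- clamp(k + gain * (alpha * lambda_real - lambda_fake), 0, 1)`, then
#' evaluates the convergence measure on a fixed held-out batch; training stops
#' the first epoch the measure drops below the threshold, or at the epoch cap.
#'
#' @param class_rows Numeric matrix of one class's (preprocessed) feature rows.
#' @param config A [began_config()].
#' @return A `began_model` with the convergence history, epochs run, final
#'   control variable and stop reason (`"threshold"` or `"epoch_cap"`).
#' @export
train_began <- function(class_rows, config = began_config()) {
  class_rows <- as.matrix(class_rows)
  if (nrow(class_rows) == 0L) stop("class_rows must be non-empty")
  if (!all(is.finite(class_rows))) stop("class_rows must be finite numeric")
  stopifnot(inherits(config, "began_config"))
  set.seed(config$seed)
  d <- ncol(class_rows)
  # internal per-feature standardization: reconstruction losses become O(1)
  # regardless of feature units, which is the scale the convergence threshold
  # and equilibrium gain are calibrated for; inverted on generation
  sc_mu <- colMeans(class_rows)
  sc_sd <- apply(class_rows, 2L, stats::sd)
  sc_sd[!is.finite(sc_sd) | sc_sd < 1e-8] <- 1
  class_rows <- sweep(sweep(class_rows, 2L, sc_mu), 2L, sc_sd, "/")
  bn <- config$bottleneck_dim
  if (is.null(bn)) bn <- min(config$latent_dim, max(1L, d %/% 2L))
  gen <- mlp_new(c(config$latent_dim, config$hidden_width, d))
  # linear bottleneck: a rectified narrow code can die wholesale and pin the
  # discriminator's reconstruction loss (see the autoencoder's code layer)
  dis <- mlp_new(c(d, config$hidden_width, bn, config$hidden_width, d),
                 linear = 2L)
  opt_g <- adam_new(mlp_params(gen))
  opt_d <- adam_new(mlp_params(dis))
  k <- 0
  lr <- config$learning_rate

  n_eval <- min(config$eval_batch_size, nrow(class_rows))
  eval_real <- class_rows[sample.int(nrow(class_rows), n_eval), , drop = FALSE]
  eval_z <- sample_latent(n_eval, config$latent_dim)

  history <- numeric(0)
  diag_real <- diag_fake <- diag_k <- numeric(0)
  stop_reason <- "epoch_cap"
  epochs_run <- 0L
  for (ep in seq_len(config$max_epochs)) {
    for (ix in minibatches(nrow(class_rows), config$batch_size)) {
      a <- class_rows[ix, , drop = FALSE]
      z <- sample_latent(length(ix), config$latent_dim)

      # discriminator update: minimize lambda(a) - k * lambda(G(z))
      gfw <- mlp_forward(gen, z)
      fake <- gfw$out
      dfw_a <- mlp_forward(dis, a, want_cache = TRUE)
      la <- mae_grad(dfw_a$out, a)
      dfw_f <- mlp_forward(dis, fake, want_cache = TRUE)
      lf <- mae_grad(dfw_f$out, fake)
      if (!is.finite(la$loss) || !is.finite(lf$loss)) {
        stop("BEGAN training diverged at epoch ", ep)
      }
      g_a <- mlp_backward(dis, dfw_a, la$dZ)
      g_f <- mlp_backward(dis, dfw_f, lf$dZ)
      g_dis <- list(
        W = Map(function(x, y) x - k * y, g_a$gW, g_f$gW),
        b = Map(function(x, y) x - k * y, g_a$gb, g_f$gb)
      )
      st <- adam_step(mlp_params(dis), g_dis, opt_d, lr)
      dis <- mlp_set_params(dis, st$params)
      opt_d <- st$state

      # generator update: minimize lambda(G(z)) through the updated discriminator
      gfw <- mlp_forward(gen, z, want_cache = TRUE)
      fake <- gfw$out
      dfw <- mlp_forward(dis, fake, want_cache = TRUE)
      lg <- mae_grad(dfw$out, fake)
      # d lambda / d fake has two paths: through D's input and the target term
      bk <- mlp_backward(dis, dfw, lg$dZ)
      dfake <- bk$dX - lg$dZ
      g_gen <- mlp_backward(gen, gfw, dfake)
      st <- adam_step(mlp_params(gen), list(W = g_gen$gW, b = g_gen$gb), opt_g, lr)
      gen <- mlp_set_params(gen, st$params)
      opt_g <- st$state

      k <- min(1, max(0, k + config$equilibrium_gain * (config$alpha * la$loss - lf$loss)))
    }
    # per-epoch convergence measure on the fixed evaluation batch
    fake_eval <- mlp_forward(gen, eval_z)$out
    l_real <- reconstruction_error(eval_real, function(b) mlp_forward(dis, b)$out)
    l_fake <- reconstruction_error(fake_eval, function(b) mlp_forward(dis, b)$out)
    m <- convergence_measure(l_real, l_fake, config$alpha)
    history <- c(history, m)
    diag_real <- c(diag_real, l_real)
    diag_fake <- c(diag_fake, l_fake)
    diag_k <- c(diag_k, k)
    epochs_run <- ep
    if (m < config$convergence_threshold) {
      stop_reason <- "threshold"
      break
    }
  }
  structure(list(
    generator = gen, discriminator = dis, k = k,
    history = history,
    diagnostics = data.frame(epoch = seq_along(history), m = history,
                             lambda_real = diag_real, lambda_fake = diag_fake,
                             k = diag_k),
    epochs_run = epochs_run, stop_reason = stop_reason,
    feature_dim = d, feature_names = colnames(class_rows),
    scale_mean = sc_mu, scale_sd = sc_sd, config = config
  ), class = "began_model")
}

#' Generate synthetic feature rows from a trained BEGAN
#'
#' @param state A trained `began_model`.
#' @param n Number of rows.
#' @param seed Integer seed.
#' @return `n` x feature-dimension numeric matrix.
#' @export
generate_synthetic <- function(state, n, seed = 1L) {
  if (!inherits(state, "began_model") || is.null(state$generator)) {
    stop("state is not a trained began_model")
  }
  stopifnot(n >= 0)
  set.seed(as.integer(seed))
  if (n == 0L) {
    out <- matrix(numeric(0), 0L, state$feature_dim)
  } else {
    z <- sample_latent(n, state$config$latent_dim)
    out <- mlp_forward(state$generator, z)$out
    out <- sweep(sweep(out, 2L, state$scale_sd, "*"), 2L, state$scale_mean, "+")
  }
  colnames(out) <- state$feature_names
  out
}

#' Decide per-class synthetic-record counts
#'
#' Binary mode assigns `binary_count` (default 6,000) synthetic rows to every
#' class; multiclass mode assigns `multiclass_count` (default 10,000) to each
#' class whose population share is below `minor_threshold` (default 10%) and 0
#' to the others.
#'
#' @param class_counts Named vector of per-class population counts.
#' @param mode `"binary"` or `"multiclass"`.
#' @param binary_count,multiclass_count,minor_threshold Policy constants.
#' @return An `augmentation_plan`: named vector of synthetic counts plus a
#'   `mode` attribute.
#' @export
make_plan <- function(class_counts, mode = c("multiclass", "binary"),
                      binary_count = 6000L, multiclass_count = 10000L,
                      minor_threshold = 0.10) {
  mode <- match.arg(mode)
  if (any(class_counts <= 0)) stop("class counts must be positive")
  counts <- if (mode == "binary") {
    stats::setNames(rep(as.integer(binary_count), length(class_counts)),
                    names(class_counts))
  } else {
    share <- class_counts / sum(class_counts)
    stats::setNames(ifelse(share < minor_threshold, as.integer(multiclass_count), 0L),
                    names(class_counts))
  }
  structure(counts, mode = mode, class = "augmentation_plan")
}

#' @export
print.began_model <- function(x, ...) {
  cat(sprintf("<began_model> %d features, %d epochs (stop: %s), final M = %.4f, k = %.4f\n",
              x$feature_dim, x$epochs_run, x$stop_reason,
              x$history[length(x$history)], x$k))
  invisible(x)
}

#' @export
print.augmentation_plan <- function(x, ...) {
  cat(sprintf("<augmentation_plan> mode = %s\n", attr(x, "mode")))
  print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}
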