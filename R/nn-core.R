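# Minimal neural-network training core shared by the BEGAN, autoencoder and
# classifier modules: dense, 1-D convolutional and LSTM layers in plain matrix
# code, with Adam updates. Everything is deterministic given R's RNG state.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigm <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# add a bias row-vector to every row of a matrix (column-major recycling)
add_bias <- function(z, b) z + rep(b, each = nrow(z))

he_init <- function(nr, nc) {
  s <- sqrt(6 / nr)
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

glorot_init <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

## ---- Adam over an arbitrary named list of numeric arrays ----

zeros_like <- function(params) lapply(params, function(p) {
  if (is.list(p)) zeros_like(p) else array(0, dim = if (is.null(dim(p))) length(p) else dim(p))
})

adam_new <- function(params) list(m = zeros_like(params), v = zeros_like(params), t = 0L)

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
      list(p = p, m = m, v = v)
    }
  }
  out <- Map(walk, params, grads, state$m, state$v)
  list(params = lapply(out, `[[`, "p"),
       state = list(m = lapply(out, `[[`, "m"), v = lapply(out, `[[`, "v"),
                    t = state$t))
}

## ---- dense multilayer perceptron ----

# sizes: c(input, hidden..., output); hidden activations are rectifiers,
# output is linear (losses apply their own nonlinearity). `linear` lists
# hidden layer indices that skip the rectifier — narrow bottlenecks need
# this so a dead rectifier cannot zero out the whole code.
mlp_new <- function(sizes, linear = integer(0)) {
  L <- length(sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (i in seq_len(L)) {
    W[[i]] <- he_init(sizes[i], sizes[i + 1L])
    b[[i]] <- numeric(sizes[i + 1L])
  }
  list(W = W, b = b, sizes = sizes, linear = as.integer(linear))
}

mlp_forward <- function(net, X, want_cache = FALSE) {
  L <- length(net$W)
  H <- X
  Zs <- if (want_cache) vector("list", L) else NULL
  Hs <- if (want_cache) vector("list", L + 1L) else NULL
  if (want_cache) Hs[[1L]] <- X
  for (i in seq_len(L)) {
    Z <- add_bias(H %*% net$W[[i]], net$b[[i]])
    H <- if (i < L && !(i %in% net$linear)) relu(Z) else Z
    if (want_cache) {
      Zs[[i]] <- Z
      Hs[[i + 1L]] <- H
    }
  }
  if (want_cache) list(out = H, Zs = Zs, Hs = Hs) else list(out = H)
}

# dZ: gradient w.r.t. the (linear) output layer pre-activation
mlp_backward <- function(net, cache, dZ) {
  L <- length(net$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  for (i in L:1) {
    gW[[i]] <- crossprod(cache$Hs[[i]], dZ)
    gb[[i]] <- colSums(dZ)
    dH <- dZ %*% t(net$W[[i]])
    if (i > 1L) {
      dZ <- if ((i - 1L) %in% net$linear) dH else dH * (cache$Zs[[i - 1L]] > 0)
    }
  }
  list(gW = gW, gb = gb, dX = dH)
}

mlp_params <- function(net) list(W = net$W, b = net$b)

mlp_set_params <- function(net, params) {
  net$W <- params$W
  net$b <- params$b
  net
}

## ---- 1-D convolution building blocks ----

# X: batch x length -> (batch*positions) x kernel patch matrix.
conv_im2col <- function(X, kernel) {
  B <- nrow(X)
  P <- ncol(X) - kernel + 1L
  out <- matrix(0, B * P, kernel)
  for (j in seq_len(kernel)) {
    out[, j] <- as.vector(X[, j:(j + P - 1L), drop = FALSE])
  }
  out
}

## ---- head models: uniform forward/backward interface ----
# A head maps a batch x input_dim matrix to batch x out_dim logits.

head_new <- function(kind, input_dim, out_dim,
                     cnn_filters = 32L, cnn_kernel = 3L, cnn_dense = 16L,
                     dnn_hidden = c(32L, 16L),
                     lstm_units = 64L, lstm_dense = 32L) {
  kind <- match.arg(kind, c("dnn", "cnn1d", "lstm"))
  h <- switch(kind,
    dnn = list(net = mlp_new(c(input_dim, dnn_hidden, out_dim))),
    cnn1d = {
      if (input_dim < cnn_kernel) stop("input dimension shorter than convolution kernel")
      P <- input_dim - cnn_kernel + 1L
      list(
        Wc = he_init(cnn_kernel, cnn_filters), bc = numeric(cnn_filters),
        W1 = he_init(P * cnn_filters, cnn_dense), b1 = numeric(cnn_dense),
        W2 = he_init(cnn_dense, out_dim), b2 = numeric(out_dim),
        kernel = cnn_kernel, filters = cnn_filters, positions = P
      )
    },
    lstm = {
      U <- lstm_units
      mk_layer <- function(din) {
        b <- numeric(4L * U)
        b[(U + 1L):(2L * U)] <- 1  # forget-gate bias
        list(Wx = glorot_init(din, 4L * U), Wh = glorot_init(U, 4L * U), b = b)
      }
      list(layer1 = mk_layer(1L), layer2 = mk_layer(U),
        Wd = he_init(U, lstm_dense), bd = numeric(lstm_dense),
        Wo = he_init(lstm_dense, out_dim), bo = numeric(out_dim),
        units = U)
    }
  )
  structure(list(kind = kind, input_dim = input_dim, out_dim = out_dim, h = h),
            class = "ctg_head")
}

head_forward <- function(head, X, want_cache = FALSE) {
  switch(head$kind,
    dnn = {
      fw <- mlp_forward(head$h$net, X, want_cache)
      list(out = fw$out, cache = if (want_cache) fw else NULL)
    },
    cnn1d = cnn_forward(head$h, X, want_cache),
    lstm = lstm_forward(head$h, X, want_cache)
  )
}

head_backward <- function(head, cache, dZ) {
  switch(head$kind,
    dnn = {
      g <- mlp_backward(head$h$net, cache, dZ)
      list(net = list(W = g$gW, b = g$gb))
    },
    cnn1d = cnn_backward(head$h, cache, dZ),
    lstm = lstm_backward(head$h, cache, dZ)
  )
}

# trainable arrays only; structural fields (kernel size, unit counts) stay put
head_params <- function(head) {
  switch(head$kind,
    dnn = list(net = mlp_params(head$h$net)),
    cnn1d = head$h[c("Wc", "bc", "W1", "b1", "W2", "b2")],
    lstm = head$h[c("layer1", "layer2", "Wd", "bd", "Wo", "bo")]
  )
}

head_set_params <- function(head, params) {
  if (head$kind == "dnn") {
    head$h$net <- mlp_set_params(head$h$net, params$net)
  } else {
    keep <- setdiff(names(head$h), names(params))
    head$h <- c(params, head$h[keep])
  }
  head
}

cnn_forward <- function(h, X, want_cache = FALSE) {
  B <- nrow(X)
  Xp <- conv_im2col(X, h$kernel)
  Zc <- add_bias(Xp %*% h$Wc, h$bc)
  A <- relu(Zc)
  Aflat <- A
  dim(Aflat) <- c(B, h$positions * h$filters)
  Z1 <- add_bias(Aflat %*% h$W1, h$b1)
  H1 <- relu(Z1)
  out <- add_bias(H1 %*% h$W2, h$b2)
  cache <- if (want_cache) list(Xp = Xp, Zc = Zc, Aflat = Aflat, Z1 = Z1, H1 = H1, B = B)
  list(out = out, cache = cache)
}

cnn_backward <- function(h, cache, dZ2) {
  gW2 <- crossprod(cache$H1, dZ2)
  gb2 <- colSums(dZ2)
  dZ1 <- (dZ2 %*% t(h$W2)) * (cache$Z1 > 0)
  gW1 <- crossprod(cache$Aflat, dZ1)
  gb1 <- colSums(dZ1)
  dA <- dZ1 %*% t(h$W1)
  dim(dA) <- c(cache$B * h$positions, h$filters)
  dZc <- dA * (cache$Zc > 0)
  gWc <- crossprod(cache$Xp, dZc)
  gbc <- colSums(dZc)
  list(Wc = gWc, bc = gbc, W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
}

lstm_layer_forward <- function(Xlist, lay, U) {
  Tn <- length(Xlist)
  B <- nrow(Xlist[[1L]])
  h <- matrix(0, B, U)
  cc <- matrix(0, B, U)
  H <- vector("list", Tn)
  cache <- vector("list", Tn)
  idx_i <- 1:U; idx_f <- (U + 1L):(2L * U)
  idx_o <- (2L * U + 1L):(3L * U); idx_g <- (3L * U + 1L):(4L * U)
  for (t in seq_len(Tn)) {
    G <- add_bias(Xlist[[t]] %*% lay$Wx + h %*% lay$Wh, lay$b)
    i <- sigm(G[, idx_i, drop = FALSE])
    f <- sigm(G[, idx_f, drop = FALSE])
    o <- sigm(G[, idx_o, drop = FALSE])
    g <- tanh(G[, idx_g, drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    cache[[t]] <- list(x = Xlist[[t]], hprev = h, cprev = cc,
                       i = i, f = f, o = o, g = g, tc = tc)
    h <- o * tc
    cc <- c_new
    H[[t]] <- h
  }
  list(H = H, cache = cache)
}

lstm_layer_backward <- function(cache, dH, lay, U) {
  Tn <- length(cache)
  B <- nrow(cache[[1L]]$x)
  gWx <- 0 * lay$Wx
  gWh <- 0 * lay$Wh
  gb <- 0 * lay$b
  dh_next <- matrix(0, B, U)
  dc_next <- matrix(0, B, U)
  dX <- vector("list", Tn)
  for (t in Tn:1) {
    k <- cache[[t]]
    dh <- dh_next + if (is.null(dH[[t]])) 0 else dH[[t]]
    do <- dh * k$tc
    dc <- dc_next + dh * k$o * (1 - k$tc^2)
    dG <- cbind(
      (dc * k$g) * k$i * (1 - k$i),
      (dc * k$cprev) * k$f * (1 - k$f),
      do * k$o * (1 - k$o),
      (dc * k$i) * (1 - k$g^2)
    )
    gWx <- gWx + crossprod(k$x, dG)
    gWh <- gWh + crossprod(k$hprev, dG)
    gb <- gb + colSums(dG)
    dX[[t]] <- dG %*% t(lay$Wx)
    dh_next <- dG %*% t(lay$Wh)
    dc_next <- dc * k$f
  }
  list(Wx = gWx, Wh = gWh, b = gb, dX = dX)
}

# feature row presented as a length-F sequence, one scalar per step
lstm_forward <- function(h, X, want_cache = FALSE) {
  Tn <- ncol(X)
  X1 <- lapply(seq_len(Tn), function(t) X[, t, drop = FALSE])
  l1 <- lstm_layer_forward(X1, h$layer1, h$units)
  l2 <- lstm_layer_forward(l1$H, h$layer2, h$units)
  hlast <- l2$H[[Tn]]
  Zd <- add_bias(hlast %*% h$Wd, h$bd)
  Hd <- relu(Zd)
  out <- add_bias(Hd %*% h$Wo, h$bo)
  cache <- if (want_cache) list(l1 = l1, l2 = l2, hlast = hlast, Zd = Zd, Hd = Hd, Tn = Tn)
  list(out = out, cache = cache)
}

lstm_backward <- function(h, cache, dZo) {
  gWo <- crossprod(cache$Hd, dZo)
  gbo <- colSums(dZo)
  dZd <- (dZo %*% t(h$Wo)) * (cache$Zd > 0)
  gWd <- crossprod(cache$hlast, dZd)
  gbd <- colSums(dZd)
  dHlast <- dZd %*% t(h$Wd)
  dH2 <- vector("list", cache$Tn)
  dH2[[cache$Tn]] <- dHlast
  g2 <- lstm_layer_backward(cache$l2$cache, dH2, h$layer2, h$units)
  g1 <- lstm_layer_backward(cache$l1$cache, g2$dX, h$layer1, h$units)
  list(layer1 = list(Wx = g1$Wx, Wh = g1$Wh, b = g1$b),
       layer2 = list(Wx = g2$Wx, Wh = g2$Wh, b = g2$b),
       Wd = gWd, bd = gbd, Wo = gWo, bo = gbo)
}

## ---- losses ----

softmax_ce_grad <- function(logits, Y) {
  P <- softmax_rows(logits)
  eps <- 1e-12
  loss <- -sum(Y * log(P + eps)) / nrow(Y)
  list(loss = loss, dZ = (P - Y) / nrow(Y))
}

mse_grad <- function(out, target) {
  d <- out - target
  list(loss = mean(d * d), dZ = 2 * d / length(d))
}

mae_grad <- function(out, target) {
  d <- out - target
  list(loss = mean(abs(d)), dZ = sign(d) / length(d))
}

## ---- generic mini-batch loops ----

minibatches <- function(n, batch_size) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

# Supervised cross-entropy training of a head on (X, Y one-hot).
# Optional validation set for early stopping (patience in epochs).
head_train <- function(head, X, Y, epochs = 100L, batch_size = 64L, lr = 1e-3,
                       X_valid = NULL, Y_valid = NULL, patience = 10L) {
  params <- head_params(head)
  opt <- adam_new(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  history <- numeric(0)
  for (ep in seq_len(epochs)) {
    ep_loss <- 0
    nb <- 0L
    for (ix in minibatches(nrow(X), batch_size)) {
      head <- head_set_params(head, params)
      fw <- head_forward(head, X[ix, , drop = FALSE], want_cache = TRUE)
      ls <- softmax_ce_grad(fw$out, Y[ix, , drop = FALSE])
      if (!is.finite(ls$loss)) stop("training diverged (non-finite loss) at epoch ", ep)
      gr <- head_backward(head, fw$cache, ls$dZ)
      st <- adam_step(params, gr, opt, lr)
      params <- st$params
      opt <- st$state
      ep_loss <- ep_loss + ls$loss
      nb <- nb + 1L
    }
    history <- c(history, ep_loss / nb)
    if (!is.null(X_valid)) {
      head <- head_set_params(head, params)
      fv <- head_forward(head, X_valid)
      vl <- softmax_ce_grad(fv$out, Y_valid)$loss
      if (vl < best$loss - 1e-9) {
        best <- list(loss = vl, params = params, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
  }
  if (!is.null(X_valid) && is.finite(best$loss)) params <- best$params
  head <- head_set_params(head, params)
  attr(head, "loss_history") <- history
  head
}

one_hot <- function(labels, levels) {
  Y <- matrix(0, length(labels), length(levels))
  Y[cbind(seq_along(labels), match(labels, levels))] <- 1
  Y
}
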