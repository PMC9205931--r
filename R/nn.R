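# Minimal vectorized CNN engine: valid 1-D convolutions over the position
# axis (the first layer's kernel spans the full 4-base axis, collapsing it),
# leaky-ReLU, dropout on dense hidden layers, softmax output, categorical
# cross-entropy, Adam. Implemented with dense matrix algebra only: batches
# are processed as one big im2col gather followed by a single crossprod per
# layer, which keeps minutes-scale CPU training practical for networks of
# this size (one to three conv layers of 4-16 filters, a few dense layers).
#
# Activation layout: a batch is a (channels*positions) x batch matrix with
# channel-within-position (position-major) row order; the raw input uses
# channels = the 4 bases, matching .encode_batch().

.leaky <- function(x, slope) {
  neg <- x < 0
  x[neg] <- x[neg] * slope
  x
}
.leaky_grad <- function(x, slope) {
  g <- array(1, dim(x))
  g[x < 0] <- slope
  g
}

# He-style initialization, deterministic given the seeded global RNG
.init_mat <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

# Build the weight list for a model_config. Convolution kernels are stored
# as (kernel_extent * in_channels) x filters matrices; dense weights as
# in x out.
.nn_init <- function(config) {
  layers <- list()
  cin <- 4L
  pin <- config$input_width
  for (cl in config$conv_layers) {
    k <- cl$kernel_extent
    if (pin - k + 1L < 1L)
      stop("convolution stack consumes more positions than the input has")
    layers[[length(layers) + 1L]] <- list(
      type = "conv", W = .init_mat(k * cin, cl$n_filters),
      b = numeric(cl$n_filters), k = k, cin = cin, pin = pin)
    cin <- cl$n_filters
    pin <- pin - k + 1L
  }
  nin <- cin * pin
  for (w in config$dense_layers) {
    layers[[length(layers) + 1L]] <- list(
      type = "dense", W = .init_mat(nin, w), b = numeric(w))
    nin <- w
  }
  layers[[length(layers) + 1L]] <- list(
    type = "out", W = .init_mat(nin, config$n_classes),
    b = numeric(config$n_classes))
  layers
}

# im2col row-gather index for a conv layer: patches of k positions with cin
# channels each, over pout output positions
.conv_idx <- function(k, cin, pout) {
  outer(seq_len(k * cin), (seq_len(pout) - 1L) * cin, `+`)
}

# Forward pass. X: (cin*pin) x B. Returns list(probs, cache) where cache
# holds per-layer pre-activations and inputs for backprop. `train` enables
# dropout on dense hidden layers.
.nn_forward <- function(layers, X, config, train = FALSE) {
  B <- ncol(X)
  cache <- vector("list", length(layers))
  cur <- X
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      pout <- ly$pin - ly$k + 1L
      idx <- .conv_idx(ly$k, ly$cin, pout)
      A <- cur[idx, , drop = FALSE]
      dim(A) <- c(ly$k * ly$cin, pout * B)
      Z <- crossprod(ly$W, A) + ly$b
      H <- .leaky(Z, config$leaky_slope)
      cache[[i]] <- list(A = A, Z = Z, pout = pout, B = B, input_dim = dim(cur))
      dim(H) <- c(ncol(ly$W) * pout, B)
      cur <- H
    } else {
      Z <- crossprod(ly$W, cur) + ly$b
      if (ly$type == "out") {
        Z <- Z - rep(apply(Z, 2L, max), each = nrow(Z))
        E <- exp(Z)
        P <- E / rep(colSums(E), each = nrow(E))
        cache[[i]] <- list(input = cur)
        cur <- P
      } else {
        H <- .leaky(Z, config$leaky_slope)
        mask <- NULL
        if (train && config$dropout_rate > 0) {
          keep <- 1 - config$dropout_rate
          mask <- matrix(stats::rbinom(length(H), 1L, keep) / keep,
                         nrow(H), ncol(H))
          H <- H * mask
        }
        cache[[i]] <- list(input = cur, Z = Z, mask = mask)
        cur <- H
      }
    }
  }
  list(probs = cur, cache = cache)
}

# Backward pass from softmax + cross-entropy. labels: 0-based integers.
# Returns gradients as a list parallel to `layers` with elements $W, $b.
.nn_backward <- function(layers, cache, probs, labels, config) {
  B <- ncol(probs)
  delta <- probs
  delta[cbind(labels + 1L, seq_len(B))] <-
    delta[cbind(labels + 1L, seq_len(B))] - 1
  delta <- delta / B
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    cc <- cache[[i]]
    if (ly$type %in% c("out", "dense")) {
      if (ly$type == "dense") {
        if (!is.null(cc$mask)) delta <- delta * cc$mask
        delta <- delta * .leaky_grad(cc$Z, config$leaky_slope)
      }
      grads[[i]] <- list(W = cc$input %*% t(delta), b = rowSums(delta))
      if (i > 1L) delta <- ly$W %*% delta
    } else {
      # delta arrives as (filters*pout) x B; reshape to filters x (pout*B)
      f <- ncol(ly$W)
      dim(delta) <- c(f, cc$pout * cc$B)
      delta <- delta * .leaky_grad(cc$Z, config$leaky_slope)
      grads[[i]] <- list(W = cc$A %*% t(delta), b = rowSums(delta))
      if (i > 1L) {
        dA <- ly$W %*% delta                       # (k*cin) x (pout*B)
        dX <- array(0, c(ly$cin, ly$pin, cc$B))
        dA <- array(dA, c(ly$cin, ly$k, cc$pout, cc$B))
        for (j in seq_len(ly$k)) {
          rng <- j:(cc$pout + j - 1L)
          dX[, rng, ] <- dX[, rng, ] + dA[, j, , ]
        }
        delta <- dX
        dim(delta) <- c(ly$cin * ly$pin, cc$B)
      }
    }
  }
  grads
}

# One Adam update in place; state holds first/second moments and step count
.adam_step <- function(layers, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (i in seq_along(layers)) {
    for (p in c("W", "b")) {
      g <- grads[[i]][[p]]
      state$m[[i]][[p]] <- beta1 * state$m[[i]][[p]] + (1 - beta1) * g
      state$v[[i]][[p]] <- beta2 * state$v[[i]][[p]] + (1 - beta2) * g * g
      mhat <- state$m[[i]][[p]] / c1
      vhat <- state$v[[i]][[p]] / c2
      layers[[i]][[p]] <- layers[[i]][[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(layers = layers, state = state)
}

.adam_init <- function(layers) {
  zero <- lapply(layers, function(ly)
    list(W = array(0, dim(ly$W)), b = numeric(length(ly$b))))
  list(m = zero, v = zero, t = 0L)
}

# total trainable parameter count
.nn_n_params <- function(layers) {
  sum(vapply(layers, function(ly) length(ly$W) + length(ly$b), numeric(1)))
}

.nn_loss <- function(probs, labels) {
  p <- probs[cbind(labels + 1L, seq_len(ncol(probs)))]
  -mean(log(pmax(p, 1e-12)))
}
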