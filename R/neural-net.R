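# Minimal feed-forward / 1-D convolutional networks for pixel-spectrum
# classification, trained with Adam on binary cross-entropy. Written on
# base-R matrix operations; sized for spectral feature vectors (hundreds of
# points) and pixel pools of a few thousand rows, where small nets are
# enough and resist overfitting.

sigmoid <- function(z) 1 / (1 + exp(-z))

# He-scaled uniform init
init_w <- function(n_in, n_out, fan_in = n_in) {
  lim <- sqrt(6 / fan_in)
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

adam_state <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (i in seq_along(params)) {
    state[[i]]$m <- beta1 * state[[i]]$m + (1 - beta1) * grads[[i]]
    state[[i]]$v <- beta2 * state[[i]]$v + (1 - beta2) * grads[[i]]^2
    mhat <- state[[i]]$m / (1 - beta1^t)
    vhat <- state[[i]]$v / (1 - beta2^t)
    params[[i]] <- params[[i]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## ---- fully-connected net ----

mlp_init <- function(n_in, hidden) {
  sizes <- c(n_in, hidden, 1L)
  params <- list()
  for (i in seq_len(length(sizes) - 1L)) {
    params[[paste0("W", i)]] <- init_w(sizes[i], sizes[i + 1L])
    params[[paste0("b", i)]] <- matrix(0, 1L, sizes[i + 1L])
  }
  params
}

mlp_forward <- function(params, x) {
  n_layers <- length(params) / 2L
  acts <- list(x)
  a <- x
  for (i in seq_len(n_layers)) {
    z <- a %*% params[[paste0("W", i)]] +
      matrix(params[[paste0("b", i)]], nrow(a), ncol(params[[paste0("W", i)]]),
             byrow = TRUE)
    a <- if (i < n_layers) pmax(z, 0) else z
    acts[[i + 1L]] <- a
  }
  list(logits = a, acts = acts)
}

mlp_backward <- function(params, acts, dlogits) {
  n_layers <- length(params) / 2L
  grads <- params
  delta <- dlogits
  for (i in rev(seq_len(n_layers))) {
    a_prev <- acts[[i]]
    grads[[paste0("W", i)]] <- crossprod(a_prev, delta)
    grads[[paste0("b", i)]] <- matrix(colSums(delta), 1L)
    if (i > 1L) {
      delta <- (delta %*% t(params[[paste0("W", i)]])) * (acts[[i]] > 0)
    }
  }
  grads
}

## ---- strided 1-D convolution ----

conv_positions <- function(len, kernel, stride) {
  starts <- seq(1L, len - kernel + 1L, by = stride)
  outer(starts, 0L:(kernel - 1L), `+`)  # [P, kernel]
}

# x: [B, L, C_in] -> columns [B*P, kernel*C_in]
im2col <- function(x, idx) {
  d <- dim(x)
  P <- nrow(idx); k <- ncol(idx)
  ind <- as.vector(t(idx))                     # p-major, j fastest
  xc <- x[, ind, , drop = FALSE]               # [B, P*k, C]
  xc <- array(xc, c(d[1L], k, P, d[3L]))       # [B, j, p, C]
  xc <- aperm(xc, c(1L, 3L, 2L, 4L))           # [B, p, j, C]
  matrix(xc, d[1L] * P, k * d[3L])
}

# reverse of im2col: accumulate window gradients back onto the input
col2im <- function(dcol, idx, B, L, C) {
  P <- nrow(idx); k <- ncol(idx)
  dx <- array(0, c(B, L, C))
  dc <- array(dcol, c(B, P, k, C))
  for (p in seq_len(P)) {
    sl <- array(dc[, p, , , drop = FALSE], c(B, k, C))
    dx[, idx[p, ], ] <- array(dx[, idx[p, ], , drop = FALSE], c(B, k, C)) + sl
  }
  dx
}

# clamp kernels and strides so every block keeps at least one output
# position even on short inputs
effective_arch <- function(n_in, arch) {
  len <- n_in
  for (i in seq_along(arch$channels)) {
    arch$kernels[i] <- max(1L, min(arch$kernels[i], len))
    arch$strides[i] <- max(1L, min(arch$strides[i], len))
    len <- length(seq(1L, len - arch$kernels[i] + 1L, by = arch$strides[i]))
  }
  arch
}

cnn_init <- function(n_in, arch) {
  params <- list()
  c_in <- 1L
  len <- n_in
  for (i in seq_along(arch$channels)) {
    k <- arch$kernels[i]
    params[[paste0("K", i)]] <- init_w(k * c_in, arch$channels[i],
                                       fan_in = k * c_in)
    params[[paste0("kb", i)]] <- matrix(0, 1L, arch$channels[i])
    len <- length(seq(1L, len - k + 1L, by = arch$strides[i]))
    c_in <- arch$channels[i]
  }
  params$Wd <- init_w(c_in, 1L)
  params$bd <- matrix(0, 1L, 1L)
  params
}

cnn_forward <- function(params, x, arch) {
  B <- nrow(x)
  a <- array(x, c(B, ncol(x), 1L))
  cache <- list()
  for (i in seq_along(arch$channels)) {
    idx <- conv_positions(dim(a)[2L], arch$kernels[i], arch$strides[i])
    cols <- im2col(a, idx)
    z <- cols %*% params[[paste0("K", i)]] +
      matrix(params[[paste0("kb", i)]], nrow(cols), arch$channels[i], byrow = TRUE)
    h <- pmax(z, 0)
    cache[[i]] <- list(a_in = a, idx = idx, cols = cols, z = z)
    a <- array(h, c(B, nrow(idx), arch$channels[i]))
  }
  gap <- apply(a, c(1L, 3L), mean)             # global average pool [B, C]
  logits <- gap %*% params$Wd +
    matrix(params$bd, B, 1L, byrow = TRUE)
  list(logits = logits, cache = cache, gap = gap, a_last = a)
}

cnn_backward <- function(params, fwd, dlogits, arch) {
  B <- nrow(dlogits)
  grads <- params
  grads$Wd <- crossprod(fwd$gap, dlogits)
  grads$bd <- matrix(colSums(dlogits), 1L)
  dgap <- dlogits %*% t(params$Wd)             # [B, C]
  d <- dim(fwd$a_last)
  da <- array(rep(dgap / d[2L], each = 1L), c(B, d[3L], d[2L]))
  da <- aperm(da, c(1L, 3L, 2L))               # broadcast over positions
  for (i in rev(seq_along(arch$channels))) {
    cc <- fwd$cache[[i]]
    P <- nrow(cc$idx)
    dh <- matrix(da, B * P, dim(da)[3L])
    dz <- dh * (cc$z > 0)
    grads[[paste0("K", i)]] <- crossprod(cc$cols, dz)
    grads[[paste0("kb", i)]] <- matrix(colSums(dz), 1L)
    if (i > 1L) {
      dcol <- dz %*% t(params[[paste0("K", i)]])
      da <- col2im(dcol, cc$idx, B, dim(cc$a_in)[2L], dim(cc$a_in)[3L])
    }
  }
  grads
}

## ---- shared training loop ----

train_net <- function(x, y, kind = c("mlp", "cnn"), hidden = c(128L, 32L),
                      arch = list(kernels = c(9L, 7L), channels = c(8L, 16L),
                                  strides = c(3L, 3L)),
                      epochs = 30L, batch_size = 64L, lr = 1e-3, seed = 1L) {
  kind <- match.arg(kind)
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  sdv[sdv < 1e-12] <- 1
  xs <- sweep(sweep(x, 2L, mu), 2L, sdv, `/`)
  n <- nrow(xs)
  if (kind == "cnn") arch <- effective_arch(ncol(xs), arch)
  with_seed(seed, {
    params <- if (kind == "mlp") mlp_init(ncol(xs), hidden) else cnn_init(ncol(xs), arch)
    state <- adam_state(params)
    t_step <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        rows <- ord[start:min(start + batch_size - 1L, n)]
        xb <- xs[rows, , drop = FALSE]
        yb <- y[rows]
        fwd <- if (kind == "mlp") mlp_forward(params, xb) else cnn_forward(params, xb, arch)
        p <- sigmoid(fwd$logits)
        dlogits <- (p - yb) / length(rows)
        grads <- if (kind == "mlp") {
          mlp_backward(params, fwd$acts, dlogits)
        } else {
          cnn_backward(params, fwd, dlogits, arch)
        }
        t_step <- t_step + 1L
        upd <- adam_step(params, grads, state, lr, t_step)
        params <- upd$params
        state <- upd$state
      }
    }
    list(kind = kind, params = params, arch = arch, hidden = hidden,
         mu = mu, sd = sdv)
  })
}

predict_net <- function(net, x) {
  xs <- sweep(sweep(x, 2L, net$mu), 2L, net$sd, `/`)
  fwd <- if (net$kind == "mlp") {
    mlp_forward(net$params, xs)
  } else {
    cnn_forward(net$params, xs, net$arch)
  }
  as.vector(sigmoid(fwd$logits))
}
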