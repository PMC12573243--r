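# Minimal dense/conv network engine.
#
# Dense activations are feature x batch matrices. Convolutional
# activations are C x (H*W*B) matrices: one column per spatial position,
# positions in row-major order, samples stacked along columns. That layout
# makes batch norm a row operation, lets flatten/unflatten be a plain
# dim<- with no data movement, and keeps the conv layers as single BLAS
# products around compiled im2col/col2im kernels (src/kernels.cpp).

GLOROT <- function(fan_in, fan_out, n) {
  lim <- sqrt(6 / (fan_in + fan_out))
  stats::runif(n, -lim, lim)
}

# -- layer constructors ------------------------------------------------------

layer_fc <- function(n_in, n_out, bias = TRUE) {
  list(type = "fc", n_in = n_in, n_out = n_out, bias = bias)
}

layer_relu <- function() list(type = "relu")

# 3x3 same-padding convolution; weight W is c_out x (9*c_in) with column
# blocks ordered by kernel offset (dr, dc), channels fast within a block
layer_conv <- function(c_in, c_out, h, w) {
  list(type = "conv", c_in = c_in, c_out = c_out, h = h, w = w, hw = h * w)
}

layer_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  list(type = "bn", c = c, momentum = momentum, eps = eps)
}

layer_pool <- function(h, w, c) {
  list(type = "pool", h = h, w = w, c = c, hw = h * w)
}

layer_up <- function(h, w, c) { # h, w: input spatial dims
  list(type = "up", h = h, w = w, c = c, hw = h * w)
}

layer_flatten <- function(c, hw) list(type = "flatten", c = c, hw = hw)

layer_unflatten <- function(c, hw) list(type = "unflatten", c = c, hw = hw)

# -- initialization ----------------------------------------------------------

init_layers <- function(layers, seed) {
  with_seed(seed, {
    for (i in seq_along(layers)) {
      ly <- layers[[i]]
      if (ly$type == "fc") {
        ly$W <- matrix(GLOROT(ly$n_in, ly$n_out, ly$n_in * ly$n_out),
                       ly$n_out, ly$n_in)
        if (ly$bias) ly$b <- numeric(ly$n_out)
      } else if (ly$type == "conv") {
        ly$W <- matrix(GLOROT(9L * ly$c_in, 9L * ly$c_out, 9L * ly$c_in * ly$c_out),
                       ly$c_out, 9L * ly$c_in)
        ly$b <- numeric(ly$c_out)
      } else if (ly$type == "bn") {
        ly$gamma <- rep(1, ly$c)
        ly$beta <- numeric(ly$c)
        ly$run_mean <- numeric(ly$c)
        ly$run_var <- rep(1, ly$c)
      }
      layers[[i]] <- ly
    }
    layers
  })
}

# -- forward -----------------------------------------------------------------

net_forward <- function(layers, X, train = TRUE, update_running = TRUE,
                        keep_cache = train) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "fc") {
      out <- ly$W %*% X
      if (ly$bias) out <- out + ly$b
      if (keep_cache) caches[[i]] <- list(X = X)
      X <- out
    } else if (ly$type == "relu") {
      mask <- X > 0
      X <- X * mask
      if (keep_cache) caches[[i]] <- list(mask = mask)
    } else if (ly$type == "conv") {
      B <- ncol(X) %/% ly$hw
      out <- conv3_fwd(X, ly$W, ly$b, ly$c_in, ly$h, ly$w, B)
      if (keep_cache) caches[[i]] <- list(A = X, B = B)
      X <- out
    } else if (ly$type == "bn") {
      if (train) {
        mu <- rowMeans(X)
        v <- rowMeans(X * X) - mu^2
        v[v < 0] <- 0
        if (update_running) {
          n <- ncol(X)
          corr <- if (n > 1) n / (n - 1) else 1
          ly$run_mean <- (1 - ly$momentum) * ly$run_mean + ly$momentum * mu
          ly$run_var <- (1 - ly$momentum) * ly$run_var + ly$momentum * v * corr
          layers[[i]] <- ly
        }
      } else {
        mu <- ly$run_mean
        v <- ly$run_var
      }
      inv_std <- 1 / sqrt(v + ly$eps)
      xhat <- (X - mu) * inv_std
      X <- xhat * ly$gamma + ly$beta
      if (keep_cache) caches[[i]] <- list(xhat = xhat, inv_std = inv_std)
    } else if (ly$type == "pool") {
      B <- ncol(X) %/% ly$hw
      pf <- pool2_fwd(X, ly$c, ly$h, ly$w, B)
      if (keep_cache) caches[[i]] <- list(arg = pf$arg, n_in_cols = ncol(X))
      X <- pf$out
    } else if (ly$type == "up") {
      B <- ncol(X) %/% ly$hw
      if (keep_cache) caches[[i]] <- list(B = B)
      X <- up2_fwd(X, ly$c, ly$h, ly$w, B)
    } else if (ly$type == "flatten") {
      B <- ncol(X) %/% ly$hw
      dim(X) <- c(ly$c * ly$hw, B)
    } else if (ly$type == "unflatten") {
      B <- ncol(X)
      dim(X) <- c(ly$c, ly$hw * B)
    } else {
      stop("unknown layer type: ", ly$type)
    }
  }
  list(out = X, caches = caches, layers = layers)
}

# -- backward ----------------------------------------------------------------

net_backward <- function(layers, caches, dY) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    ca <- caches[[i]]
    if (ly$type == "fc") {
      g <- list(W = tcrossprod(dY, ca$X))
      if (ly$bias) g$b <- rowSums(dY)
      grads[[i]] <- g
      dY <- crossprod(ly$W, dY)
    } else if (ly$type == "relu") {
      dY <- dY * ca$mask
    } else if (ly$type == "conv") {
      bw <- conv3_bwd(ca$A, ly$W, dY, ly$c_in, ly$h, ly$w, ca$B)
      grads[[i]] <- list(W = bw$dW, b = rowSums(dY))
      dY <- bw$dA
    } else if (ly$type == "bn") {
      n <- ncol(dY)
      dbeta <- rowSums(dY)
      dgamma <- rowSums(dY * ca$xhat)
      grads[[i]] <- list(gamma = dgamma, beta = dbeta)
      dY <- (ly$gamma * ca$inv_std) *
        (dY - dbeta / n - ca$xhat * (dgamma / n))
    } else if (ly$type == "pool") {
      dY <- pool2_bwd(dY, ca$arg, ly$c, ca$n_in_cols %/% 1L)
    } else if (ly$type == "up") {
      dY <- up2_bwd(dY, ly$c, ly$h, ly$w, ca$B)
    } else if (ly$type == "flatten") {
      B <- ncol(dY)
      dim(dY) <- c(ly$c, ly$hw * B)
    } else if (ly$type == "unflatten") {
      B <- ncol(dY) %/% ly$hw
      dim(dY) <- c(ly$c * ly$hw, B)
    }
  }
  grads
}

# -- Adam --------------------------------------------------------------------

adam_init <- function(layers) list(t = 0L, m = vector("list", length(layers)),
                                   v = vector("list", length(layers)))

adam_step <- function(opt, layers, grads, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    if (is.null(opt$m[[i]])) {
      opt$m[[i]] <- lapply(g, function(x) x * 0)
      opt$v[[i]] <- lapply(g, function(x) x * 0)
    }
    for (nm in names(g)) {
      opt$m[[i]][[nm]] <- beta1 * opt$m[[i]][[nm]] + (1 - beta1) * g[[nm]]
      opt$v[[i]][[nm]] <- beta2 * opt$v[[i]][[nm]] + (1 - beta2) * g[[nm]]^2
      step <- lr * (opt$m[[i]][[nm]] / bc1) /
        (sqrt(opt$v[[i]][[nm]] / bc2) + eps)
      layers[[i]][[nm]] <- layers[[i]][[nm]] - step
    }
  }
  list(opt = opt, layers = layers)
}

# -- training loop -----------------------------------------------------------

# Mean squared error over all output entries, evaluated in chunks so the
# im2col buffers stay small. Batch-norm uses per-chunk batch statistics
# (training-mode measure) without touching the running averages.
net_mse <- function(layers, X, target = X, chunk = 512L, train_stats = TRUE) {
  n <- ncol(X)
  sse <- 0
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    fw <- net_forward(layers, X[, s:e, drop = FALSE], train = train_stats,
                      update_running = FALSE, keep_cache = FALSE)
    sse <- sse + sum((fw$out - target[, s:e, drop = FALSE])^2)
  }
  sse / (nrow(target) * n)
}

# One Adam run over (X, target), both feature x sample matrices. Shuffling
# is governed solely by `seed`, so identical calls are bit-identical.
train_net <- function(layers, X, target = X, epochs, batch_size, lr = 1e-3,
                      seed, track_initial = TRUE) {
  n <- ncol(X)
  initial_mse <- if (track_initial) net_mse(layers, X, target) else NA_real_
  opt <- adam_init(layers)
  with_seed(derive_seed(seed, "shuffle"), {
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      for (s in seq(1L, n, by = batch_size)) {
        take <- perm[s:min(s + batch_size - 1L, n)]
        Xb <- X[, take, drop = FALSE]
        Tb <- target[, take, drop = FALSE]
        fw <- net_forward(layers, Xb, train = TRUE)
        layers <- fw$layers
        err <- fw$out - Tb
        if (anyNA(err) || any(is.infinite(err)))
          stop("training diverged: non-finite loss at epoch ", ep)
        dY <- 2 * err / length(err)
        grads <- net_backward(layers, fw$caches, dY)
        upd <- adam_step(opt, layers, grads, lr = lr)
        opt <- upd$opt
        layers <- upd$layers
      }
    }
  })
  final_mse <- net_mse(layers, X, target)
  list(layers = layers, initial_mse = initial_mse, final_mse = final_mse)
}
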