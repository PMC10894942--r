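# Feed-forward regression network: ReLU hidden layers, inverted dropout,
# Adam on mean-squared error. Plain matrix code; the caller controls RNG
# state (weight init, shuffling, dropout masks) via with_rng_seed().

mlp_fit <- function(x, y, widths = c(1000, 800, 600, 400, 200, 100),
                    dropout = 0.17, lr = 0.001, epochs = 1000,
                    batch_size = 100) {
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  assert_that(n >= 2, "mlp needs at least 2 training rows")
  y_center <- mean(y); y_scale <- stats::sd(y); if (y_scale == 0) y_scale <- 1
  yt <- (y - y_center) / y_scale

  sizes <- c(p, widths, 1L)
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    # He initialization for ReLU layers
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1], 0,
                                  sqrt(2 / sizes[l])), sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(v) v * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_step <- 0

  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n)
    for (s in seq(1, n, by = batch_size)) {
      idx <- ord[s:min(s + batch_size - 1, n)]
      xb <- x[idx, , drop = FALSE]; yb <- yt[idx]
      m <- length(idx)

      acts <- vector("list", L + 1L); acts[[1]] <- xb
      masks <- vector("list", L)
      for (l in seq_len(L)) {
        z <- sweep(acts[[l]] %*% W[[l]], 2, b[[l]], "+")
        if (l < L) {
          z <- pmax(z, 0)
          if (dropout > 0) {
            mask <- matrix(stats::rbinom(length(z), 1, 1 - dropout) / (1 - dropout),
                           nrow(z), ncol(z))
            z <- z * mask
            masks[[l]] <- mask
          }
        }
        acts[[l + 1]] <- z
      }

      delta <- 2 * (acts[[L + 1]] - yb) / m  # d(mse)/d(output)
      t_step <- t_step + 1
      for (l in rev(seq_len(L))) {
        gW <- crossprod(acts[[l]], delta)
        gb <- colSums(delta)
        if (l > 1) {
          delta <- delta %*% t(W[[l]])
          if (dropout > 0) delta <- delta * masks[[l - 1]]
          delta <- delta * (acts[[l]] > 0)
        }
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        corr1 <- 1 - beta1^t_step; corr2 <- 1 - beta2^t_step
        W[[l]] <- W[[l]] - lr * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps)
        b[[l]] <- b[[l]] - lr * (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + eps)
      }
    }
  }
  list(W = W, b = b, y_center = y_center, y_scale = y_scale)
}

mlp_predict <- function(model, x) {
  a <- as.matrix(x)
  L <- length(model$W)
  for (l in seq_len(L)) {
    a <- sweep(a %*% model$W[[l]], 2, model$b[[l]], "+")
    if (l < L) a <- pmax(a, 0)
  }
  as.numeric(a) * model$y_scale + model$y_center
}
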