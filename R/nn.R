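## Minimal feed-forward network engine used by the three EEG CNNs.
## Activations are 4-d arrays (batch, maps, rows, time); layers are
## environments holding parameters, ADAM state and forward caches.

nn_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  for (nm in names(list(...))) assign(nm, list(...)[[nm]], envir = e)
  e
}

nn_init_mat <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

pad_time <- function(x, padl, padr) {
  if (padl == 0 && padr == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1:3], d[4] + padl + padr))
  out[, , , padl + seq_len(d[4])] <- x
  out
}

act_fun <- function(name, x) {
  switch(name,
    elu = ifelse(x > 0, x, exp(pmin(x, 0)) - 1),
    relu = pmax(x, 0),
    leaky_relu = ifelse(x > 0, x, 0.01 * x),
    square = x^2,
    stop("unknown activation '", name,
         "'; valid values: elu, square, relu, leaky_relu", call. = FALSE))
}

act_grad <- function(name, x) {
  switch(name,
    elu = ifelse(x > 0, 1, exp(pmin(x, 0))),
    relu = (x > 0) * 1,
    leaky_relu = ifelse(x > 0, 1, 0.01),
    square = 2 * x)
}

## ---- forward passes ----------------------------------------------------

fwd_conv_time <- function(l, x) {
  d <- dim(x)
  k <- dim(l$W)[2]
  xp <- pad_time(x, l$padl, l$padr)
  Tp <- dim(xp)[4] - k + 1L
  B <- d[1]; C <- d[2]; H <- d[3]; F <- dim(l$W)[3]
  acc <- matrix(0, B * H * Tp, F)
  for (j in seq_len(k)) {
    xj <- xp[, , , j:(j + Tp - 1L), drop = FALSE]
    M <- matrix(aperm(xj, c(1, 3, 4, 2)), ncol = C)
    acc <- acc + M %*% matrix(l$W[, j, ], nrow = C)
  }
  acc <- sweep(acc, 2L, l$b, `+`)
  l$x <- x; l$xp <- xp; l$Tp <- Tp
  aperm(array(acc, c(B, H, Tp, F)), c(1, 4, 2, 3))
}

bwd_conv_time <- function(l, dy) {
  d <- dim(l$xp); k <- dim(l$W)[2]
  B <- d[1]; C <- d[2]; H <- d[3]; Tp <- l$Tp; F <- dim(l$W)[3]
  g <- matrix(aperm(dy, c(1, 3, 4, 2)), ncol = F)
  l$gW <- array(0, dim(l$W)); l$gb <- colSums(g)
  dxp <- array(0, d)
  for (j in seq_len(k)) {
    xj <- l$xp[, , , j:(j + Tp - 1L), drop = FALSE]
    M <- matrix(aperm(xj, c(1, 3, 4, 2)), ncol = C)
    l$gW[, j, ] <- t(M) %*% g
    dM <- g %*% t(matrix(l$W[, j, ], nrow = C))
    dxp[, , , j:(j + Tp - 1L)] <- dxp[, , , j:(j + Tp - 1L), drop = FALSE] +
      aperm(array(dM, c(B, H, Tp, C)), c(1, 4, 2, 3))
  }
  dxp[, , , l$padl + seq_len(dim(l$x)[4]), drop = FALSE]
}

fwd_conv_spatial <- function(l, x) {
  d <- dim(x)  # (B, C, H, T)
  B <- d[1]; C <- d[2]; H <- d[3]; T <- d[4]; F <- ncol(l$W)
  M <- matrix(aperm(x, c(1, 4, 2, 3)), ncol = C * H)
  out <- sweep(M %*% l$W, 2L, l$b, `+`)
  l$x <- x
  aperm(array(out, c(B, T, F, 1)), c(1, 3, 4, 2))
}

bwd_conv_spatial <- function(l, dy) {
  d <- dim(l$x)
  B <- d[1]; C <- d[2]; H <- d[3]; T <- d[4]; F <- ncol(l$W)
  g <- matrix(aperm(dy, c(1, 4, 2, 3)), ncol = F)
  M <- matrix(aperm(l$x, c(1, 4, 2, 3)), ncol = C * H)
  l$gW <- t(M) %*% g; l$gb <- colSums(g)
  dM <- g %*% t(l$W)
  aperm(array(dM, c(B, T, C, H)), c(1, 3, 4, 2))
}

fwd_conv_dw_spatial <- function(l, x) {
  d <- dim(x); B <- d[1]; C <- d[2]; H <- d[3]; T <- d[4]
  D <- dim(l$W)[3]
  out <- array(0, c(B, C * D, 1, T))
  for (c in seq_len(C)) {
    M <- matrix(aperm(x[, c, , , drop = FALSE], c(1, 4, 3, 2)), ncol = H)
    out[, (c - 1L) * D + seq_len(D), 1, ] <-
      aperm(array(M %*% l$W[c, , ], c(B, T, D)), c(1, 3, 2))
  }
  l$x <- x
  out
}

bwd_conv_dw_spatial <- function(l, dy) {
  d <- dim(l$x); B <- d[1]; C <- d[2]; H <- d[3]; T <- d[4]
  D <- dim(l$W)[3]
  l$gW <- array(0, dim(l$W))
  dx <- array(0, d)
  for (c in seq_len(C)) {
    g <- matrix(aperm(dy[, (c - 1L) * D + seq_len(D), 1, , drop = FALSE],
                      c(1, 4, 3, 2)), ncol = D)
    M <- matrix(aperm(l$x[, c, , , drop = FALSE], c(1, 4, 3, 2)), ncol = H)
    l$gW[c, , ] <- t(M) %*% g
    dx[, c, , ] <- aperm(array(g %*% t(l$W[c, , ]), c(B, T, H)), c(1, 3, 2))
  }
  dx
}

fwd_conv_dw_time <- function(l, x) {
  d <- dim(x); k <- ncol(l$W)
  xp <- pad_time(x, l$padl, l$padr)
  Tp <- dim(xp)[4] - k + 1L
  out <- array(0, c(d[1], d[2], 1, Tp))
  for (j in seq_len(k))
    out <- out + sweep(xp[, , 1, j:(j + Tp - 1L), drop = FALSE], 2L,
                       l$W[, j], `*`)
  l$x <- x; l$xp <- xp; l$Tp <- Tp
  out
}

bwd_conv_dw_time <- function(l, dy) {
  d <- dim(l$xp); k <- ncol(l$W); Tp <- l$Tp
  l$gW <- matrix(0, nrow(l$W), k)
  dxp <- array(0, d)
  for (j in seq_len(k)) {
    xj <- l$xp[, , 1, j:(j + Tp - 1L), drop = FALSE]
    l$gW[, j] <- apply(xj * dy, 2L, sum)
    dxp[, , 1, j:(j + Tp - 1L)] <- dxp[, , 1, j:(j + Tp - 1L), drop = FALSE] +
      sweep(dy, 2L, l$W[, j], `*`)
  }
  dxp[, , , l$padl + seq_len(dim(l$x)[4]), drop = FALSE]
}

fwd_batchnorm <- function(l, x, training) {
  d <- dim(x)
  xm <- matrix(aperm(x, c(1, 3, 4, 2)), ncol = d[2])
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(sweep(xm, 2L, mu)^2)
    l$run_mean <- 0.9 * l$run_mean + 0.1 * mu
    l$run_var <- 0.9 * l$run_var + 0.1 * v
  } else {
    mu <- l$run_mean; v <- l$run_var
  }
  invstd <- 1 / sqrt(v + 1e-5)
  xhat <- sweep(sweep(xm, 2L, mu), 2L, invstd, `*`)
  out <- sweep(sweep(xhat, 2L, l$gamma, `*`), 2L, l$beta, `+`)
  l$xhat <- xhat; l$invstd <- invstd; l$dims <- d
  aperm(array(out, c(d[1], d[3], d[4], d[2])), c(1, 4, 2, 3))
}

bwd_batchnorm <- function(l, dy) {
  d <- l$dims
  g <- matrix(aperm(dy, c(1, 3, 4, 2)), ncol = d[2])
  n <- nrow(g)
  l$ggamma <- colSums(g * l$xhat); l$gbeta <- colSums(g)
  gx <- sweep(g, 2L, l$gamma, `*`)
  dxhat <- gx
  dxm <- sweep(dxhat - matrix(colMeans(dxhat), n, d[2], byrow = TRUE) -
                 sweep(l$xhat, 2L, colMeans(dxhat * l$xhat), `*`),
               2L, l$invstd, `*`)
  aperm(array(dxm, c(d[1], d[3], d[4], d[2])), c(1, 4, 2, 3))
}

fwd_pool <- function(l, x) {
  d <- dim(x); k <- l$k; s <- l$stride
  Tn <- (d[4] - k) %/% s + 1L
  if (Tn < 1L) stop("pooling window longer than the input", call. = FALSE)
  if (l$kind == "mean") {
    out <- array(0, c(d[1:3], Tn))
    for (j in seq_len(k)) {
      idx <- seq(j, by = s, length.out = Tn)
      out <- out + x[, , , idx, drop = FALSE]
    }
    out <- out / k
  } else {
    out <- array(-Inf, c(d[1:3], Tn))
    arg <- array(1L, c(d[1:3], Tn))
    for (j in seq_len(k)) {
      idx <- seq(j, by = s, length.out = Tn)
      xj <- x[, , , idx, drop = FALSE]
      upd <- xj > out
      out[upd] <- xj[upd]
      arg[upd] <- j
    }
    l$arg <- arg
  }
  l$in_dim <- d; l$Tn <- Tn
  out
}

bwd_pool <- function(l, dy) {
  d <- l$in_dim; k <- l$k; s <- l$stride; Tn <- l$Tn
  dx <- array(0, d)
  for (j in seq_len(k)) {
    idx <- seq(j, by = s, length.out = Tn)
    contrib <- if (l$kind == "mean") dy / k else dy * (l$arg == j)
    dx[, , , idx] <- dx[, , , idx, drop = FALSE] + contrib
  }
  dx
}

fwd_dense <- function(l, x) {
  M <- matrix(x, nrow = dim(x)[1])
  l$x <- M
  sweep(M %*% l$W, 2L, l$b, `+`)
}

bwd_dense <- function(l, dy) {
  l$gW <- t(l$x) %*% dy; l$gb <- colSums(dy)
  dM <- dy %*% t(l$W)
  array(dM, l$in_dim)
}

## ---- network drive -----------------------------------------------------

nn_forward <- function(net, x, training = FALSE) {
  for (l in net) {
    x <- switch(l$type,
      conv_time = fwd_conv_time(l, x),
      conv_spatial = fwd_conv_spatial(l, x),
      conv_dw_spatial = fwd_conv_dw_spatial(l, x),
      conv_dw_time = fwd_conv_dw_time(l, x),
      batchnorm = fwd_batchnorm(l, x, training),
      act = { l$x <- x; act_fun(l$name, x) },
      pool = fwd_pool(l, x),
      logeps = { l$x <- x; log(pmax(x, 1e-6)) },
      dropout = {
        if (training) {
          l$mask <- array(stats::runif(length(x)) >= l$p, dim(x)) / (1 - l$p)
          x * l$mask
        } else x
      },
      dense = { l$in_dim <- dim(x); fwd_dense(l, x) },
      stop("unknown layer type ", l$type))
  }
  x
}

nn_backward <- function(net, grad) {
  for (l in rev(net)) {
    grad <- switch(l$type,
      conv_time = bwd_conv_time(l, grad),
      conv_spatial = bwd_conv_spatial(l, grad),
      conv_dw_spatial = bwd_conv_dw_spatial(l, grad),
      conv_dw_time = bwd_conv_dw_time(l, grad),
      batchnorm = bwd_batchnorm(l, grad),
      act = grad * act_grad(l$name, l$x),
      pool = bwd_pool(l, grad),
      logeps = grad * (l$x > 1e-6) / pmax(l$x, 1e-6),
      dropout = if (!is.null(l$mask)) grad * l$mask else grad,
      dense = bwd_dense(l, grad))
  }
  invisible(grad)
}

## parameter slots per layer type (value, gradient) pairs
nn_param_slots <- function(l) {
  switch(l$type,
    conv_time = , conv_spatial = , dense = list(c("W", "gW"), c("b", "gb")),
    conv_dw_spatial = , conv_dw_time = list(c("W", "gW")),
    batchnorm = list(c("gamma", "ggamma"), c("beta", "gbeta")),
    list())
}

nn_count_params <- function(net) {
  sum(vapply(net, function(l)
    sum(vapply(nn_param_slots(l), function(s) length(get(s[1], envir = l)), 0)),
    0))
}

nn_adam_step <- function(net, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in net) {
    for (s in nn_param_slots(l)) {
      p <- get(s[1], envir = l); g <- get(s[2], envir = l)
      mkey <- paste0("m_", s[1]); vkey <- paste0("v_", s[1])
      m <- if (exists(mkey, envir = l, inherits = FALSE)) get(mkey, envir = l)
           else array(0, dim(p) %||% length(p))
      v <- if (exists(vkey, envir = l, inherits = FALSE)) get(vkey, envir = l)
           else array(0, dim(p) %||% length(p))
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      p <- p - lr * (m / (1 - beta1^t)) / (sqrt(v / (1 - beta2^t)) + eps)
      assign(s[1], p, envir = l)
      assign(mkey, m, envir = l); assign(vkey, v, envir = l)
    }
  }
}
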