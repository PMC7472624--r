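## The three EEG decoding architectures: a shallow band-power network
## (temporal conv -> spatial conv -> square -> mean-pool -> log, the FBCSP
## analogue), a deep generic ConvNet (initial temporal+spatial block plus
## three identical conv blocks), and an EEGNet-style compact network
## (temporal conv -> depthwise spatial conv -> separable conv). Kernel
## sizes and filter counts follow the original architecture publications,
## scaled to a 6-channel x 512-sample input, and are overridable via
## `arch`. The hyperparameter-controlled activation replaces the principal
## nonlinearity in all three; dropout is 0.5 throughout.

cnn_defaults <- function(family) {
  switch(family,
    shallow_cnn = list(n_filters_time = 40, kernel_time = 25,
                       n_filters_spat = 40, pool_size = 75, pool_stride = 15),
    deep_cnn = list(n_filters = c(25, 50, 100, 200), kernel_time = 10,
                    pool_size = 3, pool_stride = 3),
    eegnet = list(F1 = 8, D = 2, F2 = 16, kernel_time = 64, kernel_sep = 16,
                  pool1 = 4, pool2 = 8),
    stop_field("family", paste0("'", family, "' is not a CNN family")))
}

same_pad <- function(k) c((k - 1L) %/% 2L, k - (k - 1L) %/% 2L - 1L)

build_cnn_net <- function(family, n_classes, input_shape, activation,
                          arch = list()) {
  a <- utils::modifyList(cnn_defaults(family), arch)
  ## validate activation early so unknown names fail at build time
  act_fun(activation, 0)
  C <- input_shape[1]; T <- input_shape[2]
  layers <- list()
  add <- function(l) layers[[length(layers) + 1L]] <<- l
  bn <- function(maps) nn_layer("batchnorm", gamma = rep(1, maps),
                                beta = rep(0, maps), run_mean = rep(0, maps),
                                run_var = rep(1, maps))
  if (family == "shallow_cnn") {
    k <- a$kernel_time
    add(nn_layer("conv_time", W = nn_init_mat(c(1, k, a$n_filters_time), k),
                 b = rep(0, a$n_filters_time), padl = 0L, padr = 0L))
    add(nn_layer("conv_spatial",
                 W = nn_init_mat(c(a$n_filters_time * C, a$n_filters_spat),
                                 a$n_filters_time * C),
                 b = rep(0, a$n_filters_spat)))
    add(bn(a$n_filters_spat))
    add(nn_layer("act", name = activation))
    add(nn_layer("pool", kind = "mean", k = a$pool_size, stride = a$pool_stride))
    add(nn_layer("logeps"))
    add(nn_layer("dropout", p = 0.5))
    Tn <- ((T - k + 1L) - a$pool_size) %/% a$pool_stride + 1L
    add(nn_layer("dense", W = nn_init_mat(c(a$n_filters_spat * Tn, n_classes),
                                          a$n_filters_spat * Tn),
                 b = rep(0, n_classes)))
  } else if (family == "deep_cnn") {
    k <- a$kernel_time; nf <- a$n_filters
    add(nn_layer("conv_time", W = nn_init_mat(c(1, k, nf[1]), k),
                 b = rep(0, nf[1]), padl = 0L, padr = 0L))
    add(nn_layer("conv_spatial", W = nn_init_mat(c(nf[1] * C, nf[1]), nf[1] * C),
                 b = rep(0, nf[1])))
    add(bn(nf[1]))
    add(nn_layer("act", name = activation))
    add(nn_layer("pool", kind = "max", k = a$pool_size, stride = a$pool_stride))
    Tn <- ((T - k + 1L) - a$pool_size) %/% a$pool_stride + 1L
    for (blk in 1:3) {
      add(nn_layer("dropout", p = 0.5))
      add(nn_layer("conv_time",
                   W = nn_init_mat(c(nf[blk], k, nf[blk + 1]), nf[blk] * k),
                   b = rep(0, nf[blk + 1]), padl = 0L, padr = 0L))
      add(bn(nf[blk + 1]))
      add(nn_layer("act", name = activation))
      add(nn_layer("pool", kind = "max", k = a$pool_size,
                   stride = a$pool_stride))
      Tn <- ((Tn - k + 1L) - a$pool_size) %/% a$pool_stride + 1L
    }
    add(nn_layer("dense", W = nn_init_mat(c(nf[4] * Tn, n_classes), nf[4] * Tn),
                 b = rep(0, n_classes)))
  } else { # eegnet
    p1 <- same_pad(a$kernel_time)
    add(nn_layer("conv_time",
                 W = nn_init_mat(c(1, a$kernel_time, a$F1), a$kernel_time),
                 b = rep(0, a$F1), padl = p1[1], padr = p1[2]))
    add(bn(a$F1))
    add(nn_layer("conv_dw_spatial", W = nn_init_mat(c(a$F1, C, a$D), C)))
    add(bn(a$F1 * a$D))
    add(nn_layer("act", name = activation))
    add(nn_layer("pool", kind = "mean", k = a$pool1, stride = a$pool1))
    add(nn_layer("dropout", p = 0.5))
    p2 <- same_pad(a$kernel_sep)
    add(nn_layer("conv_dw_time",
                 W = nn_init_mat(c(a$F1 * a$D, a$kernel_sep), a$kernel_sep),
                 padl = p2[1], padr = p2[2]))
    add(nn_layer("conv_spatial", W = nn_init_mat(c(a$F1 * a$D, a$F2), a$F1 * a$D),
                 b = rep(0, a$F2)))
    add(bn(a$F2))
    add(nn_layer("act", name = activation))
    add(nn_layer("pool", kind = "mean", k = a$pool2, stride = a$pool2))
    add(nn_layer("dropout", p = 0.5))
    Tn <- (T %/% a$pool1) %/% a$pool2
    add(nn_layer("dense", W = nn_init_mat(c(a$F2 * Tn, n_classes), a$F2 * Tn),
                 b = rep(0, n_classes)))
  }
  layers
}

## per-trial, per-channel z-scoring applied before every CNN
cnn_standardize <- function(X) {
  d <- dim(X)
  for (i in seq_len(d[1])) for (ch in seq_len(d[2])) {
    x <- X[i, ch, ]
    s <- stats::sd(x)
    X[i, ch, ] <- if (s > 0) (x - mean(x)) / s else x - mean(x)
  }
  X
}

## gradient of the batch loss w.r.t. the logits, via the softmax Jacobian
cnn_loss_grad <- function(loss, P, Y) {
  n <- nrow(P)
  if (loss == "nll") return((P - Y) / n)
  Pc <- pmin(pmax(P, 1e-12), 1 - 1e-12)
  g <- -(Y / Pc - (1 - Y) / (1 - Pc)) / n      # dL/dp
  P * (g - rowSums(g * P))                     # back through softmax
}

cnn_batch_loss <- function(loss, P, Y) {
  yi <- max.col(Y, ties.method = "first")
  if (loss == "nll") nll_loss(P, yi) else ce_loss(P, yi)
}

cnn_fit <- function(family, X, y, hp, seed = 1L, arch = list(),
                    batch_size = 64L) {
  y <- as.factor(y)
  classes <- levels(y)
  d <- dim(X)
  stopifnot(length(d) == 3L)
  loss_name <- hp$loss %||% "nll"
  if (!loss_name %in% c("nll", "ce"))
    stop_field("loss", "valid values: nll, ce")
  set.seed(seed)
  X <- cnn_standardize(X)
  net <- build_cnn_net(family, length(classes), d[2:3],
                       hp$activation %||% "elu", arch)
  Yall <- one_hot(y, classes)
  n <- d[1]
  lr <- hp$lr %||% 0.01
  epochs <- hp$epochs %||% 20L
  log <- data.frame(epoch = integer(), loss = numeric(), acc = numeric())
  diverged <- FALSE
  t_step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_hit <- 0
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      xb <- X[idx, , , drop = FALSE]
      dim(xb) <- c(length(idx), 1L, d[2], d[3])  # maps dim = 1
      logits <- nn_forward(net, xb, training = TRUE)
      P <- softmax(logits)
      Yb <- Yall[idx, , drop = FALSE]
      bl <- suppressWarnings(cnn_batch_loss(loss_name, P, Yb))
      if (!is.finite(bl)) { diverged <- TRUE; break }
      ep_loss <- ep_loss + bl * length(idx)
      ep_hit <- ep_hit + sum(max.col(P) == max.col(Yb))
      t_step <- t_step + 1L
      nn_backward(net, cnn_loss_grad(loss_name, P, Yb))
      nn_adam_step(net, lr, t_step)
    }
    if (diverged) break
    log <- rbind(log, data.frame(epoch = ep, loss = ep_loss / n,
                                 acc = ep_hit / n))
  }
  structure(list(net = net, family = family, classes = classes,
                 input_shape = d[2:3], hp = hp, seed = seed,
                 diverged = diverged, training_log = log,
                 n_parameters = nn_count_params(net)),
            class = "cnn_model")
}

cnn_predict_probs <- function(model, X, batch_size = 64L) {
  d <- dim(X)
  if (!all(d[2:3] == model$input_shape))
    stop_field("X", "input shape does not match the trained network")
  X <- cnn_standardize(X)
  P <- matrix(0, d[1], length(model$classes),
              dimnames = list(NULL, model$classes))
  if (model$diverged) { P[] <- 1 / length(model$classes); return(P) }
  for (start in seq(1L, d[1], by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, d[1])
    xb <- X[idx, , , drop = FALSE]
    dim(xb) <- c(length(idx), 1L, d[2], d[3])
    P[idx, ] <- softmax(nn_forward(model$net, xb, training = FALSE))
  }
  P
}
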