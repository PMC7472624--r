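test_that("softmax is symmetric, normalized and matches direct evaluation", {
  expect_equal(as.numeric(softmax(rep(3, 6))), rep(1 / 6, 6))
  set.seed(1)
  L <- matrix(stats::rnorm(30, sd = 5), 5, 6)
  expect_equal(rowSums(softmax(L)), rep(1, 5), tolerance = 1e-12)
  ## direct high-precision evaluation of exp(f_k)/sum_m exp(f_m)
  p <- softmax(c(10, 0, 0, 0, 0, 0))
  expect_equal(p[1], 1 / (1 + 5 * exp(-10)), tolerance = 1e-12)
  expect_error(softmax(c(1, NaN)), "NaN")
})

test_that("negative log-likelihood loss matches analytic values", {
  perfect <- diag(3)[c(1, 2, 3), ]
  expect_equal(nll_loss(perfect, 1:3), 0)
  expect_equal(nll_loss(matrix(1 / 6, 2, 6), c(1, 4)), log(6))
  expect_equal(nll_loss(rbind(c(0.5, 0.5), c(0.25, 0.75)), c(1, 1)),
               mean(c(-log(0.5), -log(0.25))))
  expect_warning(nll_loss(rbind(c(0, 1)), 1), "clamping")
})

test_that("summed binary cross-entropy matches direct evaluation and dominates the true-class term", {
  perfect <- diag(4)
  expect_equal(ce_loss(perfect, 1:4), 0)
  for (k in c(2, 5, 6)) {
    u <- matrix(1 / k, 1, k)
    direct <- -(log(1 / k) + (k - 1) * log(1 - 1 / k))
    expect_equal(ce_loss(u, 1), direct)
  }
  set.seed(2)
  P <- softmax(matrix(stats::rnorm(24), 4, 6))
  y <- sample(6, 4, replace = TRUE)
  true_term <- mean(-log(P[cbind(1:4, y)]))
  expect_gte(ce_loss(P, y), true_term)
})

test_that("both losses vanish exactly iff predictions are one-hot truths", {
  onehot <- diag(3)
  expect_identical(nll_loss(onehot, 1:3), 0)
  expect_identical(ce_loss(onehot, 1:3), 0)
  nearly <- matrix(c(0.99, 0.01, 0, 0, 1, 0, 0, 0, 1), 3, byrow = TRUE)
  expect_gt(nll_loss(nearly, 1:3), 0)
  expect_gt(ce_loss(nearly, 1:3), 0)
})

test_that("classical decoders fit, predict valid batches and are seed-stable", {
  set.seed(5)
  n <- 40
  X <- rbind(matrix(stats::rnorm(n * 2, 0), n, 2),
             matrix(stats::rnorm(n * 2, 4), n, 2))
  colnames(X) <- c("f1", "f2")
  y <- rep(c("A", "B"), each = n)
  ## linearly separable SVM reaches 100% training accuracy
  m <- fit_decoder(decoder_spec("svm", list(kernel = "linear", C = 1)), X, y)
  expect_equal(accuracy(predict(m, X), y), 1)
  ## rdf: same seed twice -> identical predictions
  r1 <- fit_decoder(decoder_spec("rdf", list(trees = 50)), X, y, seed = 9)
  r2 <- fit_decoder(decoder_spec("rdf", list(trees = 50)), X, y, seed = 9)
  expect_identical(predict(r1, X)$probs, predict(r2, X)$probs)
  ## rlda separates Gaussians and returns calibrated rows
  l <- fit_decoder(decoder_spec("rlda"), X, y)
  pb <- predict(l, X)
  expect_equal(rowSums(pb$probs), rep(1, 2 * n), tolerance = 1e-6)
  expect_gt(accuracy(pb, y), 0.95)
  ## duplicate trial -> identical probability rows
  Xd <- X[c(1, 1), , drop = FALSE]
  expect_equal(predict(l, Xd)$probs[1, ], predict(l, Xd)$probs[2, ])
  ## majority baseline scores the majority fraction
  ys <- c(rep("A", 30), rep("B", 10))
  mm <- fit_decoder(decoder_spec("majority"), Xalt <- X[1:40, ], ys)
  expect_equal(accuracy(predict(mm, X[1:40, ]), ys), 0.75)
})

test_that("prediction batches enforce their invariants", {
  P <- matrix(c(0.6, 0.4, 0.2, 0.8), 2, byrow = TRUE,
              dimnames = list(NULL, c("A", "B")))
  pb <- prediction_batch(P)
  expect_identical(pb$labels_hat, c("A", "B"))
  expect_error(prediction_batch(P * 2), "sum")
})

test_that("unknown hyperparameters and families are rejected", {
  expect_error(decoder_spec("mlp"), "family")
  expect_error(decoder_spec("svm", list(bogus = 1)), "bogus")
  expect_error(decoder_spec("svm", n_classes = 1), "n_classes")
})

test_that("CNN builders honor the architecture contracts", {
  spec6 <- function(fam) decoder_spec(fam, list(activation = "elu"),
                                      n_classes = 6,
                                      input_shape = c(6L, 512L))
  deep <- build_cnn(spec6("deep_cnn"))
  ## one initial temporal+spatial block plus three identical conv blocks
  expect_equal(sum(vapply(deep, function(l) l$type == "conv_time", TRUE)), 4L)
  for (fam in c("shallow_cnn", "deep_cnn", "eegnet")) {
    net <- build_cnn(spec6(fam))
    drops <- Filter(function(l) l$type == "dropout", net)
    expect_gt(length(drops), 0)
    expect_true(all(vapply(drops, function(l) l$p == 0.5, TRUE)))
  }
  ## parameter counts ordered eegnet < shallow < deep at the default shape
  np <- vapply(c("eegnet", "shallow_cnn", "deep_cnn"),
               function(f) attr(build_cnn(spec6(f)), "n_parameters"), 0)
  expect_true(np[1] < np[2] && np[2] < np[3])
  expect_error(build_cnn(decoder_spec("eegnet", list(activation = "tanh"))),
               "valid")
  expect_error(build_cnn(decoder_spec("svm")), "CNN")
})

test_that("a shallow CNN learns a band-power contrast above the chance band", {
  ts <- toy_trialset(snr = 4, seed = 101, trials_per_class = 30)
  arch <- list(n_filters_time = 8, n_filters_spat = 8)
  tr <- c(1:20, 31:50); te <- setdiff(1:60, tr)
  spec <- decoder_spec("shallow_cnn",
                       list(activation = "square", lr = 0.01, epochs = 15,
                            loss = "nll"), n_classes = 2)
  m <- fit_decoder(spec, ts$data[tr, , ], ts$labels[tr], seed = 5, arch = arch)
  acc <- accuracy(predict(m, ts$data[te, , ]), ts$labels[te])
  expect_gt(acc, 0.5 + 3 * sqrt(0.25 / length(te)))
})

test_that("CNN training is deterministic and records divergence instead of raising", {
  ts <- toy_trialset(snr = 1, seed = 111, trials_per_class = 8)
  arch <- list(F1 = 2, D = 2, F2 = 4, kernel_time = 16, kernel_sep = 8)
  spec <- decoder_spec("eegnet", list(activation = "elu", lr = 0.01,
                                      epochs = 3, loss = "ce"), n_classes = 2)
  m1 <- fit_decoder(spec, ts$data, ts$labels, seed = 4, arch = arch)
  m2 <- fit_decoder(spec, ts$data, ts$labels, seed = 4, arch = arch)
  expect_identical(predict(m1, ts$data)$probs, predict(m2, ts$data)$probs)
  ## absurd learning rate: flagged, uniform fallback, no exception
  spec_div <- decoder_spec("eegnet", list(activation = "relu", lr = 1e6,
                                          epochs = 3, loss = "nll"),
                           n_classes = 2)
  md <- fit_decoder(spec_div, ts$data, ts$labels, seed = 4, arch = arch)
  pb <- predict(md, ts$data)
  expect_equal(rowSums(pb$probs), rep(1, 16), tolerance = 1e-9)
  if (md$fit$diverged) expect_true(all(abs(pb$probs - 0.5) < 1e-12))
  ## parameter count is reportable
  expect_gt(n_parameters(m1), 0)
})

test_that("CNN backpropagation matches finite-difference gradients", {
  for (case in list(list(fam = "shallow_cnn", act = "square", loss = "nll",
                         arch = list(n_filters_time = 3, kernel_time = 5,
                                     n_filters_spat = 3, pool_size = 4,
                                     pool_stride = 2)),
                    list(fam = "eegnet", act = "elu", loss = "ce",
                         arch = list(F1 = 2, D = 2, F2 = 4, kernel_time = 8,
                                     kernel_sep = 4, pool1 = 2, pool2 = 2)))) {
    set.seed(1)
    net <- bcidecode:::build_cnn_net(case$fam, 2, c(3L, 32L), case$act,
                                     case$arch)
    for (l in net) if (l$type == "dropout") l$p <- 0
    x <- array(stats::rnorm(4 * 3 * 32), c(4, 1, 3, 32))
    Y <- bcidecode:::one_hot(c("a", "b", "a", "b"), c("a", "b"))
    fwd <- function() {
      P <- softmax(bcidecode:::nn_forward(net, x, training = TRUE))
      bcidecode:::cnn_batch_loss(case$loss, P, Y)
    }
    P <- softmax(bcidecode:::nn_forward(net, x, training = TRUE))
    bcidecode:::nn_backward(net, bcidecode:::cnn_loss_grad(case$loss, P, Y))
    worst <- 0
    for (l in net) for (s in bcidecode:::nn_param_slots(l)) {
      p <- get(s[1], envir = l); g <- get(s[2], envir = l)
      for (ii in sample(length(p), min(2, length(p)))) {
        eps <- 1e-5; p0 <- p[ii]
        p[ii] <- p0 + eps; assign(s[1], p, envir = l); f1 <- fwd()
        p[ii] <- p0 - eps; assign(s[1], p, envir = l); f2 <- fwd()
        p[ii] <- p0; assign(s[1], p, envir = l)
        num <- (f1 - f2) / (2 * eps)
        worst <- max(worst, abs(num - g[ii]) /
                       max(1e-4, abs(num) + abs(g[ii])))
      }
    }
    expect_lt(worst, 1e-4)
  }
})
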