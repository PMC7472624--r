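test_that("RWE of a 20 Hz sinusoid matches the reference DWT decomposition", {
  ## expected values computed with an independent wavelet implementation
  ## (db4, symmetric padding, 5 levels) on sin(2*pi*20*t), 512 samples at
  ## 128 Hz; D2 (16-32 Hz) must dominate
  ts <- sine_trialset(20, fs = 128)
  v <- rwe_extract(ts)[1, ]
  oracle <- c(D2 = 0.79213057, D3 = 0.13218195, D4 = 0.00448632,
              D5 = 0.00335508, A5 = 0.06784608)
  expect_equal(unname(v), unname(oracle), tolerance = 1e-6)
  expect_equal(unname(which.max(v)), 1L)  # D2 leads the per-channel block
})

test_that("RWE vectors have 5 features per channel summing to one", {
  ts <- toy_trialset(snr = 1, seed = 61, trials_per_class = 4)
  M <- rwe_extract(ts)
  expect_equal(ncol(M), 30L)
  for (ch in 1:6)
    expect_equal(rowSums(M[, (ch - 1) * 5 + 1:5]), rep(1, nrow(M)),
                 tolerance = 1e-9)
  expect_true(all(M >= 0 & M <= 1))
  short <- trial_set(array(stats::rnorm(2 * 6 * 16), c(2, 6, 16)),
                     c("A", "B"), "s", 128, ts$channel_names)
  expect_error(rwe_extract(short), "short")
})

test_that("wavelet energies are conserved across the decomposition tree", {
  set.seed(3)
  x <- stats::rnorm(512)
  dec <- wavedec(x, 5)
  coef_energy <- sum(vapply(dec$details, function(d) sum(d^2), 0)) +
    sum(dec$approx^2)
  parts <- c(vapply(dec$details, function(d) sum(d^2), 0), sum(dec$approx^2))
  expect_equal(sum(parts), coef_energy, tolerance = 1e-9)
  ## orthonormal filter pair: one analysis step conserves interior energy
  filt <- bcidecode:::daubechies_filter("db4")
  expect_equal(sum(filt$lo^2) + sum(filt$hi^2), 2, tolerance = 1e-12)
  expect_equal(sum(filt$lo * filt$hi), 0, tolerance = 1e-12)
})

test_that("the canonical filter bank has six bands at the stated edges", {
  fb <- build_filterbank(fs = 128)
  expect_length(fb$filters, 6L)
  expect_equal(fb$band_edges$lo, c(2, 4, 8, 12, 18, 28))
  expect_equal(fb$band_edges$hi, c(4, 8, 12, 18, 28, 40))
  expect_error(build_filterbank(data.frame(lo = numeric(), hi = numeric())),
               "band")
  expect_error(build_filterbank(data.frame(lo = 8, hi = 8), fs = 128), "lo < hi")
  expect_error(build_filterbank(data.frame(lo = 2, hi = 70), fs = 128),
               "Nyquist")
})

test_that("filter bank bands confine broadband noise to their band", {
  set.seed(4)
  arr <- array(stats::rnorm(4 * 1 * 512), c(4, 1, 512))
  ts <- trial_set(arr, rep("A", 4), "s", 128, "ch1")
  fb <- build_filterbank(fs = 128)
  out <- apply_filterbank(ts, fb)$theta
  pg <- 0
  for (i in 1:4) pg <- pg + Mod(stats::fft(out$data[i, 1, ]))^2
  f <- (0:511) * 128 / 512
  inband <- sum(pg[f >= 3 & f <= 9]) + sum(pg[f >= 128 - 9 & f <= 128 - 3])
  expect_gt(inband / sum(pg), 0.9)
})

test_that("CSP matches a brute-force generalized eigenvalue oracle", {
  for (rep in 1:5) {
    set.seed(rep * 13)
    n <- 30
    A1 <- matrix(stats::rnorm(16), 4); A2 <- matrix(stats::rnorm(16), 4)
    d1 <- array(0, c(n, 4, 200)); d2 <- array(0, c(n, 4, 200))
    for (i in 1:n) {
      d1[i, , ] <- A1 %*% matrix(stats::rnorm(800), 4)
      d2[i, , ] <- A2 %*% matrix(stats::rnorm(800), 4)
    }
    dat <- array(0, c(2 * n, 4, 200))
    dat[1:n, , ] <- d1; dat[(n + 1):(2 * n), , ] <- d2
    labels <- rep(c("A", "B"), each = n)
    cs <- fit_csp(dat, labels, nsf = 2)
    ## brute-force oracle: eig of solve(S1 + S2) %*% S1 (non-symmetric path)
    S1 <- bcidecode:::mean_normalized_cov(dat, 1:n)
    S2 <- bcidecode:::mean_normalized_cov(dat, (n + 1):(2 * n))
    eg <- eigen(solve(S1 + S2) %*% S1)
    expect_equal(sort(Re(eg$values)), sort(cs$lambda), tolerance = 1e-8)
    ## filters are eigenvectors of solve(S1+S2) %*% S1 (angle < 1e-6 rad,
    ## up to sign/scale)
    for (j in 1:4) {
      w <- cs$filters[j, ]
      k <- which.min(abs(Re(eg$values) - cs$lambda[j]))
      v <- Re(eg$vectors[, k])
      ang <- acos(pmin(1, abs(sum(w * v)) / sqrt(sum(w^2) * sum(v^2))))
      expect_lt(ang, 1e-6)
    }
    ## whitening of the composite covariance
    expect_lt(max(abs(cs$filters %*% (S1 + S2) %*% t(cs$filters) -
                        diag(4))), 1e-6)
  }
})

test_that("CSP degenerate geometry behaves as theory predicts", {
  ## identical class covariances: every eigenvalue ~ 0.5
  set.seed(7)
  dat <- array(stats::rnorm(40 * 3 * 100), c(40, 3, 100))
  cs <- fit_csp(dat, rep(c("A", "B"), each = 20), nsf = 1)
  expect_true(all(abs(cs$lambda - 0.5) < 0.1))
  ## 2-channel toy: class variance concentrated on opposite channels
  d <- array(stats::rnorm(40 * 2 * 100) * 0.01, c(40, 2, 100))
  for (i in 1:20) d[i, 1, ] <- stats::rnorm(100)
  for (i in 21:40) d[i, 2, ] <- stats::rnorm(100)
  cs <- fit_csp(d, rep(c("A", "B"), each = 20), nsf = 1)
  w <- cs$filters[1, ]
  expect_gt(abs(w[1]) / sqrt(sum(w^2)), 0.99)
  expect_error(fit_csp(d, rep("A", 40)), "two classes")
  expect_error(fit_csp(d, rep(c("A", "B"), each = 20), nsf = 3), "nsf")
})

test_that("multi-class CSP pools one-vs-rest filters capped at 2*nsf", {
  ts <- toy_trialset(snr = 2, seed = 71, classes = c("A", "B", "C"),
                     trials_per_class = 10)
  cs <- fit_csp(ts$data, ts$labels, nsf = 2)
  expect_equal(nrow(cs$filters), 4L)
  expect_length(cs$lambda, 4L)
})

test_that("FBCSP produces 6 x 2nsf candidates and selects by mutual information", {
  ts <- toy_trialset(snr = 1, seed = 81, trials_per_class = 12)
  bands <- lapply(apply_filterbank(ts, build_filterbank(fs = 128)),
                  function(x) x$data)
  fm <- fbcsp_fit(bands, ts$labels, nsf = 2, miql = 4, nof = 8)
  expect_length(fm$mi_scores, 24L)
  expect_true(all(fm$mi_scores >= 0))
  expect_equal(fm$selected,
               order(-fm$mi_scores, seq_along(fm$mi_scores))[1:8])
  F <- fbcsp_transform(fm, bands)
  expect_equal(dim(F), c(24L, 8L))
  expect_error(fbcsp_fit(bands, ts$labels, nsf = 2, miql = 4, nof = 30),
               "nof")
})

test_that("mutual information is maximal for label-determined features and unbiased under the null", {
  set.seed(6)
  y <- rep(c("A", "B"), each = 100)
  det_feat <- ifelse(y == "A", 1, 5) + stats::rnorm(200, 0, 1e-6)
  expect_gt(mutual_information(det_feat, y, 4), 0.99)
  ## null feature: MI within 3 SD of the permutation-null mean
  x <- stats::rnorm(200)
  mi_obs <- mutual_information(x, y, 4)
  null <- replicate(200, mutual_information(x, sample(y), 4))
  expect_lt(abs(mi_obs - mean(null)), 3 * stats::sd(null))
})

test_that("a label-determined candidate is always selected by FBCSP", {
  set.seed(9)
  ts <- toy_trialset(snr = 0, seed = 91, trials_per_class = 10)
  bands <- lapply(apply_filterbank(ts, build_filterbank(fs = 128)),
                  function(x) x$data)
  ## plant a deterministic label signature in band 1, channel 1 variance
  scale <- ifelse(ts$labels == "A", 6, 1)
  for (i in seq_len(20)) bands[[1]][i, 1, ] <- bands[[1]][i, 1, ] * scale[i]
  fm <- fbcsp_fit(bands, ts$labels, nsf = 2, miql = 4, nof = 4)
  expect_gte(max(fm$mi_scores[1:4]), max(fm$mi_scores[-(1:4)]))
  expect_true(any(fm$selected %in% 1:4))
})
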