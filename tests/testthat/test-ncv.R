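test_that("grid enumeration counts and order follow the declared dimensions", {
  expect_length(enumerate_grid(default_grid("svm")), 64L)
  combos <- enumerate_grid(hp_grid("x", list(a = 1:2, b = c("u", "v"))))
  expect_length(combos, 4L)
  ## first dimension varies slowest
  expect_equal(vapply(combos, `[[`, 0, "a"), c(1, 1, 2, 2))
  expect_equal(vapply(combos, `[[`, "", "b"), c("u", "v", "u", "v"))
  expect_length(enumerate_grid(hp_grid("x", list(a = 1, b = 2))), 1L)
  expect_error(hp_grid("x", list(a = integer())), "non-empty")
})

test_that("4-fold plans give 75/25 outer splits stratified by class", {
  labels <- rep(letters[1:6], each = 40)
  plan <- make_folds(labels, k = 4, seed = 3)
  for (i in 1:4) {
    expect_equal(sum(plan$outer_assignments == i), 60L)
    ## class balance within each fold
    per_class <- table(labels[plan$outer_assignments == i])
    expect_true(max(per_class) - min(per_class) <= 1)
    ## inner folds partition exactly the k-1 outer training folds
    ia <- plan$inner_assignments[[i]]
    expect_true(all(is.na(ia[plan$outer_assignments == i])))
    expect_equal(sum(!is.na(ia)), 180L)
    for (j in 1:4) {
      cnt <- table(labels[!is.na(ia) & ia == j])
      expect_true(max(cnt) - min(cnt) <= 1)
    }
  }
  ## non-divisible sizes differ by at most one
  plan2 <- make_folds(rep(c("a", "b"), c(11, 10)), k = 4, seed = 1)
  sizes <- tabulate(plan2$outer_assignments)
  expect_lte(max(sizes) - min(sizes), 1L)
  expect_error(make_folds(rep(c("a", "b"), c(3, 40)), k = 4), "fewer than")
  expect_error(make_folds(labels, k = 1), "k")
})

test_that("theta selection uses the mean rule with first-in-order ties", {
  expect_equal(select_theta_star(c(t1 = 0.30, t2 = 0.25)), c(t1 = 1L))
  ## majority-of-folds loser can win on the mean
  tab <- rbind(t1 = c(0.30, 0.31, 0.32, 0.10),
               t2 = c(0.28, 0.29, 0.30, 0.40))
  m <- apply(tab, 1, mean)
  expect_equal(unname(select_theta_star(m)), 2L)
  expect_equal(unname(which.max(apply(tab > tab[c(2, 1), ], 1, sum))), 1L)
  ## exact tie -> earliest
  expect_equal(unname(select_theta_star(c(0.4, 0.4, 0.3))), 1L)
  expect_error(select_theta_star(numeric()), "empty")
})

test_that("inner tables contain one accuracy per (theta, outer, inner) and mean correctly", {
  ts <- toy_trialset(snr = 1, seed = 121, trials_per_class = 8)
  prep <- prepare_decoding_data(ts, "svm")
  plan <- make_folds(prep$labels, k = 2, seed = 5)
  grid <- hp_grid("svm", list(kernel = "linear", C = c(0.1, 10), g = 0.1))
  combos <- enumerate_grid(grid)
  srch <- inner_search(prep, plan, combos, seed = 5)
  expect_equal(dim(srch$inner_table), c(2L, 2L, 2L))
  expect_true(all(srch$inner_table >= 0 & srch$inner_table <= 1))
  expect_equal(srch$mean_acc, apply(srch$inner_table, 1, mean))
  ## duplicated combination rows are identical (deterministic per-fit seeds
  ## depend only on the fold position and combination index order)
  combos_dup <- c(combos, combos)
  srch2 <- inner_search(prep, plan, combos_dup, seed = 5)
  expect_equal(unname(srch2$mean_acc[1:2]), unname(srch$mean_acc))
})

test_that("selected theta matches exhaustive manual selection across seeds", {
  ts <- toy_trialset(snr = 0.5, seed = 131, trials_per_class = 8)
  prep <- prepare_decoding_data(ts, "svm")
  combos <- enumerate_grid(hp_grid("svm", list(kernel = "linear",
                                               C = c(0.1, 10), g = 0.1)))
  for (seed in 1:20) {
    plan <- make_folds(prep$labels, k = 2, seed = seed)
    srch <- inner_search(prep, plan, combos, seed = seed)
    ## manual exhaustive enumeration through the identical fit interface
    manual <- matrix(0, length(combos), 4)
    cell <- 0
    for (i in 1:2) for (j in 1:2) {
      cell <- cell + 1
      ia <- plan$inner_assignments[[i]]
      tr <- which(!is.na(ia) & ia != j)
      va <- which(!is.na(ia) & ia == j)
      for (t in seq_along(combos))
        manual[t, cell] <- bcidecode:::fit_and_score(
          prep, combos[[t]], tr, va,
          seed = bcidecode:::child_seed(seed, 3L, i, j))
    }
    expect_equal(unname(select_theta_star(srch$mean_acc)),
                 unname(which.max(rowMeans(manual))))
  }
})

test_that("inner tables never touch the corresponding outer test fold", {
  ts <- toy_trialset(snr = 1, seed = 141, trials_per_class = 8)
  prep <- prepare_decoding_data(ts, "svm")
  plan <- make_folds(prep$labels, k = 2, seed = 7)
  combos <- enumerate_grid(hp_grid("svm", list(kernel = "linear", C = 1,
                                               g = 0.1)))
  srch <- inner_search(prep, plan, combos, seed = 7)
  ## permute the labels of outer fold 1's test trials
  prep2 <- prep
  i1 <- which(plan$outer_assignments == 1)
  set.seed(1)
  prep2$labels[i1] <- sample(prep2$labels[i1])
  srch2 <- inner_search(prep2, plan, combos, seed = 7)
  expect_identical(srch$inner_table[, 1, ], srch2$inner_table[, 1, ])
})

test_that("nested CV returns coherent results for the rLDA-FBCSP pipeline", {
  ts <- toy_trialset(snr = 2, seed = 151, classes = c("A", "B", "C"),
                     trials_per_class = 8)
  r <- run_ncv(ts, "rlda", small_rlda_grid(), k = 4, seed = 2)
  expect_s3_class(r, "cv_result")
  expect_length(r$outer_accs, 4L)
  expect_equal(r$mean_test_acc, mean(r$outer_accs))
  expect_true(all(r$outer_accs >= 0 & r$outer_accs <= 1))
  expect_equal(unname(r$theta_star_index),
               unname(select_theta_star(r$mean_acc)))
  ## strong signal: well above chance
  expect_gt(r$mean_test_acc, 1 / 3 + 3 * sqrt((1 / 3) * (2 / 3) / 24))
})

test_that("intra-subject runs are per-subject and reduce to plain nCV for one subject", {
  ds <- generate_dataset(toy_protocol(n_subjects = 1, trials_per_class = 8),
                         signal_model_spec(snr = 1, seed = 9))
  grid <- hp_grid("svm", list(kernel = "linear", C = c(0.1, 10), g = 0.1))
  intra <- run_intra_subject(ds, "svm", grid, k = 2, seed = 13)
  solo <- run_ncv(ds[[1]], "svm", grid, k = 2,
                  seed = bcidecode:::child_seed(13, 7L, 1))
  expect_equal(intra[[1]]$mean_test_acc, solo$mean_test_acc)
  expect_equal(intra[[1]]$theta_star, solo$theta_star)
  co <- attr(intra, "cohort")
  expect_equal(co$mean, co$max)
  expect_equal(co$sd, 0)
})

test_that("inter-subject selection pools inner accuracies across subjects", {
  ds <- generate_dataset(toy_protocol(n_subjects = 2, trials_per_class = 8),
                         signal_model_spec(snr = 1, seed = 10,
                                           subject_gain_sd = 0))
  grid <- hp_grid("svm", list(kernel = "linear", C = c(0.1, 10), g = 0.1))
  inter <- run_inter_subject(ds, "svm", grid, k = 2, seed = 17)
  ## one shared combination
  expect_identical(inter[[1]]$theta_star, inter[[2]]$theta_star)
  ## the pooled mean is the average of the per-subject means
  pooled <- (inter[[1]]$mean_acc + inter[[2]]$mean_acc) / 2
  expect_equal(inter[[1]]$pooled_mean_acc, pooled)
  expect_equal(unname(inter[[1]]$theta_star_index),
               unname(select_theta_star(pooled)))
  ## single subject: inter reduces to intra
  one_inter <- run_inter_subject(ds[1], "svm", grid, k = 2, seed = 17)
  one_intra <- run_intra_subject(ds[1], "svm", grid, k = 2, seed = 17)
  expect_equal(one_inter[[1]]$mean_test_acc, one_intra[[1]]$mean_test_acc)
  expect_equal(one_inter[[1]]$theta_star, one_intra[[1]]$theta_star)
})
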