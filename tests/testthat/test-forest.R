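test_that("class balancing upsamples the smaller class with replacement", {
  set.seed(1)
  bal <- balance_classes(1:10, 11:20)
  expect_equal(length(bal$idx), 20L)
  expect_equal(table(bal$y), table(rep(1:2, each = 10)), ignore_attr = TRUE)

  set.seed(2)
  bal2 <- balance_classes(1:10, 21:23)
  expect_equal(length(bal2$idx), 20L)
  expect_equal(sum(bal2$y == 1L), 10L)
  expect_equal(sum(bal2$y == 2L), 10L)
  expect_true(all(bal2$idx[bal2$y == 2L] %in% 21:23))
  expect_identical(bal2$idx[bal2$y == 1L], 1:10)  # larger class kept whole

  set.seed(3); a <- balance_classes(1:5, 1:9)
  set.seed(3); b <- balance_classes(1:5, 1:9)
  expect_identical(a, b)

  expect_error(balance_classes(integer(0), 1:3), "non-empty")
})

test_that("a separable pair trains trees that all classify both causes", {
  ds <- separable_pair_data(10L)
  X <- va_symptom_matrix(ds)
  pf <- vaforest:::train_pair(X, ds$cause, "A", "B", ds$items,
                              ntree = 10L, m = 4L, seed = 5L)
  expect_equal(length(pf$trees), 10L)
  for (tr in pf$trees) {
    expect_equal(predict_tree(tr, X), ds$cause)
  }
  pf1 <- vaforest:::train_pair(X, ds$cause, "A", "B", ds$items,
                               ntree = 1L, m = 4L, seed = 5L)
  expect_equal(length(pf1$trees), 1L)
})

test_that("identical symptom distributions give near-chance pair votes", {
  set.seed(13)
  n <- 60L
  x <- matrix(rbinom(2L * n * 12L, 1, 0.5), 2L * n, 12L)
  colnames(x) <- sprintf("i%02d", 1:12)
  rownames(x) <- sprintf("d%03d", seq_len(2L * n))
  ds <- va_data(x, rep(c("A", "B"), each = n), causes = c("A", "B"))
  fit <- va_forest(ds, ntree = 50L, m = 3L, seed = 17L)
  # fresh null examples: votes for A should straddle ntree/2
  x_new <- matrix(rbinom(200L * 12L, 1, 0.5), 200L, 12L)
  colnames(x_new) <- colnames(x)
  rownames(x_new) <- sprintf("n%03d", 1:200)
  new_ds <- va_data(x_new, rep(c("A", "B"), 100), causes = c("A", "B"))
  sc <- va_score(fit, new_ds)
  expect_lt(abs(mean(sc[, "A"]) / 50 - 0.5), 0.1)
})

test_that("model counts, vote conservation and score bounds hold", {
  ds <- va_simulate(n_causes = 3, n_items = 24, signal_items = 4,
                    deaths_per_cause = 25, seed = 8)
  fit <- va_forest(ds, ntree = 10, m = 5, top_n = 10, seed = 8)
  N <- 3L; n <- 10L
  expect_equal(length(fit$forests), N * (N - 1L) / 2L)
  sc <- va_score(fit, ds)
  expect_true(all(rowSums(sc) == n * N * (N - 1L) / 2L))
  expect_true(all(sc >= 0L & sc <= n * (N - 1L)))
  # train score matrix stored with the model, same invariant
  expect_true(all(rowSums(fit$train_scores) == n * N * (N - 1L) / 2L))

  # example identical to a training record of a separable cause scores the
  # maximum n*(N-1); m = all items so every node can reach a signal item
  ds_sep <- va_simulate(n_causes = 3, n_items = 24, signal_items = 6,
                        p_signal = 1, p_background = 0,
                        deaths_per_cause = 10, seed = 9)
  fit_sep <- va_forest(ds_sep, ntree = 10, m = 24, seed = 9)
  sc_sep <- va_score(fit_sep, ds_sep)
  expect_true(all(sc_sep[cbind(seq_len(nrow(sc_sep)),
                               match(ds_sep$cause, ds_sep$causes))] ==
                    10L * 2L))
})

test_that("permuting the cause list permutes scores identically", {
  ds <- va_simulate(n_causes = 3, n_items = 18, signal_items = 4,
                    deaths_per_cause = 15, seed = 4)
  perm <- c(2L, 3L, 1L)
  ds_perm <- va_data(ds$x, ds$cause, causes = ds$causes[perm], hce = ds$hce)
  fit <- va_forest(ds, ntree = 8, seed = 11)
  fit_perm <- va_forest(ds_perm, ntree = 8, seed = 11)
  sc <- va_score(fit, ds)
  sc_perm <- va_score(fit_perm, ds)
  expect_equal(sc_perm, sc[, ds$causes[perm]])
})

test_that("same seed, data and config give an identical model", {
  ds <- va_simulate(n_causes = 3, n_items = 18, signal_items = 4,
                    deaths_per_cause = 15, seed = 4)
  f1 <- va_forest(ds, ntree = 5, seed = 2)
  f2 <- va_forest(ds, ntree = 5, seed = 2)
  expect_identical(f1, f2)
})

test_that("model persistence round-trips predictions", {
  ds <- va_simulate(n_causes = 3, n_items = 18, signal_items = 4,
                    deaths_per_cause = 15, seed = 4)
  fit <- va_forest(ds, ntree = 5, seed = 2)
  dir <- withr::local_tempdir()
  write_va_forest(fit, file.path(dir, "model"))
  fit2 <- read_va_forest(file.path(dir, "model"))
  expect_identical(fit2$causes, fit$causes)
  expect_equal(fit2$train_scores, fit$train_scores)
  expect_identical(predict(fit2, ds), predict(fit, ds))
})

test_that("one-vs-all coupling trains one forest per cause", {
  ds <- va_simulate(n_causes = 3, n_items = 18, signal_items = 4,
                    deaths_per_cause = 15, seed = 4)
  fit <- va_forest(ds, ntree = 5, coupling = "one_vs_all", seed = 2)
  expect_equal(length(fit$forests), 3L)
  sc <- va_score(fit, ds)
  expect_true(all(sc >= 0L & sc <= 5L))
  expect_gt(mean(predict(fit, ds) == ds$cause), 0.8)
})
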