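test_that("bootstrap sampling has the right size, support and seed behaviour", {
  expect_error(bootstrap_sample(integer(0)), "empty")
  expect_identical(bootstrap_sample(5L), c(5L))  # single record repeated once

  set.seed(42)
  b1 <- bootstrap_sample(1:20)
  set.seed(42)
  b2 <- bootstrap_sample(1:20)
  expect_identical(b1, b2)
  expect_equal(length(b1), 20L)
  expect_true(all(b1 %in% 1:20))

  # distinct fraction ~ 1 - (1 - 1/n)^n ~ 1 - e^-1; binomial-style 3 s.e. band
  n <- 1000L
  set.seed(7)
  frac <- length(unique(bootstrap_sample(seq_len(n)))) / n
  p <- 1 - (1 - 1 / n)^n
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(frac - p), 3 * se)
})

test_that("best_split maximizes Gini decrease, matching a brute-force oracle", {
  # one perfectly separating candidate
  X <- cbind(a = c(1L, 1L, 0L, 0L), b = c(1L, 0L, 1L, 0L))
  y <- c(1L, 1L, 2L, 2L)
  expect_equal(best_split(X, 1:4, y, 1:2), 1L)

  # all candidates constant -> none
  Xc <- cbind(a = rep(1L, 4), b = rep(0L, 4))
  expect_true(is.na(best_split(Xc, 1:4, y, 1:2)))

  # random instances vs exhaustive impurity enumeration
  gini_dec_oracle <- function(X, y, j) {
    n <- length(y)
    g <- function(yy) {
      if (!length(yy)) return(0)
      p <- mean(yy == 1L); 2 * p * (1 - p)
    }
    r <- X[, j] == 1L
    if (all(r) || !any(r)) return(NA_real_)
    g(y) - (sum(r) * g(y[r]) + sum(!r) * g(y[!r])) / n
  }
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(4:30, 1)
    K <- sample(2:6, 1)
    X <- matrix(rbinom(n * K, 1, runif(1, 0.2, 0.8)), n, K)
    colnames(X) <- paste0("i", seq_len(K))
    y <- sample(c(1L, 2L), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    dec <- vapply(seq_len(K), function(j) gini_dec_oracle(X, y, j), numeric(1))
    got <- best_split(X, seq_len(n), y, seq_len(K))
    if (all(is.na(dec))) {
      expect_true(is.na(got))
    } else {
      expect_equal(got, which.max(dec))  # which.max: first max = earlier item
    }
  }
})

test_that("grow_tree handles pure nodes, separating items and seeds", {
  X <- cbind(a = c(1L, 1L, 0L, 0L), b = c(1L, 0L, 1L, 0L))
  # all one class -> single leaf
  t1 <- grow_tree(X, rep(1L, 4), classes = c("A", "B"), m = 2)
  expect_equal(length(t1$item), 1L)
  expect_equal(t1$label[1], "A")

  # perfect separator with m = all items -> depth-1 tree on "a", 100% accuracy
  y <- c(1L, 1L, 2L, 2L)
  t2 <- grow_tree(X, y, classes = c("A", "B"), m = 2)
  expect_equal(t2$item[1], "a")
  expect_equal(length(t2$item), 3L)
  expect_equal(predict_tree(t2, X), c("A", "A", "B", "B"))

  # identical seed -> identical structure
  set.seed(3); ta <- grow_tree(X, y, classes = c("A", "B"), m = 1)
  set.seed(3); tb <- grow_tree(X, y, classes = c("A", "B"), m = 1)
  expect_identical(ta, tb)

  expect_error(grow_tree(X, c(1L, 3L, 2L, 1L), classes = c("A", "B"), m = 1),
               "1 or 2")
})

test_that("trees classify conflict-free training data perfectly (purity)", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 40L; K <- 8L
    X <- matrix(rbinom(n * K, 1, 0.5), n, K)
    colnames(X) <- paste0("i", seq_len(K))
    # labels as a deterministic function of the vector -> no conflicts
    key <- apply(X, 1, paste, collapse = "")
    y <- ifelse(as.integer(substr(key, 1, 1)) + as.integer(substr(key, 2, 2)) >= 1,
                1L, 2L)
    if (length(unique(y)) < 2) next
    tr <- grow_tree(X, y, classes = c("A", "B"), m = K)
    expect_equal(predict_tree(tr, X), c("A", "B")[y])
    # node count bound
    expect_lte(length(tr$item), 2L * n - 1L)
  }
})

test_that("the expert-style malaria tree reproduces its conjunctive rule", {
  tr <- expert_malaria_tree()
  expect_equal(predict_tree(tr, expert_case(1, 1, 0, 0, 0)), "malaria")
  # any violated conjunct -> other
  expect_equal(predict_tree(tr, expert_case(0, 1, 0, 0, 0)), "other")
  expect_equal(predict_tree(tr, expert_case(1, 0, 0, 0, 0)), "other")
  expect_equal(predict_tree(tr, expert_case(1, 1, 1, 0, 0)), "other")
  expect_equal(predict_tree(tr, expert_case(1, 1, 0, 1, 0)), "other")
  expect_equal(predict_tree(tr, expert_case(1, 1, 0, 0, 1)), "other")
})

test_that("prediction is pure and errors when a tested item is absent", {
  tr <- expert_malaria_tree()
  m <- expert_case(1, 1, 0, 0, 0)
  expect_identical(predict_tree(tr, m), predict_tree(tr, m))
  m2 <- m[, -1, drop = FALSE]
  expect_error(predict_tree(tr, m2), "absent")
})

test_that("tree JSON round-trip preserves structure and predictions", {
  set.seed(9)
  X <- matrix(rbinom(80, 1, 0.5), 10, 8)
  colnames(X) <- paste0("i", 1:8)
  y <- rep(c(1L, 2L), 5)
  tr <- grow_tree(X, y, classes = c("A", "B"), m = 3)
  lst <- vaforest:::tree_to_list(tr)
  json <- jsonlite::toJSON(lst, auto_unbox = TRUE)
  tr2 <- vaforest:::tree_from_list(jsonlite::fromJSON(json, simplifyVector = FALSE))
  expect_identical(tr2$item, tr$item)
  expect_identical(tr2$label, tr$label)
  expect_identical(predict_tree(tr2, X), predict_tree(tr, X))
})
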