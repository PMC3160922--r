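# Brute-force oracle: full descending sort of train scores, rank = 1 + number
# of train scores strictly greater than the test score.
rank_oracle <- function(test_score, train_column) {
  1L + sum(sort(train_column, decreasing = TRUE) > test_score)
}

test_that("rank_entry reproduces the worked score-to-rank cases", {
  train <- c(25, 20, 15, 10)
  # score 20 is the second-highest against the column -> rank 2
  expect_equal(rank_entry(20, train), 2L)
  # larger than every train score -> rank 1
  expect_equal(rank_entry(30, train), 1L)
  # score 12 -> rank 4, by the brute-force oracle too
  expect_equal(rank_entry(12, train), 4L)
  expect_equal(rank_entry(12, train), rank_oracle(12, train))
  # worse than everything -> rank T + 1
  expect_equal(rank_entry(5, train), 5L)
  expect_error(rank_entry(1, numeric(0)), "non-empty")
})

test_that("rank_entry agrees with the sort-and-count oracle incl. ties", {
  set.seed(31)
  for (i in 1:300) {
    Tn <- sample(1:30, 1)
    train <- sample(0:15, Tn, replace = TRUE)  # small range forces ties
    s <- sample(0:15, 1)
    expect_identical(rank_entry(s, train), rank_oracle(s, train))
  }
})

test_that("rank_transform works column-wise and flags mismatched columns", {
  train <- cbind(c1 = c(25, 20, 15, 10), c2 = c(4, 3, 2, 1))
  test <- cbind(c1 = c(20, 12), c2 = c(5, 0))
  rk <- rank_transform(test, train)
  expect_identical(rk, cbind(c1 = c(2L, 4L), c2 = c(1L, 5L)))

  # self-transform of all-distinct columns is a permutation of 1..T
  set.seed(5)
  m <- cbind(a = sample(100, 8), b = sample(100, 8))
  self <- rank_transform(m, m)
  expect_setequal(self[, "a"], 1:8)
  expect_setequal(self[, "b"], 1:8)

  # constant train column: any test score >= the constant gets rank 1
  const <- cbind(a = rep(7, 5))
  expect_equal(unname(rank_transform(cbind(a = c(7, 8, 6)), const)[, 1]),
               c(1L, 1L, 6L))

  expect_error(rank_transform(cbind(x = 1), cbind(y = 1)), "identical cause")
})

test_that("assignment follows rank, not raw score", {
  # Train columns make cause A's scores systematically high, so a mediocre
  # raw score for A ranks poorly while a lower raw score for B ranks first.
  train <- cbind(A = c(90, 80, 70, 60), B = c(40, 30, 20, 10))
  test <- cbind(A = 65, B = 50)             # A outscores B ...
  rk <- rank_transform(test, train)
  expect_true(rk[1, "B"] < rk[1, "A"])      # ... but B outranks A
  expect_equal(unname(va_assign(rk, test, k = 1)[1, 1]), "B")
  # the max-score variant picks A instead
  expect_equal(unname(assign_by_score(test, k = 1)[1, 1]), "A")
})

test_that("assignment ordering, ties and prefix consistency behave", {
  rk <- matrix(c(3L, 2L, 1L), 1, dimnames = list("e", c("C1", "C2", "C3")))
  sc <- matrix(c(10, 20, 30), 1, dimnames = list("e", c("C1", "C2", "C3")))
  expect_equal(unname(va_assign(rk, sc, k = 1)[1, 1]), "C3")
  expect_equal(unname(va_assign(rk, sc, k = 2)[1, ]), c("C3", "C2"))

  # all ranks tied -> raw score, then cause order
  rk_t <- matrix(1L, 1, 3, dimnames = list("e", c("C1", "C2", "C3")))
  sc_t <- matrix(c(5, 9, 9), 1, dimnames = list("e", c("C1", "C2", "C3")))
  expect_equal(unname(va_assign(rk_t, sc_t, k = 2)[1, ]), c("C2", "C3"))

  # prefix consistency of top-k lists
  set.seed(41)
  rkm <- matrix(sample(1:50, 40, replace = TRUE), 8, 5,
                dimnames = list(NULL, paste0("c", 1:5)))
  scm <- matrix(sample(1:100, 40, replace = TRUE), 8, 5,
                dimnames = list(NULL, paste0("c", 1:5)))
  for (k in 1:3) {
    expect_identical(va_assign(rkm, scm, k = k),
                     va_assign(rkm, scm, k = k + 1L)[, 1:k, drop = FALSE])
  }
  expect_error(va_assign(rkm, scm, k = 5), "k must")

  # max-score variant basics
  sc1 <- matrix(c(10, 30, 20), 1, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(unname(assign_by_score(sc1, 1)[1, 1]), "b")
  sc2 <- matrix(5, 1, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(unname(assign_by_score(sc2, 1)[1, 1]), "a")
})

test_that("rank and score assignment agree when train columns share one
           distribution", {
  set.seed(51)
  # identically distributed train columns: rank normalization is monotone in
  # the score, so both rules pick the same cause off tie cases
  col1 <- sample(0:9999, 400)
  train <- cbind(a = col1, b = sample(col1), c = sample(col1))
  test <- matrix(sample(0:9999, 60, replace = TRUE), 20, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  rk <- rank_transform(test, train)
  expect_equal(va_assign(rk, test, k = 1)[, 1], assign_by_score(test, k = 1)[, 1])
})
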