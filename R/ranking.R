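#' Rank of a test score within a training score column
#'
#' The rank of a test score is 1 plus the number of training scores strictly
#' greater than it: the best possible rank is 1 and a higher score always
#' gets a smaller (better) rank. A test score equal to a training score takes
#' the better rank — e.g. a score of 20 against the column {25, 20, 15, 10}
#' is the second-highest score and has rank 2.
#'
#' @param test_score numeric scalar or vector of test scores.
#' @param train_column numeric vector of training scores for one cause
#'   (non-empty).
#' @return integer rank(s) in `[1, length(train_column) + 1]`.
#' @export
rank_entry <- function(test_score, train_column) {
  if (!length(train_column)) stop("training column must be non-empty")
  s <- sort(train_column)  # ascending
  # strictly greater train scores = T - (# train scores <= test)
  as.integer(1L + length(s) - findInterval(test_score, s))
}

#' Rank-normalize a test Score Matrix against the Train Score Matrix
#'
#' Converts vote tallies to ranks entry by entry: each test score is replaced
#' by its rank among the corresponding cause column of the Train Score
#' Matrix. This is a nonparametric whitening that makes the scores of
#' different causes directly comparable — a cause whose forests hand out
#' systematically high (or low) scores is judged relative to its own training
#' distribution rather than on the raw tally.
#'
#' @param test_scores examples x causes score matrix (e.g. [va_score()]
#'   output on test data).
#' @param train_scores training-examples x causes Train Score Matrix; must
#'   have the same cause columns as `test_scores`.
#' @return integer Rank Matrix with the dimensions and dimnames of
#'   `test_scores`; rank 1 is best.
#' @export
rank_transform <- function(test_scores, train_scores) {
  if (!identical(colnames(test_scores), colnames(train_scores))) {
    stop("test and train score matrices must have identical cause columns")
  }
  ranks <- test_scores
  for (j in seq_len(ncol(test_scores))) {
    ranks[, j] <- rank_entry(test_scores[, j], train_scores[, j])
  }
  storage.mode(ranks) <- "integer"
  ranks
}

#' Assign the top-k best-ranked causes per example
#'
#' Causes are ordered by ascending rank number (rank 1 = most likely); ties
#' are broken by higher raw score, then by cause-list order. The second-best
#' ranked cause is the second prediction, and so on.
#'
#' @param rank_matrix examples x causes Rank Matrix from [rank_transform()].
#' @param score_matrix matching raw Score Matrix, used for tie-breaking.
#' @param k number of causes to return per example; `1 <= k < N` (at `k = N`
#'   the chance correction of the partial concordance is undefined).
#' @return character matrix, examples x k, most likely cause first.
#' @export
va_assign <- function(rank_matrix, score_matrix, k = 1L) {
  N <- ncol(rank_matrix)
  if (k < 1L || k >= N) stop("k must satisfy 1 <= k < number of causes")
  causes <- colnames(rank_matrix)
  out <- matrix(NA_character_, nrow(rank_matrix), k,
                dimnames = list(rownames(rank_matrix), NULL))
  for (i in seq_len(nrow(rank_matrix))) {
    o <- order(rank_matrix[i, ], -score_matrix[i, ], seq_len(N))
    out[i, ] <- causes[o[seq_len(k)]]
  }
  out
}

#' Assign the top-k highest-scoring causes per example (max-score variant)
#'
#' The comparison variant that skips rank normalization: causes are ordered
#' by descending raw score, ties broken by cause-list order.
#'
#' @param score_matrix examples x causes Score Matrix.
#' @param k number of causes per example (1 <= k < N).
#' @return character matrix, examples x k.
#' @export
assign_by_score <- function(score_matrix, k = 1L) {
  N <- ncol(score_matrix)
  if (k < 1L || k >= N) stop("k must satisfy 1 <= k < number of causes")
  causes <- colnames(score_matrix)
  out <- matrix(NA_character_, nrow(score_matrix), k,
                dimnames = list(rownames(score_matrix), NULL))
  for (i in seq_len(nrow(score_matrix))) {
    o <- order(-score_matrix[i, ], seq_len(N))
    out[i, ] <- causes[o[seq_len(k)]]
  }
  out
}
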