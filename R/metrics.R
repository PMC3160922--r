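#' Chance-corrected concordance (CCC)
#'
#' Per cause j, concordance is the fraction of true-j deaths assigned cause j
#' (the cause-specific sensitivity), corrected so that random assignment over
#' N causes scores 0 and perfect assignment scores 1:
#' \deqn{CCC_j = (C_j - 1/N) / (1 - 1/N).}
#' The average CCC is the unweighted mean over causes; causes with no true
#' deaths in `truth` have undefined CCC (`NA`) and are excluded from the
#' average.
#'
#' @param truth character vector of gold-standard causes.
#' @param pred character vector of top-1 predicted causes, same length.
#' @param causes the cause list (defines N).
#' @return a `va_ccc` list: `per_cause` (named vector of CCC_j), `average`,
#'   `n_causes`.
#' @export
va_ccc <- function(truth, pred, causes) {
  if (!length(truth)) stop("empty truth vector")
  if (length(truth) != length(pred)) stop("truth and pred lengths differ")
  if (!all(truth %in% causes)) stop("truth contains a cause not on the list")
  N <- length(causes)
  per_cause <- vapply(causes, function(cz) {
    nj <- sum(truth == cz)
    if (nj == 0L) return(NA_real_)
    Cj <- sum(truth == cz & pred == cz) / nj
    (Cj - 1 / N) / (1 - 1 / N)
  }, numeric(1))
  structure(list(per_cause = per_cause,
                 average = mean(per_cause, na.rm = TRUE),
                 n_causes = N),
            class = "va_ccc")
}

#' @export
print.va_ccc <- function(x, ...) {
  cat("Chance-corrected concordance (N = ", x$n_causes, " causes)\n", sep = "")
  cat("  average: ", format(x$average, digits = 4), "\n", sep = "")
  print(round(x$per_cause, 4))
  invisible(x)
}

#' Partial chance-corrected concordance, PCCC(k)
#'
#' C(k) is the fraction of deaths whose true cause appears among their k
#' best-ranked predicted causes; random assignment puts the truth in a
#' k-list with probability k/N, so
#' \deqn{PCCC(k) = (C(k) - k/N) / (1 - k/N).}
#' Undefined at k = N (division by zero), hence the requirement k < N.
#'
#' @param truth character vector of gold-standard causes.
#' @param topk character matrix of predictions, one row per death, at least
#'   `k` columns (columns beyond `k` are ignored).
#' @param k list length to evaluate.
#' @param N number of causes on the list.
#' @return scalar PCCC(k).
#' @export
va_pccc <- function(truth, topk, k, N) {
  if (k < 1L || k >= N) stop("k must satisfy 1 <= k < N")
  topk <- as.matrix(topk)
  if (nrow(topk) != length(truth)) stop("truth and prediction sizes differ")
  if (ncol(topk) < k) stop("prediction lists shorter than k")
  hit <- vapply(seq_along(truth),
                function(i) truth[i] %in% topk[i, seq_len(k)], logical(1))
  Ck <- mean(hit)
  (Ck - k / N) / (1 - k / N)
}

#' Cause-specific mortality fractions from assignments
#'
#' @param pred character vector of (top-1) causes.
#' @param causes cause list.
#' @return named numeric vector of fractions summing to 1.
#' @export
va_csmf <- function(pred, causes) {
  if (!length(pred)) stop("empty prediction vector")
  frac <- as.vector(table(factor(pred, levels = causes))) / length(pred)
  names(frac) <- causes
  frac
}

#' CSMF accuracy
#'
#' One minus the total absolute error between estimated and true
#' cause-specific mortality fractions, normalized by the largest error any
#' method could make given the true composition:
#' \deqn{1 - \sum_j |true_j - est_j| / (2 (1 - \min_j true_j)).}
#' Ranges from 0 (worst possible estimate) to 1 (exact).
#'
#' @param true_csmf,est_csmf numeric CSMF vectors over the same causes
#'   (non-negative, each summing to 1).
#' @return scalar in [0, 1].
#' @export
csmf_accuracy <- function(true_csmf, est_csmf) {
  if (length(true_csmf) != length(est_csmf)) stop("CSMF lengths differ")
  for (v in list(true_csmf, est_csmf)) {
    if (any(v < 0) || abs(sum(v) - 1) > 1e-9) stop("invalid CSMF vector")
  }
  1 - sum(abs(true_csmf - est_csmf)) / (2 * (1 - min(true_csmf)))
}

#' Per-cause regression of estimated on true CSMF across splits
#'
#' Ordinary least squares of the estimated cause fraction on the true cause
#' fraction over validation splits, summarising how faithfully the method
#' tracks the true fraction for one cause: slope 1 and intercept 0 is
#' perfect; slope near 0 with a positive intercept means the method assigns
#' roughly the same fraction regardless of the truth.
#'
#' @param true_frac,est_frac numeric vectors over splits (length >= 3).
#' @return list with `slope`, `intercept`, `rmse` (root mean squared
#'   residual). If the true fractions have zero variance the slope and
#'   intercept are `NA` and `degenerate` is `TRUE`.
#' @export
csmf_regression <- function(true_frac, est_frac) {
  if (length(true_frac) < 3L) stop("need at least 3 splits")
  if (length(true_frac) != length(est_frac)) stop("lengths differ")
  if (stats::var(true_frac) == 0) {
    return(list(slope = NA_real_, intercept = NA_real_,
                rmse = stats::sd(est_frac), degenerate = TRUE))
  }
  fit <- stats::lm(est_frac ~ true_frac)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       rmse = sqrt(mean(stats::residuals(fit)^2)),
       degenerate = FALSE)
}

#' Median with a distribution-free 95% uncertainty interval
#'
#' The interval is the order-statistic (binomial) confidence interval for the
#' median: with n sorted values, the endpoints are the values at positions
#' `qbinom(0.025, n, 1/2)` and `qbinom(0.975, n, 1/2) + 1` (clamped to
#' [1, n]).
#'
#' @param values numeric vector (length >= 2).
#' @param level confidence level (default 0.95).
#' @return named numeric vector `c(median, lower, upper)`.
#' @export
median_ui <- function(values, level = 0.95) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 values")
  n <- length(values)
  s <- sort(values)
  alpha <- (1 - level) / 2
  lo <- max(1L, stats::qbinom(alpha, n, 0.5))
  hi <- min(n, stats::qbinom(1 - alpha, n, 0.5) + 1L)
  c(median = stats::median(s), lower = s[lo], upper = s[hi])
}
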