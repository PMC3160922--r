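#' Cause-stratified train/test split
#'
#' Assigns, independently within each cause, a random `train_frac` of that
#' cause's records to the training set (`ceiling(train_frac * n_c)`, capped
#' so at least one record is left for testing) and the remainder to the test
#' set. Train and test never share a record.
#'
#' @param ds a [va_data]; every cause must have at least 2 records.
#' @param train_frac fraction of each cause's records for training
#'   (default 0.75).
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(ds, train_frac = 0.75) {
  counts <- table(factor(ds$cause, levels = ds$causes))
  small <- names(counts)[counts < 2L]
  if (length(small)) stop("cause with < 2 records cannot be split: ", small[1L])
  train <- integer(0)
  for (cz in ds$causes) {
    idx <- which(ds$cause == cz)
    n_train <- min(ceiling(train_frac * length(idx)), length(idx) - 1L)
    train <- c(train, idx[sample.int(length(idx), n_train)])
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(ds$cause), train))
}

#' Dirichlet resampling of a test set's cause composition
#'
#' Draws target cause fractions from an uninformative Dirichlet(1, ..., 1)
#' distribution, rounds them to counts preserving the original test size
#' (largest-remainder rounding), and resamples the test records with
#' replacement within each cause to meet the targets. This makes the test
#' composition differ from the training composition in every split, so the
#' evaluation is not an artifact of one particular cause distribution. Mass
#' drawn for a cause with no test records is reallocated proportionally to
#' the causes that have records (and the event recorded in the result).
#'
#' @param ds a [va_data].
#' @param test_idx integer indices of the (non-empty) test records.
#' @return list with `idx` (resampled record indices, a multiset of
#'   `test_idx`), `fractions` (the Dirichlet draw), `counts` (per-cause
#'   target counts) and `dropped_causes` (causes whose mass was reallocated).
#' @export
dirichlet_resample <- function(ds, test_idx) {
  if (!length(test_idx)) stop("empty test set")
  N <- length(ds$causes)
  g <- stats::rgamma(N, shape = 1)
  fractions <- g / sum(g)
  names(fractions) <- ds$causes
  present <- ds$causes %in% ds$cause[test_idx]
  dropped <- ds$causes[!present & fractions > 0]
  target <- fractions
  if (any(!present)) {
    target[!present] <- 0
    target <- target / sum(target)
  }
  size <- length(test_idx)
  counts <- largest_remainder_round(target * size, size)
  names(counts) <- ds$causes
  idx <- integer(0)
  for (j in seq_len(N)) {
    if (counts[j] == 0L) next
    pool <- test_idx[ds$cause[test_idx] == ds$causes[j]]
    idx <- c(idx, pool[sample.int(length(pool), counts[j], replace = TRUE)])
  }
  list(idx = idx, fractions = fractions, counts = counts,
       dropped_causes = dropped)
}

# Round non-negative reals to integers summing to `total`: floor everything,
# then give the remaining units to the largest fractional parts (ties to the
# earlier position).
largest_remainder_round <- function(x, total) {
  f <- floor(x)
  r <- total - sum(f)
  if (r > 0) {
    o <- order(-(x - f), seq_along(x))
    f[o[seq_len(r)]] <- f[o[seq_len(r)]] + 1
  }
  as.integer(f)
}

#' Run the full split/train/resample/evaluate validation design
#'
#' For each split: draw a cause-stratified 75/25 train/test partition, fit
#' the pairwise forest model on the training records only (Tariff item
#' selection included, so no information leaks from test to train), resample
#' the test set's cause composition from a Dirichlet draw, classify the
#' resampled test deaths by rank assignment, and record chance-corrected
#' concordance (per cause and averaged), partial concordance PCCC(k), CSMF
#' accuracy and the per-cause true/estimated CSMF pair. Metrics are
#' summarised across splits as medians with distribution-free 95%
#' uncertainty intervals.
#'
#' The whole run is a deterministic function of (data, configuration, seed):
#' each split consumes its own derived substream.
#'
#' @param ds a [va_data] with >= 2 records per cause.
#' @param n_splits number of splits (500 mirrors the original design; 20 is
#'   a desk-scale default).
#' @param train_frac training fraction per cause.
#' @param k_max largest top-k list evaluated (default `min(N - 1, 5)`).
#' @param assignment cause assignment by `"rank"` (default) or `"score"`.
#' @param seed integer run seed.
#' @param ... model options passed to [va_forest()] (`ntree`, `m`, `top_n`,
#'   `coupling`, `feature_pool`, `balance`).
#' @param verbose print per-split progress to stderr.
#' @return a `va_validation` object: `per_split` (long data frame with
#'   columns split, metric, cause, value), `csmf_pairs` (split x cause true
#'   and estimated fractions), `config`, `causes`, `n_splits`, `seed`.
#' @export
va_validate <- function(ds, n_splits = 20L, train_frac = 0.75,
                        k_max = NULL, assignment = c("rank", "score"),
                        seed = 1L, ..., verbose = FALSE) {
  assignment <- match.arg(assignment)
  N <- length(ds$causes)
  if (is.null(k_max)) k_max <- min(N - 1L, 5L)
  k_max <- min(as.integer(k_max), N - 1L)
  model_opts <- list(...)
  rows <- list()
  csmf_rows <- list()
  for (s in seq_len(n_splits)) {
    split_seed <- substream_seed(as.integer(seed), sprintf("split%06d", s), 0L)
    set.seed(split_seed)
    sp <- stratified_split(ds, train_frac)
    train_ds <- va_subset_records(ds, sp$train)
    fit <- do.call(va_forest, c(list(data = train_ds, seed = split_seed),
                                model_opts))
    set.seed(substream_seed(as.integer(seed), sprintf("split%06d", s), 1L))
    rs <- dirichlet_resample(ds, sp$test)
    test_ds <- va_subset_records(ds, rs$idx)
    scores <- va_score(fit, test_ds)
    ranks <- rank_transform(scores, fit$train_scores)
    topk <- if (assignment == "rank") va_assign(ranks, scores, k = k_max)
            else assign_by_score(scores, k = k_max)
    truth <- test_ds$cause
    ccc <- va_ccc(truth, topk[, 1L], ds$causes)
    true_csmf <- va_csmf(truth, ds$causes)
    est_csmf <- va_csmf(topk[, 1L], ds$causes)
    acc <- csmf_accuracy(true_csmf, est_csmf)
    m_rows <- data.frame(
      split = s,
      metric = c("avg_ccc", "csmf_accuracy",
                 paste0("ccc_", ds$causes),
                 paste0("pccc_k", seq_len(k_max))),
      cause = c("ALL", "ALL", ds$causes, rep("ALL", k_max)),
      value = c(ccc$average, acc, unname(ccc$per_cause),
                vapply(seq_len(k_max),
                       function(k) va_pccc(truth, topk, k, N), numeric(1))),
      stringsAsFactors = FALSE
    )
    rows[[s]] <- m_rows
    csmf_rows[[s]] <- data.frame(
      split = s, cause = ds$causes,
      true_csmf = unname(true_csmf), est_csmf = unname(est_csmf),
      stringsAsFactors = FALSE
    )
    if (verbose) message("split ", s, "/", n_splits,
                         ": avg CCC = ", round(ccc$average, 3),
                         ", CSMF accuracy = ", round(acc, 3))
  }
  structure(
    list(per_split = do.call(rbind, rows),
         csmf_pairs = do.call(rbind, csmf_rows),
         config = c(list(n_splits = as.integer(n_splits),
                         train_frac = train_frac, k_max = k_max,
                         assignment = assignment, seed = as.integer(seed)),
                    model_opts),
         causes = ds$causes, n_splits = as.integer(n_splits),
         seed = as.integer(seed)),
    class = "va_validation"
  )
}

#' @export
summary.va_validation <- function(object, ...) {
  ps <- object$per_split
  metrics <- unique(ps$metric)
  out <- do.call(rbind, lapply(metrics, function(mz) {
    v <- ps$value[ps$metric == mz]
    if (sum(!is.na(v)) < 2L) {
      data.frame(metric = mz, median = stats::median(v, na.rm = TRUE),
                 lower = NA_real_, upper = NA_real_, n_splits = sum(!is.na(v)),
                 stringsAsFactors = FALSE)
    } else {
      ui <- median_ui(v)
      data.frame(metric = mz, median = ui[["median"]], lower = ui[["lower"]],
                 upper = ui[["upper"]], n_splits = sum(!is.na(v)),
                 stringsAsFactors = FALSE)
    }
  }))
  rownames(out) <- NULL
  class(out) <- c("summary.va_validation", "data.frame")
  out
}

#' @export
print.summary.va_validation <- function(x, ...) {
  cat("Validation summary (median [95% UI] across splits)\n")
  df <- as.data.frame(x)
  df$median <- round(df$median, 4)
  df$lower <- round(df$lower, 4)
  df$upper <- round(df$upper, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
print.va_validation <- function(x, ...) {
  cat("Validation run: ", x$n_splits, " stratified Dirichlet-resampled splits, ",
      length(x$causes), " causes, seed ", x$seed, "\n", sep = "")
  s <- summary(x)
  key <- s[s$metric %in% c("avg_ccc", "csmf_accuracy"), ]
  cat("  median average CCC: ", round(key$median[key$metric == "avg_ccc"], 3),
      "\n  median CSMF accuracy: ",
      round(key$median[key$metric == "csmf_accuracy"], 3), "\n", sep = "")
  invisible(x)
}

#' Per-cause CSMF regression across validation splits
#'
#' @param object a `va_validation`.
#' @return data frame with one row per cause: slope, intercept, rmse.
#' @export
va_csmf_regression <- function(object) {
  cp <- object$csmf_pairs
  out <- do.call(rbind, lapply(object$causes, function(cz) {
    sub <- cp[cp$cause == cz, ]
    r <- csmf_regression(sub$true_csmf, sub$est_csmf)
    data.frame(cause = cz, slope = r$slope, intercept = r$intercept,
               rmse = r$rmse, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Plot validation results
#'
#' Draws the PCCC(k) curve (median across splits with its 95% interval) and
#' a per-cause CCC boxplot.
#'
#' @param x a `va_validation`.
#' @param which `"pccc"` or `"ccc"`.
#' @param ... passed to the underlying base-graphics call.
#' @export
plot.va_validation <- function(x, which = c("pccc", "ccc"), ...) {
  which <- match.arg(which)
  ps <- x$per_split
  if (which == "pccc") {
    km <- grep("^pccc_k", unique(ps$metric), value = TRUE)
    ks <- as.integer(sub("pccc_k", "", km))
    o <- order(ks)
    med <- vapply(km[o], function(mz)
      stats::median(ps$value[ps$metric == mz], na.rm = TRUE), numeric(1))
    graphics::plot(ks[o], med, type = "b", pch = 19,
                   xlab = "k (causes assigned)", ylab = "PCCC(k)",
                   main = "Partial chance-corrected concordance", ...)
  } else {
    cm <- grep("^ccc_", unique(ps$metric), value = TRUE)
    vals <- lapply(cm, function(mz) ps$value[ps$metric == mz])
    names(vals) <- sub("ccc_", "", cm)
    graphics::boxplot(vals, ylab = "CCC", las = 2,
                      main = "Chance-corrected concordance by cause", ...)
    graphics::abline(h = 0, lty = 2)
  }
  invisible(x)
}

#' Write validation outputs to a directory
#'
#' Writes `per_split.csv` (long format), `summary.csv` (median and 95% UI
#' per metric), `csmf_pairs.csv` and `manifest.json` (configuration and
#' seed). Deterministic: identical runs produce byte-identical files.
#'
#' @param object a `va_validation`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_va_validation <- function(object, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(object$per_split, file.path(dir, "per_split.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(summary(object)),
                   file.path(dir, "summary.csv"), row.names = FALSE)
  utils::write.csv(object$csmf_pairs, file.path(dir, "csmf_pairs.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(config = object$config, causes = object$causes),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
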