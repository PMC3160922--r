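#' Cause-specific endorsement profiles for synthetic VA data
#'
#' Builds a causes x items matrix of endorsement probabilities: each cause
#' gets `signal_items` designated signal items endorsed with probability
#' `p_signal`, every other item is background noise endorsed with probability
#' `p_background`. A fraction `overlap` of each cause's signal items is
#' shared with the next cause on the list (cyclically), which creates
#' confusable cause pairs and controls the difficulty of the classification
#' problem: `overlap = 0` with `p_signal = 1`, `p_background = 0` gives
#' disjoint deterministic signatures (Bayes error 0), `overlap = 1` makes all
#' causes share one signal block, and `p_signal = p_background` erases the
#' signal entirely (a chance-level problem).
#'
#' Optionally, a fraction `hce_frac` of each cause's signal items is flagged
#' as health-care-experience (HCE) items with their own, typically stronger,
#' endorsement probability `p_signal_hce` — emulating items that are only
#' informative when the household had health-system contact.
#'
#' @param n_causes number of causes (>= 2).
#' @param n_items total number of dichotomous items; must be at least
#'   `n_causes * signal_items * (1 - overlap)`.
#' @param signal_items signal items per cause.
#' @param p_signal endorsement probability of a cause's signal items.
#' @param p_background endorsement probability of all other items.
#' @param overlap fraction in [0, 1] of signal items shared with the next
#'   cause (cyclic).
#' @param hce_frac fraction of each cause's signal items flagged HCE.
#' @param p_signal_hce endorsement probability of HCE signal items (default
#'   `min(1, p_signal + 0.1)`).
#' @return a `va_profiles` list: `prob` (causes x items probability matrix),
#'   `signal` (per-cause signal item sets), `hce` (per-item flags), `causes`,
#'   `items`.
#' @export
va_profiles <- function(n_causes = 5L, n_items = 60L, signal_items = 8L,
                        p_signal = 0.8, p_background = 0.1, overlap = 0,
                        hce_frac = 0, p_signal_hce = min(1, p_signal + 0.1)) {
  stopifnot(n_causes >= 2L, signal_items >= 1L,
            overlap >= 0, overlap <= 1,
            p_signal >= 0, p_signal <= 1, p_background >= 0, p_background <= 1)
  shared <- round(overlap * signal_items)
  stride <- signal_items - shared
  span <- max(n_causes * stride, signal_items)
  if (n_items < span) {
    stop("item budget infeasible: need at least ", span, " items")
  }
  causes <- sprintf("cause%02d", seq_len(n_causes))
  items <- sprintf("item%03d", seq_len(n_items))
  prob <- matrix(p_background, n_causes, n_items,
                 dimnames = list(causes, items))
  signal <- vector("list", n_causes)
  names(signal) <- causes
  hce <- rep(FALSE, n_items)
  names(hce) <- items
  for (i in seq_len(n_causes)) {
    pos <- ((i - 1L) * stride + seq_len(signal_items) - 1L) %% span + 1L
    signal[[i]] <- items[pos]
    n_hce <- floor(hce_frac * signal_items)
    if (n_hce > 0L) {
      hce_pos <- pos[seq_len(n_hce)]
      hce[hce_pos] <- TRUE
      prob[i, hce_pos] <- p_signal_hce
      prob[i, pos[-seq_len(n_hce)]] <- p_signal
    } else {
      prob[i, pos] <- p_signal
    }
  }
  structure(list(prob = prob, signal = signal, hce = hce,
                 causes = causes, items = items),
            class = "va_profiles")
}

#' @export
print.va_profiles <- function(x, ...) {
  cat("Synthetic cause profiles: ", length(x$causes), " causes x ",
      length(x$items), " items (", sum(x$hce), " HCE)\n", sep = "")
  invisible(x)
}

#' Sample a synthetic VA dataset from cause profiles
#'
#' Each death's item responses are drawn independently from its cause's
#' endorsement probabilities (no within-cause item correlation); each cell is
#' then masked missing with probability `missing_rate`.
#'
#' @param profiles a [va_profiles] object.
#' @param deaths_per_cause integer scalar or per-cause vector of death counts.
#' @param missing_rate probability that any cell is recorded missing.
#' @return a [va_data] with gold-standard labels and HCE flags.
#' @export
va_sample_dataset <- function(profiles, deaths_per_cause = 100L,
                              missing_rate = 0) {
  n_causes <- length(profiles$causes)
  counts <- rep_len(as.integer(deaths_per_cause), n_causes)
  if (any(counts < 1L)) stop("deaths_per_cause must be >= 1")
  n <- sum(counts)
  K <- length(profiles$items)
  cause <- rep(profiles$causes, counts)
  x <- matrix(0L, n, K, dimnames = list(sprintf("d%05d", seq_len(n)),
                                        profiles$items))
  row <- 0L
  for (i in seq_len(n_causes)) {
    p <- profiles$prob[i, ]
    block <- matrix(stats::rbinom(counts[i] * K, 1L, rep(p, each = counts[i])),
                    counts[i], K)
    x[row + seq_len(counts[i]), ] <- block
    row <- row + counts[i]
  }
  if (missing_rate > 0) {
    mask <- matrix(stats::runif(n * K) < missing_rate, n, K)
    x[mask] <- NA_integer_
  }
  va_data(x, cause, causes = profiles$causes, hce = profiles$hce)
}

#' Simulate a synthetic verbal autopsy dataset
#'
#' Convenience wrapper building profiles ([va_profiles()]) and sampling a
#' dataset ([va_sample_dataset()]) in one seeded call. The defaults are the
#' desk-scale preset used throughout the package's tests and examples:
#' 5 causes, 60 items, 8 signal items per cause endorsed at 0.8 versus a 0.1
#' background, 100 deaths per cause — separable enough that the full pipeline
#' should recover causes well, small enough that a multi-split validation
#' runs in minutes.
#'
#' @param n_causes,n_items,signal_items,p_signal,p_background,overlap,hce_frac,p_signal_hce
#'   passed to [va_profiles()].
#' @param deaths_per_cause,missing_rate passed to [va_sample_dataset()].
#' @param seed integer seed; the dataset is a deterministic function of the
#'   arguments.
#' @return a [va_data].
#' @export
va_simulate <- function(n_causes = 5L, n_items = 60L, signal_items = 8L,
                        p_signal = 0.8, p_background = 0.1, overlap = 0,
                        hce_frac = 0, p_signal_hce = min(1, p_signal + 0.1),
                        deaths_per_cause = 100L, missing_rate = 0,
                        seed = 1L) {
  set.seed(as.integer(seed))
  prof <- va_profiles(n_causes, n_items, signal_items, p_signal, p_background,
                      overlap, hce_frac, p_signal_hce)
  va_sample_dataset(prof, deaths_per_cause, missing_rate)
}
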