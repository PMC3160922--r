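#' Tariff scores for every (item, cause) pair
#'
#' The tariff of item i for cause j is a robust standardization of the
#' cause-specific endorsement rate across causes:
#' \deqn{tariff(i,j) = (x_{ij} - median_j(x_{i.})) / IQR_j(x_{i.})}
#' where \eqn{x_{ij}} is the fraction of cause-j training deaths endorsing
#' item i (missing responses counted as not endorsed), the median and IQR are
#' taken over causes, and the IQR uses linear-interpolation (type 7)
#' quantiles. The IQR is floored at 0.001 so that an item whose quartiles
#' collapse (e.g. endorsed for a single cause out of many) keeps its signal
#' rather than dividing by zero; an item with identical rates across causes
#' has a zero numerator and hence tariff 0 for every cause. Strongly
#' negative tariffs are as informative as strongly positive ones, so item
#' importance downstream is `|tariff|`.
#'
#' @param ds a [va_data] training dataset with at least one record per cause.
#' @return a `va_tariff`: numeric matrix items x causes with an
#'   `endorsement_rates` attribute holding the underlying rate matrix.
#' @export
va_tariff <- function(ds) {
  counts <- table(factor(ds$cause, levels = ds$causes))
  if (any(counts == 0L)) {
    stop("cause with 0 training records: ", names(counts)[counts == 0L][1L])
  }
  X <- va_symptom_matrix(ds)
  # rates: items x causes
  rates <- sapply(ds$causes, function(cz) colMeans(X[ds$cause == cz, , drop = FALSE]))
  rates <- matrix(rates, nrow = ncol(X), dimnames = list(ds$items, ds$causes))
  med <- apply(rates, 1L, stats::median)
  iqr <- apply(rates, 1L, function(r) {
    q <- stats::quantile(r, c(0.25, 0.75), names = FALSE, type = 7)
    q[2L] - q[1L]
  })
  tt <- (rates - med) / pmax(iqr, 0.001)
  structure(tt, endorsement_rates = rates, class = c("va_tariff", "matrix", "array"))
}

#' Most informative items for a cause
#'
#' Returns the `top_n` items with the largest absolute tariff for the cause,
#' ties broken by item order. With all-zero tariffs this degenerates to the
#' first `top_n` items in item order. If fewer than `top_n` items exist, all
#' are returned.
#'
#' @param tt a [va_tariff] matrix.
#' @param cause cause identifier (a column of `tt`).
#' @param top_n number of items to keep (default 40).
#' @return character vector of item identifiers, most informative first.
#' @export
top_items <- function(tt, cause, top_n = 40L) {
  if (top_n < 1L) stop("top_n must be >= 1")
  if (!cause %in% colnames(tt)) stop("unknown cause: ", cause)
  o <- order(-abs(tt[, cause]), seq_len(nrow(tt)))
  rownames(tt)[o[seq_len(min(top_n, nrow(tt)))]]
}

#' @export
print.va_tariff <- function(x, ...) {
  cat("Tariff table: ", nrow(x), " items x ", ncol(x), " causes\n", sep = "")
  invisible(x)
}
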