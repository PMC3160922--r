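#' Verbal autopsy dataset
#'
#' Container for dichotomous verbal-autopsy interview data: one row per death,
#' one column per sign/symptom item, coded 1 (endorsed), 0 (not endorsed) or
#' `NA` (missing), together with a gold-standard cause label per death and an
#' ordered cause list. The cause and item orders are fixed at construction and
#' are used for every deterministic tie-break downstream.
#'
#' Missing responses are preserved as `NA` in storage; they are treated as
#' "not endorsed" wherever a tree branches on an item or an endorsement rate
#' is computed (see [va_tariff()]). That policy lives in one place
#' ([va_symptom_matrix()]) so it can be revisited without touching callers.
#'
#' @param x integer/numeric matrix of 0/1/`NA` symptom codes with row names
#'   (death identifiers, unique) and column names (item identifiers).
#' @param cause character vector of gold-standard causes, one per row of `x`.
#' @param causes ordered cause list; defaults to the sorted unique causes.
#'   Every value of `cause` must be a member.
#' @param hce logical vector, one per item, marking health-care-experience
#'   (HCE) items; defaults to all `FALSE`.
#' @return An object of class `va_data` with elements `x`, `cause`, `causes`,
#'   `items`, `hce`.
#' @seealso [read_va_data()], [filter_items()], [va_simulate()]
#' @export
va_data <- function(x, cause, causes = NULL, hce = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (is.null(rownames(x))) stop("symptom matrix must have death-id row names")
  if (is.null(colnames(x))) stop("symptom matrix must have item column names")
  if (anyDuplicated(rownames(x))) {
    dup <- rownames(x)[duplicated(rownames(x))][1L]
    stop("duplicate death id: ", dup)
  }
  if (anyDuplicated(colnames(x))) stop("duplicate item identifiers")
  bad <- !(x %in% c(0L, 1L, NA_integer_))
  if (any(bad)) stop("symptom values must be 0, 1 or missing")
  cause <- as.character(cause)
  if (length(cause) != nrow(x)) stop("one cause label per record required")
  if (is.null(causes)) causes <- sort(unique(cause), method = "radix")
  causes <- as.character(causes)
  if (anyDuplicated(causes)) stop("cause list entries must be unique")
  unknown <- which(!(cause %in% causes))
  if (length(unknown)) {
    stop("record ", unknown[1L], " (", rownames(x)[unknown[1L]],
         ") has cause '", cause[unknown[1L]], "' not on the cause list")
  }
  if (length(causes) < 2L) stop("at least 2 causes required")
  if (is.null(hce)) hce <- rep(FALSE, ncol(x))
  hce <- as.logical(hce)
  if (length(hce) != ncol(x)) stop("one HCE flag per item required")
  names(hce) <- colnames(x)
  structure(
    list(x = x, cause = cause, causes = causes, items = colnames(x), hce = hce),
    class = "va_data"
  )
}

#' @export
print.va_data <- function(x, ...) {
  cat("Verbal autopsy dataset: ", nrow(x$x), " deaths, ", length(x$items),
      " items (", sum(x$hce), " HCE), ", length(x$causes), " causes\n", sep = "")
  tab <- table(factor(x$cause, levels = x$causes))
  cat("Deaths per cause:\n")
  print(tab)
  invisible(x)
}

#' @export
dim.va_data <- function(x) dim(x$x)

#' Symptom matrix with the branching policy applied
#'
#' Returns the 0/1 symptom matrix used by tree induction and endorsement-rate
#' computation: missing values are coded as not endorsed (0). This is the
#' single point where the missing-data policy is applied.
#'
#' @param ds a [va_data] object.
#' @return integer matrix of 0/1 values, same dimnames as `ds$x`.
#' @export
va_symptom_matrix <- function(ds) {
  x <- ds$x
  x[is.na(x)] <- 0L
  x
}

#' Read a verbal autopsy dataset from CSV
#'
#' The CSV has columns `death_id,gold_cause,<item_1>,...,<item_K>` with item
#' values 1/0/empty (empty = missing). A sidecar YAML configuration may declare
#' the cause list (fixing its order) and the HCE item identifiers. Item columns
#' are ordered lexicographically at load time; this order is preserved by
#' [write_va_data()] so a load/write/load round trip is exact.
#'
#' @param path CSV file path.
#' @param config optional path to a YAML sidecar with fields `causes` and
#'   `hce_items`, or a list with those fields.
#' @param hce_mode `"include"` keeps all items; `"exclude"` drops items flagged
#'   HCE, emulating settings without household recall of health-care contact.
#' @return a [va_data] object.
#' @export
read_va_data <- function(path, config = NULL, hce_mode = c("include", "exclude")) {
  hce_mode <- match.arg(hce_mode)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c("death_id", "gold_cause")
  if (!all(need %in% names(df))) stop("CSV must have death_id and gold_cause columns")
  item_cols <- setdiff(names(df), need)
  if (!length(item_cols)) stop("CSV has no item columns")
  item_cols <- sort(item_cols, method = "radix")
  x <- sapply(item_cols, function(cn) {
    v <- df[[cn]]
    v[v == ""] <- NA
    iv <- suppressWarnings(as.integer(v))
    if (any(!is.na(v) & (is.na(iv) | !(iv %in% c(0L, 1L)))))
      stop("item '", cn, "' has non-dichotomous values")
    iv
  })
  x <- matrix(as.integer(x), nrow = nrow(df), dimnames = list(df$death_id, item_cols))
  cfg <- config
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  causes <- if (!is.null(cfg$causes)) as.character(cfg$causes) else NULL
  hce_items <- if (!is.null(cfg$hce_items)) as.character(cfg$hce_items) else character()
  unknown_hce <- setdiff(hce_items, item_cols)
  if (length(unknown_hce)) stop("HCE item not in data: ", unknown_hce[1L])
  ds <- va_data(x, df$gold_cause, causes = causes, hce = item_cols %in% hce_items)
  if (hce_mode == "exclude" && any(ds$hce)) {
    ds <- filter_items(ds, ds$items[!ds$hce])
  }
  ds
}

#' Write a verbal autopsy dataset to CSV (plus optional YAML sidecar)
#'
#' @param ds a [va_data] object.
#' @param path output CSV path.
#' @param config_path optional path for a YAML sidecar recording the cause list
#'   and HCE items.
#' @return `path`, invisibly.
#' @export
write_va_data <- function(ds, path, config_path = NULL) {
  xc <- ds$x
  xc[is.na(xc)] <- NA  # written as empty cells
  df <- data.frame(death_id = rownames(ds$x), gold_cause = ds$cause,
                   xc, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  if (!is.null(config_path)) {
    yaml::write_yaml(
      list(causes = as.list(ds$causes), hce_items = as.list(ds$items[ds$hce])),
      config_path
    )
  }
  invisible(path)
}

#' Restrict a dataset to a subset of items
#'
#' Column-subsets the symptom matrix; records are unchanged. Used for the
#' Tariff-based item reduction and for excluding HCE items.
#'
#' @param ds a [va_data] object.
#' @param keep character vector of item identifiers to retain (subset of
#'   `ds$items`); must be non-empty.
#' @return a [va_data] object with only the kept items, in their original
#'   relative order.
#' @export
filter_items <- function(ds, keep) {
  keep <- as.character(keep)
  if (!length(keep)) stop("cannot filter to an empty item set")
  unknown <- setdiff(keep, ds$items)
  if (length(unknown)) stop("unknown item: ", unknown[1L])
  sel <- ds$items[ds$items %in% keep]
  va_data(ds$x[, sel, drop = FALSE], ds$cause, causes = ds$causes,
          hce = ds$hce[sel])
}

# Row-subset (by integer indices, possibly with repeats, e.g. a bootstrap or
# Dirichlet-resampled multiset). Row names are made unique so va_data's
# duplicate-id check still holds for resampled records.
va_subset_records <- function(ds, idx) {
  x <- ds$x[idx, , drop = FALSE]
  rownames(x) <- make.unique(rownames(ds$x)[idx], sep = "#")
  va_data(x, ds$cause[idx], causes = ds$causes, hce = ds$hce)
}
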