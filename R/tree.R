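#' Bootstrap resample of record indices
#'
#' Draws `n` records with replacement from `n` records, the resampling step
#' that precedes every tree in the forest.
#'
#' @param idx vector of record indices (non-empty).
#' @return vector of the same length, each element drawn from `idx`.
#' @export
bootstrap_sample <- function(idx) {
  if (!length(idx)) stop("cannot bootstrap an empty record set")
  idx[sample.int(length(idx), length(idx), replace = TRUE)]
}

# Gini impurity of a two-class node with n1 of class 1 out of n.
gini_impurity <- function(n1, n) {
  p <- n1 / n
  2 * p * (1 - p)
}

#' Best binary split among candidate items
#'
#' Evaluates each candidate item's split of the node's records into endorsed
#' (right) and not-endorsed (left) children and returns the item with the
#' largest Gini impurity decrease. Candidates that are constant on the node's
#' records do not split and are skipped; if every candidate is constant the
#' function returns `NA`. Ties are broken in favour of the item earlier in
#' item (column) order.
#'
#' @param X 0/1 integer matrix (missing already coded 0), records in rows.
#' @param rows integer indices of the node's records.
#' @param y integer class codes (1 or 2), aligned with the rows of `X`.
#' @param cand integer column indices of the candidate items.
#' @return the chosen column index, or `NA_integer_` if no candidate splits.
#' @export
best_split <- function(X, rows, y, cand) {
  cand <- sort(cand)
  n <- length(rows)
  xs <- X[rows, cand, drop = FALSE]
  y1 <- y[rows] == 1L
  nR <- colSums(xs)                      # endorsed counts per candidate
  nR1 <- colSums(xs * y1)                # endorsed & class-1
  n1 <- sum(y1)
  valid <- nR > 0L & nR < n
  if (!any(valid)) return(NA_integer_)
  nL <- n - nR
  nL1 <- n1 - nR1
  child <- (nR * gini_impurity(nR1, nR) + nL * gini_impurity(nL1, nL)) / n
  decrease <- gini_impurity(n1, n) - child
  decrease[!valid] <- -Inf
  cand[which.max(decrease)]
}

#' Grow one randomized two-class decision tree
#'
#' Recursive induction on (already bootstrap-resampled) two-class records: at
#' each node `m` items are drawn uniformly without replacement from the node's
#' remaining item pool (items not yet tested on the path; all of them if fewer
#' than `m` remain), the best Gini split is taken, and the records are
#' partitioned into the endorsed (right) and not-endorsed (left) branches.
#' A node becomes a leaf when it is pure, its item pool is exhausted, or no
#' candidate splits it; the leaf is labelled with the node's majority class,
#' ties going to the class earlier in cause order (`classes[1]`).
#'
#' @param X 0/1 integer matrix with item column names.
#' @param y integer vector of class codes 1/2 aligned with rows of `X`.
#' @param classes character vector of the two cause labels, in cause-list
#'   order; code 1 means `classes[1]`.
#' @param m number of candidate items per node.
#' @param pool integer column indices forming the tree's item pool (defaults
#'   to all columns).
#' @return A `va_tree`: a flat node table (`item` item names or `NA`,
#'   `left`/`right` child row indices, `label` leaf labels) plus the class
#'   pair. Row 1 is the root; every root-to-leaf path tests an item at most
#'   once.
#' @export
grow_tree <- function(X, y, classes, m, pool = seq_len(ncol(X))) {
  if (length(classes) != 2L) stop("a tree distinguishes exactly 2 classes")
  if (!all(y %in% c(1L, 2L))) stop("class codes must be 1 or 2")
  if (m < 1L) stop("m must be >= 1")
  item <- character(0); left <- integer(0); right <- integer(0); label <- character(0)
  n_nodes <- 0L
  new_node <- function() {
    n_nodes <<- n_nodes + 1L
    item[n_nodes] <<- NA_character_
    left[n_nodes] <<- NA_integer_
    right[n_nodes] <<- NA_integer_
    label[n_nodes] <<- NA_character_
    n_nodes
  }
  majority <- function(rows) {
    if (sum(y[rows] == 1L) >= sum(y[rows] == 2L)) classes[1L] else classes[2L]
  }
  build <- function(rows, pool) {
    id <- new_node()
    ys <- y[rows]
    if (all(ys == ys[1L]) || !length(pool)) {
      label[id] <<- majority(rows)
      return(id)
    }
    cand <- if (length(pool) <= m) pool else pool[sample.int(length(pool), m)]
    s <- best_split(X, rows, y, cand)
    if (is.na(s)) {
      label[id] <<- majority(rows)
      return(id)
    }
    go_right <- X[rows, s] == 1L
    item[id] <<- colnames(X)[s]
    sub_pool <- pool[pool != s]
    left[id] <<- build(rows[!go_right], sub_pool)
    right[id] <<- build(rows[go_right], sub_pool)
    id
  }
  build(seq_along(y), sort(pool))
  structure(
    list(item = item, left = left, right = right, label = label,
         classes = classes),
    class = "va_tree"
  )
}

#' Predict classes from a decision tree
#'
#' Each record starts at the root and moves right if the node's item is
#' endorsed, left otherwise, until it reaches a leaf. Missing values must
#' already be coded 0 (not endorsed).
#'
#' @param tree a `va_tree`.
#' @param X 0/1 integer matrix whose columns cover every item the tree tests.
#' @return character vector of predicted class labels, one per row of `X`.
#' @export
predict_tree <- function(tree, X) {
  ii <- match(tree$item, colnames(X))
  untested <- which(!is.na(tree$item) & is.na(ii))
  if (length(untested)) {
    stop("tree tests item '", tree$item[untested[1L]], "' absent from the input")
  }
  n <- nrow(X)
  at <- rep.int(1L, n)
  out <- character(n)
  # parents precede children, so one forward pass routes every record
  for (r in seq_along(tree$item)) {
    sel <- which(at == r)
    if (!length(sel)) next
    if (is.na(tree$item[r])) {
      out[sel] <- tree$label[r]
    } else {
      endorsed <- X[sel, ii[r]] == 1L
      at[sel] <- ifelse(endorsed, tree$right[r], tree$left[r])
    }
  }
  out
}

#' @export
print.va_tree <- function(x, ...) {
  cat("Decision tree (", x$classes[1L], " vs ", x$classes[2L], "): ",
      length(x$item), " nodes, ", sum(!is.na(x$label)), " leaves\n", sep = "")
  invisible(x)
}

# Nested-list form of a tree (for JSON persistence): internal nodes are
# list(item=, left=, right=), leaves list(leaf=).
tree_to_list <- function(tree) {
  rec <- function(r) {
    if (is.na(tree$item[r])) list(leaf = tree$label[r])
    else list(item = tree$item[r], left = rec(tree$left[r]), right = rec(tree$right[r]))
  }
  list(classes = as.list(tree$classes), root = rec(1L))
}

tree_from_list <- function(lst) {
  item <- character(0); left <- integer(0); right <- integer(0); label <- character(0)
  n_nodes <- 0L
  rec <- function(node) {
    n_nodes <<- n_nodes + 1L
    id <- n_nodes
    item[id] <<- NA_character_; left[id] <<- NA_integer_
    right[id] <<- NA_integer_; label[id] <<- NA_character_
    if (!is.null(node$leaf)) {
      label[id] <<- node$leaf
    } else {
      item[id] <<- node$item
      left[id] <<- rec(node$left)
      right[id] <<- rec(node$right)
    }
    id
  }
  rec(lst$root)
  structure(
    list(item = item, left = left, right = right, label = label,
         classes = unlist(lst$classes)),
    class = "va_tree"
  )
}
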