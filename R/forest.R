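# Deterministic 32-bit string hash used to key RNG substreams by cause
# identity (not position), so permuting the cause list permutes results
# without changing them.
str_hash32 <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# Substream seed for tree `j` (j = 0 is the pair's balancing step) of the
# classifier identified by `key` under run seed `seed`.
substream_seed <- function(seed, key, j) {
  as.integer((str_hash32(key) + (seed %% 65536) * 32749 + j * 7919) %% 2147483647)
}

#' Balance two classes by upsampling
#'
#' Resamples the smaller class with replacement up to the size of the larger
#' class, so both classes contribute equally to tree induction. All records of
#' the larger class are kept.
#'
#' @param idx_a,idx_b record indices of the two classes (both non-empty).
#' @return list with `idx` (combined balanced indices, class a first) and
#'   `y` (class codes 1/2).
#' @export
balance_classes <- function(idx_a, idx_b) {
  if (!length(idx_a) || !length(idx_b)) stop("both classes must be non-empty")
  na <- length(idx_a); nb <- length(idx_b)
  if (na < nb) idx_a <- idx_a[sample.int(na, nb, replace = TRUE)]
  if (nb < na) idx_b <- idx_b[sample.int(nb, na, replace = TRUE)]
  list(idx = c(idx_a, idx_b),
       y = rep(c(1L, 2L), c(length(idx_a), length(idx_b))))
}

# Train the forest for one unordered cause pair: restrict to the pair's item
# pool, balance classes, grow ntree trees on fresh bootstrap resamples.
train_pair <- function(X, cause, cause_a, cause_b, pool_items, ntree, m, seed,
                       balance = TRUE) {
  idx_a <- which(cause == cause_a)
  idx_b <- which(cause == cause_b)
  if (!length(idx_a) || !length(idx_b)) {
    stop("empty class in pair (", cause_a, ", ", cause_b, ")")
  }
  key <- paste(cause_a, cause_b, sep = "\x1f")
  set.seed(substream_seed(seed, key, 0L))
  bal <- if (balance) balance_classes(idx_a, idx_b) else
    list(idx = c(idx_a, idx_b),
         y = rep(c(1L, 2L), c(length(idx_a), length(idx_b))))
  pool <- match(pool_items, colnames(X))
  Xp <- X[bal$idx, , drop = FALSE]
  trees <- vector("list", ntree)
  for (j in seq_len(ntree)) {
    set.seed(substream_seed(seed, key, j))
    boot <- bootstrap_sample(seq_along(bal$y))
    trees[[j]] <- grow_tree(Xp[boot, , drop = FALSE], bal$y[boot],
                            classes = c(cause_a, cause_b), m = m, pool = pool)
  }
  list(cause_a = cause_a, cause_b = cause_b, pool = pool_items, trees = trees)
}

#' Fit a pairwise random-forest verbal autopsy model
#'
#' Trains the full one-vs-one model: a Tariff table is computed from the
#' training data, each unordered cause pair gets an item pool (by default the
#' union of the two causes' `top_n` most informative items) and a forest of
#' `ntree` randomized decision trees grown on class-balanced bootstrap
#' resamples with `m` candidate items per node. The finished model also stores
#' the Train Score Matrix — the vote tallies of the model on its own training
#' records — which is the reference distribution for rank-based cause
#' assignment (see [rank_transform()]).
#'
#' All randomness is driven by `seed` through per-pair, per-tree substreams
#' keyed by cause identifiers, so refitting with the same data, configuration
#' and seed reproduces the model exactly, and permuting the cause list
#' permutes (but does not change) the result.
#'
#' @param data a [va_data] training dataset; every cause on the cause list
#'   must have at least one record.
#' @param ntree trees per pairwise forest (default 100).
#' @param m candidate items per tree node (default 5).
#' @param top_n informative items retained per cause by the Tariff reduction
#'   (default 40).
#' @param coupling `"one_vs_one"` (default) trains a forest per cause pair;
#'   `"one_vs_all"` trains one forest per cause against all others.
#' @param feature_pool `"pair_union"` (default) gives each pair the union of
#'   its two causes' top-`top_n` item sets; `"global_union"` gives every
#'   classifier the union over all causes.
#' @param balance upsample the smaller class to equal size (default `TRUE`).
#' @param seed integer run seed recorded in the model.
#' @return an object of class `va_forest`.
#' @examples
#' ds <- va_simulate(n_causes = 3, n_items = 20, signal_items = 4,
#'                   deaths_per_cause = 20, seed = 1)
#' fit <- va_forest(ds, ntree = 10, seed = 1)
#' predict(fit, ds)[1:3]
#' @export
va_forest <- function(data, ntree = 100L, m = 5L, top_n = 40L,
                      coupling = c("one_vs_one", "one_vs_all"),
                      feature_pool = c("pair_union", "global_union"),
                      balance = TRUE, seed = 1L) {
  coupling <- match.arg(coupling)
  feature_pool <- match.arg(feature_pool)
  stopifnot(ntree >= 1L, m >= 1L, top_n >= 1L)
  if (!inherits(data, "va_data")) stop("data must be a va_data object")
  tt <- va_tariff(data)  # also validates >=1 record per cause
  X <- va_symptom_matrix(data)
  causes <- data$causes
  N <- length(causes)
  top <- lapply(causes, function(cz) top_items(tt, cz, top_n))
  names(top) <- causes
  global_pool <- sort(unique(unlist(top)))
  forests <- list()
  if (coupling == "one_vs_one") {
    for (a in seq_len(N - 1L)) {
      for (b in seq.int(a + 1L, N)) {
        # canonical pair orientation (lexicographic by cause id) so training
        # depends on the cause set, not on cause-list positions
        pr <- sort(c(causes[a], causes[b]), method = "radix")
        ca <- pr[1L]; cb <- pr[2L]
        pool_items <- if (feature_pool == "pair_union")
          data$items[data$items %in% union(top[[ca]], top[[cb]])] else global_pool
        forests[[paste(ca, cb, sep = "\x1f")]] <-
          train_pair(X, data$cause, ca, cb, pool_items, ntree, m, seed, balance)
      }
    }
  } else {
    for (cz in causes) {
      pool_items <- if (feature_pool == "pair_union") top[[cz]] else global_pool
      idx_a <- which(data$cause == cz)
      idx_b <- which(data$cause != cz)
      key <- paste(cz, ".other", sep = "\x1f")
      set.seed(substream_seed(seed, key, 0L))
      bal <- if (balance) balance_classes(idx_a, idx_b) else
        list(idx = c(idx_a, idx_b),
             y = rep(c(1L, 2L), c(length(idx_a), length(idx_b))))
      pool <- match(pool_items, colnames(X))
      Xp <- X[bal$idx, , drop = FALSE]
      trees <- vector("list", ntree)
      for (j in seq_len(ntree)) {
        set.seed(substream_seed(seed, key, j))
        boot <- bootstrap_sample(seq_along(bal$y))
        trees[[j]] <- grow_tree(Xp[boot, , drop = FALSE], bal$y[boot],
                                classes = c(cz, ".other"), m = m, pool = pool)
      }
      forests[[cz]] <- list(cause_a = cz, cause_b = ".other",
                            pool = pool_items, trees = trees)
    }
  }
  model <- structure(
    list(causes = causes, items = data$items, hce = data$hce,
         config = list(ntree = as.integer(ntree), m = as.integer(m),
                       top_n = as.integer(top_n), coupling = coupling,
                       feature_pool = feature_pool, balance = balance,
                       seed = as.integer(seed)),
         tariff = tt, top_items = top, forests = forests,
         train_scores = NULL, train_ids = rownames(data$x)),
    class = "va_forest"
  )
  model$train_scores <- va_score(model, data)
  model
}

#' Score examples with a fitted model
#'
#' Tallies, for each example and cause, the number of trees (over all pairwise
#' forests involving that cause) voting for the cause. Every pair contributes
#' exactly `ntree` votes split between its two causes, so under one-vs-one
#' coupling each row of the score matrix sums to `ntree * N(N-1)/2`.
#'
#' @param model a [va_forest].
#' @param newdata a [va_data] (its gold labels, if any, are ignored) whose
#'   items cover the model's items.
#' @return integer Score Matrix, examples x causes.
#' @export
va_score <- function(model, newdata) {
  if (!inherits(newdata, "va_data")) stop("newdata must be a va_data object")
  missing_items <- setdiff(model$items, newdata$items)
  if (length(missing_items)) {
    stop("newdata lacks model item: ", missing_items[1L])
  }
  X <- va_symptom_matrix(newdata)
  n <- nrow(X)
  scores <- matrix(0L, n, length(model$causes),
                   dimnames = list(rownames(X), model$causes))
  for (pf in model$forests) {
    votes_a <- integer(n)
    for (tr in pf$trees) {
      votes_a <- votes_a + (predict_tree(tr, X) == pf$cause_a)
    }
    scores[, pf$cause_a] <- scores[, pf$cause_a] + votes_a
    if (pf$cause_b != ".other") {
      scores[, pf$cause_b] <- scores[, pf$cause_b] +
        (length(pf$trees) - votes_a)
    }
  }
  scores
}

#' @export
print.va_forest <- function(x, ...) {
  cfg <- x$config
  cat("Pairwise random-forest VA model\n")
  cat("  causes: ", length(x$causes), " (", paste(utils::head(x$causes, 5),
      collapse = ", "), if (length(x$causes) > 5) ", ..." else "", ")\n", sep = "")
  cat("  coupling: ", cfg$coupling, ", forests: ", length(x$forests),
      ", trees: ", length(x$forests) * cfg$ntree, "\n", sep = "")
  cat("  ntree = ", cfg$ntree, ", m = ", cfg$m, ", top_n = ", cfg$top_n,
      ", seed = ", cfg$seed, "\n", sep = "")
  invisible(x)
}

#' @export
summary.va_forest <- function(object, ...) {
  res <- list(
    n_causes = length(object$causes),
    n_forests = length(object$forests),
    n_trees = length(object$forests) * object$config$ntree,
    config = object$config,
    pool_sizes = vapply(object$forests, function(f) length(f$pool), integer(1)),
    train_size = length(object$train_ids)
  )
  class(res) <- "summary.va_forest"
  res
}

#' @export
print.summary.va_forest <- function(x, ...) {
  cat("Pairwise random-forest VA model: ", x$n_causes, " causes, ",
      x$n_forests, " forests, ", x$n_trees, " trees\n", sep = "")
  cat("Trained on ", x$train_size, " deaths; item pools per classifier: ",
      min(x$pool_sizes), "-", max(x$pool_sizes), " items\n", sep = "")
  invisible(x)
}

#' Predict causes of death
#'
#' Scores `newdata`, converts the scores to ranks against the model's Train
#' Score Matrix ([rank_transform()]) and assigns the best-ranked cause (or the
#' `k` best-ranked causes). `method = "score"` skips rank normalization and
#' assigns the highest-scoring cause instead (the max-score variant).
#'
#' @param object a [va_forest].
#' @param newdata a [va_data] of examples to classify.
#' @param type `"cause"` returns the top-1 cause per death; `"topk"` an
#'   examples x k matrix of ordered causes; `"rank"`/`"score"` the underlying
#'   matrices.
#' @param k list length for `type = "topk"` (1 <= k < N).
#' @param method `"rank"` (default) or `"score"` assignment.
#' @param ... unused.
#' @return per `type`: character vector, character matrix, or integer matrix.
#' @export
predict.va_forest <- function(object, newdata,
                              type = c("cause", "topk", "rank", "score"),
                              k = 1L, method = c("rank", "score"), ...) {
  type <- match.arg(type)
  method <- match.arg(method)
  scores <- va_score(object, newdata)
  if (type == "score") return(scores)
  ranks <- rank_transform(scores, object$train_scores)
  if (type == "rank") return(ranks)
  kk <- if (type == "cause") 1L else as.integer(k)
  assigned <- if (method == "rank") va_assign(ranks, scores, k = kk)
              else assign_by_score(scores, k = kk)
  if (type == "cause") assigned[, 1L] else assigned
}

#' Persist a fitted model to a directory
#'
#' Writes `config.yaml` (configuration, cause list, items, HCE flags),
#' `tariff.csv`, one JSON file of trees per classifier under `trees/`, and
#' `train_scores.csv`. The serialization is deterministic: the same data,
#' configuration and seed produce byte-identical files.
#'
#' @param model a [va_forest].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_va_forest <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "trees"), showWarnings = FALSE)
  yaml::write_yaml(
    list(config = model$config, causes = as.list(model$causes),
         items = as.list(model$items),
         hce_items = as.list(model$items[model$hce]),
         train_ids = as.list(model$train_ids)),
    file.path(dir, "config.yaml")
  )
  utils::write.csv(as.data.frame(unclass(model$tariff)),
                   file.path(dir, "tariff.csv"))
  for (i in seq_along(model$forests)) {
    pf <- model$forests[[i]]
    payload <- list(cause_a = pf$cause_a, cause_b = pf$cause_b,
                    pool = as.list(pf$pool),
                    trees = lapply(pf$trees, tree_to_list))
    jsonlite::write_json(payload, file.path(dir, "trees",
                                            sprintf("pair_%03d.json", i)),
                         auto_unbox = TRUE, digits = NA)
  }
  utils::write.csv(as.data.frame(model$train_scores),
                   file.path(dir, "train_scores.csv"))
  invisible(dir)
}

#' Load a model written by [write_va_forest()]
#'
#' @param dir model directory.
#' @return a [va_forest].
#' @export
read_va_forest <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  items <- unlist(cfg$items)
  hce <- items %in% unlist(cfg$hce_items)
  names(hce) <- items
  tariff <- as.matrix(utils::read.csv(file.path(dir, "tariff.csv"),
                                      row.names = 1, check.names = FALSE))
  tree_files <- sort(list.files(file.path(dir, "trees"), full.names = TRUE))
  forests <- list()
  for (f in tree_files) {
    p <- jsonlite::read_json(f)
    pf <- list(cause_a = p$cause_a, cause_b = p$cause_b,
               pool = unlist(p$pool),
               trees = lapply(p$trees, tree_from_list))
    nm <- if (pf$cause_b == ".other") pf$cause_a else
      paste(pf$cause_a, pf$cause_b, sep = "\x1f")
    forests[[nm]] <- pf
  }
  train_scores <- as.matrix(utils::read.csv(file.path(dir, "train_scores.csv"),
                                            row.names = 1, check.names = FALSE))
  storage.mode(train_scores) <- "integer"
  structure(
    list(causes = unlist(cfg$causes), items = items, hce = hce,
         config = cfg$config, tariff = tariff, top_items = NULL,
         forests = forests, train_scores = train_scores,
         train_ids = unlist(cfg$train_ids)),
    class = "va_forest"
  )
}
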