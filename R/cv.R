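# Learner interface: a learner is a list with
#   fit(table, labels) -> model
#   predict(model, newdata) -> list(class = character, prob = matrix | NULL)
# so that trees, baselines, or any user model plug into the same
# cross-validation and feature-selection machinery.

#' Decision-tree learner for cross-validation and feature selection
#'
#' Wraps [induce_tree()] / [predict.osa_tree()] in the learner interface
#' used by [evaluate_cv()] and [select_features()].
#'
#' @param min_leaf,confidence,prune Passed to [induce_tree()].
#' @return A learner list with `fit` and `predict` functions.
#' @export
tree_learner <- function(min_leaf = 2, confidence = 0.25, prune = TRUE) {
  list(
    fit = function(table, labels) {
      induce_tree(table, labels, min_leaf = min_leaf,
                  confidence = confidence, prune = prune)
    },
    predict = function(model, newdata) {
      list(class = predict(model, newdata, type = "class"),
           prob = predict(model, newdata, type = "prob"))
    }
  )
}

#' Majority-class baseline learner
#'
#' Predicts the most frequent training class for every sample; a
#' chance-level reference for cross-validated metrics.
#'
#' @return A learner list with `fit` and `predict` functions.
#' @export
majority_learner <- function() {
  list(
    fit = function(table, labels) {
      tab <- table(labels)
      list(class = names(tab)[which.max(tab)],
           prob = as.numeric(tab / sum(tab)), classes = names(tab))
    },
    predict = function(model, newdata) {
      n <- nrow(newdata)
      prob <- matrix(rep(model$prob, each = n), nrow = n,
                     dimnames = list(NULL, model$classes))
      list(class = rep(model$class, n), prob = prob)
    }
  )
}

#' Stratified fold assignment
#'
#' Assigns samples to `k` folds preserving class proportions: members of
#' each class are shuffled and dealt round-robin with a fold counter shared
#' across classes, so overall fold sizes differ by at most one and each
#' class is spread evenly.
#'
#' @param labels Class labels.
#' @param k Number of folds.
#' @param seed Integer seed for the shuffles.
#' @return Integer vector of fold indices in `1..k`.
#' @export
stratified_folds <- function(labels, k = 10, seed = 1) {
  labels <- as.character(labels)
  n <- length(labels)
  stopifnot(k >= 2, k <= n)
  with_seed(seed, {
    fold <- integer(n)
    counter <- 0L
    for (cl in sort(unique(labels))) {
      idx <- sample(which(labels == cl))
      fold[idx] <- (counter + seq_along(idx) - 1L) %% k + 1L
      counter <- counter + length(idx)
    }
    fold
  })
}

#' Stratified k-fold cross-validated evaluation
#'
#' Trains the learner on k-1 folds and predicts the held-out fold, for every
#' fold; the pooled out-of-fold confusion matrix yields overall accuracy and
#' Cohen's kappa, and per-class TP rate, FP rate, precision, recall,
#' F-measure and one-vs-rest ROC area (computed from the learner's class
#' scores). When the rarest class has fewer than `k` members, `k` is reduced
#' to that count with a warning.
#'
#' @param table Data frame of features.
#' @param labels Class labels, one per row.
#' @param learner A learner list (e.g. [tree_learner()]).
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @return An object of class `osa_cv_metrics`: `accuracy` (percent),
#'   `kappa`, `per_class` (data frame with a trailing weighted-average row),
#'   `confusion` (rows = truth), `folds`, `k`, `predicted`, `scores`.
#' @export
evaluate_cv <- function(table, labels, learner, k = 10, seed = 1) {
  stopifnot(is.data.frame(table), nrow(table) == length(labels))
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) {
    stop("cross-validation needs at least two classes", call. = FALSE)
  }
  min_n <- min(table(labels))
  if (min_n < k) {
    warning(sprintf("rarest class has %d members; reducing folds to %d",
                    min_n, min_n))
    k <- min_n
  }
  fold <- stratified_folds(labels, k, seed)

  pred <- character(length(labels))
  scores <- matrix(NA_real_, nrow = length(labels), ncol = length(classes),
                   dimnames = list(NULL, classes))
  for (f in seq_len(k)) {
    test <- fold == f
    model <- learner$fit(table[!test, , drop = FALSE], labels[!test])
    out <- learner$predict(model, table[test, , drop = FALSE])
    pred[test] <- out$class
    if (!is.null(out$prob)) {
      hit <- intersect(colnames(out$prob), classes)
      scores[test, hit] <- out$prob[, hit, drop = FALSE]
    }
  }

  confusion <- table(factor(labels, classes), factor(pred, classes))
  acc <- 100 * sum(diag(confusion)) / length(labels)
  kap <- cohen_kappa(unclass(confusion))

  per_class <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(labels == cl & pred == cl)
    fn <- sum(labels == cl & pred != cl)
    fp <- sum(labels != cl & pred == cl)
    tn <- sum(labels != cl & pred != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    auc <- if (all(is.finite(scores[, cl]))) {
      roc_auc(scores[, cl], labels == cl)
    } else NA_real_
    data.frame(class = cl,
               tp_rate = rec,
               fp_rate = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
               precision = prec, recall = rec,
               f_measure = if (is.na(prec) || is.na(rec) || prec + rec == 0)
                 NA_real_ else 2 * prec * rec / (prec + rec),
               roc_area = auc, n = tp + fn,
               stringsAsFactors = FALSE)
  }))
  w <- per_class$n / sum(per_class$n)
  avg <- data.frame(class = "weighted_avg",
                    t(colSums(per_class[, 2:7] * w, na.rm = FALSE)),
                    n = sum(per_class$n), stringsAsFactors = FALSE)
  names(avg) <- names(per_class)
  per_class <- rbind(per_class, avg)

  structure(list(accuracy = acc, kappa = kap, per_class = per_class,
                 confusion = confusion, folds = fold, k = k,
                 predicted = pred, scores = scores),
            class = "osa_cv_metrics")
}

#' @export
print.osa_cv_metrics <- function(x, ...) {
  cat(sprintf("<osa_cv_metrics> %d-fold stratified CV: accuracy %.1f%%, kappa %.4f\n",
              x$k, x$accuracy, x$kappa))
  print(transform(x$per_class,
                  tp_rate = round(tp_rate, 3), fp_rate = round(fp_rate, 3),
                  precision = round(precision, 3), recall = round(recall, 3),
                  f_measure = round(f_measure, 3),
                  roc_area = round(roc_area, 3)), row.names = FALSE)
  invisible(x)
}

#' Wrapper feature selection by best-first search
#'
#' Searches the space of feature subsets with greedy hill climbing plus
#' backtracking (best-first): subsets are expanded by single-feature
#' additions or removals, each candidate is scored by the cross-validated
#' accuracy of the base learner restricted to that subset, and when no
#' expansion of the current node improves, the search backtracks to the best
#' unexpanded subset. The search stops after `stall` consecutive expansions
#' without improvement of the global best. Ties are broken toward smaller
#' subsets, then feature order.
#'
#' @param table Data frame of features.
#' @param labels Class labels.
#' @param learner Base learner scored on each subset (default
#'   [tree_learner()]).
#' @param k Folds of the internal scoring CV (default 5).
#' @param stall Non-improving expansions allowed before stopping.
#' @param seed Integer seed shared by every internal CV so subset scores are
#'   comparable.
#' @return Character vector of selected feature names (at least one), with
#'   attribute `"score"` holding its CV accuracy.
#' @export
select_features <- function(table, labels, learner = tree_learner(), k = 5,
                            stall = 5, seed = 1) {
  stopifnot(is.data.frame(table), ncol(table) >= 2)
  feats <- names(table)
  key <- function(sub) paste(sort(sub), collapse = "|")
  score_subset <- function(sub) {
    if (!length(sub)) return(-Inf)
    m <- tryCatch(
      evaluate_cv(table[, sub, drop = FALSE], labels, learner, k = k,
                  seed = seed),
      error = function(e) stop(sprintf("base learner failed on {%s}: %s",
                                       paste(sub, collapse = ", "),
                                       conditionMessage(e)), call. = FALSE))
    m$accuracy
  }

  # seed the search with every single feature
  open <- lapply(feats, function(f) f)
  open_scores <- vapply(open, score_subset, 0)
  visited <- new.env(parent = emptyenv())
  for (s in open) assign(key(s), TRUE, visited)

  best_idx <- which.max(open_scores)
  best <- open[[best_idx]]
  best_score <- open_scores[best_idx]
  stalled <- 0L

  while (length(open) && stalled < stall) {
    i <- which.max(open_scores)
    node <- open[[i]]
    open <- open[-i]
    open_scores <- open_scores[-i]

    candidates <- c(lapply(setdiff(feats, node), function(f) c(node, f)),
                    if (length(node) > 1)
                      lapply(seq_along(node), function(j) node[-j]))
    improved <- FALSE
    for (sub in candidates) {
      kk <- key(sub)
      if (!is.null(visited[[kk]])) next
      assign(kk, TRUE, visited)
      sc <- score_subset(sub)
      open <- c(open, list(sub))
      open_scores <- c(open_scores, sc)
      better <- sc > best_score + 1e-9 ||
        (abs(sc - best_score) <= 1e-9 && length(sub) < length(best))
      if (better) {
        best <- sub
        best_score <- sc
        improved <- TRUE
      }
    }
    stalled <- if (improved) 0L else stalled + 1L
  }
  structure(sort(best), score = best_score)
}
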