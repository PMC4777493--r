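# Gain-ratio (C4.5-style) decision-tree induction.
#
# Numeric features split by a binary threshold placed midway between
# consecutive distinct sorted values; categorical features split multiway on
# their observed levels. At each node the split maximizing
# gain ratio = information gain / split information is chosen; growth stops
# on pure nodes, nodes smaller than 2 * min_leaf, or when no split has
# positive gain. Optional pessimistic error-based pruning (subtree
# replacement with the C4.5 upper confidence bound on the error rate,
# default confidence 0.25) follows induction.

entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

class_counts <- function(labels, levels) {
  tabulate(match(labels, levels), nbins = length(levels))
}

# all candidate splits of one feature with their gain/split-info/gain-ratio
feature_splits <- function(x, labels, levels, min_leaf) {
  n <- length(labels)
  H <- entropy_bits(class_counts(labels, levels))
  out <- list()
  if (is.numeric(x)) {
    ux <- sort(unique(x))
    if (length(ux) >= 2) {
      thr <- (ux[-1] + ux[-length(ux)]) / 2
      for (t in thr) {
        left <- x <= t
        nl <- sum(left)
        if (nl < min_leaf || n - nl < min_leaf) next
        Hs <- (nl * entropy_bits(class_counts(labels[left], levels)) +
                 (n - nl) * entropy_bits(class_counts(labels[!left], levels))) / n
        gain <- H - Hs
        si <- entropy_bits(c(nl, n - nl))
        out[[length(out) + 1]] <- data.frame(
          threshold = t, gain = gain, split_info = si,
          gain_ratio = if (si > 0) gain / si else NA_real_)
      }
    }
  } else {
    lev <- unique(as.character(x))
    if (length(lev) >= 2) {
      sizes <- vapply(lev, function(l) sum(x == l), 0)
      if (min(sizes) >= min_leaf) {
        Hs <- sum(vapply(lev, function(l) {
          sum(x == l) * entropy_bits(class_counts(labels[x == l], levels))
        }, 0)) / n
        gain <- H - Hs
        si <- entropy_bits(sizes)
        out[[length(out) + 1]] <- data.frame(
          threshold = NA_real_, gain = gain, split_info = si,
          gain_ratio = if (si > 0) gain / si else NA_real_)
      }
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Enumerate candidate splits and their gain ratios
#'
#' Scores every admissible split of every feature at the root of a table:
#' binary threshold splits at midpoints of consecutive distinct values for
#' numeric features, one multiway split for categorical features. Exposed so
#' the split criterion can be inspected and verified directly.
#'
#' @param table Data frame of features (numeric or categorical).
#' @param labels Class labels, one per row.
#' @param min_leaf Minimum samples per branch.
#' @return Data frame with columns `feature`, `threshold`, `gain`,
#'   `split_info`, `gain_ratio` (one row per candidate split), or an empty
#'   data frame when no split is admissible.
#' @export
gain_ratio_splits <- function(table, labels, min_leaf = 2) {
  stopifnot(is.data.frame(table), nrow(table) == length(labels))
  levels <- sort(unique(as.character(labels)))
  res <- lapply(names(table), function(f) {
    sp <- feature_splits(table[[f]], as.character(labels), levels, min_leaf)
    if (is.null(sp)) return(NULL)
    cbind(feature = f, sp, stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res)) {
    return(data.frame(feature = character(0), threshold = numeric(0),
                      gain = numeric(0), split_info = numeric(0),
                      gain_ratio = numeric(0)))
  }
  do.call(rbind, res)
}

# C4.5 upper confidence bound on the error rate of a leaf observing E
# errors in N cases (one-tailed normal approximation at the given CF)
pessimistic_error <- function(E, N, confidence) {
  if (N == 0) return(0)
  z <- stats::qnorm(1 - confidence)
  f <- E / N
  (f + z^2 / (2 * N) + z * sqrt(f / N - f^2 / N + z^2 / (4 * N^2))) /
    (1 + z^2 / N)
}

grow_node <- function(table, labels, levels, min_leaf) {
  counts <- class_counts(labels, levels)
  majority <- levels[which.max(counts)]
  leaf <- list(type = "leaf", class = majority, dist = counts,
               n = length(labels))
  if (sum(counts > 0) <= 1 || length(labels) < 2 * min_leaf) return(leaf)

  splits <- gain_ratio_splits(table, labels, min_leaf)
  splits <- splits[!is.na(splits$gain_ratio) & splits$gain > 1e-12, ,
                   drop = FALSE]
  if (!nrow(splits)) return(leaf)
  best <- splits[which.max(splits$gain_ratio), ]

  x <- table[[best$feature]]
  if (is.numeric(x)) {
    sides <- ifelse(x <= best$threshold, "<=", ">")
    branch_names <- c("<=", ">")
  } else {
    sides <- as.character(x)
    branch_names <- unique(sides)
  }
  children <- lapply(branch_names, function(b) {
    keep <- sides == b
    grow_node(table[keep, , drop = FALSE], labels[keep], levels, min_leaf)
  })
  names(children) <- branch_names
  list(type = "split", feature = best$feature,
       threshold = if (is.numeric(x)) best$threshold else NA_real_,
       children = children, class = majority, dist = counts,
       n = length(labels))
}

node_subtree_error <- function(node, confidence) {
  if (node$type == "leaf") {
    E <- node$n - max(node$dist)
    return(node$n * pessimistic_error(E, node$n, confidence))
  }
  sum(vapply(node$children, node_subtree_error, 0, confidence = confidence))
}

prune_node <- function(node, confidence) {
  if (node$type == "leaf") return(node)
  node$children <- lapply(node$children, prune_node, confidence = confidence)
  as_leaf_err <- node$n *
    pessimistic_error(node$n - max(node$dist), node$n, confidence)
  if (as_leaf_err <= node_subtree_error(node, confidence) + 0.1) {
    return(list(type = "leaf", class = node$class, dist = node$dist,
                n = node$n))
  }
  node
}

node_depth <- function(node) {
  if (node$type == "leaf") return(0L)
  1L + max(vapply(node$children, node_depth, 0L))
}

#' Induce a gain-ratio decision tree
#'
#' Top-down induction in the C4.5 style (the J48 reading of it): the split
#' maximizing gain ratio is chosen at each node, numeric features via binary
#' midpoint thresholds and categorical features via multiway splits;
#' induction stops on pure or small nodes; pessimistic error-based subtree
#' replacement prunes the result.
#'
#' @param table Data frame of features.
#' @param labels Class labels, one per row (>= 2 classes unless the data is
#'   single-class, which yields a single leaf).
#' @param min_leaf Minimum samples per branch (default 2).
#' @param confidence Pruning confidence (default 0.25); smaller prunes
#'   harder.
#' @param prune Apply pruning (default `TRUE`).
#' @return An object of class `osa_tree` with fields `root`, `classes`,
#'   `depth`, `n_train`.
#' @examples
#' tab <- data.frame(x = c(1, 2, 3, 10, 11, 12))
#' tr <- induce_tree(tab, c("a", "a", "a", "b", "b", "b"))
#' predict(tr, data.frame(x = c(2, 11)))
#' @export
induce_tree <- function(table, labels, min_leaf = 2, confidence = 0.25,
                        prune = TRUE) {
  stopifnot(is.data.frame(table))
  labels <- as.character(labels)
  if (nrow(table) == 0) stop("empty training data", call. = FALSE)
  if (nrow(table) != length(labels)) {
    stop("labels must match table rows", call. = FALSE)
  }
  levels <- sort(unique(labels))
  root <- grow_node(table, labels, levels, min_leaf)
  if (prune) root <- prune_node(root, confidence)
  structure(list(root = root, classes = levels, depth = node_depth(root),
                 n_train = nrow(table)),
            class = "osa_tree")
}

tree_route <- function(node, row) {
  while (node$type == "split") {
    x <- row[[node$feature]]
    branch <- if (!is.na(node$threshold)) {
      if (is.na(x)) return(node)               # fall back to node majority
      if (x <= node$threshold) "<=" else ">"
    } else {
      as.character(x)
    }
    child <- node$children[[branch]]
    if (is.null(child)) return(node)           # unseen level
    node <- child
  }
  node
}

#' Predict classes or class scores from a decision tree
#'
#' Class scores are the training class frequencies of the leaf a sample
#' lands in; they serve as the ranking scores for ROC analysis.
#'
#' @param object An `osa_tree`.
#' @param newdata Data frame of features.
#' @param type `"class"` for labels, `"prob"` for a matrix of per-class leaf
#'   frequencies.
#' @param ... Unused.
#' @return Character vector or numeric matrix with one row per sample.
#' @export
predict.osa_tree <- function(object, newdata, type = c("class", "prob"),
                             ...) {
  type <- match.arg(type)
  stopifnot(is.data.frame(newdata))
  nodes <- lapply(seq_len(nrow(newdata)),
                  function(i) tree_route(object$root, newdata[i, , drop = FALSE]))
  if (type == "class") {
    vapply(nodes, function(nd) object$classes[which.max(nd$dist)], "")
  } else {
    probs <- t(vapply(nodes, function(nd) nd$dist / sum(nd$dist),
                      numeric(length(object$classes))))
    colnames(probs) <- object$classes
    probs
  }
}

rules_of <- function(node, path) {
  if (node$type == "leaf") {
    dist <- paste(node$dist, collapse = "/")
    cond <- if (length(path)) paste(path, collapse = " AND ") else "TRUE"
    return(sprintf("IF %s THEN %s (%s)", cond, node$class, dist))
  }
  unlist(lapply(names(node$children), function(b) {
    cond <- if (!is.na(node$threshold)) {
      sprintf("%s %s %.4g", node$feature, b, node$threshold)
    } else {
      sprintf("%s = %s", node$feature, b)
    }
    rules_of(node$children[[b]], c(path, cond))
  }))
}

#' Render a decision tree as if-then rules
#'
#' @param tree An `osa_tree`.
#' @return Character vector, one rule per leaf, with the training class
#'   distribution of each leaf appended.
#' @export
tree_rules <- function(tree) {
  stopifnot(inherits(tree, "osa_tree"))
  rules_of(tree$root, character(0))
}

#' @export
print.osa_tree <- function(x, ...) {
  cat(sprintf("<osa_tree> depth %d, %d training samples, classes: %s\n",
              x$depth, x$n_train, paste(x$classes, collapse = ", ")))
  writeLines(paste(" ", tree_rules(x)))
  invisible(x)
}
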