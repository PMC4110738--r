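#' Build a labelled edge-weight dataset from an ensemble report
#'
#' Every network contributes one row; every randomized (non-regulatory)
#' edge weight is a numeric attribute named by its edge identifier, and the
#' class column is `P` (positive response) or `N` (negative).  All requested
#' positives are taken in network order (so they are identical across
#' seeds); the negatives are a seeded uniform random sample.
#'
#' @param report an `ensemble_report`.
#' @param n_pos number of positive networks (defaults to all of them).
#' @param n_neg number of negative networks to sample.
#' @param seed sampling seed.
#' @return data frame with attribute columns plus a `class` factor;
#'   attributes `n_pos`, `n_neg`, `seed` record the composition.
#' @export
make_dataset <- function(report, n_pos = NULL, n_neg, seed) {
  pos <- positives(report); neg <- negatives(report)
  if (is.null(n_pos)) n_pos <- length(pos)
  if (n_pos > length(pos))
    stop(sprintf("requested %d positives but only %d exist", n_pos,
                 length(pos)))
  if (n_neg > length(neg))
    stop(sprintf("requested %d negatives but only %d exist", n_neg,
                 length(neg)))
  take_pos <- pos[seq_len(n_pos)]
  take_neg <- with_seed(seed, sample(neg, n_neg))
  ids <- c(take_pos, take_neg)
  df <- as.data.frame(report$weights[ids, , drop = FALSE])
  df$class <- factor(rep(c("P", "N"), c(n_pos, n_neg)), levels = c("P", "N"))
  attr(df, "n_pos") <- n_pos; attr(df, "n_neg") <- n_neg
  attr(df, "seed") <- seed
  df
}

#' Three-class dataset from a split-range report
#'
#' All networks of an `exp3` report, labelled by their `CS`/`CD`/`CN` class.
#'
#' @param report the `ensemble_report` of [experiment3()].
#' @return data frame with attribute columns plus a `class` factor.
#' @export
make_multiclass_dataset <- function(report) {
  if (is.null(report$profiles$class))
    stop("report carries no CS/CD/CN classes; run experiment3() first")
  df <- as.data.frame(
    report$weights[report$profiles$network_id, , drop = FALSE])
  df$class <- factor(report$profiles$class, levels = c("CS", "CD", "CN"))
  df
}

#' Decision-tree parameters
#'
#' @param min_leaf minimum number of rows in a leaf.
#' @param cf pruning confidence (smaller prunes harder); `NA` disables
#'   pruning.
#' @param max_depth maximum tree depth (root = 1).
#' @return list of class `tree_params`.
#' @export
tree_params <- function(min_leaf = 2L, cf = 0.25, max_depth = Inf) {
  structure(list(min_leaf = as.integer(min_leaf), cf = cf,
                 max_depth = max_depth), class = "tree_params")
}

# best binary split (x <= thr) of one numeric attribute; NULL if none.
# Ties keep the lowest threshold; the scan itself is compiled.
best_split_attr <- function(x, y, min_leaf) {
  s <- cpp_best_split(as.double(x), as.integer(y), nlevels(y),
                      as.integer(min_leaf))
  if (s[1] == 0) return(NULL)
  list(threshold = s[2], gain = s[3], ratio = s[4])
}

# Clopper-Pearson-style upper confidence limit on the error rate, the
# pessimistic estimate used for error-based pruning
pessimistic_errors <- function(e, n, cf) {
  if (n == 0L) return(0)
  n * stats::qbeta(1 - cf, e + 1, pmax(n - e, 1e-9))
}

# index-based recursion over a numeric attribute matrix X and class factor y
grow_tree <- function(X, y, idx, attrs, params, depth) {
  yi <- y[idx]
  counts <- tabulate(yi, nbins = nlevels(y))
  maj <- levels(y)[which.max(counts)]
  leaf <- list(type = "leaf", class = maj, counts = counts,
               n = length(idx))
  if (length(idx) < 2L * params$min_leaf || sum(counts > 0L) == 1L ||
      depth >= params$max_depth)
    return(leaf)
  best <- NULL
  for (a in attrs) {   # attrs in name order: ties favour the earlier name
    s <- best_split_attr(X[idx, a], yi, params$min_leaf)
    if (!is.null(s) &&
        (is.null(best) || s$ratio > best$ratio + 1e-12))
      best <- c(s, list(attribute = a))
  }
  if (is.null(best)) return(leaf)
  go_left <- X[idx, best$attribute] <= best$threshold
  list(type = "node", attribute = best$attribute,
       threshold = best$threshold, counts = counts,
       class = maj, n = length(idx),
       left = grow_tree(X, y, idx[go_left], attrs, params, depth + 1L),
       right = grow_tree(X, y, idx[!go_left], attrs, params, depth + 1L))
}

prune_tree <- function(node, cf) {
  if (node$type == "leaf") {
    node$est_errors <- pessimistic_errors(node$n - max(node$counts),
                                          node$n, cf)
    return(node)
  }
  node$left <- prune_tree(node$left, cf)
  node$right <- prune_tree(node$right, cf)
  subtree_err <- node$left$est_errors + node$right$est_errors
  leaf_err <- pessimistic_errors(node$n - max(node$counts), node$n, cf)
  if (leaf_err <= subtree_err + 0.1) {
    return(list(type = "leaf", class = node$class, counts = node$counts,
                n = node$n, est_errors = leaf_err))
  }
  node$est_errors <- subtree_err
  node
}

#' Induce a gain-ratio decision tree
#'
#' A C4.5-style learner: binary splits on numeric attribute thresholds
#' chosen by gain ratio (ties broken by attribute name order, then lower
#' threshold), a minimum-leaf-size constraint, and pessimistic error-based
#' subtree pruning.  Deterministic for fixed input and parameters.
#'
#' @param df data frame of numeric attributes plus a `class` factor column.
#' @param params a [tree_params()].
#' @return object of class `c45_tree`.
#' @export
induce_tree <- function(df, params = tree_params()) {
  stopifnot("class" %in% names(df), is.factor(df$class))
  attrs <- sort(setdiff(names(df), "class"))
  X <- as.matrix(df[attrs])
  storage.mode(X) <- "double"
  root <- grow_tree(X, df$class, seq_len(nrow(df)), attrs, params, 1L)
  if (!is.na(params$cf)) root <- prune_tree(root, params$cf)
  structure(list(root = root, classes = levels(df$class), attrs = attrs,
                 params = params), class = "c45_tree")
}

#' @export
predict.c45_tree <- function(object, newdata, ...) {
  X <- as.matrix(newdata[object$attrs])
  storage.mode(X) <- "double"
  out <- character(nrow(X))
  for (i in seq_len(nrow(X))) {
    node <- object$root
    while (node$type == "node") {
      node <- if (X[i, node$attribute] <= node$threshold) node$left
              else node$right
    }
    out[i] <- node$class
  }
  factor(out, levels = object$classes)
}

print_node <- function(node, indent) {
  pad <- strrep("  ", indent)
  if (node$type == "leaf") {
    cat(sprintf("%s-> %s (%s)\n", pad, node$class,
                paste(node$counts, collapse = "/")))
  } else {
    cat(sprintf("%s%s <= %s:\n", pad, node$attribute, node$threshold))
    print_node(node$left, indent + 1L)
    cat(sprintf("%s%s >  %s:\n", pad, node$attribute, node$threshold))
    print_node(node$right, indent + 1L)
  }
}

#' @export
print.c45_tree <- function(x, ...) {
  print_node(x$root, 0L)
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' Splits the rows into `k` stratified folds (seeded), trains one tree per
#' fold on the remaining rows, and pools the held-out predictions.
#' Accuracy is reported per class (the class's recall), matching how
#' positive- and negative-network accuracies are read separately.
#'
#' @param df dataset as for [induce_tree()].
#' @param k number of folds.
#' @param seed fold-assignment seed.
#' @param params a [tree_params()].
#' @return list of class `crossval_result`: `class_accuracy` (named
#'   percentages), `confusion` (true x predicted), `fold_trees` (list of
#'   `k` trees), `k`, `seed`.
#' @export
crossval <- function(df, k = 10L, seed = 1L, params = tree_params()) {
  y <- df$class
  if (any(table(y) < k))
    stop("every class needs at least k = ", k, " rows")
  fold <- integer(nrow(df))
  with_seed(seed, for (l in levels(y)) {
    idx <- which(y == l)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  })
  pred <- factor(rep(NA_character_, nrow(df)), levels = levels(y))
  trees <- vector("list", k)
  for (f in seq_len(k)) {
    train <- df[fold != f, , drop = FALSE]
    test <- df[fold == f, , drop = FALSE]
    trees[[f]] <- induce_tree(train, params)
    pred[fold == f] <- predict(trees[[f]], test)
  }
  confusion <- table(true = y, predicted = pred)
  acc <- 100 * diag(confusion) / rowSums(confusion)
  structure(list(class_accuracy = acc, confusion = confusion,
                 fold_trees = trees, k = k, seed = seed),
            class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  cat(sprintf("<crossval_result> %d folds; per-class accuracy: %s\n", x$k,
              paste(sprintf("%s %.2f%%", names(x$class_accuracy),
                            x$class_accuracy), collapse = ", ")))
  invisible(x)
}

collect_levels <- function(node, depth, max_level, acc) {
  if (node$type == "leaf" || depth > max_level) return(acc)
  acc[[length(acc) + 1L]] <- data.frame(level = depth,
                                        attribute = node$attribute,
                                        threshold = node$threshold,
                                        stringsAsFactors = FALSE)
  acc <- collect_levels(node$left, depth + 1L, max_level, acc)
  collect_levels(node$right, depth + 1L, max_level, acc)
}

#' Commonly tested attributes per tree level
#'
#' Across the fold trees of one cross-validation run, counts in how many
#' trees each attribute is tested at each level (root = level 1; an
#' attribute tested by several nodes of one tree at the same level counts
#' once) and reports, for attributes tested in at least `min_count` trees,
#' the median of their split thresholds at that level.
#'
#' @param fold_trees list of `c45_tree` objects (e.g.
#'   `crossval(...)$fold_trees`).
#' @param max_level deepest level reported.
#' @param min_count minimum number of trees (out of the folds) in which an
#'   attribute must be tested at a level to be reported.
#' @return data frame of class `tree_summary` with columns `level`,
#'   `attribute`, `count`, `median_threshold`, ordered by level, then
#'   descending count, then attribute name.
#' @export
summarize_levels <- function(fold_trees, max_level = 4L, min_count = 6L) {
  per_tree <- lapply(fold_trees, function(tr) {
    d <- collect_levels(tr$root, 1L, max_level, list())
    d <- if (length(d) == 0L)
      data.frame(level = integer(), attribute = character(),
                 threshold = numeric()) else do.call(rbind, d)
    # one vote per tree per (level, attribute); threshold = within-tree median
    if (nrow(d) > 0L)
      d <- do.call(rbind, lapply(
        split(d, paste(d$level, d$attribute)),
        function(g) data.frame(level = g$level[1L],
                               attribute = g$attribute[1L],
                               threshold = median(g$threshold))))
    d
  })
  all <- do.call(rbind, per_tree)
  if (is.null(all) || nrow(all) == 0L) {
    out <- data.frame(level = integer(), attribute = character(),
                      count = integer(), median_threshold = numeric())
    class(out) <- c("tree_summary", "data.frame")
    return(out)
  }
  agg <- do.call(rbind, lapply(
    split(all, paste(sprintf("%02d", all$level), all$attribute)),
    function(g) data.frame(level = g$level[1L], attribute = g$attribute[1L],
                           count = nrow(g),
                           median_threshold = median(g$threshold))))
  agg <- agg[agg$count >= min_count, , drop = FALSE]
  agg <- agg[order(agg$level, -agg$count, agg$attribute), , drop = FALSE]
  rownames(agg) <- NULL
  class(agg) <- c("tree_summary", "data.frame")
  agg
}

#' Export a dataset as CSV or ARFF
#'
#' @param df dataset from [make_dataset()] or [make_multiclass_dataset()].
#' @param path output file.
#' @param format `"csv"` or `"arff"` (class as a nominal attribute).
#' @param relation ARFF relation name.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(df, path, format = c("csv", "arff"),
                          relation = "pheronet") {
  format <- match.arg(format)
  if (format == "csv") {
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    attrs <- setdiff(names(df), "class")
    lines <- c(sprintf("@relation %s", relation),
               sprintf("@attribute %s numeric", attrs),
               sprintf("@attribute class {%s}",
                       paste(levels(df$class), collapse = ",")),
               "@data",
               vapply(seq_len(nrow(df)), function(i)
                 paste(c(as.character(unlist(df[i, attrs])),
                         as.character(df$class[i])), collapse = ","), ""))
    writeLines(lines, path)
  }
  invisible(path)
}
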