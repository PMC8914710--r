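#' Gini impurity of a node
#'
#' `G = 1 - sum(p_c^2)` where `p_c` is the (weighted) fraction of class `c`
#' at the node. `G = 0` for a pure node and at most `1 - 1/n` for `n`
#' classes.
#'
#' @param counts Non-negative per-class (weighted) counts.
#' @return The impurity value.
#' @export
gini_impurity <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("gini error: negative class counts")
  tot <- sum(counts)
  if (tot <= 0) stop("gini error: empty node")
  1 - sum((counts / tot)^2)
}

#' Balanced class weights
#'
#' `w_c = N / (n_classes * N_c)`, so every class contributes equal total
#' weight; this counteracts the dominance of no-action samples during tree
#' training.
#'
#' @param labels Class labels (character or factor).
#' @return Named numeric vector of per-class weights.
#' @export
balanced_class_weights <- function(labels) {
  tab <- table(as.character(labels))
  if (any(tab == 0)) {
    warning("classes with zero samples excluded from weighting")
    tab <- tab[tab > 0]
  }
  if (length(tab) == 1L)
    warning("degenerate training set: a single class is present")
  w <- sum(tab) / (length(tab) * as.numeric(tab))
  names(w) <- names(tab)
  w
}

#' Pre-pruning hyperparameters for the decision tree
#'
#' @param max_depth Maximum tree depth (root at depth 0).
#' @param min_samples_leaf Minimum raw sample count in each leaf.
#' @param min_samples_split Minimum raw sample count for a node to be split;
#'   defaults to `2 * min_samples_leaf`.
#' @return A `tree_hyperparams` list.
#' @export
tree_hyperparams <- function(max_depth = 10L, min_samples_leaf = 5L,
                             min_samples_split = 2L * min_samples_leaf) {
  max_depth <- as.integer(max_depth)
  min_samples_leaf <- as.integer(min_samples_leaf)
  min_samples_split <- as.integer(min_samples_split)
  if (max_depth < 1L) stop("hyperparameter error: max_depth must be >= 1")
  if (min_samples_leaf < 1L || min_samples_split < 2L * min_samples_leaf)
    stop("hyperparameter error: need min_samples_split >= 2*min_samples_leaf >= 2")
  structure(list(max_depth = max_depth, min_samples_leaf = min_samples_leaf,
                 min_samples_split = min_samples_split),
            class = "tree_hyperparams")
}

as_feature_input <- function(x) {
  if (inherits(x, "feature_track")) feature_matrix(x)
  else as.matrix(x)
}

#' Best axis-aligned split of a sample set
#'
#' Scans all features and all midpoints between consecutive distinct sorted
#' values, minimising the weight-averaged Gini impurity of the two children.
#' Ties go to the lowest feature index, then the smallest threshold. Returns
#' `NULL` when no candidate reduces the parent impurity (e.g. a pure node or
#' all-identical features).
#'
#' @param x Feature matrix (or `feature_track`).
#' @param y Class labels.
#' @param sample_weights Optional per-sample weights (default 1).
#' @param min_samples_leaf Minimum raw count in each child.
#' @return `list(feature_index, threshold)` or `NULL`.
#' @export
best_split <- function(x, y, sample_weights = NULL, min_samples_leaf = 1L) {
  X <- as_feature_input(x)
  y <- factor(y)
  if (is.null(sample_weights)) sample_weights <- rep(1, nrow(X))
  res <- cpp_best_split(X, as.integer(y) - 1L, as.numeric(sample_weights),
                        seq_len(nrow(X)) - 1L, nlevels(y),
                        as.integer(min_samples_leaf))
  if (res$feature == 0L) return(NULL)
  list(feature_index = res$feature, threshold = res$threshold)
}

#' Fit a CART decision tree on frequency-domain features
#'
#' Greedy recursive binary partitioning with the Gini impurity criterion.
#' Growth stops when the depth limit is reached, a node is smaller than
#' `min_samples_split`, no split keeps `min_samples_leaf` samples in both
#' children, or the node is pure. Leaves predict the class with the largest
#' weighted mass. Samples equal to a split threshold go left.
#'
#' @param x Feature matrix or `feature_track`.
#' @param y Class labels (one per row of `x`).
#' @param hyperparams A [tree_hyperparams()].
#' @param class_weights Named per-class weights; defaults to
#'   [balanced_class_weights()] of `y`.
#' @return An `emg_tree` model.
#' @export
fit_tree <- function(x, y, hyperparams = tree_hyperparams(),
                     class_weights = NULL) {
  X <- as_feature_input(x)
  y <- factor(as.character(y))
  stopifnot(nrow(X) == length(y))
  if (is.null(class_weights)) class_weights <- balanced_class_weights(y)
  classes <- levels(y)
  if (!all(classes %in% names(class_weights)))
    stop("class_weights must cover every class present in y")
  w <- as.numeric(class_weights[as.character(y)])
  yi <- as.integer(y) - 1L
  k <- length(classes)
  hp <- hyperparams
  if (k == 1L) warning("single-class input: fitting a depth-0 tree")

  make_leaf <- function(idx) {
    mass <- vapply(seq_len(k) - 1L,
                   function(c) sum(w[idx + 1L][yi[idx + 1L] == c]), 0)
    names(mass) <- classes
    list(leaf = TRUE, mass = mass, label = classes[which.max(mass)])
  }
  grow <- function(idx, depth) {
    n <- length(idx)
    if (depth >= hp$max_depth || n < hp$min_samples_split ||
        length(unique(yi[idx + 1L])) <= 1L)
      return(make_leaf(idx))
    res <- cpp_best_split(X, yi, w, idx, k, hp$min_samples_leaf)
    if (res$feature == 0L) return(make_leaf(idx))
    goleft <- X[idx + 1L, res$feature] <= res$threshold
    list(leaf = FALSE, feature = res$feature, threshold = res$threshold,
         left = grow(idx[goleft], depth + 1L),
         right = grow(idx[!goleft], depth + 1L))
  }
  root <- grow(seq_len(nrow(X)) - 1L, 0L)
  structure(list(root = root, classes = classes,
                 class_weights = class_weights[classes], hyperparams = hp,
                 feature_names = colnames(X)),
            class = "emg_tree")
}

tree_depth <- function(node) {
  if (node$leaf) 0L else 1L + max(tree_depth(node$left), tree_depth(node$right))
}

#' @export
print.emg_tree <- function(x, ...) {
  cat(sprintf("<emg_tree> %d classes (%s), depth %d\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              tree_depth(x$root)))
  invisible(x)
}

#' Predict classes from a fitted decision tree
#'
#' @param object An `emg_tree`.
#' @param newdata Feature matrix or `feature_track`.
#' @param ... Unused.
#' @return Character vector of predicted class labels.
#' @export
predict.emg_tree <- function(object, newdata, ...) {
  X <- as_feature_input(newdata)
  n <- nrow(X)
  out <- character(n)
  descend <- function(node, rows) {
    if (length(rows) == 0L) return(invisible())
    if (node$leaf) {
      out[rows] <<- node$label
      return(invisible())
    }
    goleft <- X[rows, node$feature] <= node$threshold
    descend(node$left, rows[goleft])
    descend(node$right, rows[!goleft])
  }
  descend(object$root, seq_len(n))
  out
}

#' Default pre-pruning hyperparameter grid
#'
#' Depth in `{2, 3, 4, 6, 8, 10}` crossed with minimum leaf size in
#' `{5, 20, 50, 100}`; the split threshold is tied to `2 * min_samples_leaf`.
#'
#' @return A list of [tree_hyperparams()].
#' @export
default_tree_grid <- function() {
  g <- expand.grid(max_depth = c(2L, 3L, 4L, 6L, 8L, 10L),
                   min_samples_leaf = c(5L, 20L, 50L, 100L))
  lapply(seq_len(nrow(g)), function(i)
    tree_hyperparams(g$max_depth[i], g$min_samples_leaf[i]))
}

#' Grid search over pre-pruning hyperparameters
#'
#' Evaluates every hyperparameter combination by window-stratified k-fold
#' cross-validation ([crossvalidate()]) and returns the combination with the
#' highest mean window-level accuracy. Ties are broken toward the simplest
#' model: smaller `max_depth`, then larger `min_samples_leaf`.
#'
#' @param track Labelled `feature_track`.
#' @param windows Ground-truth action windows (see [build_action_windows()]).
#' @param grid List of [tree_hyperparams()]; defaults to
#'   [default_tree_grid()].
#' @param k Number of folds.
#' @param seed Integer seed controlling the shuffled fold assignment.
#' @param no_action Label used for data outside action windows.
#' @param unknown_windows Optional unknown-action windows (ground truth
#'   no-action); when given, each candidate is scored on the pooled accuracy
#'   so the selection accounts for robustness to unknown actions, the way the
#'   per-participant tuning considered all classes.
#' @param movement_windows Optional annotated movement intervals used for
#'   training labels (see [crossvalidate()]).
#' @return The selected `tree_hyperparams`, with the grid accuracies attached
#'   as attribute `"accuracy"`.
#' @export
grid_search_prepruning <- function(track, windows, grid = default_tree_grid(),
                                   k = 10L, seed = 1L,
                                   no_action = "no_action",
                                   unknown_windows = NULL,
                                   movement_windows = NULL) {
  if (length(grid) == 0L) stop("grid must be non-empty")
  acc <- vapply(grid, function(hp) {
    cv <- crossvalidate(track, windows, method = "tree", k = k, seed = seed,
                        hyperparams = hp, no_action = no_action,
                        unknown_windows = unknown_windows,
                        movement_windows = movement_windows)
    if (is.null(cv$unknown)) cv$accuracy else cv$unknown$accuracy
  }, 0)
  depth <- vapply(grid, `[[`, 0L, "max_depth")
  leaf <- vapply(grid, `[[`, 0L, "min_samples_leaf")
  best <- order(-acc, depth, -leaf)[1L]
  out <- grid[[best]]
  attr(out, "accuracy") <- acc
  out
}
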