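# Exhaustive split-search oracle: all features, all midpoints between
# consecutive distinct sorted values, weighted Gini objective; ties to the
# lowest feature index then smallest threshold.
oracle_split <- function(X, y, w, min_leaf = 1L) {
  y <- as.character(y)
  classes <- sort(unique(y))
  gini <- function(wts) {
    tot <- sum(wts)
    if (tot <= 0) return(0)
    1 - sum((wts / tot)^2)
  }
  mass <- function(rows) vapply(classes, function(c)
    sum(w[rows][y[rows] == c]), 0)
  parent <- gini(mass(seq_len(nrow(X))))
  best <- NULL; best_score <- parent - 1e-12
  for (f in seq_len(ncol(X))) {
    vs <- sort(unique(X[, f]))
    if (length(vs) < 2) next
    for (thr in (vs[-1] + vs[-length(vs)]) / 2) {
      l <- which(X[, f] <= thr); r <- which(X[, f] > thr)
      if (length(l) < min_leaf || length(r) < min_leaf) next
      wl <- mass(l); wr <- mass(r)
      sc <- (sum(wl) * gini(wl) + sum(wr) * gini(wr)) / (sum(wl) + sum(wr))
      if (sc < best_score) {
        best_score <- sc
        best <- list(feature_index = f, threshold = thr)
      }
    }
  }
  best
}

test_that("Gini impurity matches its pairwise-disagreement definition", {
  expect_equal(gini_impurity(c(1, 0)), 0)
  expect_equal(gini_impurity(c(5, 5)), 0.5)
  expect_equal(gini_impurity(c(7, 2, 1)), 0.46)
  expect_error(gini_impurity(c(0, 0)), "empty")
  set.seed(21)
  for (i in 1:25) {
    counts <- rpois(sample(2:6, 1), 5) + 1
    p <- counts / sum(counts)
    # brute force: probability two independent draws fall in different classes
    brute <- sum(outer(p, p)) - sum(p^2)
    expect_equal(gini_impurity(counts), brute, tolerance = 1e-12)
  }
})

test_that("balanced class weights equalise class mass", {
  w <- balanced_class_weights(rep(c("A", "B"), c(90, 10)))
  expect_equal(unname(w["A"]), 100 / (2 * 90))
  expect_equal(unname(w["B"]), 100 / (2 * 10))
  expect_equal(90 * w[["A"]], 10 * w[["B"]])
  expect_equal(unname(balanced_class_weights(rep(c("x", "y"), 5))),
               c(1, 1))
  expect_warning(w1 <- balanced_class_weights(rep("only", 4)), "single class")
  expect_equal(unname(w1), 1)
})

test_that("best_split agrees with exhaustive enumeration", {
  X1 <- matrix(1:4, 4, 1)
  s <- best_split(X1, c("A", "A", "B", "B"))
  expect_equal(s$feature_index, 1L)
  expect_equal(s$threshold, 2.5)
  expect_null(best_split(X1, rep("A", 4)))
  set.seed(22)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    p <- sample(2:4, 1)
    X <- matrix(round(rnorm(n * p), 1), n, p)  # rounded -> ties occur
    y <- sample(letters[1:3], n, replace = TRUE)
    w <- sample(c(1, 2.5), n, replace = TRUE)
    got <- best_split(X, y, sample_weights = w, min_samples_leaf = 2L)
    want <- oracle_split(X, y, w, min_leaf = 2L)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("a perfectly separating feature is chosen", {
  set.seed(23)
  X <- cbind(rnorm(40), rep(c(0, 1), each = 20))
  y <- rep(c("u", "v"), each = 20)
  s <- best_split(X, y)
  expect_equal(s$feature_index, 2L)
  expect_equal(s$threshold, 0.5)
})

test_that("tree fitting is consistent on separable data and bounded on XOR", {
  set.seed(24)
  X <- cbind(c(rnorm(60), rnorm(60) + 8), rnorm(120))
  y <- rep(c("a", "b"), each = 60)
  m <- fit_tree(X, y)
  expect_equal(mean(predict(m, X) == y), 1)
  # depth-1 stump on XOR cannot beat 0.75 training accuracy
  Xx <- cbind(rep(c(0, 1, 0, 1), 30), rep(c(0, 0, 1, 1), 30))
  yx <- ifelse(xor(Xx[, 1] > 0.5, Xx[, 2] > 0.5), "p", "q")
  m1 <- fit_tree(Xx, yx, tree_hyperparams(1, 1, 2))
  expect_lte(mean(predict(m1, Xx) == yx), 0.75)
  # unlimited depth on distinct vectors: zero training error
  set.seed(25)
  Xd <- matrix(rnorm(200), 50, 4)
  yd <- sample(c("a", "b", "c"), 50, replace = TRUE)
  md <- fit_tree(Xd, yd, tree_hyperparams(50, 1, 2))
  expect_equal(mean(predict(md, Xd) == yd), 1)
})

test_that("integer class weights equal sample duplication", {
  set.seed(26)
  X <- matrix(rnorm(200), 50, 4)
  y <- rep(c("a", "b"), c(35, 15))
  hp <- tree_hyperparams(20, 1, 2)
  m_w <- fit_tree(X, y, hp, class_weights = c(a = 1, b = 3))
  Xd <- rbind(X, X[y == "b", ], X[y == "b", ])
  yd <- c(y, rep("b", 30))
  m_d <- fit_tree(Xd, yd, hp, class_weights = c(a = 1, b = 1))
  strip_mass <- function(node) {
    if (node$leaf) return(list(leaf = TRUE, label = node$label))
    list(leaf = FALSE, feature = node$feature, threshold = node$threshold,
         left = strip_mass(node$left), right = strip_mass(node$right))
  }
  expect_identical(strip_mass(m_w$root), strip_mass(m_d$root))
})

test_that("predictions are piecewise constant between thresholds", {
  set.seed(27)
  X <- matrix(rnorm(400), 100, 4)
  y <- ifelse(X[, 2] > 0.2, "hi", "lo")
  m <- fit_tree(X, y, tree_hyperparams(4, 5))
  thresholds <- c()
  walk <- function(n) {
    if (!n$leaf) {
      thresholds <<- c(thresholds, n$threshold)
      walk(n$left); walk(n$right)
    }
  }
  walk(m$root)
  v <- X[7, , drop = FALSE]
  base <- predict(m, v)
  for (j in 1:4) {
    v2 <- v
    gap <- min(abs(thresholds - v[j]))
    v2[j] <- v[j] + 0.4 * gap  # stays on the same side of every threshold
    expect_identical(predict(m, v2), base)
  }
})

test_that("single-class training yields a depth-0 tree with a warning", {
  X <- matrix(rnorm(40), 10, 4)
  msgs <- capture_warnings(m <- fit_tree(X, rep("z", 10)))
  expect_true(any(grepl("single-class", msgs)))
  expect_true(m$root$leaf)
  expect_equal(unique(predict(m, X)), "z")
})

test_that("training predictions agree with an independent CART fit", {
  skip_if_not_installed("rpart")
  set.seed(28)
  n <- 400
  X <- matrix(rnorm(4 * n), n, 4)
  y <- factor(ifelse(X[, 1] + rnorm(n, sd = 0.4) > 0, "a", "b"))
  ours <- fit_tree(X, y, tree_hyperparams(3, 20),
                   class_weights = c(a = 1, b = 1))
  df <- data.frame(y = y, X)
  rp <- rpart::rpart(y ~ ., df, method = "class",
                     control = rpart::rpart.control(maxdepth = 3,
                                                    minbucket = 20,
                                                    minsplit = 40, cp = 0,
                                                    xval = 0))
  acc_ours <- mean(predict(ours, X) == y)
  acc_rp <- mean(predict(rp, df, type = "class") == y)
  expect_equal(acc_ours, acc_rp, tolerance = 0.03)
})

test_that("grid search honours its tie-breaking rules", {
  cls <- list(A = c(30, 10, 150, 150), B = c(90, 30, 300, 300))
  ds <- block_dataset(cls, reps = 6, jitter = 0.02)
  one <- list(tree_hyperparams(4, 20))
  expect_identical(
    grid_search_prepruning(ds$track, ds$windows, grid = one, k = 3,
                           seed = 5, movement_windows = ds$movements),
    structure(one[[1]],
              accuracy = attr(grid_search_prepruning(
                ds$track, ds$windows, grid = one, k = 3, seed = 5,
                movement_windows = ds$movements), "accuracy")))
  # easy, separable data: every candidate ties; simplest model returned
  grid <- list(tree_hyperparams(6, 5), tree_hyperparams(2, 5),
               tree_hyperparams(2, 20))
  hp <- grid_search_prepruning(ds$track, ds$windows, grid = grid, k = 3,
                               seed = 5, movement_windows = ds$movements)
  acc <- attr(hp, "accuracy")
  expect_true(all(acc == acc[1]))  # ties indeed
  expect_equal(hp$max_depth, 2L)
  expect_equal(hp$min_samples_leaf, 20L)  # larger leaf preferred at ties
})
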