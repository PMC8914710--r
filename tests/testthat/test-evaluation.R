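test_that("action windows span twice the nominal duration", {
  ev <- emg_events(c(10, 30), c("SR", "OR"), c(1, 2))
  w <- build_action_windows(ev, span = c(0, 50))
  sr <- w[w$label == "SR", ]
  expect_equal(c(sr$start, sr$end), c(10, 12))
  or <- w[w$label == "OR", ]
  expect_equal(or$end - or$start, 4)
  # complement partitioned into no-action windows near the mean length
  na <- w[w$label == "no_action", ]
  expect_gt(nrow(na), 0)
  expect_equal(sum(w$end - w$start), 50, tolerance = 1e-9)
  # empty log: the whole span is no-action
  w0 <- build_action_windows(emg_events(numeric(0), character(0), numeric(0)),
                             span = c(0, 20))
  expect_true(all(w0$label == "no_action"))
  expect_equal(sum(w0$end - w0$start), 20)
  # overlapping action windows violate the protocol
  ev2 <- emg_events(c(10, 11), c("SR", "SF"), c(1, 1))
  expect_error(build_action_windows(ev2, span = c(0, 50)), "overlapping")
})

test_that("window scoring follows the any-wrong-action rule", {
  w <- data.frame(start = 10, end = 12, label = "SR",
                  stringsAsFactors = FALSE)
  sc <- score_window_predictions(c("no_action", "SR", "no_action"),
                                 c(10.2, 10.9, 11.5), w)
  expect_equal(sc$windows$outcome, "SR")
  expect_equal(sc$accuracy, 1)
  # a single wrong action anywhere poisons the window
  sc2 <- score_window_predictions(c("SR", "SF", "SR", "SR"),
                                  c(10.2, 10.5, 10.9, 11.5), w)
  expect_equal(sc2$windows$outcome, "SF")
  expect_equal(sc2$accuracy, 0)
  # earliest wrong action is charged, regardless of input order
  sc3 <- score_window_predictions(c("SB", "SF", "SR"), c(11, 10.4, 10.6), w)
  expect_equal(sc3$windows$outcome, "SF")
  # no detection at all counts as no-action
  sc4 <- score_window_predictions(c("no_action", "no_action"), c(10.3, 11), w)
  expect_equal(sc4$windows$outcome, "no_action")
  # no-action window: any action prediction is a false positive
  wn <- data.frame(start = 0, end = 2, label = "no_action")
  sc5 <- score_window_predictions(c("no_action", "SR"), c(0.5, 1.5), wn)
  expect_equal(sc5$windows$outcome, "SR")
  sc6 <- score_window_predictions(c("no_action", "no_action"), c(0.5, 1.5),
                                  wn)
  expect_equal(sc6$accuracy, 1)
  # windows without predictions are excluded with a warning
  w2 <- rbind(w, data.frame(start = 40, end = 42, label = "SR"))
  expect_warning(sc7 <- score_window_predictions("SR", 10.5, w2), "excluded")
  expect_equal(sum(sc7$confusion), 1)
})

test_that("confusion row sums equal the window counts per class", {
  cls <- list(A = c(30, 10, 150, 150), B = c(90, 30, 300, 300))
  ds <- block_dataset(cls, reps = 5, jitter = 0.05)
  lab <- label_feature_vectors(ds$track, ds$movements)
  lab[is.na(lab)] <- "no_action"
  sc <- score_window_predictions(lab, track_midpoints(ds$track), ds$windows)
  expect_equal(unname(rowSums(sc$confusion)),
               unname(as.vector(table(factor(ds$windows$label,
                                             rownames(sc$confusion))))))
})

test_that("stratified folds spread classes evenly and deterministically", {
  w <- data.frame(start = seq(0, 39), end = seq(1, 40),
                  label = rep(c("SR", "SF"), each = 20))
  f <- stratified_window_folds(w, 10, seed = 3)
  expect_equal(attr(f, "k"), 10L)
  tab <- table(w$label, f)
  expect_true(all(tab == 2))
  expect_identical(stratified_window_folds(w, 10, seed = 3), f)
  expect_false(identical(stratified_window_folds(w, 10, seed = 4), f))
  # k reduced to the smallest class count
  w9 <- data.frame(start = 0:8, end = 1:9, label = rep("SR", 9))
  w9 <- rbind(w9, data.frame(start = 10:29, end = 11:30,
                             label = rep("no_action", 20)))
  expect_warning(f9 <- stratified_window_folds(w9, 10, seed = 1), "reduced")
  expect_equal(attr(f9, "k"), 9L)
  expect_error(stratified_window_folds(w, 1, seed = 1), "k must be >= 2")
  # partition: every window in exactly one fold
  expect_true(all(f %in% 1:10) && length(f) == nrow(w))
})

test_that("cross-validation is perfect on separable data for both methods", {
  cls <- list(A = c(30, 10, 150, 150), B = c(90, 30, 300, 300))
  ds <- block_dataset(cls, reps = 6, jitter = 0)  # constant vectors: ties
  cv_t <- crossvalidate(ds$track, ds$windows, "tree", k = 3, seed = 7,
                        hyperparams = tree_hyperparams(4, 5),
                        movement_windows = ds$movements)
  expect_equal(cv_t$accuracy, 1)
  cv_th <- crossvalidate(ds$track, ds$windows, "threshold", k = 3, seed = 7)
  expect_equal(cv_th$accuracy, 1)
  # k = 2 gives the same answer on easy data
  cv2 <- crossvalidate(ds$track, ds$windows, "tree", k = 2, seed = 7,
                       hyperparams = tree_hyperparams(4, 5),
                       movement_windows = ds$movements)
  expect_equal(cv2$accuracy, 1)
})

test_that("shuffled labels drop accuracy to about the no-information rate", {
  cls <- list(A = c(30, 10, 150, 150), B = c(90, 30, 300, 300),
              C = c(9, 3, 80, 80))
  ds <- block_dataset(cls, reps = 5, jitter = 0.05)
  accs <- vapply(1:10, function(s) {
    w <- ds$windows
    mv <- ds$movements
    perm <- with_seed_test(s, sample(nrow(mv)))
    mv$label <- mv$label[perm]
    is_act <- w$label != "no_action"
    w$label[is_act] <- mv$label  # windows follow the shuffled movements
    crossvalidate(ds$track, w, "tree", k = 3, seed = s,
                  hyperparams = tree_hyperparams(4, 5),
                  movement_windows = mv)$accuracy
  }, 0)
  nir <- mean(ds$windows$label == "no_action")
  expect_lt(mean(accs), 1)
  expect_equal(mean(accs), nir, tolerance = 0.12)
})

test_that("unknown windows are pooled with every fold's test set", {
  cls <- list(A = c(30, 10, 150, 150), B = c(90, 30, 300, 300))
  ds <- block_dataset(cls, reps = 5, jitter = 0.02)
  unk <- ds$windows[ds$windows$label == "B", ]
  known <- ds$windows[ds$windows$label != "B", ]
  mv <- ds$movements[ds$movements$label == "A", ]
  cv <- crossvalidate(ds$track, known, "tree", k = 3, seed = 9,
                      hyperparams = tree_hyperparams(4, 5),
                      unknown_windows = unk, movement_windows = mv)
  expect_false(is.null(cv$unknown))
  # every fold saw all 5 unknown windows: their truth rows add 15 windows
  expect_equal(sum(cv$unknown$confusion) - sum(cv$confusion), 3 * nrow(unk))
  # class B (trained nowhere) must not be predicted
  expect_false("B" %in% colnames(cv$confusion)[colSums(cv$confusion) > 0])
})
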