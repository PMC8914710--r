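#' Replicate the able-bodied (trapezius-sensor) tree evaluations
#'
#' Simulates one `protocol_a` session, extracts features, and runs the three
#' decision-tree evaluations on it:
#'
#' * `binary` — SR detection: SR vs everything else (SF and SB windows are
#'   ground-truthed no-action), window-stratified k-fold cross-validation.
#' * `binary_unknown` — the same folds and fold models, with every fold's
#'   test set pooled with the held-out unknown-action windows (SRH and OR,
#'   ground-truthed no-action).
#' * `multiclass` — four-way no-action / SR / SF / SB classification trained
#'   on all data (SRH and OR labelled no-action).
#'
#' Pre-pruning hyperparameters are selected per task by a grid search over
#' [default_tree_grid()] using `grid_k`-fold cross-validation before the
#' reported k-fold run.
#'
#' @param seed Master seed (simulation + fold shuffling).
#' @param k Folds for the reported cross-validation.
#' @param grid_k Folds inside the hyperparameter grid search.
#' @return List with the three evaluation results (`$binary`,
#'   `$binary_unknown`, `$multiclass`), the selected hyperparameters, the
#'   session's realised SNRs and the feature track size.
#' @export
eval_protocol_a <- function(seed, k = 10L, grid_k = 3L) {
  sess <- simulate_preset("protocol_a", seed)[[1L]]
  track <- session_features(sess)
  w <- sess$windows
  unknown <- c("SRH", "OR")
  w_known <- w[!w$label %in% unknown, , drop = FALSE]
  w_unknown <- w[w$label %in% unknown, , drop = FALSE]
  mv <- sess$movements

  # binary task: SR vs rest (SF/SB ground-truthed as no-action)
  w_bin <- w_known
  w_bin$label[w_bin$label != "SR"] <- "no_action"
  mv_bin <- mv[mv$label == "SR", , drop = FALSE]
  hp_bin <- grid_search_prepruning(track, w_bin, k = grid_k, seed = seed,
                                   unknown_windows = w_unknown,
                                   movement_windows = mv_bin)
  cv_bin <- crossvalidate(track, w_bin, method = "tree", k = k, seed = seed,
                          hyperparams = hp_bin, unknown_windows = w_unknown,
                          movement_windows = mv_bin)

  # four-way task trained on all data (SRH/OR labelled no-action)
  w_multi <- w
  w_multi$label[w_multi$label %in% unknown] <- "no_action"
  mv_multi <- mv[!mv$label %in% unknown, , drop = FALSE]
  hp_multi <- grid_search_prepruning(track, w_multi, k = grid_k, seed = seed,
                                     movement_windows = mv_multi)
  cv_multi <- crossvalidate(track, w_multi, method = "tree", k = k,
                            seed = seed, hyperparams = hp_multi,
                            movement_windows = mv_multi)

  list(binary = cv_bin[c("confusion", "accuracy", "k")],
       binary_unknown = cv_bin$unknown,
       multiclass = cv_multi[c("confusion", "accuracy", "k")],
       hyperparams = list(binary = hp_bin, multiclass = hp_multi),
       snr_db = sess$snr_db, n_vectors = nrow(track))
}

#' Replicate the platysma-sensor thresholding evaluation
#'
#' Simulates both days of the `protocol_b_p2` preset and, for each day
#' separately (sensor gain differs between days, so models never pool days),
#' runs the three-way no-action / SR / PC thresholding classifier under
#' window-stratified k-fold cross-validation.
#'
#' @param seed Master seed.
#' @param k Folds (default 5).
#' @return List with `per_day` evaluation results (confusion, accuracy,
#'   realised SNR, and the full-day fitted class order), `accuracy_mean` over
#'   days and `accuracy_best` (the better day).
#' @export
eval_protocol_b <- function(seed, k = 5L) {
  sessions <- simulate_preset("protocol_b_p2", seed)
  per_day <- lapply(sessions, function(s) {
    track <- session_features(s)
    cv <- crossvalidate(track, s$windows, method = "threshold", k = k,
                        seed = seed, mode = "multiclass")
    cv$snr_db <- s$snr_db
    full <- fit_thresholds(instance_maxima(track, s$windows),
                           mode = "multiclass")
    cv$class_order <- full$class_order
    cv[c("confusion", "accuracy", "k", "snr_db", "class_order")]
  })
  acc <- vapply(per_day, `[[`, 0, "accuracy")
  list(per_day = per_day, accuracy_mean = mean(acc),
       accuracy_best = max(acc))
}
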