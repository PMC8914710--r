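#' Build ground-truth action and no-action windows
#'
#' Each event yields an action window `[t_instruction, t_instruction +
#' 2 * nominal_duration)` — twice the nominal action duration, starting when
#' the instruction is given. The remainder of the recording span is
#' partitioned into no-action windows whose length matches the mean action
#' window, so window-level scores count action and no-action evidence in
#' comparable units. Overlapping action windows are a protocol violation and
#' raise an error.
#'
#' @param events An `emg_events` log (may be empty).
#' @param span `c(t_start, t_end)` of the recording (s).
#' @param no_action Label for complement windows.
#' @return Data frame with `start`, `end`, `label`; class `action_windows`.
#' @export
build_action_windows <- function(events, span, no_action = "no_action") {
  stopifnot(length(span) == 2L, span[2] > span[1])
  if (nrow(events) > 0) {
    start <- events$t_instruction_s
    end <- start + 2 * events$nominal_duration_s
    if (any(start < span[1]) || any(end > span[2]))
      stop("window validation error: events outside the recording span")
    if (any(start[-1] < end[-length(end)]))
      stop("window validation error: overlapping action windows")
    aw <- data.frame(start = start, end = end, label = events$action,
                     stringsAsFactors = FALSE)
    mean_len <- mean(end - start)
  } else {
    aw <- data.frame(start = numeric(0), end = numeric(0),
                     label = character(0), stringsAsFactors = FALSE)
    mean_len <- span[2] - span[1]
  }
  gaps_start <- c(span[1], aw$end)
  gaps_end <- c(aw$start, span[2])
  na_rows <- list()
  for (g in seq_along(gaps_start)) {
    len <- gaps_end[g] - gaps_start[g]
    if (len < 0.3 * mean_len) next  # slivers carry no scoring information
    nsub <- max(1L, round(len / mean_len))
    edges <- seq(gaps_start[g], gaps_end[g], length.out = nsub + 1L)
    na_rows[[g]] <- data.frame(start = edges[-length(edges)], end = edges[-1],
                               label = no_action, stringsAsFactors = FALSE)
  }
  out <- rbind(aw, do.call(rbind, na_rows))
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("action_windows", "data.frame")
  out
}

#' Label feature vectors by window membership
#'
#' With the default `"midpoint"` rule a feature vector is labelled with a
#' window's label iff its analysis-window midpoint lies inside that window.
#' With the `"containment"` rule the whole analysis window must lie inside
#' the labelled interval — a conservative rule for training labels, so that
#' vectors straddling a movement boundary (whose spectra mix movement and
#' rest) are not taught as movement examples. Vectors matching no window get
#' `NA`.
#'
#' @param track A `feature_track`.
#' @param windows Window data frame (`start`, `end`, `label`).
#' @param rule `"midpoint"` or `"containment"`.
#' @return Character vector of labels (with `NA` outside all windows).
#' @export
label_feature_vectors <- function(track, windows,
                                  rule = c("midpoint", "containment")) {
  rule <- match.arg(rule)
  lab <- rep(NA_character_, nrow(track))
  if (rule == "midpoint") {
    mid <- track_midpoints(track)
    for (i in seq_len(nrow(windows))) {
      sel <- mid >= windows$start[i] & mid < windows$end[i]
      lab[sel] <- windows$label[i]
    }
  } else {
    wd <- attr(track, "welch_spec")$window_dur
    t_end <- track$t_s
    t_start <- t_end - wd
    for (i in seq_len(nrow(windows))) {
      sel <- t_start >= windows$start[i] & t_end <= windows$end[i]
      lab[sel] <- windows$label[i]
    }
  }
  lab
}

#' Score per-vector predictions at the action-window level
#'
#' A truth-action window counts as the *first wrong action predicted in it*
#' if any vector inside it predicts a different action; otherwise as the
#' correct action if it is predicted anywhere inside; otherwise as no-action.
#' A no-action window counts as the first action predicted inside it (a false
#' positive), or as correct when every prediction is no-action. Windows
#' without any prediction are excluded with a warning.
#'
#' @param pred Character vector of per-vector predicted labels.
#' @param times Midpoint times of the vectors (s).
#' @param windows Window data frame (`start`, `end`, `label`).
#' @param no_action The no-action label.
#' @param labels Optional fixed label set for the confusion matrix (so that
#'   matrices from different folds share dimensions).
#' @return List with `confusion` (rows = truth, columns = prediction),
#'   `accuracy` (trace over total) and `windows` (per-window outcome).
#' @export
score_window_predictions <- function(pred, times, windows,
                                     no_action = "no_action",
                                     labels = NULL) {
  stopifnot(length(pred) == length(times))
  labs <- if (is.null(labels)) sort(unique(c(no_action, windows$label, pred)))
          else labels
  got <- character(nrow(windows))
  keep <- logical(nrow(windows))
  ord <- order(times)
  pred <- pred[ord]; times <- times[ord]
  for (i in seq_len(nrow(windows))) {
    sel <- times >= windows$start[i] & times < windows$end[i]
    if (!any(sel)) next
    keep[i] <- TRUE
    p <- pred[sel]
    truth <- windows$label[i]
    wrong <- p[p != no_action & p != truth]
    got[i] <- if (length(wrong) > 0) wrong[1]
      else if (truth != no_action && any(p == truth)) truth
      else no_action
  }
  if (!all(keep))
    warning(sum(!keep), " window(s) without predictions excluded from scoring")
  truth_f <- factor(windows$label[keep], levels = labs)
  got_f <- factor(got[keep], levels = labs)
  cm <- table(truth = truth_f, prediction = got_f)
  res <- data.frame(start = windows$start[keep], end = windows$end[keep],
                    truth = windows$label[keep], outcome = got[keep],
                    stringsAsFactors = FALSE)
  list(confusion = cm, accuracy = sum(diag(cm)) / sum(cm), windows = res)
}

#' Stratified fold assignment over windows
#'
#' Windows of each class are shuffled (deterministically, from `seed`) and
#' dealt round-robin over the folds, so every class is spread as evenly as
#' counts allow. If some class has fewer than `k` windows, `k` is reduced to
#' that count with a warning — mirroring evaluation on participants with few
#' action occurrences.
#'
#' @param windows Window data frame (`start`, `end`, `label`).
#' @param k Requested number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of fold indices in `1..k_eff`, with attribute `"k"`.
#' @export
stratified_window_folds <- function(windows, k, seed) {
  if (k < 2L) stop("fold parameter error: k must be >= 2")
  cnt <- table(windows$label)
  k_eff <- as.integer(min(k, min(cnt)))
  if (k_eff < k)
    warning("k reduced to ", k_eff, " (smallest class has ", min(cnt),
            " windows)")
  if (k_eff < 2L) stop("fold parameter error: a class has < 2 windows")
  fold <- integer(nrow(windows))
  with_seed(seed, {
    for (cl in names(cnt)) {
      idx <- which(windows$label == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k_eff), length(idx))
    }
  })
  attr(fold, "k") <- k_eff
  fold
}

#' Cross-validated window-level evaluation of a classifier
#'
#' Splits the ground-truth windows into stratified folds; for each fold fits
#' the classifier on the remaining folds (the tree on the labelled feature
#' vectors of those windows, the thresholding classifier on the per-instance
#' feature maxima) and scores the held-out windows with the window-level
#' rule. Fold confusions are summed. Optionally each fold's model is also
#' tested against designated "unknown" windows (actions absent from
#' training, ground-truthed as no-action).
#'
#' @param track A `feature_track`.
#' @param windows Ground-truth windows for the task.
#' @param method `"tree"` or `"threshold"`.
#' @param k Number of folds.
#' @param seed Integer seed (fold shuffling).
#' @param hyperparams [tree_hyperparams()] for the tree method.
#' @param mode Threshold mode; default `"multiclass"` when more than one
#'   action class is present, else `"binary"`.
#' @param unknown_windows Optional window data frame of unknown-action
#'   occurrences; they are relabelled no-action and pooled with every fold's
#'   test windows, and the pooled scores are returned alongside the plain
#'   ones under `$unknown` (the same fitted fold models are used for both).
#'   Their data are never used for training.
#' @param movement_windows Optional data frame (`start`, `end`, `label`) of
#'   annotated movement intervals (e.g. from audiovisual ground truth, or a
#'   simulation's `$movements`). When supplied, tree training labels come
#'   from these intervals — vectors outside any movement are no-action —
#'   rather than from the full double-length action windows, which would
#'   label pre- and post-movement rest as action. Scoring always uses the
#'   action windows.
#' @param no_action The no-action label.
#' @return List: `confusion`, `accuracy`, `per_fold` accuracies, `k`, the
#'   per-window outcomes, and optionally `unknown` (pooled confusion and
#'   accuracy).
#' @export
crossvalidate <- function(track, windows, method = c("tree", "threshold"),
                          k = 10L, seed = 1L,
                          hyperparams = tree_hyperparams(),
                          mode = NULL, unknown_windows = NULL,
                          movement_windows = NULL,
                          no_action = "no_action") {
  method <- match.arg(method)
  fold <- stratified_window_folds(windows, k, seed)
  k_eff <- attr(fold, "k")
  X <- feature_matrix(track)
  mid <- track_midpoints(track)
  if (!is.null(unknown_windows) && nrow(unknown_windows) > 0) {
    unknown_spans <- unknown_windows[, c("start", "end")]
    unknown_windows <- data.frame(start = unknown_windows$start,
                                  end = unknown_windows$end,
                                  label = no_action, stringsAsFactors = FALSE)
  } else {
    unknown_windows <- NULL
    unknown_spans <- NULL
  }
  base_lab <- if (!is.null(movement_windows)) {
    l <- label_feature_vectors(track, movement_windows, rule = "containment")
    l[is.na(l)] <- no_action
    # data of unknown actions stay out of training entirely
    if (!is.null(unknown_spans)) {
      ex <- label_feature_vectors(
        track, cbind(unknown_spans, label = "x", stringsAsFactors = FALSE))
      l[!is.na(ex)] <- NA
    }
    l
  }
  all_labels <- sort(unique(c(no_action, windows$label)))
  cm <- cm_u <- NULL
  per_fold <- numeric(k_eff)
  outcomes <- list()
  for (f in seq_len(k_eff)) {
    train_w <- windows[fold != f, , drop = FALSE]
    test_w <- windows[fold == f, , drop = FALSE]
    if (method == "tree") {
      if (is.null(movement_windows)) {
        lab <- label_feature_vectors(track, train_w)
      } else {
        lab <- base_lab
        # held-out occurrences (this fold's action windows) never train
        held <- windows[fold == f & windows$label != no_action, , drop = FALSE]
        if (nrow(held) > 0) {
          ex <- label_feature_vectors(track, held)
          lab[!is.na(ex)] <- NA
        }
      }
      sel <- !is.na(lab) & !track$flag
      model <- fit_tree(X[sel, , drop = FALSE], lab[sel],
                        hyperparams = hyperparams)
      pred <- predict(model, X)
      pred[track$flag] <- no_action
    } else {
      mx <- instance_maxima(track, train_w, no_action = no_action)
      md <- if (is.null(mode)) {
        if (length(unique(mx$label)) > 1L) "multiclass" else "binary"
      } else mode
      model <- fit_thresholds(mx, mode = md)
      pred <- predict_threshold(model, track, no_action = no_action)
    }
    sc <- score_window_predictions(pred, mid, test_w, no_action = no_action,
                                   labels = all_labels)
    cm <- if (is.null(cm)) sc$confusion else cm + sc$confusion
    per_fold[f] <- sc$accuracy
    outcomes[[f]] <- cbind(sc$windows, fold = f)
    if (!is.null(unknown_windows)) {
      sc_u <- score_window_predictions(
        pred, mid, rbind(test_w, unknown_windows),
        no_action = no_action, labels = all_labels)
      cm_u <- if (is.null(cm_u)) sc_u$confusion else cm_u + sc_u$confusion
    }
  }
  out <- list(confusion = cm, accuracy = sum(diag(cm)) / sum(cm),
              per_fold = per_fold, k = k_eff,
              windows = do.call(rbind, outcomes))
  if (!is.null(cm_u))
    out$unknown <- list(confusion = cm_u,
                        accuracy = sum(diag(cm_u)) / sum(cm_u))
  out
}
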