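#' Per-instance feature maxima over action windows
#'
#' For every occurrence (ground-truth action window) of an action, takes the
#' element-wise maximum of each of the four features over the feature vectors
#' whose analysis-window midpoint falls inside the occurrence. These maxima
#' are the training statistics of the thresholding classifier.
#'
#' @param track A `feature_track`.
#' @param windows Action windows (data frame with `start`, `end`, `label`);
#'   no-action windows are ignored.
#' @param no_action The no-action label.
#' @return Data frame: one row per occurrence with `label` and the four
#'   feature maxima. Occurrences containing no feature vector are excluded
#'   with a warning.
#' @export
instance_maxima <- function(track, windows, no_action = "no_action") {
  aw <- windows[windows$label != no_action, , drop = FALSE]
  mid <- track_midpoints(track)
  X <- feature_matrix(track)
  rows <- lapply(seq_len(nrow(aw)), function(i) {
    sel <- mid >= aw$start[i] & mid < aw$end[i] & !track$flag
    if (!any(sel)) return(NULL)
    m <- apply(X[sel, , drop = FALSE], 2, max)
    data.frame(label = aw$label[i], total_power = m[1], psd_peak = m[2],
               mnf_hz = m[3], mdf_hz = m[4], stringsAsFactors = FALSE)
  })
  empty <- vapply(rows, is.null, TRUE)
  if (any(empty))
    warning(sum(empty), " action window(s) without feature vectors excluded")
  out <- do.call(rbind, rows[!empty])
  if (is.null(out))
    out <- data.frame(label = character(0), total_power = numeric(0),
                      psd_peak = numeric(0), mnf_hz = numeric(0),
                      mdf_hz = numeric(0))
  rownames(out) <- NULL
  out
}

feature_cols <- c("total_power", "psd_peak", "mnf_hz", "mdf_hz")

#' Fit the median / third-quartile thresholding classifier
#'
#' For each action class the lower decision bound of every feature is the
#' median of that feature's per-occurrence maxima. In multi-class mode the
#' third quartile (linear-interpolation quantile) additionally caps each
#' class from above, so classes occupy axis-aligned bands ordered by band
#' power. Classes are ordered by ascending median band power.
#'
#' @param maxima Output of [instance_maxima()].
#' @param mode `"binary"` (a single action class, lower bounds only) or
#'   `"multiclass"` (lower and upper bounds).
#' @return A `threshold_model`.
#' @export
fit_thresholds <- function(maxima, mode = c("binary", "multiclass")) {
  mode <- match.arg(mode)
  if (nrow(maxima) == 0L) stop("no action occurrences to fit thresholds on")
  classes <- unique(maxima$label)
  if (mode == "binary" && length(classes) != 1L)
    stop("binary mode expects exactly one action class")
  cnt <- table(maxima$label)
  if (any(cnt < 2L))
    warning("class(es) with a single occurrence: thresholds are degenerate")
  lower <- t(vapply(classes, function(cl) {
    apply(maxima[maxima$label == cl, feature_cols, drop = FALSE], 2,
          stats::median)
  }, numeric(4)))
  upper <- NULL
  if (mode == "multiclass") {
    upper <- t(vapply(classes, function(cl) {
      apply(maxima[maxima$label == cl, feature_cols, drop = FALSE], 2,
            stats::quantile, probs = 0.75, names = FALSE, type = 7)
    }, numeric(4)))
    rownames(upper) <- classes
    colnames(upper) <- feature_cols
  }
  rownames(lower) <- classes
  colnames(lower) <- feature_cols
  ord <- classes[order(lower[, "total_power"])]
  structure(list(mode = mode, class_order = ord,
                 lower = lower[ord, , drop = FALSE],
                 upper = if (!is.null(upper)) upper[ord, , drop = FALSE],
                 quantile_method = "linear interpolation (type 7)"),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("<threshold_model> %s, classes by ascending power: %s\n",
              x$mode, paste(x$class_order, collapse = " < ")))
  invisible(x)
}

#' Predict per-vector labels with a threshold model
#'
#' Binary mode: a vector is the action iff all four features are at or above
#' the action's lower thresholds. Multi-class mode: classes are scanned from
#' the highest-power class downward and a vector is assigned the highest
#' class whose lower bounds it satisfies; for a non-top class the vector must
#' additionally lie at or below that class's third-quartile upper bounds,
#' otherwise it falls through to no-action (a conservative rule for
#' between-band vectors). Flagged (zero-power) vectors are always no-action.
#'
#' @param m A `threshold_model`.
#' @param track A `feature_track` (or 4-column feature matrix).
#' @param no_action Label to emit for unclassified vectors.
#' @return Character vector of labels, one per feature vector.
#' @export
predict_threshold <- function(m, track, no_action = "no_action") {
  X <- as_feature_input(track)
  n <- nrow(X)
  out <- rep(no_action, n)
  ord <- m$class_order
  open <- rep(TRUE, n)  # not yet claimed by a higher class
  for (cl in rev(ord)) {
    lo <- m$lower[cl, ]
    sat <- open &
      X[, 1] >= lo[1] & X[, 2] >= lo[2] & X[, 3] >= lo[3] & X[, 4] >= lo[4]
    if (m$mode == "multiclass" && cl != ord[length(ord)]) {
      up <- m$upper[cl, ]
      inband <- X[, 1] <= up[1] & X[, 2] <= up[2] &
        X[, 3] <= up[3] & X[, 4] <= up[4]
      out[sat & inband] <- cl
      # vectors above the band's cap fall through to no-action, but are
      # claimed: they are not offered to lower classes
    } else {
      out[sat] <- cl
    }
    open <- open & !sat
  }
  if (inherits(track, "feature_track")) out[track$flag] <- no_action
  out
}

#' @export
predict.threshold_model <- function(object, newdata, ...) {
  predict_threshold(object, newdata, ...)
}
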