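# Shared fixtures, all generated in code.

with_seed_test <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

sine_recording <- function(freq, amp = 1, dur = 10, fs = 2500, t0 = 0) {
  tt <- (seq_len(round(dur * fs)) - 1) / fs
  emg_recording(amp * sin(2 * pi * freq * tt), fs = fs, t0 = t0)
}

# A feature track built directly from a matrix of feature vectors at a fixed
# stride (bypasses the spectral pipeline; used to test classifiers/scoring
# in isolation).
manual_track <- function(X, stride = 0.1, window_dur = 0.2, t0 = window_dur) {
  X <- as.matrix(X)
  out <- data.frame(
    t_s = t0 + (seq_len(nrow(X)) - 1) * stride,
    total_power = X[, 1], psd_peak = X[, 2], mnf_hz = X[, 3],
    mdf_hz = X[, 4],
    flag = FALSE)
  attr(out, "welch_spec") <- welch_spec(window_dur = window_dur,
                                        stride = stride)
  attr(out, "fs") <- 1000
  class(out) <- c("feature_track", "data.frame")
  out
}

# Piecewise-constant synthetic feature track: rest everywhere, one block of
# class vectors inside each action window. Returns track + windows (+ true
# movement intervals). Classes are given as named feature 4-vectors.
block_dataset <- function(class_vectors, reps = 6, rest = c(1, 0.5, 40, 38),
                          stride = 0.1, jitter = 0) {
  labels <- names(class_vectors)
  cycle <- 8   # seconds per occurrence: 3 rest, 1 action, 4 rest
  events_t <- c(); events_a <- c()
  t_total <- 2
  occ <- list()
  for (r in seq_len(reps)) for (a in labels) {
    events_t <- c(events_t, t_total + 3)
    events_a <- c(events_a, a)
    occ[[length(occ) + 1L]] <- c(t_total + 3.3, t_total + 4.3, a)
    t_total <- t_total + cycle
  }
  t_total <- t_total + 2
  ev <- emg_events(events_t, events_a, rep(1, length(events_t)))
  windows <- build_action_windows(ev, span = c(0, t_total))
  n <- floor(t_total / stride)
  X <- matrix(rep(rest, each = n), n, 4)
  tt <- 0.2 + (seq_len(n) - 1) * stride
  mid <- tt - 0.1
  set.seed(42)
  X <- X * (1 + jitter * matrix(runif(length(X), -1, 1), n, 4))
  mv <- data.frame(start = as.numeric(vapply(occ, `[[`, "", 1)),
                   end = as.numeric(vapply(occ, `[[`, "", 2)),
                   label = vapply(occ, `[[`, "", 3),
                   stringsAsFactors = FALSE)
  for (i in seq_len(nrow(mv))) {
    sel <- mid >= mv$start[i] & mid < mv$end[i]
    v <- class_vectors[[mv$label[i]]]
    X[sel, ] <- matrix(rep(v, each = sum(sel)), sum(sel), 4) *
      (1 + jitter * matrix(runif(sum(sel) * 4, -1, 1), sum(sel), 4))
  }
  track <- manual_track(X, stride = stride)
  list(track = track, windows = windows, movements = mv, events = ev,
       span = c(0, t_total))
}

# Small, fast synthetic protocol for end-to-end tests (not a preset).
tiny_protocol <- function(reps = 3, fs = 2000, seed_gap = 2) {
  protocol_spec(
    fs = fs,
    sources = list(low = source_profile("low", c(40, 90)),
                   high = source_profile("high", c(150, 300))),
    actions = list(
      movement_spec("A", 0.8, "quick", c(high = 1), target_snr_db = 8),
      movement_spec("B", 0.8, "quick", c(low = 1), target_snr_db = 5)),
    repetitions = reps, relax_dur = 1.5, prepare_dur = 1.5,
    gap_dur = seed_gap, noise_floor = 1, lowfreq_level = 3,
    lowfreq_band = c(20, 40), order = "blocked", amp_jitter = 0.2,
    sync_level = 0.7, decim_factor = 1L, stride = 0.02)
}
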