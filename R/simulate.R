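#' Spectral profile of an EMG source
#'
#' A source is band-limited Gaussian activity with cosine-tapered band edges
#' and an optional linear amplitude tilt across the band. Sources reaching
#' the sensor from a distance (crosstalk) are modelled with lower-frequency
#' bands, reflecting tissue low-pass filtering.
#'
#' @param name Muscle / source label.
#' @param band `c(lo, hi)` spectral support in Hz, inside `[20, 500]`.
#' @param shape Amplitude tilt exponent across the band (0 = flat).
#' @return A `source_profile`.
#' @export
source_profile <- function(name, band, shape = 0) {
  band <- as.numeric(band)
  if (length(band) != 2L || band[1] < 20 || band[2] > 500 ||
      band[1] >= band[2])
    stop("source parameter error: band must satisfy 20 <= lo < hi <= 500")
  structure(list(name = name, band = band, shape = shape),
            class = "source_profile")
}

#' Movement specification for the generator
#'
#' @param action Action label (e.g. `"SR"`).
#' @param nominal_duration Action duration in seconds.
#' @param envelope `"quick"` (ballistic rise-fall), `"graded"` (gradual
#'   rise-fall, typical of weak or impaired voluntary activation), `"hold"`
#'   (rise-plateau-fall) or `"object"` (slow double bump: lift then lower).
#' @param source_gains Named non-negative gains mixing the protocol's
#'   [source_profile()]s at the sensor; a non-zero gain on a non-target
#'   source is crosstalk.
#' @param target_snr_db Action-band SNR at the sensor, in dB, measured as
#'   action-window over rest-window 20--500 Hz band power.
#' @return A `movement_spec`.
#' @export
movement_spec <- function(action, nominal_duration,
                          envelope = c("quick", "graded", "hold", "object"),
                          source_gains, target_snr_db) {
  envelope <- match.arg(envelope)
  if (nominal_duration <= 0)
    stop("movement parameter error: nominal_duration must be > 0")
  source_gains <- unlist(source_gains)
  if (any(source_gains < 0) || !any(source_gains > 0))
    stop("movement parameter error: need non-negative gains, at least one > 0")
  structure(list(action = action, nominal_duration = nominal_duration,
                 envelope = envelope, source_gains = source_gains,
                 target_snr_db = target_snr_db),
            class = "movement_spec")
}

#' Protocol specification for a synthetic session
#'
#' Encodes the acquisition protocol the generator emulates: instruction
#' cycles (relax, prepare, act), repetitions, the sensor's noise floor and a
#' low-frequency baseline-activity component (motion artefact residue and
#' distant tonic activity concentrated below ~40 Hz, which is what makes
#' contractions raise the spectral features above rest).
#'
#' @param fs Sampling rate (Hz); must be at least twice the highest source
#'   band edge.
#' @param sources Named list of [source_profile()]s.
#' @param actions List of [movement_spec()]s.
#' @param repetitions Occurrences per action.
#' @param relax_dur,prepare_dur,gap_dur Cycle timing (s): relax, prepare
#'   (instruction at the end of prepare), and the gap after the action
#'   window.
#' @param noise_floor White sensor/amplifier noise RMS (µV).
#' @param lowfreq_level RMS (µV) of the low-frequency baseline component.
#' @param lowfreq_band Band (Hz) of the baseline component.
#' @param order `"blocked"` (one action per trial block, as with on-screen
#'   instructions) or `"interleaved"` (alternating verbal instructions).
#' @param amp_jitter Per-repetition uniform amplitude jitter fraction (0.3 =
#'   effort varied by ±30%).
#' @param sync_level Synchronised-firing fraction of burst power (see
#'   [synth_burst()]).
#' @param reaction_delay `c(min, max)` delay (s) between instruction and
#'   movement onset.
#' @param n_days Number of recorded days (sessions).
#' @param day_gains Per-day sensor gain multipliers (skin/placement effects).
#' @param decim_factor Decimation factor used at analysis time.
#' @param stride Analysis stride (s) used at analysis time.
#' @param muscle_site,participant_id Metadata for the recording.
#' @return A `protocol_spec`.
#' @export
protocol_spec <- function(fs, sources, actions, repetitions,
                          relax_dur = 2, prepare_dur = 2, gap_dur = 0.7,
                          noise_floor = 5, lowfreq_level = 5,
                          lowfreq_band = c(20, 40),
                          order = c("blocked", "interleaved"),
                          amp_jitter = 0.3, sync_level = 0.5,
                          reaction_delay = c(0.35, 0.5),
                          n_days = 1L, day_gains = 1,
                          decim_factor = 1L, stride = 0.01,
                          muscle_site = "unspecified",
                          participant_id = "sim") {
  order <- match.arg(order)
  hi <- max(vapply(sources, function(s) s$band[2], 0))
  if (fs < 2 * hi)
    stop("protocol parameter error: fs must be >= twice the top source band")
  if (repetitions < 0) stop("protocol parameter error: repetitions >= 0")
  if (noise_floor <= 0) stop("protocol parameter error: noise_floor > 0")
  if (length(day_gains) != n_days)
    stop("protocol parameter error: one day gain per day")
  for (a in actions)
    if (!all(names(a$source_gains) %in% names(sources)))
      stop("protocol parameter error: unknown source in ", a$action)
  structure(list(fs = fs, sources = sources, actions = actions,
                 repetitions = as.integer(repetitions),
                 relax_dur = relax_dur, prepare_dur = prepare_dur,
                 gap_dur = gap_dur, noise_floor = noise_floor,
                 lowfreq_level = lowfreq_level, lowfreq_band = lowfreq_band,
                 order = order, amp_jitter = amp_jitter,
                 sync_level = sync_level,
                 reaction_delay = reaction_delay, n_days = as.integer(n_days),
                 day_gains = day_gains, decim_factor = as.integer(decim_factor),
                 stride = stride, muscle_site = muscle_site,
                 participant_id = participant_id),
            class = "protocol_spec")
}

# Band-limited unit-RMS Gaussian noise via frequency-domain shaping with
# cosine-tapered band edges (taper width 15% of the bandwidth).
shaped_noise <- function(n, fs, band, shape = 0) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)  # two-sided magnitude axis
  lo <- band[1]; hi <- band[2]
  w <- 0.15 * (hi - lo)
  mask <- numeric(n)
  inside <- f >= lo & f <= hi
  mask[inside] <- 1
  rise <- f >= lo - w & f < lo
  mask[rise] <- 0.5 * (1 + cos(pi * (lo - f[rise]) / w))
  fall <- f > hi & f <= hi + w
  mask[fall] <- 0.5 * (1 + cos(pi * (f[fall] - hi) / w))
  if (shape != 0) {
    rel <- pmin(pmax((f - lo) / (hi - lo), 0), 1)
    mask <- mask * rel^shape
  }
  y <- Re(stats::fft(X * mask, inverse = TRUE)) / n
  y / stats::sd(y)
}

envelope_shape <- function(kind, n) {
  u <- seq(0, 1, length.out = n)
  switch(kind,
    quick = {
      # ballistic contraction: ~70 ms recruitment/release ramps with a
      # gentle arch peaking mid-movement
      r <- 0.07
      base <- pmin(1, pmin(u, 1 - u) / r)
      base <- 0.5 * (1 - cos(pi * pmin(base, 1)))
      base * (0.8 + 0.2 * sin(pi * u))
    },
    graded = sin(pi * u)^0.5,
    hold = {
      e <- rep(1, n)
      r <- u < 0.15
      e[r] <- 0.5 * (1 - cos(pi * u[r] / 0.15))
      fll <- u > 0.85
      e[fll] <- 0.5 * (1 - cos(pi * (1 - u[fll]) / 0.15))
      e
    },
    object = {
      b1 <- ifelse(u < 0.55, sin(pi * u / 0.55)^2, 0)
      b2 <- ifelse(u > 0.45, 0.9 * sin(pi * (u - 0.45) / 0.55)^2, 0)
      pmax(b1, b2)
    },
    stop("unknown envelope kind: ", kind))
}

#' Stationary background noise trace
#'
#' Zero-mean white Gaussian noise with the requested RMS — the sensor /
#' amplifier noise floor of a synthetic session.
#'
#' @param duration Length in seconds.
#' @param fs Sampling rate (Hz).
#' @param level Target RMS (µV), > 0.
#' @param seed Integer seed (same seed, same trace).
#' @return An `emg_recording`.
#' @export
synth_background <- function(duration, fs, level, seed) {
  if (level <= 0) stop("background parameter error: level must be > 0")
  n <- round(duration * fs)
  x <- with_seed(seed, stats::rnorm(n, sd = level))
  emg_recording(x, fs = fs, channel_name = "synthetic_background")
}

#' Synthesise one movement burst
#'
#' Mixes the protocol's sources according to the movement's gains (each
#' source an independent band-limited Gaussian process), normalises the mix
#' to unit RMS and applies the movement's amplitude envelope over its nominal
#' duration. Within each source the instantaneous spectrum shifts upward with
#' the instantaneous effort (`effort * envelope`): stronger phases draw more
#' power from the upper part of the source band, mimicking the recruitment of
#' faster motor units, so spectral features rise and fall together with
#' power. The caller scales the burst to the target SNR.
#'
#' @param m A [movement_spec()].
#' @param sources Named list of [source_profile()]s.
#' @param fs Sampling rate (Hz).
#' @param seed Integer seed.
#' @param effort Relative effort of this repetition (scales both the
#'   amplitude and the spectral shift).
#' @param sync Fraction (0--1) of burst power carried by a synchronised
#'   firing component: a deterministic tone swept along the instantaneous
#'   band centroid, emulating the spectral peak produced by synchronised
#'   motor-unit discharge. 0 gives pure filtered-noise EMG.
#' @return Numeric vector of `round(nominal_duration * fs)` samples.
#' @export
synth_burst <- function(m, sources, fs, seed, effort = 1, sync = 0.5) {
  n <- round(m$nominal_duration * fs)
  env <- envelope_shape(m$envelope, n)
  w <- pmin(0.05 + 0.6 * effort * env, 0.97)  # upper-band weight per sample
  gz <- m$source_gains[m$source_gains > 0]
  # gain-weighted band edges across contributing sources
  blo <- sum(vapply(names(gz), function(s) sources[[s]]$band[1], 0) * gz^2) /
    sum(gz^2)
  bhi <- sum(vapply(names(gz), function(s) sources[[s]]$band[2], 0) * gz^2) /
    sum(gz^2)
  c_lo <- blo + 0.3 * (bhi - blo)   # centroid of the lower sub-band
  c_hi <- blo + 0.7 * (bhi - blo)   # centroid of the upper sub-band
  with_seed(seed, {
    mix <- numeric(n)
    for (s in names(m$source_gains)) {
      g <- m$source_gains[[s]]
      if (g <= 0) next
      band <- sources[[s]]$band
      cut <- band[1] + c(0.6, 0.4) * diff(band)
      lo <- shaped_noise(n, fs, c(band[1], cut[1]), sources[[s]]$shape)
      hi <- shaped_noise(n, fs, c(cut[2], band[2]), sources[[s]]$shape)
      mix <- mix + g * (sqrt(1 - w) * lo + sqrt(w) * hi)
    }
    mix <- mix / stats::sd(mix)
    if (sync > 0) {
      f_inst <- c_lo + w * (c_hi - c_lo)
      tone <- sqrt(2) * sin(cumsum(2 * pi * f_inst / fs) +
                              stats::runif(1, 0, 2 * pi))
      mix <- sqrt(1 - sync) * mix + sqrt(sync) * tone
    }
    effort * mix * env
  })
}

window_mask <- function(n, fs, w) {
  i0 <- pmax(1L, floor(w$start * fs) + 1L)
  i1 <- pmin(n, ceiling(w$end * fs))
  m <- logical(n)
  for (k in seq_along(i0)) if (i1[k] >= i0[k]) m[i0[k]:i1[k]] <- TRUE
  m
}

#' Action-band signal-to-noise ratio of a recording
#'
#' `10 * log10(P_action / P_rest)` per action, where `P` is the mean
#' band-limited (default 20--500 Hz, zero-phase Butterworth) power over the
#' action windows of that action resp. over the no-action windows.
#'
#' @param r An `emg_recording`.
#' @param windows Ground-truth windows (`start`, `end`, `label`).
#' @param band Analysis band (Hz).
#' @param no_action The no-action label.
#' @return Named numeric vector of per-action SNRs (dB).
#' @export
measure_snr <- function(r, windows, band = c(20, 500),
                        no_action = "no_action") {
  acts <- setdiff(unique(windows$label), no_action)
  if (length(acts) == 0L || !any(windows$label == no_action))
    stop("snr parameter error: need at least one action and one rest window")
  ny <- r$fs / 2
  spec <- filter_spec("bandpass", c(band[1], min(band[2], 0.95 * ny)),
                      phase = "zero_phase")
  x2 <- bandpass_emg(r, spec)$samples^2
  n <- length(x2)
  p_rest <- mean(x2[window_mask(n, r$fs,
                                windows[windows$label == no_action, ])])
  if (p_rest <= 0) {
    warning("zero rest-band power: SNR is infinite")
    return(stats::setNames(rep(Inf, length(acts)), acts))
  }
  vapply(stats::setNames(acts, acts), function(a) {
    pa <- mean(x2[window_mask(n, r$fs, windows[windows$label == a, ])])
    10 * log10(pa / p_rest)
  }, 0)
}

#' Synthesise a full instruction-cycle session
#'
#' Lays out relax / prepare / act cycles for every action and repetition,
#' synthesises background noise plus per-repetition bursts (with amplitude
#' jitter and reaction delay), and scales each action's bursts so that the
#' realised action-window SNR ([measure_snr()]) meets the movement's target.
#' Per-burst random substreams are derived from `(seed, action, repetition)`,
#' so editing one action leaves the others' waveforms unchanged.
#'
#' @param spec A [protocol_spec()].
#' @param seed Master integer seed.
#' @param day Day index (applies `spec$day_gains[day]` to the whole trace).
#' @return A `sim_session`: list with `recording`, `events`, `windows`,
#'   `movements` (the true movement intervals — the synthetic analogue of the
#'   audiovisual ground-truth annotation), `snr_db` (realised, per action),
#'   `spec`, `day`.
#' @export
synth_session <- function(spec, seed, day = 1L) {
  fs <- spec$fs
  acts <- spec$actions
  reps <- spec$repetitions
  occ <- list()
  if (reps > 0 && length(acts) > 0) {
    if (spec$order == "blocked") {
      for (ia in seq_along(acts)) for (r in seq_len(reps))
        occ[[length(occ) + 1L]] <- c(ia, r)
    } else {
      for (r in seq_len(reps)) for (ia in seq_along(acts))
        occ[[length(occ) + 1L]] <- c(ia, r)
    }
  }
  t <- 0
  t_instr <- numeric(length(occ))
  for (k in seq_along(occ)) {
    ia <- occ[[k]][1]
    t <- t + spec$relax_dur + spec$prepare_dur
    t_instr[k] <- t
    t <- t + 2 * acts[[ia]]$nominal_duration + spec$gap_dur
  }
  total <- t + spec$relax_dur  # trailing rest
  n <- round(total * fs)
  events <- emg_events(
    t_instruction_s = t_instr,
    action = vapply(occ, function(o) acts[[o[1]]]$action, ""),
    nominal_duration_s = vapply(occ, function(o)
      acts[[o[1]]]$nominal_duration, 0))
  windows <- build_action_windows(events, span = c(0, total))

  mv_start <- mv_end <- numeric(length(occ))
  mv_label <- character(length(occ))

  bg <- with_seed(derive_seed(seed, 1L),
                  stats::rnorm(n, sd = spec$noise_floor) +
                    spec$lowfreq_level *
                      shaped_noise(n, fs, spec$lowfreq_band))

  bp <- filter_spec("bandpass", c(20, min(500, 0.95 * fs / 2)),
                    phase = "zero_phase")
  fbg2 <- bandpass_emg(emg_recording(bg, fs), bp)$samples^2

  tracks <- vector("list", length(acts))
  gains <- numeric(length(acts))
  for (ia in seq_along(acts)) {
    m <- acts[[ia]]
    tr <- numeric(n)
    for (k in seq_along(occ)) {
      if (occ[[k]][1] != ia) next
      r <- occ[[k]][2]
      sub <- derive_seed(seed, 100L + ia, r)
      par <- with_seed(derive_seed(sub, 7L), c(
        stats::runif(1, 1 - spec$amp_jitter, 1 + spec$amp_jitter),
        stats::runif(1, spec$reaction_delay[1], spec$reaction_delay[2])))
      burst <- synth_burst(m, spec$sources, fs, seed = sub, effort = par[1],
                           sync = spec$sync_level)
      i0 <- round((t_instr[k] + par[2]) * fs) + 1L
      i1 <- min(n, i0 + length(burst) - 1L)
      tr[i0:i1] <- tr[i0:i1] + burst[seq_len(i1 - i0 + 1L)]
      mv_start[k] <- t_instr[k] + par[2]
      mv_end[k] <- mv_start[k] + m$nominal_duration
      mv_label[k] <- m$action
    }
    tracks[[ia]] <- tr
    if (reps > 0) {
      aw <- windows[windows$label == m$action, , drop = FALSE]
      msk <- window_mask(n, fs, aw)
      p_noise <- mean(fbg2[msk])
      ftr2 <- bandpass_emg(emg_recording(tr, fs), bp)$samples^2
      p_burst <- mean(ftr2[msk])
      R <- 10^(m$target_snr_db / 10)
      if (R <= 1)
        stop("infeasible SNR: target at or below the noise floor")
      gains[ia] <- sqrt((R - 1) * p_noise / p_burst)
    }
  }
  x <- bg
  for (ia in seq_along(acts)) x <- x + gains[ia] * tracks[[ia]]
  x <- x * spec$day_gains[day]
  rec <- emg_recording(x, fs = fs, channel_name = "semg",
                       muscle_site = spec$muscle_site,
                       participant_id = spec$participant_id)
  snr <- if (reps > 0) measure_snr(rec, windows) else NULL
  movements <- data.frame(start = mv_start, end = mv_end, label = mv_label,
                          stringsAsFactors = FALSE)
  structure(list(recording = rec, events = events, windows = windows,
                 movements = movements, snr_db = snr, spec = spec, day = day),
            class = "sim_session")
}

#' @export
print.sim_session <- function(x, ...) {
  cat(sprintf("<sim_session> day %d: %d events, %.1f s @ %g Hz\n",
              x$day, nrow(x$events), recording_duration(x$recording),
              x$recording$fs))
  if (!is.null(x$snr_db))
    cat("  realised SNR (dB):",
        paste(sprintf("%s=%.2f", names(x$snr_db), x$snr_db), collapse = ", "),
        "\n")
  invisible(x)
}
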