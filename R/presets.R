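#' Built-in acquisition-protocol presets
#'
#' Three ready-made [protocol_spec()]s emulating the acquisition settings the
#' classifiers target:
#'
#' * `protocol_a` — able-bodied protocol: trapezius descendens sensor at
#'   10 kHz, on-screen instructions in blocked trials (relax 2 s, prepare
#'   2 s, act), 12 repetitions of five actions. Quick shoulder raise (SR,
#'   direct source, SNR 6 dB), shoulder forward (SF, distant low-band
#'   crosstalk, SNR 2.5 dB), shoulder backward (SB, nearby mid-band
#'   crosstalk, SNR 4 dB), raise-and-hold (SRH, slower isometric recruitment
#'   at reduced effort) and object raise (OR, mixed sources, slow double
#'   bump). Effort varied by ±30% per repetition, as instructed in that
#'   protocol. Analysis decimates by 4 and strides 10 ms.
#' * `protocol_b_p2` — tetraplegic participant, platysma sensor at 2.15 kHz,
#'   verbal instructions interleaving platysma contraction (PC, direct,
#'   SNR 9 dB) and shoulder raise (SR, attenuated low-band crosstalk from the
#'   trapezius, SNR 4.5 dB), 15 occurrences of each per day over two days
#'   whose sensor gains differ (skin permittivity / placement). Long rest
#'   intervals reproduce the recorded no-action : action sample ratio
#'   (~11.5 : 1).
#' * `protocol_b_p1` — tetraplegic participant with weak trapezius control:
#'   trapezius sensor, SR attempts only, very low SNR (2 dB).
#'
#' @param name Preset name.
#' @return A `protocol_spec`.
#' @export
protocol_preset <- function(name = c("protocol_a", "protocol_b_p2",
                                     "protocol_b_p1")) {
  name <- match.arg(name)
  switch(name,
    protocol_a = protocol_spec(
      fs = 10000,
      sources = list(
        trapezius_fast = source_profile("trapezius_fast", c(210, 330)),
        trapezius_slow = source_profile("trapezius_slow", c(30, 55)),
        girdle = source_profile("girdle", c(130, 220)),
        distant = source_profile("distant", c(70, 130))),
      actions = list(
        movement_spec("SR", 1.0, "quick", c(trapezius_fast = 1),
                      target_snr_db = 6),
        movement_spec("SF", 1.0, "quick", c(distant = 1),
                      target_snr_db = 2.5),
        movement_spec("SB", 1.0, "quick", c(girdle = 1),
                      target_snr_db = 5),
        movement_spec("SRH", 2.0, "hold", c(trapezius_slow = 1),
                      target_snr_db = 2.5),
        movement_spec("OR", 2.0, "object",
                      c(trapezius_slow = 0.95, distant = 0.2),
                      target_snr_db = 3)),
      repetitions = 12L, relax_dur = 2, prepare_dur = 2, gap_dur = 0.7,
      noise_floor = 1, lowfreq_level = 3, lowfreq_band = c(20, 40),
      order = "blocked", amp_jitter = 0.3, sync_level = 0.8,
      decim_factor = 4L, stride = 0.01,
      muscle_site = "trapezius_descendens", participant_id = "sim_able"),
    protocol_b_p2 = protocol_spec(
      fs = 2150,
      sources = list(
        platysma = source_profile("platysma", c(70, 240)),
        trapezius_crosstalk = source_profile("trapezius_crosstalk",
                                             c(35, 150))),
      actions = list(
        movement_spec("PC", 1.0, "graded", c(platysma = 1),
                      target_snr_db = 9),
        movement_spec("SR", 1.0, "graded", c(trapezius_crosstalk = 1),
                      target_snr_db = 5.5)),
      repetitions = 15L, relax_dur = 2, prepare_dur = 2, gap_dur = 18.9,
      noise_floor = 1.5, lowfreq_level = 9.45, lowfreq_band = c(20, 40),
      order = "interleaved", amp_jitter = 0.5, sync_level = 0.85,
      n_days = 2L, day_gains = c(1, 0.8),
      decim_factor = 1L, stride = 0.01,
      muscle_site = "platysma", participant_id = "sim_P2"),
    protocol_b_p1 = protocol_spec(
      fs = 2150,
      sources = list(
        trapezius_weak = source_profile("trapezius_weak", c(40, 100))),
      actions = list(
        movement_spec("SR", 1.0, "graded", c(trapezius_weak = 1),
                      target_snr_db = 2)),
      repetitions = 5L, relax_dur = 2, prepare_dur = 2, gap_dur = 12,
      noise_floor = 1.5, lowfreq_level = 9.45, lowfreq_band = c(20, 40),
      order = "blocked", amp_jitter = 0.2, sync_level = 0.75,
      n_days = 2L, day_gains = c(1, 0.9),
      decim_factor = 1L, stride = 0.02,
      muscle_site = "trapezius_descendens", participant_id = "sim_P1"))
}

#' Simulate every day of a preset protocol
#'
#' @param name Preset name (see [protocol_preset()]).
#' @param seed Master integer seed.
#' @return List of `sim_session`, one per day.
#' @export
simulate_preset <- function(name, seed) {
  spec <- protocol_preset(name)
  lapply(seq_len(spec$n_days), function(d)
    synth_session(spec, seed = derive_seed(seed, 9000L + d), day = d))
}

#' Condition a session's recording and extract its feature track
#'
#' Runs the standard chain — 20--500 Hz band-pass at the native rate,
#' decimation per the protocol, sliding Welch features at the protocol's
#' stride — on a simulated session (or on a recording with explicit
#' settings).
#'
#' @param x A `sim_session` or `emg_recording`.
#' @param decim_factor Decimation factor (taken from the session's protocol
#'   when `x` is a session).
#' @param stride Analysis stride in seconds (likewise).
#' @param welch Optional [welch_spec()] overriding everything but the stride.
#' @return A `feature_track`.
#' @export
session_features <- function(x, decim_factor = NULL, stride = NULL,
                             welch = NULL) {
  if (inherits(x, "sim_session")) {
    if (is.null(decim_factor)) decim_factor <- x$spec$decim_factor
    if (is.null(stride)) stride <- x$spec$stride
    x <- x$recording
  }
  if (is.null(decim_factor)) decim_factor <- 1L
  if (is.null(stride)) stride <- 0.01
  ny <- x$fs / (2 * max(1L, decim_factor))
  cond <- preprocess_emg(
    x, band = filter_spec("bandpass", c(20, min(500, 0.95 * ny))),
    decim = if (decim_factor > 1L) decimation_spec(decim_factor))
  spec <- if (is.null(welch)) welch_spec(stride = stride) else {
    welch$stride <- stride
    welch
  }
  sliding_features(cond, spec)
}
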