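#' Specify a Butterworth filter
#'
#' @param kind `"bandpass"` or `"lowpass"`.
#' @param cutoffs Corner frequency(ies) in Hz: two ascending values for a
#'   band-pass, one for a low-pass.
#' @param order Analog prototype order (default 4, the order used for both
#'   the 20--500 Hz EMG band-pass and the 2 Hz envelope low-pass).
#' @param phase `"causal"` single-pass filtering (suited to online use) or
#'   `"zero_phase"` forward-backward filtering for offline analysis.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(kind = c("bandpass", "lowpass"), cutoffs,
                        order = 4L, phase = c("causal", "zero_phase")) {
  kind <- match.arg(kind)
  phase <- match.arg(phase)
  cutoffs <- as.numeric(cutoffs)
  if (any(!is.finite(cutoffs)) || any(cutoffs <= 0))
    stop("filter parameter error: cutoffs must be positive and finite")
  if (kind == "bandpass") {
    if (length(cutoffs) != 2L || diff(cutoffs) <= 0)
      stop("filter parameter error: bandpass needs two ascending cutoffs")
  } else if (length(cutoffs) != 1L) {
    stop("filter parameter error: lowpass needs one cutoff")
  }
  if (order < 1L) stop("filter parameter error: order must be >= 1")
  structure(list(kind = kind, cutoffs = cutoffs, order = as.integer(order),
                 family = "butterworth", phase = phase),
            class = "filter_spec")
}

#' Specify FIR decimation
#'
#' @param factor Integer downsampling ratio (>= 1).
#' @param fir_order Order of the anti-alias FIR filter (default 80).
#' @return A `decimation_spec` list.
#' @export
decimation_spec <- function(factor = 4L, fir_order = 80L) {
  factor <- as.integer(factor)
  fir_order <- as.integer(fir_order)
  if (is.na(factor) || factor < 1L)
    stop("decimation parameter error: factor must be >= 1")
  if (is.na(fir_order) || fir_order < 1L)
    stop("decimation parameter error: fir_order must be >= 1")
  structure(list(factor = factor, fir_order = fir_order),
            class = "decimation_spec")
}

# Butterworth coefficients for a spec at sampling rate fs (bilinear design).
butter_coeffs <- function(spec, fs) {
  ny <- fs / 2
  if (any(spec$cutoffs >= ny))
    stop("filter parameter error: cutoff at or above Nyquist (", ny, " Hz)")
  w <- spec$cutoffs / ny
  type <- if (spec$kind == "bandpass") "pass" else "low"
  signal::butter(spec$order, w, type = type)
}

# Causal IIR filtering with startup-transient suppression: the input is
# padded in front with a constant run of its first sample long enough for the
# filter's step response to settle, so the filter effectively starts from the
# step steady state.
causal_filter <- function(ba, x, fs, lowest_hz) {
  npad <- min(length(x), ceiling(fs * max(2 / lowest_hz, 0.5)) * 3L)
  xp <- c(rep(x[1], npad), x)
  yp <- as.numeric(signal::filter(ba, xp))
  yp[(npad + 1L):length(yp)]
}

apply_butter <- function(r, spec) {
  ba <- butter_coeffs(spec, r$fs)
  lowest <- min(spec$cutoffs)
  y <- if (spec$phase == "zero_phase") {
    as.numeric(signal::filtfilt(ba, r$samples))
  } else {
    causal_filter(ba, r$samples, r$fs, lowest)
  }
  out <- r
  out$samples <- y
  out
}

#' Band-pass filter an sEMG recording
#'
#' Applies the Butterworth band-pass (default corners 20 and 500 Hz, order 4)
#' that isolates the informative EMG band before spectral analysis.
#'
#' @param r An `emg_recording`.
#' @param spec A band-pass [filter_spec()].
#' @return A filtered `emg_recording` with unchanged length and `fs`.
#' @export
bandpass_emg <- function(r, spec = filter_spec("bandpass", c(20, 500))) {
  stopifnot(inherits(r, "emg_recording"), inherits(spec, "filter_spec"))
  if (spec$kind != "bandpass")
    stop("filter parameter error: bandpass_emg needs a bandpass spec")
  apply_butter(r, spec)
}

#' Extract the EMG envelope
#'
#' Full-wave rectifies the (band-limited) signal and low-pass filters it
#' (default 2 Hz, 4th-order Butterworth). The envelope tracks contraction
#' intensity; for a stationary burst its plateau approximates the rectified
#' mean of the signal. It is provided for visualisation and is not an input
#' to the classifiers.
#'
#' @param r A band-passed `emg_recording`.
#' @param lp A low-pass [filter_spec()].
#' @return An `emg_recording` holding the envelope.
#' @export
envelope_emg <- function(r, lp = filter_spec("lowpass", 2)) {
  stopifnot(inherits(r, "emg_recording"), inherits(lp, "filter_spec"))
  if (lp$kind != "lowpass")
    stop("filter parameter error: envelope_emg needs a lowpass spec")
  rect <- r
  rect$samples <- abs(r$samples)
  apply_butter(rect, lp)
}

#' Decimate a recording with an anti-alias FIR filter
#'
#' Low-pass filters with a linear-phase FIR (cutoff at the new Nyquist
#' frequency) and keeps every `factor`-th sample. The FIR group delay is
#' compensated so the output stays aligned with the input time axis. With
#' `factor = 1` the input is returned untouched.
#'
#' @param r An `emg_recording`.
#' @param spec A [decimation_spec()].
#' @return An `emg_recording` with `fs / factor` sampling rate and
#'   `ceiling(n / factor)` samples.
#' @export
decimate_emg <- function(r, spec = decimation_spec()) {
  stopifnot(inherits(r, "emg_recording"), inherits(spec, "decimation_spec"))
  if (spec$factor == 1L) return(r)
  n <- length(r$samples)
  h <- signal::fir1(spec$fir_order, 1 / spec$factor)
  half <- (length(h) - 1L) %/% 2L
  xp <- c(rep(r$samples[1], half), r$samples,
          rep(r$samples[n], length(h) - 1L - half))
  y <- stats::filter(xp, h, method = "convolution", sides = 1)
  y <- as.numeric(y)[length(h):(length(h) + n - 1L)]
  out <- r
  out$samples <- y[seq(1L, n, by = spec$factor)]
  out$fs <- r$fs / spec$factor
  out
}

#' Standard signal conditioning chain
#'
#' Band-pass filtering followed by optional decimation, in that order (the
#' band-pass runs at the native rate). This is the conditioning applied
#' before feature extraction; envelope extraction is separate
#' ([envelope_emg()]) and feeds visualisation only.
#'
#' @param r An `emg_recording`.
#' @param band A band-pass [filter_spec()].
#' @param decim A [decimation_spec()], or `NULL` to skip decimation.
#' @return The conditioned `emg_recording`.
#' @export
preprocess_emg <- function(r, band = filter_spec("bandpass", c(20, 500)),
                           decim = NULL) {
  out <- bandpass_emg(r, band)
  if (!is.null(decim)) out <- decimate_emg(out, decim)
  out
}
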