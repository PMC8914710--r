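#' Specify Welch PSD estimation and sliding-window feature extraction
#'
#' Defaults mirror the analysis settings the classifiers are built on: a
#' 0.2 s trailing analysis window, 0.05 s Hann-tapered segments with 50%
#' overlap, and a PSD bin spacing no coarser than 8 Hz (obtained by
#' zero-padding the segment FFT).
#'
#' @param window_dur Analysis window length (s).
#' @param segment_dur Welch segment length (s).
#' @param overlap_frac Segment overlap fraction in `[0, 1)`.
#' @param target_resolution Upper bound on PSD bin spacing (Hz).
#' @param stride Hop between consecutive analysis windows (s).
#' @param band Frequency band (Hz) over which the four features are computed.
#' @param feature_variant `"frequency"` for mean/median *frequency* (spectral
#'   centroid and half-power frequency, the standard EMG descriptors) or
#'   `"amplitude"` for the mean/median of the PSD amplitudes themselves.
#' @return A `welch_spec` list.
#' @export
welch_spec <- function(window_dur = 0.2, segment_dur = 0.05,
                       overlap_frac = 0.5, target_resolution = 8,
                       stride = 0.01, band = c(20, 500),
                       feature_variant = c("frequency", "amplitude")) {
  feature_variant <- match.arg(feature_variant)
  if (overlap_frac < 0 || overlap_frac >= 1)
    stop("welch parameter error: overlap_frac must be in [0, 1)")
  if (segment_dur > window_dur)
    stop("welch parameter error: segment_dur must be <= window_dur")
  if (stride <= 0) stop("welch parameter error: stride must be > 0")
  if (target_resolution <= 0)
    stop("welch parameter error: target_resolution must be > 0")
  structure(list(window_dur = window_dur, segment_dur = segment_dur,
                 overlap_frac = overlap_frac,
                 target_resolution = target_resolution, stride = stride,
                 band = as.numeric(band), feature_variant = feature_variant),
            class = "welch_spec")
}

# Smallest 5-smooth integer >= n. R's mixed-radix FFT degrades badly on
# prime lengths, so the zero-padded FFT length snaps up to the next length
# with factors {2, 3, 5} only; the bin spacing stays <= the target.
next_fast_len <- function(n) {
  n <- as.integer(ceiling(n))
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

welch_geometry <- function(fs, spec) {
  L <- max(2L, round(spec$segment_dur * fs))
  hop <- max(1L, L - floor(spec$overlap_frac * L))
  nfft <- next_fast_len(max(L, fs / spec$target_resolution))
  nf <- nfft %/% 2L + 1L
  win <- 0.5 * (1 - cos(2 * pi * (0:(L - 1L)) / L))  # periodic Hann
  scale <- 1 / (fs * sum(win^2))
  list(L = L, hop = hop, nfft = nfft, nf = nf, win = win, scale = scale,
       freqs = (0:(nf - 1L)) * fs / nfft)
}

# Core Welch engine: `segs` is an L x (nseg * nwin) matrix of raw segments
# (consecutive blocks of nseg columns belong to one analysis window).
# Returns the nf x nwin matrix of one-sided PSDs (uV^2/Hz).
welch_core <- function(segs, nseg, geom) {
  L <- geom$L
  segs <- segs - rep(colMeans(segs), each = L)  # per-segment detrend
  segs <- segs * geom$win
  if (geom$nfft > L)
    segs <- rbind(segs, matrix(0, geom$nfft - L, ncol(segs)))
  A2 <- abs(stats::mvfft(segs)[seq_len(geom$nf), , drop = FALSE])^2
  nwin <- ncol(segs) / nseg
  P <- if (nseg == 1L) A2 else {
    M <- matrix(0, nseg * nwin, nwin)
    M[cbind(seq_len(nseg * nwin), rep(seq_len(nwin), each = nseg))] <- 1 / nseg
    A2 %*% M
  }
  P <- P * geom$scale
  P[2:(geom$nf - 1L), ] <- 2 * P[2:(geom$nf - 1L), ]
  if (geom$nfft %% 2L == 1L) P[geom$nf, ] <- 2 * P[geom$nf, ]
  P
}

#' Welch power spectral density of one sample window
#'
#' Averages Hann-tapered, mean-detrended, 50%-overlapped segment
#' periodograms, zero-padded so the bin spacing does not exceed
#' `target_resolution`. The one-sided density is normalised so that its
#' integral over frequency approximates the signal variance (Parseval).
#'
#' @param x Numeric sample window.
#' @param fs Sampling rate (Hz).
#' @param spec A [welch_spec()] (only the segment fields are used).
#' @return A `psd_estimate` list with `freqs` (Hz) and `power` (µV²/Hz).
#' @export
welch_psd <- function(x, fs, spec = welch_spec()) {
  geom <- welch_geometry(fs, spec)
  x <- as.numeric(x)
  if (length(x) < geom$L)
    stop("welch parameter error: window shorter than one segment")
  off <- seq(1L, length(x) - geom$L + 1L, by = geom$hop)
  segs <- matrix(x[outer(0:(geom$L - 1L), off, "+")], nrow = geom$L)
  P <- welch_core(segs, length(off), geom)
  structure(list(freqs = geom$freqs, power = as.numeric(P)),
            class = "psd_estimate")
}

band_indices <- function(freqs, band) {
  which(freqs >= band[1] & freqs <= band[2])
}

#' Band power by trapezoidal integration of a PSD
#'
#' @param p A `psd_estimate`.
#' @param band `c(lo, hi)` in Hz; defaults to the 20--500 Hz EMG band. PSD
#'   values at the band edges are linearly interpolated.
#' @return Band power in µV².
#' @export
total_power <- function(p, band = c(20, 500)) {
  band <- as.numeric(band)
  if (length(band) != 2L || band[2] <= band[1])
    stop("band parameter error: need band = c(lo, hi) with hi > lo")
  lo <- max(band[1], min(p$freqs)); hi <- min(band[2], max(p$freqs))
  if (hi <= lo) stop("band parameter error: band outside PSD support")
  keep <- p$freqs > lo & p$freqs < hi
  f <- c(lo, p$freqs[keep], hi)
  y <- c(stats::approx(p$freqs, p$power, lo)$y, p$power[keep],
         stats::approx(p$freqs, p$power, hi)$y)
  sum(diff(f) * (y[-1] + y[-length(y)]) / 2)
}

#' Mean (power-weighted) frequency of a PSD
#'
#' The spectral centroid `sum(f * P) / sum(P)` over the PSD bins (optionally
#' restricted to a band). Returns `NaN` for an all-zero PSD; callers flag and
#' substitute 0.
#'
#' @param p A `psd_estimate`.
#' @param band Optional `c(lo, hi)` restriction (Hz).
#' @return Mean frequency in Hz.
#' @export
mean_frequency <- function(p, band = NULL) {
  idx <- if (is.null(band)) seq_along(p$freqs) else band_indices(p$freqs, band)
  tot <- sum(p$power[idx])
  if (tot <= 0) return(NaN)
  sum(p$freqs[idx] * p$power[idx]) / tot
}

#' Median (half-power) frequency of a PSD
#'
#' Each bin's power is treated as uniformly spread over its width; the median
#' frequency is where the cumulative band power reaches half the total, with
#' linear interpolation inside the crossing bin. A point-mass PSD therefore
#' returns that bin's frequency exactly.
#'
#' @inheritParams mean_frequency
#' @return Median frequency in Hz.
#' @export
median_frequency <- function(p, band = NULL) {
  idx <- if (is.null(band)) seq_along(p$freqs) else band_indices(p$freqs, band)
  f <- p$freqs[idx]; pw <- p$power[idx]
  tot <- sum(pw)
  if (tot <= 0) return(NaN)
  if (length(f) == 1L) return(f)
  df <- f[2] - f[1]
  cum <- c(0, cumsum(pw))
  half <- tot / 2
  j <- findInterval(half, cum, left.open = TRUE)  # half in (cum[j], cum[j+1]]
  j <- min(max(j, 1L), length(f))
  (f[j] - df / 2) + (half - cum[j]) / pw[j] * df
}

#' Sliding-window frequency-domain features
#'
#' Slides a trailing analysis window across the recording (the window ending
#' at time `t` covers `[t - window_dur, t)`) and computes, from the Welch PSD
#' of each window, the four classification features: band power, PSD peak,
#' mean frequency and median frequency, all over `spec$band`. Windows with
#' zero band power yield an all-zero, flagged row.
#'
#' @param r A conditioned `emg_recording`.
#' @param spec A [welch_spec()].
#' @return A `feature_track`: a data frame with columns `t_s`, `total_power`,
#'   `psd_peak`, `mnf_hz`, `mdf_hz`, `flag`, carrying the spec and sampling
#'   metadata as attributes.
#' @export
sliding_features <- function(r, spec = welch_spec()) {
  stopifnot(inherits(r, "emg_recording"), inherits(spec, "welch_spec"))
  fs <- r$fs
  geom <- welch_geometry(fs, spec)
  win_n <- round(spec$window_dur * fs)
  stride_n <- max(1L, round(spec$stride * fs))
  N <- length(r$samples)
  if (N < win_n) {
    warning("recording shorter than the analysis window; empty feature track")
    return(empty_track(spec, fs))
  }
  starts <- seq(1L, N - win_n + 1L, by = stride_n)
  off <- seq(0L, win_n - geom$L, by = geom$hop)
  nseg <- length(off)
  band <- c(max(spec$band[1], 0), min(spec$band[2], max(geom$freqs)))
  bidx <- band_indices(geom$freqs, band)
  fb <- geom$freqs[bidx]
  # trapezoid weights over the band bins (band edges coincide with bins here)
  wtrap <- rep(0, length(bidx))
  if (length(bidx) > 1L) {
    d <- diff(fb)
    wtrap <- c(d / 2, 0) + c(0, d / 2)
  }
  seg_tmpl <- as.vector(outer(seq_len(geom$L), off, "+"))
  batch <- 64L
  nwin <- length(starts)
  tp <- pk <- mnf <- mdf <- numeric(nwin)
  df <- if (length(fb) > 1L) fb[2] - fb[1] else 0
  for (b in seq(1L, nwin, by = batch)) {
    j <- b:min(b + batch - 1L, nwin)
    segs <- matrix(r$samples[outer(seg_tmpl, starts[j] - 1L, "+")],
                   nrow = geom$L)
    P <- welch_core(segs, nseg, geom)[bidx, , drop = FALSE]
    tp[j] <- as.numeric(crossprod(P, wtrap))
    top <- max.col(t(P), ties.method = "first")
    pk[j] <- P[cbind(top, seq_along(j))]
    cs <- colSums(P)
    if (spec$feature_variant == "frequency") {
      mnf[j] <- as.numeric(crossprod(P, fb)) / cs
      for (kk in seq_along(j)) {
        pw <- P[, kk]
        tot <- cs[kk]
        if (tot <= 0) { mdf[j[kk]] <- NaN; next }
        cum <- c(0, cumsum(pw))
        half <- tot / 2
        jj <- min(max(findInterval(half, cum, left.open = TRUE), 1L),
                  length(fb))
        mdf[j[kk]] <- (fb[jj] - df / 2) + (half - cum[jj]) / pw[jj] * df
      }
    } else {
      mnf[j] <- colMeans(P)
      mdf[j] <- apply(P, 2, stats::median)
    }
  }
  flag <- !is.finite(mnf) | !is.finite(mdf) | tp <= 0
  tp[flag] <- 0; pk[flag] <- 0; mnf[flag] <- 0; mdf[flag] <- 0
  out <- data.frame(
    t_s = r$t0 + (starts - 1L + win_n) / fs,
    total_power = tp, psd_peak = pk, mnf_hz = mnf, mdf_hz = mdf,
    flag = flag)
  attr(out, "welch_spec") <- spec
  attr(out, "fs") <- fs
  class(out) <- c("feature_track", "data.frame")
  out
}

empty_track <- function(spec, fs) {
  out <- data.frame(t_s = numeric(0), total_power = numeric(0),
                    psd_peak = numeric(0), mnf_hz = numeric(0),
                    mdf_hz = numeric(0), flag = logical(0))
  attr(out, "welch_spec") <- spec
  attr(out, "fs") <- fs
  class(out) <- c("feature_track", "data.frame")
  out
}

#' Feature matrix of a feature track
#'
#' @param track A `feature_track`.
#' @return Numeric matrix with columns `total_power`, `psd_peak`, `mnf_hz`,
#'   `mdf_hz`.
#' @export
feature_matrix <- function(track) {
  as.matrix(track[, c("total_power", "psd_peak", "mnf_hz", "mdf_hz")])
}

#' Analysis-window midpoints of a feature track
#'
#' Windows are trailing, so the midpoint of the window ending at `t_s` is
#' `t_s - window_dur / 2`. Midpoints are the time stamps used to assign
#' feature vectors to ground-truth action windows.
#'
#' @param track A `feature_track`.
#' @return Numeric vector of midpoint times (s).
#' @export
track_midpoints <- function(track) {
  spec <- attr(track, "welch_spec")
  track$t_s - spec$window_dur / 2
}
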