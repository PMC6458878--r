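# Zero-phase Butterworth filtering.  Slopes are specified per pass in
# dB/octave and mapped to filter order at 6 dB/octave per order; the
# forward-backward (zero-phase) application doubles the attenuation, which
# matches the convention of specifying the per-pass slope.

slope_to_order <- function(slope_db_oct) {
  ord <- slope_db_oct / 6
  if (abs(ord - round(ord)) > 1e-9 || ord < 1)
    stop_input("slope %g dB/octave is not a multiple of 6", slope_db_oct)
  as.integer(round(ord))
}

# Butterworth high/low-pass as second-order sections: analog prototype
# poles with bilinear transform per conjugate pair.  Numerically robust at
# very low normalized cutoffs, where the expanded polynomial form is
# ill-conditioned.  Even orders only (the slopes used here give 4 and 8).
.butter_sos <- function(order, fc, srate, type = c("high", "low")) {
  type <- match.arg(type)
  if (order %% 2 != 0) stop_input("SOS design expects an even order")
  wc <- tan(pi * fc / srate)            # prewarped analog cutoff
  k <- seq_len(order / 2)
  theta <- pi * (2 * k - 1) / (2 * order) + pi / 2
  p_proto <- complex(modulus = 1, argument = theta)   # upper-half poles
  sections <- lapply(p_proto, function(p) {
    pp <- if (type == "low") wc * p else wc / p
    re <- Re(pp); m2 <- Mod(pp)^2
    a0 <- 1 - 2 * re + m2
    a <- c(1, (2 * m2 - 2) / a0, (1 + 2 * re + m2) / a0)
    b <- if (type == "low") m2 * c(1, 2, 1) / a0 else c(1, -2, 1) / a0
    list(b = b, a = a)
  })
  sections
}

.sos_response_db <- function(sections, srate, freqs) {
  z <- exp(1i * 2 * pi * freqs / srate)
  h <- rep(1 + 0i, length(z))
  for (s in sections) {
    num <- s$b[1] + s$b[2] / z + s$b[3] / z^2
    den <- s$a[1] + s$a[2] / z + s$a[3] / z^2
    h <- h * num / den
  }
  20 * log10(Mod(h))
}

# one-directional IIR pass on a time x channels matrix (vectorized over
# channels via stats::filter, which runs its C loop column-wise)
# zero-phase (forward-backward) filtering with odd-reflection padding,
# applied to all channels of a recording at once; flt is either a list of
# second-order sections or a single {b, a} filter
.apply_filtfilt <- function(rec, flt) {
  sections <- if (!is.null(flt$b)) list(list(b = flt$b, a = flt$a)) else flt
  n <- ncol(rec$samples)
  klen <- max(vapply(sections, function(s) max(length(s$b), length(s$a)), 0L))
  p <- min(n - 1, 3 * (klen - 1) * length(sections))
  bmat <- t(vapply(sections, function(s) c(s$b, rep(0, klen - length(s$b))),
                   numeric(klen)))
  amat <- t(vapply(sections, function(s) c(s$a, rep(0, klen - length(s$a))),
                   numeric(klen)))
  y <- .filtfilt_cascade_cpp(bmat, amat, t(rec$samples), as.integer(p))
  out <- rec
  out$samples <- t(y)
  rownames(out$samples) <- rec$channel_names
  out
}

#' Band-pass filter a recording
#'
#' Zero-phase Butterworth band-pass implemented as a high-pass and a
#' low-pass cascade so the two edges can carry different slopes (defaults:
#' 0.1 Hz at 24 dB/octave and 80 Hz at 48 dB/octave, i.e. single-pass
#' orders 4 and 8).  Each single-pass response is -3 dB at its cutoff; the
#' forward-backward application gives -6 dB at the cutoffs.
#'
#' @param rec An \code{\link{eeg_recording}}.
#' @param low,high Cutoff frequencies in Hz.
#' @param low_slope,high_slope Single-pass slopes in dB/octave.
#' @return The filtered recording.
#' @export
bandpass <- function(rec, low = 0.1, high = 80,
                     low_slope = 24, high_slope = 48) {
  nyq <- rec$srate / 2
  if (high >= nyq) stop_input("high cutoff %g Hz >= Nyquist %g Hz", high, nyq)
  if (low <= 0 || low >= high) stop_input("invalid cutoffs")
  # the expanded polynomial form is ill-conditioned for very low
  # normalized cutoffs; use second-order sections there, the cheaper
  # single polynomial pass elsewhere
  mk <- function(cut, slope, type) {
    if (cut / nyq < 0.01) .butter_sos(slope_to_order(slope), cut,
                                      rec$srate, type)
    else signal::butter(slope_to_order(slope), cut / nyq, type = type)
  }
  .apply_filtfilt(.apply_filtfilt(rec, mk(low, low_slope, "high")),
                  mk(high, high_slope, "low"))
}

#' Band-rejection (notch) filter a recording
#'
#' Zero-phase Butterworth band-stop filter, by default centered at 50 Hz
#' with 1 Hz bandwidth and a 24 dB/octave single-pass slope, used to remove
#' power-line noise.
#'
#' @param rec An \code{\link{eeg_recording}}.
#' @param center Center frequency in Hz.
#' @param bandwidth Stop-band width in Hz.
#' @param slope Single-pass slope in dB/octave.
#' @return The filtered recording.
#' @export
bandreject <- function(rec, center = 50, bandwidth = 1, slope = 24) {
  nyq <- rec$srate / 2
  edges <- c(center - bandwidth / 2, center + bandwidth / 2)
  if (edges[2] >= nyq) stop_input("rejection band reaches Nyquist")
  flt <- signal::butter(slope_to_order(slope), edges / nyq, type = "stop")
  .apply_filtfilt(rec, flt)
}

#' Magnitude response of the designed filters
#'
#' Single-pass Butterworth magnitude (dB) at given frequencies, for
#' verifying cutoff and roll-off behavior.
#'
#' @param type \code{"high"}, \code{"low"} or \code{"stop"}.
#' @param cutoff Cutoff (scalar) or band edges (length 2) in Hz.
#' @param slope Slope in dB/octave.
#' @param srate Sampling rate in Hz.
#' @param freqs Frequencies at which to evaluate (Hz).
#' @return Magnitude in dB at \code{freqs}.
#' @export
filter_response_db <- function(type, cutoff, slope, srate, freqs) {
  if (type %in% c("high", "low")) {
    sections <- .butter_sos(slope_to_order(slope), cutoff, srate, type)
    return(.sos_response_db(sections, srate, freqs))
  }
  flt <- signal::butter(slope_to_order(slope), cutoff / (srate / 2), type = type)
  z <- exp(1i * 2 * pi * freqs / srate)
  num <- vapply(z, function(zz) sum(flt$b * zz^(-(seq_along(flt$b) - 1))), 0i)
  den <- vapply(z, function(zz) sum(flt$a * zz^(-(seq_along(flt$a) - 1))), 0i)
  20 * log10(Mod(num / den))
}
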