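# Spectral quantification: Hamming-windowed 2 s FFT power with 1 s overlap,
# logarithmized per window and then averaged (log-then-average order), on a
# 0.5 Hz frequency grid.  Band power is the mean dB over the band's bins,
# inclusive on both edges.

#' Welch-style log-power spectrum
#'
#' Applies a Hamming window of \code{window_s} seconds with
#' \code{overlap_s} seconds overlap to each data segment, computes the FFT
#' power of every window as a power spectral density (uV^2/Hz), converts to
#' dB (10 log10) and averages the dB values over windows.  With 2 s windows
#' the frequency resolution is exactly 0.5 Hz.
#'
#' @param x An \code{\link{eeg_segments}} object or an
#'   \code{\link{eeg_recording}} (treated as one segment).
#' @param window_s Window length in seconds (default 2).
#' @param overlap_s Window overlap in seconds (default 1).
#' @return Object of class \code{"eeg_psd"}: \code{freqs} (Hz),
#'   \code{power_db} (channels x frequencies), \code{n_windows},
#'   \code{channel_names}, \code{eye_state}, \code{condition}.
#' @export
compute_psd <- function(x, window_s = 2, overlap_s = 1) {
  if (inherits(x, "eeg_recording"))
    x <- eeg_segments(list(x$samples), x$srate, x$channel_names,
                      eye_state = "EO")
  if (!inherits(x, "eeg_segments")) stop_input("x must be eeg_segments or eeg_recording")
  srate <- x$srate
  nwin <- round(window_s * srate)
  hop <- round((window_s - overlap_s) * srate)
  if (hop < 1) stop_input("overlap must be shorter than the window")
  win <- hamming_window(nwin)
  u <- sum(win^2)                      # window power for PSD normalization
  nf <- nwin %/% 2 + 1
  freqs <- seq(0, srate / 2, length.out = nf)
  nch <- length(x$channel_names)

  acc <- matrix(0, nch, nf)
  count <- 0
  for (seg in x$segments) {
    n <- ncol(seg)
    if (n < nwin) next
    starts <- seq(1, n - nwin + 1, by = hop)
    for (s in starts) {
      sub <- seg[, s:(s + nwin - 1), drop = FALSE] * rep(win, each = nch)
      ft <- stats::mvfft(t(sub))[seq_len(nf), , drop = FALSE]
      p <- 2 * (Mod(ft)^2) / (srate * u)
      p[1, ] <- p[1, ] / 2
      if (nwin %% 2 == 0) p[nf, ] <- p[nf, ] / 2
      acc <- acc + t(db(p))
      count <- count + 1
    }
  }
  if (count == 0) stop_input("no complete %g s window in the data", window_s)
  structure(list(freqs = freqs, power_db = acc / count, n_windows = count,
                 channel_names = x$channel_names,
                 eye_state = x$eye_state %||% NA_character_,
                 condition = x$condition %||% NA_character_),
            class = "eeg_psd")
}

#' @export
print.eeg_psd <- function(x, ...) {
  cat(sprintf("<eeg_psd: %d channels, %g-%g Hz (%g Hz bins), %d windows>\n",
              nrow(x$power_db), min(x$freqs), max(x$freqs),
              x$freqs[2] - x$freqs[1], x$n_windows))
  invisible(x)
}

#' Band power in dB
#'
#' Mean of the dB spectrum over all frequency bins f with
#' \code{low <= f <= high} (edges inclusive on the grid), then mean over the
#' requested channels.
#'
#' @param psd An \code{eeg_psd}.
#' @param band A \code{\link{band}} or numeric \code{c(low, high)}.
#' @param channels Channel labels (default: all).
#' @return Band power in dB (single number).
#' @export
band_power <- function(psd, band, channels = NULL) {
  sel_f <- psd$freqs >= band[[1]] - 1e-9 & psd$freqs <= band[[2]] + 1e-9
  if (!any(sel_f)) stop_input("band [%g, %g] contains no frequency bins",
                              band[[1]], band[[2]])
  channels <- channels %||% psd$channel_names
  idx <- match(channels, psd$channel_names)
  if (anyNA(idx)) stop_input("unknown channel(s): %s",
                             paste(channels[is.na(idx)], collapse = ", "))
  mean(rowMeans(psd$power_db[idx, sel_f, drop = FALSE]))
}

#' Estimate the individual alpha peak frequency (IAF)
#'
#' For every 2 s window the frequency of the local maximum of the
#' channel-mean log-power within the search range is located; the IAF is the
#' average of the per-window peak frequencies, rounded to the 0.5 Hz grid.
#' The default average is the median: near the edges of the search range
#' the per-window peak distribution is truncated, which biases the
#' arithmetic mean toward the center, while the median stays anchored on
#' the true peak.
#' To keep single-window estimation noise from producing spurious maxima on
#' peakless 1/f spectra, each window's spectrum is smoothed over 3 bins and
#' a local maximum only counts as a peak when it rises above the chord
#' between the search-range endpoints by \code{prominence_db}.  Windows
#' without such a peak are dropped; if more than half of the windows lack a
#' peak the estimate falls back to the spectral center of gravity over the
#' search range (method tag \code{"gravity-fallback"}).
#'
#' @param rec An \code{\link{eeg_recording}} (>= 30 s recommended) or
#'   \code{eeg_segments}.
#' @param search Search range in Hz (default \code{c(7, 13)}).
#' @param channels Channels averaged before peak picking (default: all).
#' @param prominence_db Minimum height of a window peak above the spectral
#'   chord (default 2.5 dB; high enough that estimation noise on a peakless
#'   1/f spectrum rarely qualifies, low enough to keep windows with weak
#'   genuine peaks).
#' @param average How the per-window peaks are combined:
#'   \code{"median"} (default, robust near the search-range edges) or
#'   \code{"mean"}.
#' @return Object of class \code{"iaf_estimate"} with \code{iaf},
#'   \code{per_window_peaks} and \code{method}
#'   (\code{"peak-mean"} or \code{"gravity-fallback"}).
#' @export
estimate_iaf <- function(rec, search = c(7, 13), channels = NULL,
                         prominence_db = 2.5,
                         average = c("median", "mean")) {
  average <- match.arg(average)
  if (inherits(rec, "eeg_recording"))
    segs <- eeg_segments(list(rec$samples), rec$srate, rec$channel_names,
                         eye_state = "EO")
  else segs <- rec
  srate <- segs$srate
  nwin <- round(2 * srate)
  hop <- round(1 * srate)
  win <- hamming_window(nwin)
  u <- sum(win^2)
  nf <- nwin %/% 2 + 1
  freqs <- seq(0, srate / 2, length.out = nf)
  channels <- channels %||% segs$channel_names
  idx <- match(channels, segs$channel_names)
  if (anyNA(idx)) stop_input("unknown channel(s)")
  in_range <- which(freqs >= search[1] - 1e-9 & freqs <= search[2] + 1e-9)

  peaks <- numeric(0)
  mean_db <- rep(0, nf); count <- 0
  for (seg in segs$segments) {
    n <- ncol(seg)
    if (n < nwin) next
    for (s in seq(1, n - nwin + 1, by = hop)) {
      sub <- seg[idx, s:(s + nwin - 1), drop = FALSE] *
        rep(win, each = length(idx))
      ft <- stats::mvfft(t(sub))[seq_len(nf), , drop = FALSE]
      p <- rowMeans(2 * (Mod(ft)^2) / (srate * u))
      pdb <- db(p)
      mean_db <- mean_db + pdb; count <- count + 1
      r <- pdb[in_range]
      if (length(r) >= 3) {
        # 3-bin smoothing tames single-window chi-square noise
        rs <- r
        rs[2:(length(r) - 1)] <- (r[-c(1, 2)] + r[-c(1, length(r))] +
                                    r[-((length(r) - 1):length(r))]) / 3
        chord <- seq(rs[1], rs[length(rs)], length.out = length(rs))
        interior <- 2:(length(rs) - 1)
        loc <- interior[rs[interior] > rs[interior - 1] &
                          rs[interior] > rs[interior + 1] &
                          rs[interior] - chord[interior] > prominence_db]
        if (length(loc))
          peaks <- c(peaks, freqs[in_range][loc[which.max(rs[loc])]])
      }
    }
  }
  if (count == 0) stop_input("no complete 2 s window in the data")
  mean_db <- mean_db / count

  if (length(peaks) > count / 2) {
    iaf <- round_to_grid(if (average == "median") stats::median(peaks)
                         else mean(peaks))
    method <- "peak-mean"
  } else {
    lin <- undb(mean_db[in_range])
    if (!any(is.finite(lin)) || sum(lin) <= 0)
      stop_input("no alpha peak found and center of gravity undefined")
    iaf <- round_to_grid(sum(freqs[in_range] * lin) / sum(lin))
    method <- "gravity-fallback"
  }
  structure(list(iaf = iaf, per_window_peaks = peaks, method = method,
                 search = search),
            class = "iaf_estimate")
}

#' @export
print.iaf_estimate <- function(x, ...) {
  cat(sprintf("<iaf_estimate: %.1f Hz (%s, %d window peaks)>\n",
              x$iaf, x$method, length(x$per_window_peaks)))
  invisible(x)
}

#' Alpha/delta band-power ratio
#'
#' Per channel, the ratio of rewarded-band dB power to inhibited-band dB
#' power; the per-channel ratios are then averaged over the requested
#' channels (ratio-then-average order).  The log-scale ratio is undefined
#' for non-positive denominator dB values; such channels raise an error.
#'
#' @param psd An \code{eeg_psd}.
#' @param reward Rewarded (individual alpha) band.
#' @param inhibit Inhibited band (default the fixed 3-4 Hz delta range).
#' @param channels Channels to average (default the four training
#'   electrodes FC1, FC2, F3, F4; pass \code{psd$channel_names} for all).
#' @return Ratio (dimensionless).
#' @export
alpha_delta_ratio <- function(psd, reward, inhibit = inhibit_band(),
                              channels = training_channels()) {
  idx <- match(channels, psd$channel_names)
  if (anyNA(idx)) stop_input("unknown channel(s): %s",
                             paste(channels[is.na(idx)], collapse = ", "))
  ratios <- vapply(channels, function(ch) {
    a <- band_power(psd, reward, ch)
    d <- band_power(psd, inhibit, ch)
    if (d <= 0)
      stop_input("non-positive inhibit-band dB on channel %s: log-scale ratio undefined", ch)
    a / d
  }, 0)
  mean(ratios)
}
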