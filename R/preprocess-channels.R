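# Bad-channel detection, spherical-spline interpolation and average
# referencing.

#' Detect bad channels
#'
#' Automated stand-in for visual channel inspection.  Flags channels that
#' are (a) dead: variance below an absolute floor or a vanishing fraction of
#' the median channel variance, (b) very noisy: robust z-score of
#' log-variance above a threshold, or (c) jumping: a step in the sliding
#' median exceeding a multiple of the channel's robust derivative scale.
#' Deterministic given the thresholds.  More than ten flagged channels
#' (~15\% of the montage) raises a dataset-rejection error.
#'
#' @param rec An \code{\link{eeg_recording}} with >= 60 s of data.
#' @param z_thresh Robust z threshold on log-variance (default 5).
#' @param dead_floor Absolute dead-channel variance floor in uV^2.
#' @param dead_rel Relative dead floor as a fraction of the median variance.
#' @param jump_mult Step threshold in multiples of the MAD of the channel
#'   derivative (default 20).
#' @param max_bad Dataset-rejection limit (default 10).
#' @return Character vector of flagged channel names.
#' @export
detect_bad_channels <- function(rec, z_thresh = 5, dead_floor = 1e-3,
                                dead_rel = 1e-6, jump_mult = 20,
                                max_bad = 10) {
  if (rec_duration(rec) < 60)
    stop_input("need at least 60 s of data for channel statistics")
  x <- rec$samples
  v <- apply(x, 1, stats::var)
  med_v <- stats::median(v)
  dead <- v < dead_floor | v < dead_rel * med_v

  lv <- log(pmax(v, 1e-300))
  mad_lv <- stats::mad(lv)
  zz <- if (mad_lv > 0) (lv - stats::median(lv)) / mad_lv else rep(0, length(lv))
  noisy <- zz > z_thresh

  # sliding-median step detector: compare medians of adjacent 1 s windows
  fs <- rec$srate
  wn <- max(1, round(fs))
  nb <- ncol(x) %/% wn
  jumpy <- rep(FALSE, nrow(x))
  if (nb >= 2) {
    for (ch in seq_len(nrow(x))) {
      m <- vapply(seq_len(nb), function(b)
        stats::median(x[ch, ((b - 1) * wn + 1):(b * wn)]), 0)
      step <- max(abs(diff(m)))
      s <- stats::mad(diff(x[ch, ]))
      jumpy[ch] <- s > 0 && step > jump_mult * s
    }
  }

  bad <- rec$channel_names[dead | noisy | jumpy]
  if (length(bad) > max_bad)
    stop_input("dataset rejected: %d bad channels exceed the limit of %d",
               length(bad), max_bad)
  bad
}

# Perrin-style spherical spline basis: g(x) = 1/(4 pi) sum (2n+1)/(n(n+1))^m P_n(x)
.spline_g <- function(x, m = 4, nterms = 20) {
  # Legendre polynomials by recurrence, accumulated for all x at once
  p_prev <- rep(1, length(x))   # P_0
  p_cur <- x                    # P_1
  acc <- (2 * 1 + 1) / (1 * 2)^m * p_cur
  for (n in 2:nterms) {
    p_next <- ((2 * n - 1) * x * p_cur - (n - 1) * p_prev) / n
    acc <- acc + (2 * n + 1) / (n * (n + 1))^m * p_next
    p_prev <- p_cur; p_cur <- p_next
  }
  acc / (4 * pi)
}

#' Interpolate channels by spherical splines
#'
#' Replaces the listed channels with spherical-spline interpolations from
#' the remaining channels, using idealized spherical electrode positions of
#' the 5/10 layout.  Non-interpolated channels are unchanged.  At most ten
#' channels may be interpolated.
#'
#' @param rec An \code{\link{eeg_recording}}.
#' @param channels Channel names to interpolate (may be empty).
#' @param m Spline stiffness (default 4).
#' @param lambda Ridge regularization of the spline system.
#' @return The recording with interpolated channels.
#' @export
interpolate_channels <- function(rec, channels, m = 4, lambda = 1e-5) {
  if (!length(channels)) return(rec)
  if (length(channels) > 10)
    stop_input("refusing to interpolate more than 10 channels")
  idx_bad <- match(channels, rec$channel_names)
  if (anyNA(idx_bad)) stop_input("unknown channel(s): %s",
                                 paste(channels[is.na(idx_bad)], collapse = ", "))
  pos <- electrode_positions(rec$channel_names)
  good <- setdiff(seq_along(rec$channel_names), idx_bad)
  if (length(good) < 4) stop_input("too few good channels for interpolation")

  cosang <- tcrossprod(pos)            # cos of angle between electrodes
  cosang <- pmin(pmax(cosang, -1), 1)
  G <- .spline_g(cosang[good, good, drop = FALSE], m = m)
  Gsolve <- rbind(cbind(G + diag(lambda, length(good)), 1),
                  c(rep(1, length(good)), 0))
  Gb <- .spline_g(cosang[idx_bad, good, drop = FALSE], m = m)

  data_good <- rec$samples[good, , drop = FALSE]
  rhs <- rbind(data_good, 0)
  coefs <- solve(Gsolve, rhs)          # (ngood+1) x time
  interp <- cbind(Gb, 1) %*% coefs
  out <- rec
  out$samples[idx_bad, ] <- interp
  out
}

#' Average-reference a recording, reintroducing the recording reference
#'
#' For FCz-referenced data the implicit reference is reintroduced as a zero
#' channel before computing and subtracting the per-sample mean over all
#' channels, yielding the 65-channel average-referenced montage.  The
#' operation is idempotent, and every column of the output sums to zero.
#'
#' @param rec An \code{\link{eeg_recording}}.
#' @param ref_channel Name of the implicit reference to reintroduce
#'   (default \code{"FCz"}; skipped if already present or if the recording
#'   is not referenced to it).
#' @return The re-referenced recording (reference \code{"average"}).
#' @export
rereference_average <- function(rec, ref_channel = "FCz") {
  x <- rec$samples
  names_out <- rec$channel_names
  if (identical(rec$reference, ref_channel) &&
      !(ref_channel %in% names_out)) {
    x <- rbind(x, 0)
    names_out <- c(names_out, ref_channel)
  }
  x <- sweep(x, 2, colMeans(x))
  out <- eeg_recording(x, rec$srate, names_out, reference = "average",
                       events = rec$events)
  out$artifacts <- rec$artifacts
  out
}
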