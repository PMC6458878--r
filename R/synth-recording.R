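# Spectral synthesis of resting-state EEG: inverse FFT of the subject's
# target amplitude spectrum with independent random phases per channel and
# per EO/EC block.  Analytically checkable by construction: the one-sided
# PSD of the synthesized signal equals the target spectrum in expectation.

#' Recording specification
#'
#' Describes the technical layout of a synthesized recording.  Defaults
#' match the resting-state protocol (64-channel cap referenced to FCz,
#' 1000 Hz, 8 minutes, alternating 30 s eyes-open/eyes-closed blocks); the
#' neurofeedback training montage is obtained with
#' \code{channels = training_channels(), srate = 250}.
#'
#' @param duration_s Recording length in seconds.
#' @param srate Sampling rate in Hz.
#' @param channels Channel labels.
#' @param reference Reference descriptor.
#' @param block_s Length of one EO/EC block in seconds (block durations are
#'   not prescribed by the protocol; 30 s is the package default).
#' @param eye_pattern \code{"alternating"} EO/EC blocks, or a single-state
#'   recording (\code{"EO_only"} / \code{"EC_only"}).
#' @param first_state First eye state of an alternating recording.
#' @param channel_db_jitter_sd Per-channel broadband gain jitter (dB).
#' @return Object of class \code{"recording_spec"}.
#' @export
recording_spec <- function(duration_s = 480, srate = 1000,
                           channels = montage_channels(include_ref = FALSE),
                           reference = "FCz",
                           block_s = 30,
                           eye_pattern = c("alternating", "EO_only", "EC_only"),
                           first_state = c("EO", "EC"),
                           channel_db_jitter_sd = 0.3) {
  eye_pattern <- match.arg(eye_pattern)
  first_state <- match.arg(first_state)
  stopifnot(duration_s > 0, srate > 0, block_s > 0, channel_db_jitter_sd >= 0)
  structure(list(duration_s = duration_s, srate = srate,
                 channels = channels, reference = reference,
                 block_s = block_s, eye_pattern = eye_pattern,
                 first_state = first_state,
                 channel_db_jitter_sd = channel_db_jitter_sd),
            class = "recording_spec")
}

# Gaussian signal with one-sided PSD P(f_k): x = Re IFFT of sqrt(N fs P / 2) e^{i phi}
.synth_block <- function(psd, n, srate) {
  nf <- length(psd)                      # n %/% 2 + 1 frequencies
  phi <- stats::runif(nf, 0, 2 * pi)
  Z <- sqrt(n * srate * psd / 2) * exp(1i * phi)
  Z[1] <- 0
  if (n %% 2 == 0) Z[nf] <- sqrt(n * srate * psd[nf]) * cos(phi[nf])
  full <- c(Z, Conj(Z[seq(nf - ifelse(n %% 2 == 0, 1, 0), 2)]))
  Re(stats::fft(full, inverse = TRUE)) / n
}

#' Synthesize a resting-state EEG recording
#'
#' Generates a colored-noise + oscillation mixture from a subject profile:
#' 1/f^chi background, a Gaussian alpha bump centered at the subject's true
#' alpha peak frequency (eyes-closed amplitude = eyes-open x
#' \code{ec_alpha_gain}), and an elevated delta bump.  Alpha and delta
#' amplitudes follow the profile's per-timepoint / per-condition cells
#' (training effect and WT-condition term).  EO/EC boundaries are written as
#' event markers.
#'
#' @param profile A \code{\link{generate_subject_profile}} result.
#' @param timepoint \code{"t1"}, \code{"t2"} or \code{"t3"}.
#' @param condition \code{"NT"} or \code{"WT"}.
#' @param spec A \code{\link{recording_spec}}.
#' @param seed Optional seed for reproducible phases.
#' @return An \code{\link{eeg_recording}}.
#' @export
synthesize_recording <- function(profile, timepoint = "t1", condition = "NT",
                                 spec = recording_spec(), seed = NULL) {
  timepoint <- match.arg(timepoint, c("t1", "t2", "t3"))
  condition <- match.arg(condition, c("NT", "WT"))
  if (!is.null(seed)) return(with_seed(seed,
    synthesize_recording(profile, timepoint, condition, spec)))

  n_total <- round(spec$duration_s * spec$srate)
  if (spec$eye_pattern == "alternating" &&
      spec$duration_s < 2 * spec$block_s)
    stop_input("duration (%g s) shorter than one EO/EC cycle (%g s)",
               spec$duration_s, 2 * spec$block_s)

  block_n <- round(spec$block_s * spec$srate)
  starts <- seq(1, n_total, by = block_n)
  states <- switch(spec$eye_pattern,
    EO_only = rep("EO", length(starts)),
    EC_only = rep("EC", length(starts)),
    alternating = {
      two <- if (spec$first_state == "EO") c("EO", "EC") else c("EC", "EO")
      rep(two, length.out = length(starts))
    })
  if (spec$eye_pattern != "alternating") { starts <- 1L; states <- states[1] }

  nch <- length(spec$channels)
  jit <- 10^(stats::rnorm(nch, 0, spec$channel_db_jitter_sd) / 20)
  samples <- matrix(0, nch, n_total)

  for (b in seq_along(starts)) {
    i0 <- starts[b]
    i1 <- if (b < length(starts)) starts[b + 1] - 1 else n_total
    nb <- i1 - i0 + 1
    freqs <- seq(0, spec$srate / 2, length.out = nb %/% 2 + 1)
    psd <- target_psd(profile, freqs, timepoint, condition, states[b])
    for (ch in seq_len(nch))
      samples[ch, i0:i1] <- jit[ch] * .synth_block(psd, nb, spec$srate)
  }

  events <- data.frame(sample = as.integer(starts),
                       label = paste0(states, "_start"),
                       stringsAsFactors = FALSE)
  eeg_recording(samples, spec$srate, spec$channels,
                reference = spec$reference, events = events)
}
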