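# Closed-loop neurofeedback session simulator: online band power on the
# 4-electrode training montage, artifact gating, a bounded monotone
# feedback mapping, and a deliberately minimal one-parameter learner.

#' Neurofeedback protocol specification
#'
#' @param iaf Individual alpha peak frequency (Hz) anchoring the reward
#'   band.
#' @param reward Reward band (default \code{\link{reward_band}(iaf)}).
#' @param inhibit Inhibit band (default 3-4 Hz).
#' @param electrodes Training electrodes.
#' @param srate Sampling rate (Hz, default 250).
#' @param session_s Session length in seconds (default 15 minutes).
#' @param chunk_s,hop_s Online window length and hop (s).
#' @param baseline_s Feedback-baseline accumulation period (s).
#' @param gate_ptp Peak-to-peak gate threshold in uV (NA = set from data).
#' @param gate_line_db 45-55 Hz gate threshold in dB (NA = set from data).
#' @return Object of class \code{"protocol_spec"}.
#' @export
protocol_spec <- function(iaf = 10, reward = reward_band(iaf),
                          inhibit = inhibit_band(),
                          electrodes = training_channels(),
                          srate = 250, session_s = 900,
                          chunk_s = 0.5, hop_s = 0.25, baseline_s = 30,
                          gate_ptp = NA, gate_line_db = NA) {
  if (session_s <= 0) stop_input("session_length must be positive")
  if (reward[["low"]] <= inhibit[["high"]] && reward[["high"]] >= inhibit[["low"]])
    stop_input("reward and inhibit bands must be disjoint")
  structure(as.list(environment()), class = "protocol_spec")
}

# Hamming-tapered one-sided PSD of the trailing chunk; chunks shorter than
# 1 s are zero-padded to a 1 Hz frequency grid.  Returns freqs and the
# nf x channels PSD matrix.
.chunk_psd <- function(buffer, srate, chunk_s) {
  n <- round(chunk_s * srate)
  if (ncol(buffer) < n)
    stop_input("buffer (%d samples) shorter than one %g s chunk",
               ncol(buffer), chunk_s)
  x <- buffer[, (ncol(buffer) - n + 1):ncol(buffer), drop = FALSE]
  win <- hamming_window(n)
  u <- sum(win^2)
  nfft <- max(n, round(srate))
  xw <- matrix(0, nfft, nrow(x))
  xw[seq_len(n), ] <- t(x * rep(win, each = nrow(x)))
  nf <- nfft %/% 2 + 1
  ft <- stats::mvfft(xw)[seq_len(nf), , drop = FALSE]
  p <- 2 * Mod(ft)^2 / (srate * u)
  p[1, ] <- p[1, ] / 2
  if (nfft %% 2 == 0) p[nf, ] <- p[nf, ] / 2
  list(freqs = seq(0, srate / 2, length.out = nf), p = p)
}

#' Online band power of the most recent chunk
#'
#' Causal band-power estimate: Hamming-tapered FFT power (PSD, dB) of the
#' trailing \code{chunk_s} seconds of the buffer, averaged over the band's
#' frequency bins per channel (in dB, matching \code{\link{band_power}})
#' and then over channels.  Chunks shorter than 1 s are zero-padded to a
#' 1 Hz grid.
#'
#' @param buffer Channels x time matrix of the most recent samples.
#' @param band Frequency band.
#' @param srate Sampling rate in Hz.
#' @param chunk_s Analysis chunk length in seconds.
#' @return Band power in dB.
#' @export
online_band_power <- function(buffer, band, srate = 250, chunk_s = 0.5) {
  ps <- .chunk_psd(buffer, srate, chunk_s)
  sel <- ps$freqs >= band[[1]] - 1e-9 & ps$freqs <= band[[2]] + 1e-9
  if (!any(sel)) stop_input("band contains no frequency bins at this chunk length")
  mean(colMeans(db(ps$p[sel, , drop = FALSE])))
}

# total linear band power in dB (used by the artifact gate, where empty
# bins must not drag a log-scale mean down)
.band_power_linear_db <- function(buffer, band, srate) {
  ps <- .chunk_psd(buffer, srate, ncol(buffer) / srate)
  sel <- ps$freqs >= band[[1]] - 1e-9 & ps$freqs <= band[[2]] + 1e-9
  df <- ps$freqs[2] - ps$freqs[1]
  db(mean(colSums(ps$p[sel, , drop = FALSE])) * df)
}

#' Artifact gate for online chunks
#'
#' Fires when the chunk's peak-to-peak amplitude exceeds the movement
#' threshold or when 45-55 Hz band power exceeds the line-noise threshold;
#' gated chunks are excluded from feedback.
#'
#' @param buffer Channels x time matrix (one chunk).
#' @param srate Sampling rate in Hz.
#' @param ptp_limit Peak-to-peak limit in uV.
#' @param line_limit_db 45-55 Hz power limit in dB.
#' @return \code{TRUE} if the chunk must be excluded from feedback.
#' @export
artifact_gate <- function(buffer, srate = 250, ptp_limit = Inf,
                          line_limit_db = Inf) {
  ptp <- max(apply(buffer, 1, function(ch) diff(range(ch))))
  if (ptp > ptp_limit) return(TRUE)
  if (is.finite(line_limit_db)) {
    lp <- .band_power_linear_db(buffer, c(45, 55), srate)
    if (lp > line_limit_db) return(TRUE)
  }
  FALSE
}

#' Learner state for the closed-loop simulation
#'
#' A minimal one-parameter learner: its alpha amplitude is modulated by a
#' gain that drifts in proportion to the time-averaged reward feedback.
#'
#' @param alpha_gain Initial multiplicative alpha-amplitude gain (> 0).
#' @param learning_rate Drift rate per second of above-midpoint speed.
#' @param noise SD of multiplicative gain noise per sqrt-second.
#' @return Object of class \code{"learner_state"}.
#' @export
learner_state <- function(alpha_gain = 1, learning_rate = 0, noise = 0) {
  if (alpha_gain <= 0) stop_input("alpha_gain must be positive")
  structure(list(alpha_gain = alpha_gain, learning_rate = learning_rate,
                 noise = noise), class = "learner_state")
}

#' One feedback step
#'
#' Maps the chunk's reward/inhibit band power to bounded feedback: ship
#' speed is a monotone increasing logistic of reward power minus a rolling
#' baseline; autopilot accuracy is monotone decreasing in inhibit power.
#' Gated chunks emit no band-power values and freeze the displayed
#' feedback.
#'
#' @param state Feedback state list (from \code{feedback_state()}): rolling
#'   baselines and last outputs.
#' @param buffer Channels x time chunk.
#' @param spec A \code{\link{protocol_spec}}.
#' @return List with the \code{sample} (time, powers, speed, accuracy,
#'   gated) and the updated \code{state}.
#' @export
feedback_step <- function(state, buffer, spec) {
  gated <- artifact_gate(buffer, spec$srate,
                         state$gate_ptp %||% Inf,
                         state$gate_line_db %||% Inf)
  if (gated) {
    sample <- list(reward_power = NA_real_, inhibit_power = NA_real_,
                   speed = state$last_speed, accuracy = state$last_accuracy,
                   gated = TRUE)
    return(list(sample = sample, state = state))
  }
  rp <- online_band_power(buffer, spec$reward, spec$srate, spec$chunk_s)
  ip <- online_band_power(buffer, spec$inhibit, spec$srate, spec$chunk_s)
  # rolling baseline: EWMA accumulated over the first baseline_s seconds
  if (state$t <= spec$baseline_s) {
    w <- 0.1
    state$base_r <- if (is.na(state$base_r)) rp else (1 - w) * state$base_r + w * rp
    state$base_i <- if (is.na(state$base_i)) ip else (1 - w) * state$base_i + w * ip
  }
  k <- 2  # dB softness of the logistic map
  speed <- stats::plogis((rp - state$base_r) / k)
  accuracy <- stats::plogis(-(ip - state$base_i) / k)
  state$last_speed <- speed
  state$last_accuracy <- accuracy
  list(sample = list(reward_power = rp, inhibit_power = ip, speed = speed,
                     accuracy = accuracy, gated = FALSE),
       state = state)
}

#' @rdname feedback_step
#' @export
feedback_state <- function(gate_ptp = Inf, gate_line_db = Inf) {
  list(base_r = NA_real_, base_i = NA_real_, t = 0,
       last_speed = 0.5, last_accuracy = 0.5,
       gate_ptp = gate_ptp, gate_line_db = gate_line_db)
}

#' Simulate one closed-loop neurofeedback session
#'
#' Synthesizes the learner's 4-channel EEG chunk by chunk from the subject
#' profile (alpha amplitude modulated by the learner's current gain), runs
#' the online band-power / gate / feedback loop, and lets the learner's
#' alpha gain drift proportionally to the time-averaged speed feedback.
#'
#' @param profile A \code{subject_profile}.
#' @param learner A \code{\link{learner_state}}.
#' @param spec A \code{\link{protocol_spec}}.
#' @param seed Optional seed.
#' @param blink_prob Probability of injecting a blink transient into a
#'   chunk (exercises the gate).
#' @return List with \code{log} (data frame: time, reward_power,
#'   inhibit_power, speed, autopilot_accuracy, gated), \code{learner}
#'   (final state), \code{gated_fraction}, and \code{all_gated} flag.
#' @export
simulate_session <- function(profile, learner, spec = protocol_spec(),
                             seed = NULL, blink_prob = 0) {
  if (!is.null(seed))
    return(with_seed(seed, simulate_session(profile, learner, spec,
                                            blink_prob = blink_prob)))
  n_chunk <- round(spec$chunk_s * spec$srate)
  nf <- n_chunk %/% 2 + 1
  freqs <- seq(0, spec$srate / 2, length.out = nf)
  base_psd_parts <- list(
    bg = ifelse(freqs > 0, profile$background_level /
                  pmax(freqs, 1e-6)^profile$background_exponent, 0),
    alpha = profile$alpha_amp^2 *
      exp(-(freqs - profile$iaf_true)^2 / (2 * profile$alpha_bump_sigma^2)),
    delta = profile$delta_amp^2 *
      exp(-(freqs - profile$delta_bump_center)^2 / (2 * profile$delta_bump_sigma^2)))
  nch <- length(spec$electrodes)

  # set gate thresholds from a short calibration stretch when not given
  calib <- .synth_block(base_psd_parts$bg + base_psd_parts$alpha +
                          base_psd_parts$delta, n_chunk, spec$srate)
  scale0 <- diff(range(calib))
  gate_ptp <- if (is.na(spec$gate_ptp)) 4 * scale0 else spec$gate_ptp
  gate_line <- if (is.na(spec$gate_line_db)) {
    .band_power_linear_db(matrix(calib, 1), c(45, 55), spec$srate) + 15
  } else spec$gate_line_db

  fstate <- feedback_state(gate_ptp, gate_line)
  times <- seq(0, spec$session_s - spec$chunk_s, by = spec$hop_s)
  log_rows <- vector("list", length(times))
  gain <- learner$alpha_gain
  for (i in seq_along(times)) {
    psd <- base_psd_parts$bg + gain^2 * base_psd_parts$alpha +
      base_psd_parts$delta
    chunk <- t(vapply(seq_len(nch), function(ch)
      .synth_block(psd, n_chunk, spec$srate), numeric(n_chunk)))
    if (blink_prob > 0 && stats::runif(1) < blink_prob) {
      shape <- 3 * gate_ptp *
        exp(-((seq_len(n_chunk) - n_chunk / 2)^2) / (2 * (n_chunk / 6)^2))
      chunk <- chunk + rep(shape, each = nch)
    }
    fstate$t <- times[i]
    step <- feedback_step(fstate, chunk, spec)
    fstate <- step$state
    s <- step$sample
    if (!s$gated && learner$learning_rate != 0) {
      # reinforcement abstraction: the gain drifts upward in proportion to
      # the reward feedback, faster when the display runs above midpoint
      drift <- learner$learning_rate * s$speed * spec$hop_s
      gain <- gain * exp(drift)
    }
    if (learner$noise > 0)
      gain <- gain * exp(stats::rnorm(1, 0, learner$noise * sqrt(spec$hop_s)))
    gain <- min(max(gain, 0.1), 10)   # bounded learner: gain stays physiologic
    log_rows[[i]] <- data.frame(time = times[i],
                                reward_power = s$reward_power,
                                inhibit_power = s$inhibit_power,
                                speed = s$speed,
                                autopilot_accuracy = s$accuracy,
                                gated = s$gated)
  }
  log <- do.call(rbind, log_rows)
  out_learner <- learner
  out_learner$alpha_gain <- gain
  list(log = log, learner = out_learner,
       gated_fraction = mean(log$gated),
       all_gated = all(log$gated))
}
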