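# Artifact injection with ground-truth annotations.  Amplitudes default to
# multiples of the recording's own robust scale so the artifact classes stay
# meaningful regardless of the absolute power calibration.

#' Artifact injection configuration
#'
#' @param blink_rate Blink transients per minute (frontal-dominant
#'   topography).
#' @param blink_amp Peak blink amplitude in uV; default 6 x the recording's
#'   median channel SD.
#' @param blink_dur_s Blink duration (s).
#' @param muscle_rate Broadband muscle bursts per minute (random channels).
#' @param muscle_amp Burst SD in uV; default 3 x median channel SD.
#' @param muscle_dur_s Burst duration (s).
#' @param line_amp 50 Hz line-noise amplitude in uV (0 = none); default
#'   scale-free absolute value.
#' @param n_dead Number of channels silenced ("dead").
#' @param n_jump Number of channels given a DC step ("jump").
#' @param jump_amp Step height in uV; default 12 x median channel SD.
#' @param seed Optional seed.
#' @return Object of class \code{"artifact_config"}.
#' @export
artifact_config <- function(blink_rate = 0, blink_amp = NULL, blink_dur_s = 0.3,
                            muscle_rate = 0, muscle_amp = NULL,
                            muscle_dur_s = 0.5,
                            line_amp = 0,
                            n_dead = 0, n_jump = 0, jump_amp = NULL,
                            seed = NULL) {
  stopifnot(blink_rate >= 0, muscle_rate >= 0, line_amp >= 0,
            n_dead >= 0, n_jump >= 0)
  structure(as.list(environment()), class = "artifact_config")
}

#' Inject artifacts into a recording
#'
#' Adds eye-blink transients (largest over the Fp/AF rows), broadband
#' muscle bursts on random channel subsets, 50 Hz line noise, and optional
#' dead and jump channels.  Every injected event is annotated in the
#' returned recording's \code{$artifacts} data frame (ground truth for
#' detector tests).  With all rates zero the input is returned unchanged.
#'
#' @param rec An \code{\link{eeg_recording}}.
#' @param config An \code{\link{artifact_config}}.
#' @return The recording with artifacts added and an \code{$artifacts}
#'   annotation table.
#' @export
inject_artifacts <- function(rec, config = artifact_config()) {
  if (config$blink_rate == 0 && config$muscle_rate == 0 &&
      config$line_amp == 0 && config$n_dead == 0 && config$n_jump == 0)
    return(rec)
  if (!is.null(config$seed)) {
    cfg <- config
    cfg$seed <- NULL
    return(with_seed(config$seed, inject_artifacts(rec, cfg)))
  }

  x <- rec$samples
  n <- ncol(x); nch <- nrow(x); fs <- rec$srate
  minutes <- n / fs / 60
  scale <- stats::median(apply(x, 1, stats::sd))
  ann <- list()
  add_ann <- function(type, channel, start, dur)
    ann[[length(ann) + 1]] <<- data.frame(type = type, channel = channel,
                                          start_sample = start,
                                          duration_samples = dur,
                                          stringsAsFactors = FALSE)

  if (config$blink_rate > 0) {
    w <- tryCatch(frontal_weights(rec$channel_names),
                  error = function(e) rep(1, nch))
    nb <- max(1, round(config$blink_rate * minutes))
    dur <- round(config$blink_dur_s * fs)
    amp <- config$blink_amp %||% (6 * scale)
    shape <- amp * exp(-((seq_len(dur) - dur / 2)^2) / (2 * (dur / 6)^2))
    for (s in sort(sample.int(n - dur, nb))) {
      x[, s:(s + dur - 1)] <- x[, s:(s + dur - 1)] + outer(w, shape)
      add_ann("blink", NA_character_, s, dur)
    }
  }
  if (config$muscle_rate > 0) {
    nm <- max(1, round(config$muscle_rate * minutes))
    dur <- round(config$muscle_dur_s * fs)
    amp <- config$muscle_amp %||% (3 * scale)
    for (s in sort(sample.int(n - dur, nm))) {
      chs <- sample.int(nch, min(3, nch))
      env <- sin(pi * seq_len(dur) / dur)
      for (ch in chs) {
        x[ch, s:(s + dur - 1)] <- x[ch, s:(s + dur - 1)] +
          amp * env * stats::rnorm(dur)
        add_ann("muscle", rec$channel_names[ch], s, dur)
      }
    }
  }
  if (config$line_amp > 0) {
    tt <- (seq_len(n) - 1) / fs
    for (ch in seq_len(nch)) {
      phi <- stats::runif(1, 0, 2 * pi)
      x[ch, ] <- x[ch, ] + config$line_amp * sin(2 * pi * 50 * tt + phi)
    }
    add_ann("line_noise", NA_character_, 1L, n)
  }
  special <- sample.int(nch, min(nch, config$n_dead + config$n_jump))
  dead <- utils::head(special, config$n_dead)
  jump <- utils::tail(special, length(special) - length(dead))
  for (ch in dead) {
    x[ch, ] <- stats::rnorm(n, 0, 1e-4)
    add_ann("dead", rec$channel_names[ch], 1L, n)
  }
  amp_j <- config$jump_amp %||% (12 * scale)
  for (ch in jump) {
    s <- sample.int(n, 1)
    x[ch, s:n] <- x[ch, s:n] + amp_j
    add_ann("jump", rec$channel_names[ch], s, n - s + 1L)
  }

  out <- rec
  out$samples <- x
  rownames(out$samples) <- rec$channel_names
  out$artifacts <- if (length(ann)) do.call(rbind, ann) else
    data.frame(type = character(), channel = character(),
               start_sample = integer(), duration_samples = integer())
  out
}
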