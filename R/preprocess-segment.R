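# Span rejection and EO/EC segmentation.

#' Reject high-amplitude spans
#'
#' Deterministic surrogate for visual rejection of residual vertical
#' artifacts: 1 s spans in which any channel exceeds the amplitude
#' threshold are dropped.  The threshold is either an absolute value in uV
#' or (default) a multiple of the recording's robust amplitude scale
#' (median channel MAD), which keeps the rule meaningful across absolute
#' power calibrations.
#'
#' @param rec An \code{\link{eeg_recording}}.
#' @param threshold_uv Absolute threshold in uV (overrides
#'   \code{threshold_sigma} when given).
#' @param threshold_sigma Threshold in robust-sigma units (default 8).
#' @param span_s Span length in seconds (default 1).
#' @return List with \code{recording} (spans replaced are *not* cut out of
#'   the continuous data; instead a keep-mask is returned for the
#'   segmentation step), \code{keep} (logical per sample), and
#'   \code{n_rejected} spans.
#' @export
reject_spans <- function(rec, threshold_uv = NULL, threshold_sigma = 8,
                         span_s = 1) {
  x <- rec$samples
  thr <- threshold_uv %||%
    (threshold_sigma * stats::median(apply(x, 1, stats::mad)))
  wn <- max(1, round(span_s * rec$srate))
  n <- ncol(x)
  keep <- rep(TRUE, n)
  n_rej <- 0L
  for (s in seq(1, n, by = wn)) {
    e <- min(n, s + wn - 1)
    if (max(abs(x[, s:e])) > thr) {
      keep[s:e] <- FALSE
      n_rej <- n_rej + 1L
    }
  }
  list(recording = rec, keep = keep, n_rejected = n_rej, threshold = thr)
}

#' Segment a recording into eyes-open and eyes-closed conditions
#'
#' Spans between \code{EO_start} / \code{EC_start} markers are assigned to
#' the matching eye state.  Trailing partial spans are kept if they are at
#' least one analysis window (2 s) long.  An optional keep-mask (from
#' \code{\link{reject_spans}}) removes rejected stretches; contiguous kept
#' runs shorter than one analysis window are dropped.
#'
#' @param rec An \code{\link{eeg_recording}} with eye-state events.
#' @param condition Condition tag carried into the output.
#' @param keep Optional logical per-sample keep-mask.
#' @param provenance Named list of provenance counters to attach.
#' @param min_s Minimum usable span length in seconds (default 2).
#' @return List with elements \code{EO} and \code{EC}, each an
#'   \code{\link{eeg_segments}} object (or \code{NULL} when the state does
#'   not occur).
#' @export
segment_eo_ec <- function(rec, condition = NA_character_, keep = NULL,
                          provenance = list(), min_s = 2) {
  ev <- rec$events[rec$events$label %in% c("EO_start", "EC_start"), ,
                   drop = FALSE]
  if (!nrow(ev)) stop_input("no EO/EC event markers in the recording")
  n <- ncol(rec$samples)
  keep <- keep %||% rep(TRUE, n)
  min_n <- round(min_s * rec$srate)

  bounds <- c(ev$sample, n + 1)
  out <- list(EO = list(), EC = list())
  for (i in seq_len(nrow(ev))) {
    state <- sub("_start", "", ev$label[i])
    s <- ev$sample[i]; e <- bounds[i + 1] - 1
    if (e - s + 1 < min_n) next
    km <- keep[s:e]
    r <- rle(km)
    pos <- cumsum(c(1, r$lengths))
    for (j in seq_along(r$values)) {
      if (!r$values[j] || r$lengths[j] < min_n) next
      a <- s + pos[j] - 1
      b <- a + r$lengths[j] - 1
      out[[state]] <- c(out[[state]],
                        list(rec$samples[, a:b, drop = FALSE]))
    }
  }
  mk <- function(state) {
    if (!length(out[[state]])) return(NULL)
    eeg_segments(out[[state]], rec$srate, rec$channel_names,
                 eye_state = state, condition = condition,
                 provenance = provenance)
  }
  list(EO = mk("EO"), EC = mk("EC"))
}
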