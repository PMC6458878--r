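#' Multichannel EEG recording container
#'
#' A light-weight container for a continuous multichannel EEG time series
#' with channel metadata, sampling rate, reference descriptor and eyes-open /
#' eyes-closed event markers.
#'
#' @param samples Numeric matrix, channels x time, in microvolts.
#' @param srate Sampling rate in Hz.
#' @param channel_names Character vector, one label per row of
#'   \code{samples}.
#' @param reference Reference descriptor, e.g. \code{"FCz"} for the
#'   recording montage, \code{"linked-earlobes"} for the training montage,
#'   or \code{"average"} after re-referencing.
#' @param events Data frame with columns \code{sample} (1-based latency) and
#'   \code{label} (e.g. \code{"EO_start"}, \code{"EC_start"}), sorted by
#'   latency.
#' @return Object of class \code{"eeg_recording"}.
#' @export
eeg_recording <- function(samples, srate, channel_names,
                          reference = "FCz",
                          events = data.frame(sample = integer(),
                                              label = character())) {
  if (!is.matrix(samples) || !is.numeric(samples))
    stop_input("samples must be a numeric channels x time matrix")
  if (length(channel_names) != nrow(samples))
    stop_input("channel_names length (%d) != number of rows (%d)",
               length(channel_names), nrow(samples))
  if (anyDuplicated(channel_names))
    stop_input("duplicate channel names")
  if (!is.numeric(srate) || length(srate) != 1 || srate <= 0)
    stop_input("srate must be a single positive number")
  if (!all(c("sample", "label") %in% names(events)))
    stop_input("events must have columns 'sample' and 'label'")
  if (is.unsorted(events$sample)) stop_input("events must be sorted by latency")
  rownames(samples) <- channel_names
  structure(list(samples = samples, srate = srate,
                 channel_names = as.character(channel_names),
                 reference = reference,
                 events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording: %d channels, %.1f s @ %g Hz, ref %s, %d events>\n",
              nrow(x$samples), ncol(x$samples) / x$srate, x$srate,
              x$reference, nrow(x$events)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An \code{eeg_recording}.
#' @return Duration in seconds.
#' @export
rec_duration <- function(rec) ncol(rec$samples) / rec$srate

#' Cleaned, segmented EEG data
#'
#' Holds the per-eye-state segments of a preprocessed recording together
#' with provenance counters of the cleaning actions taken.
#'
#' @param segments List of channels x time matrices sharing channel order
#'   and sampling rate.
#' @param srate Sampling rate in Hz.
#' @param channel_names Channel labels (including a reintroduced reference).
#' @param eye_state \code{"EO"} or \code{"EC"}.
#' @param condition Recording condition tag (e.g. \code{"NT"}, \code{"WT"}).
#' @param provenance Named list of counters (\code{removed_components},
#'   \code{interpolated}, \code{rejected_spans}, ...).
#' @return Object of class \code{"eeg_segments"}.
#' @export
eeg_segments <- function(segments, srate, channel_names,
                         eye_state = c("EO", "EC"), condition = NA_character_,
                         provenance = list()) {
  eye_state <- match.arg(eye_state)
  if (!length(segments)) stop_input("no segments")
  nch <- vapply(segments, nrow, 0L)
  if (any(nch != length(channel_names)))
    stop_input("all segments must share the channel count")
  if ((provenance$interpolated %||% 0) > 10)
    stop_input("more than 10 interpolated channels recorded in provenance")
  structure(list(segments = segments, srate = srate,
                 channel_names = as.character(channel_names),
                 eye_state = eye_state, condition = condition,
                 provenance = provenance),
            class = "eeg_segments")
}

#' @export
print.eeg_segments <- function(x, ...) {
  cat(sprintf("<eeg_segments %s/%s: %d segments, %.1f s total, %d channels @ %g Hz>\n",
              x$condition, x$eye_state, length(x$segments),
              sum(vapply(x$segments, ncol, 0L)) / x$srate,
              length(x$channel_names), x$srate))
  invisible(x)
}
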