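#' Full preprocessing chain
#'
#' Runs the resting-state preprocessing pipeline on a raw recording:
#' band-pass (0.1-80 Hz, 24/48 dB per octave) and 50 Hz band-rejection
#' filtering; automated bad-channel detection; restricted-Infomax ICA on
#' the remaining channels with automated artifact-component classification
#' and removal; spherical-spline interpolation of the bad channels;
#' amplitude-threshold span rejection; average referencing with the
#' implicit FCz reference reintroduced; and EO/EC segmentation.  The
#' \code{"light"} chain skips the channel/ICA stages (appropriate for
#' artifact-free synthetic data).
#'
#' @param rec A raw \code{\link{eeg_recording}} (FCz referenced).
#' @param condition Condition tag (\code{"NT"} / \code{"WT"}).
#' @param mode \code{"full"} or \code{"light"}.
#' @param ica_seed Seed for the ICA stage.
#' @param threshold_uv,threshold_sigma Span-rejection threshold, see
#'   \code{\link{reject_spans}}.
#' @param ... Passed to \code{\link{detect_bad_channels}}.
#' @return List with \code{EO} and \code{EC} \code{\link{eeg_segments}};
#'   each carries a \code{provenance} list with counters
#'   \code{bad_channels}, \code{removed_components}, \code{interpolated}
#'   and \code{rejected_spans}.
#' @export
preprocess_recording <- function(rec, condition = NA_character_,
                                 mode = c("full", "light"), ica_seed = 1,
                                 threshold_uv = NULL, threshold_sigma = 8,
                                 ...) {
  mode <- match.arg(mode)
  rec <- bandpass(rec)
  rec <- bandreject(rec)

  bad <- character()
  n_removed <- 0L
  if (mode == "full") {
    bad <- detect_bad_channels(rec, ...)
    ica <- decompose_ica(rec, exclude = bad, seed = ica_seed)
    arte <- classify_artifact_components(ica, rec)
    rec <- remove_components(rec, ica, arte)
    n_removed <- length(arte)
    if (length(bad)) rec <- interpolate_channels(rec, bad)
  }

  rej <- reject_spans(rec, threshold_uv = threshold_uv,
                      threshold_sigma = threshold_sigma)
  rec <- rereference_average(rec)
  prov <- list(bad_channels = length(bad),
               removed_components = n_removed,
               interpolated = length(bad),
               rejected_spans = rej$n_rejected)
  segment_eo_ec(rec, condition = condition, keep = rej$keep,
                provenance = prov)
}
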