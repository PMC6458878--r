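#' Standard EEG frequency bands
#'
#' The conventional band table used for resting-state power analysis:
#' delta 0.5-4, theta 4.5-8, lower alpha 8.5-10, upper alpha 10.5-12,
#' alpha 8.5-12, beta1 12.5-15, beta2 15.5-23, beta3 23.5-35 and
#' gamma 35.5-45 Hz.  Band edges are inclusive on the 0.5 Hz analysis grid;
#' adjacent bands as defined do not share bins.
#'
#' @return A data frame with columns \code{band}, \code{low}, \code{high} (Hz).
#' @export
standard_bands <- function() {
  data.frame(
    band = c("delta", "theta", "lower_alpha", "upper_alpha", "alpha",
             "beta1", "beta2", "beta3", "gamma"),
    low  = c(0.5, 4.5, 8.5, 10.5, 8.5, 12.5, 15.5, 23.5, 35.5),
    high = c(4.0, 8.0, 10.0, 12.0, 12.0, 15.0, 23.0, 35.0, 45.0),
    stringsAsFactors = FALSE
  )
}

#' Frequency band constructor
#'
#' @param low,high Band edges in Hz, inclusive on the analysis grid.
#' @return Named numeric vector \code{c(low, high)} of class \code{"band"}.
#' @export
band <- function(low, high) {
  if (!is.numeric(low) || !is.numeric(high) || length(low) != 1 || length(high) != 1)
    stop_input("band edges must be single numbers")
  low <- unname(low); high <- unname(high)
  if (low > high) stop_input("band low (%g) exceeds high (%g)", low, high)
  structure(c(low = low, high = high), class = "band")
}

#' @export
print.band <- function(x, ...) {
  cat(sprintf("<band %g-%g Hz>\n", x[["low"]], x[["high"]])); invisible(x)
}

#' Individualized reward band around the alpha peak
#'
#' The neurofeedback reward range is set to +/-2 Hz around the individual
#' alpha peak frequency, so the band is always 4 Hz wide.  No clipping is
#' applied at the lower alpha border; if the band would overlap the 3-4 Hz
#' inhibit range an error is raised because reward and inhibit must be
#' disjoint.
#'
#' @param iaf Individual alpha peak frequency in Hz, or an
#'   \code{\link{estimate_iaf}} result.
#' @return A \code{\link{band}} \code{[iaf - 2, iaf + 2]}.
#' @export
reward_band <- function(iaf) {
  if (inherits(iaf, "iaf_estimate")) iaf <- iaf$iaf
  if (!is.numeric(iaf) || length(iaf) != 1 || !is.finite(iaf))
    stop_input("iaf must be a single finite frequency in Hz")
  b <- band(iaf - 2, iaf + 2)
  inh <- inhibit_band()
  if (b[["low"]] <= inh[["high"]] && b[["high"]] >= inh[["low"]])
    stop_input("reward band [%g, %g] overlaps the 3-4 Hz inhibit band", b[["low"]], b[["high"]])
  b
}

#' Trained inhibit band (fixed delta range)
#'
#' @return The fixed 3-4 Hz delta \code{\link{band}} used for inhibition.
#' @export
inhibit_band <- function() band(3, 4)

#' Full band scheme for one participant
#'
#' @param iaf Individual alpha peak frequency in Hz.
#' @return List with \code{standard} (data frame), \code{trained_reward} and
#'   \code{trained_inhibit} bands.
#' @export
band_scheme <- function(iaf) {
  list(standard = standard_bands(),
       trained_reward = reward_band(iaf),
       trained_inhibit = inhibit_band())
}
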