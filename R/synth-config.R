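# Cohort-level generative configuration.
#
# The per-condition / per-timepoint band-power targets below encode the study
# conditions this generator emulates: trained delta-band values near 51-52 dB
# and alpha/delta log-power ratios in the 0.955-0.978 range at baseline and
# post-training, for both resting-state conditions (NT: no task; WT: with the
# instruction to attend to the tinnitus percept).  Values are on the scale of
# the measured PSD (10*log10 uV^2/Hz after log-then-average Welch analysis);
# the synthesis-side chi^2 log-mean bias is compensated internally.

#' Population configuration for synthetic cohorts
#'
#' Defines the distributions from which subject profiles are drawn and the
#' mean band-power trajectory (timepoints t1-t3, conditions NT/WT) that the
#' cohort follows, together with the behavioral score structure.
#'
#' @param n Number of subjects.
#' @param age_mean,age_sd,age_range Age distribution (years), truncated
#'   normal.
#' @param iaf_mean,iaf_sd,iaf_range Individual alpha peak frequency (Hz),
#'   truncated normal.
#' @param background_exponent_mean,background_exponent_sd 1/f^chi exponent of
#'   the aperiodic background.
#' @param ec_alpha_gain_mean,ec_alpha_gain_sd Multiplicative eyes-closed
#'   alpha amplitude gain (truncated at 1: EC alpha never below EO).
#' @param alpha_db,delta_db 3 x 2 matrices (rows t1-t3, columns NT/WT) of
#'   cohort-mean band power in dB for the rewarded individual alpha band and
#'   the 3-4 Hz inhibit band (eyes-open analysis scale).
#' @param alpha_sd_between,delta_sd_between Between-subject SD (dB) of the
#'   subject-level band-power offsets, shared across cells.
#' @param alpha_sd_within,delta_sd_within Within-subject residual SD (dB)
#'   drawn independently per (timepoint, condition) cell.
#' @param alpha_bump_sigma,delta_bump_sigma Spectral widths (Hz) of the
#'   Gaussian alpha and delta bumps.
#' @param delta_bump_center Center frequency (Hz) of the delta bump.
#' @param bump_prominence_db Height (dB) of the alpha-band target above the
#'   aperiodic background within the alpha band; fixes the absolute
#'   background calibration.
#' @param behavior Behavioral score configuration, see
#'   \code{\link{effect_config}}.
#' @return Object of class \code{"cohort_config"}.
#' @export
cohort_config <- function(n = 24,
                          age_mean = 46.29, age_sd = 12.22,
                          age_range = c(24, 71),
                          iaf_mean = 10, iaf_sd = 1,
                          iaf_range = c(7.5, 12.5),
                          background_exponent_mean = 1.2,
                          background_exponent_sd = 0.15,
                          ec_alpha_gain_mean = 1.7, ec_alpha_gain_sd = 0.3,
                          alpha_db = cbind(NT = c(49.56, 49.81, 49.84),
                                           WT = c(49.85, 50.05, 49.90)),
                          delta_db = cbind(NT = c(51.90, 51.94, 51.65),
                                           WT = c(51.87, 51.18, 51.55)),
                          alpha_sd_between = 1.5, delta_sd_between = 1.86,
                          alpha_sd_within = 0.5, delta_sd_within = 0.95,
                          alpha_bump_sigma = 1.0, delta_bump_sigma = 1.2,
                          delta_bump_center = 2.5,
                          bump_prominence_db = 6,
                          behavior = effect_config()) {
  stopifnot(n >= 1, age_sd >= 0, iaf_sd >= 0, ec_alpha_gain_sd >= 0,
            all(dim(alpha_db) == c(3, 2)), all(dim(delta_db) == c(3, 2)),
            alpha_sd_between >= 0, delta_sd_between >= 0,
            alpha_sd_within >= 0, delta_sd_within >= 0,
            alpha_bump_sigma > 0, delta_bump_sigma > 0)
  if (iaf_range[1] < 7.5 - 1e-9 || iaf_range[2] > 12.5 + 1e-9)
    stop_input("iaf_range must lie within [7.5, 12.5]")
  rownames(alpha_db) <- rownames(delta_db) <- c("t1", "t2", "t3")
  structure(as.list(environment()), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config: n = %d, IAF ~ N(%g, %g) on [%g, %g]>\n",
              x$n, x$iaf_mean, x$iaf_sd, x$iaf_range[1], x$iaf_range[2]))
  invisible(x)
}

#' Behavioral effect configuration
#'
#' Marginal means, variance components and the alpha-coupling of the
#' behavioral outcome tables.  Defaults encode a cohort with mild-to-slight
#' tinnitus distress (THI ~29, TQ ~24 at baseline), a distress decrease after
#' training that persists at follow-up, a loudness decrease that reverts, and
#' a configurable Pearson correlation between each subject's trained
#' alpha-band change (t2 - t1, dB) and the TQ sum-score change.
#'
#' @param means 3 x 4 matrix (rows THI/TQ/loudness, columns t1-t4) of
#'   population means.
#' @param sd_between,sd_within Per-outcome between-subject and
#'   within-subject residual SDs (same row order as \code{means}).
#' @param tq_alpha_corr Target Pearson correlation between the subject's
#'   alpha band change and the TQ change (t2 - t1); must be in [-1, 1].
#' @param ranges 3 x 2 matrix of instrument ranges used for clipping.
#' @return Object of class \code{"effect_config"}.
#' @export
effect_config <- function(means = rbind(thi = c(29.33, 23.92, 24.83, 24.75),
                                        tq = c(23.75, 21.62, 21.54, 20.58),
                                        loudness = c(53.25, 43.67, 51.67, 55.46)),
                          sd_between = c(thi = 13.0, tq = 10.5, loudness = 15.4),
                          sd_within = c(thi = 6.79, tq = 4.99, loudness = 12.1),
                          tq_alpha_corr = -0.4,
                          ranges = rbind(thi = c(0, 100), tq = c(0, 84),
                                         loudness = c(1, 100))) {
  stopifnot(all(dim(means) == c(3, 4)), length(sd_between) == 3,
            length(sd_within) == 3, all(sd_between >= 0), all(sd_within >= 0),
            all(dim(ranges) == c(3, 2)))
  if (!is.numeric(tq_alpha_corr) || length(tq_alpha_corr) != 1 ||
      is.na(tq_alpha_corr) || abs(tq_alpha_corr) > 1)
    stop_input("tq_alpha_corr must be a correlation in [-1, 1]")
  colnames(means) <- paste0("t", 1:4)
  structure(list(means = means, sd_between = sd_between,
                 sd_within = sd_within, tq_alpha_corr = tq_alpha_corr,
                 ranges = ranges),
            class = "effect_config")
}
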