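# Subject profiles: generative ground truth for one synthetic participant.
#
# The spectral model of a subject is
#   P(f) = c_bg / f^chi  +  A_a^2 exp(-(f - IAF)^2 / 2 s_a^2)
#                        +  A_d^2 exp(-(f - f_d)^2 / 2 s_d^2)      [uV^2/Hz]
# Amplitudes are solved numerically per (timepoint, condition) cell so that
# the mean dB over the band bins of the *measured* log-then-average spectrum
# equals the drawn target (the chi^2_2 log-mean bias of -2.51 dB is added on
# the synthesis side).  The background level is anchored to the subject's
# baseline alpha target minus a fixed prominence, making the absolute dB
# calibration an explicit constant of the generator, not physiology.

.TPS <- c("t1", "t2", "t3")
.CONDS <- c("NT", "WT")

band_bins <- function(low, high, step = 0.5) {
  lo <- ceiling(low / step - 1e-9) * step
  seq(lo, high + 1e-9, by = step)
}

# mean dB over band bins of background + bump with amplitude amp
.cell_band_db <- function(amp, f, bg, bump_shape) {
  mean(db(bg + amp^2 * bump_shape))
}

.solve_amp <- function(target_db, f, bg, bump_shape) {
  f0 <- .cell_band_db(0, f, bg, bump_shape)
  if (f0 >= target_db) return(0)   # background alone meets or exceeds target
  up <- 1
  while (.cell_band_db(up, f, bg, bump_shape) < target_db) up <- up * 4
  stats::uniroot(function(a) .cell_band_db(a, f, bg, bump_shape) - target_db,
                 c(0, up), tol = 1e-10)$root
}

#' Draw one synthetic subject profile
#'
#' Samples a subject's generative ground truth (alpha peak frequency,
#' aperiodic exponent, band-power trajectory, age, behavioral baselines) from
#' the population distributions of a \code{\link{cohort_config}} and solves
#' the spectral amplitudes that realize the drawn band-power targets.
#'
#' @param seed Integer seed making the draw reproducible.
#' @param config A \code{\link{cohort_config}}.
#' @param subject_id Subject identifier (default \code{"S01"}).
#' @param solve_spectra Solve the spectral amplitudes (default \code{TRUE});
#'   skipping the solver is cheaper for Monte-Carlo studies that only use
#'   the drawn band-power targets and behavioral fields.
#' @return Object of class \code{"subject_profile"} with fields including
#'   \code{iaf_true}, \code{alpha_amp}, \code{delta_amp},
#'   \code{background_exponent}, \code{ec_alpha_gain},
#'   \code{responder_gain} (3 x 2 matrix of alpha amplitude multipliers),
#'   \code{alpha_band_db} / \code{delta_band_db} (drawn measured-scale
#'   targets), \code{behavioral_baseline} and \code{age}.
#' @export
generate_subject_profile <- function(seed, config = cohort_config(),
                                     subject_id = "S01",
                                     solve_spectra = TRUE) {
  if (!inherits(config, "cohort_config")) stop_input("config must be a cohort_config")
  with_seed(seed, {
    iaf <- rtruncnorm(1, config$iaf_mean, config$iaf_sd,
                      config$iaf_range[1], config$iaf_range[2])
    chi <- rtruncnorm(1, config$background_exponent_mean,
                      config$background_exponent_sd, 0.2, 3)
    ec_gain <- rtruncnorm(1, config$ec_alpha_gain_mean,
                          config$ec_alpha_gain_sd, 1, Inf)
    age <- rtruncnorm(1, config$age_mean, config$age_sd,
                      config$age_range[1], config$age_range[2])

    a_i <- stats::rnorm(1, 0, config$alpha_sd_between)
    d_i <- stats::rnorm(1, 0, config$delta_sd_between)
    eps_a <- matrix(stats::rnorm(6, 0, config$alpha_sd_within), 3, 2,
                    dimnames = list(.TPS, .CONDS))
    eps_d <- matrix(stats::rnorm(6, 0, config$delta_sd_within), 3, 2,
                    dimnames = list(.TPS, .CONDS))
    alpha_db_cells <- config$alpha_db + a_i + eps_a
    delta_db_cells <- config$delta_db + d_i + eps_d

    beh <- config$behavior
    baseline <- stats::setNames(numeric(3), rownames(beh$means))
    for (k in 1:3)
      baseline[k] <- rtruncnorm(1, beh$means[k, 1], beh$sd_between[k],
                                beh$ranges[k, 1], beh$ranges[k, 2])

    # --- spectral calibration -------------------------------------------
    iaf_grid <- round_to_grid(iaf)
    fa <- band_bins(iaf_grid - 2, iaf_grid + 2)
    fd <- band_bins(3, 4)
    # background anchored at baseline NT alpha target minus the prominence
    target_syn_a <- alpha_db_cells + LOG_PSD_BIAS_DB
    target_syn_d <- delta_db_cells + LOG_PSD_BIAS_DB
    c_bg <- 10^((target_syn_a["t1", "NT"] - config$bump_prominence_db +
                   chi * mean(10 * log10(fa))) / 10)
    bg_a <- c_bg / fa^chi
    bg_d <- c_bg / fd^chi
    bump_a <- exp(-(fa - iaf)^2 / (2 * config$alpha_bump_sigma^2))
    bump_d <- exp(-(fd - config$delta_bump_center)^2 /
                    (2 * config$delta_bump_sigma^2))

    amp_a <- amp_d <- matrix(0, 3, 2, dimnames = list(.TPS, .CONDS))
    if (solve_spectra) {
      for (tp in .TPS) for (cd in .CONDS) {
        amp_a[tp, cd] <- .solve_amp(target_syn_a[tp, cd], fa, bg_a, bump_a)
        amp_d[tp, cd] <- .solve_amp(target_syn_d[tp, cd], fd, bg_d, bump_d)
      }
    }
    base_a <- amp_a["t1", "NT"]
    responder <- if (base_a > 0) amp_a / base_a else amp_a * 0 + 1

    structure(list(
      subject_id = subject_id,
      iaf_true = iaf,
      alpha_amp = base_a,
      delta_amp = amp_d["t1", "NT"],
      alpha_amp_cells = amp_a,
      delta_amp_cells = amp_d,
      responder_gain = responder,
      background_exponent = chi,
      background_level = c_bg,
      ec_alpha_gain = ec_gain,
      alpha_band_db = alpha_db_cells,
      delta_band_db = delta_db_cells,
      alpha_bump_sigma = config$alpha_bump_sigma,
      delta_bump_sigma = config$delta_bump_sigma,
      delta_bump_center = config$delta_bump_center,
      alpha_change_db = unname(alpha_db_cells["t2", "WT"] - alpha_db_cells["t1", "WT"]),
      behavioral_baseline = baseline,
      age = age
    ), class = "subject_profile")
  })
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile %s: IAF %.2f Hz, chi %.2f, age %.0f, EC gain %.2f>\n",
              x$subject_id, x$iaf_true, x$background_exponent, x$age,
              x$ec_alpha_gain))
  invisible(x)
}

#' Draw a cohort of subject profiles
#'
#' @param config A \code{\link{cohort_config}}.
#' @param seed Master seed; per-subject seeds are derived from it.
#' @param solve_spectra See \code{\link{generate_subject_profile}}.
#' @return List of \code{\link{generate_subject_profile}} results.
#' @export
generate_cohort_profiles <- function(config = cohort_config(), seed = 1,
                                     solve_spectra = TRUE) {
  seeds <- child_seeds(seed, config$n)
  ids <- sprintf("S%02d", seq_len(config$n))
  mapply(generate_subject_profile, seed = seeds, subject_id = ids,
         MoreArgs = list(config = config, solve_spectra = solve_spectra),
         SIMPLIFY = FALSE)
}

#' Noise-free target power spectral density of a profile
#'
#' Analytic ground truth used by the oracle tests: the PSD (uV^2/Hz) the
#' generator aims at before windowing and estimation noise, on the
#' synthesis scale (i.e. including the log-mean bias compensation).
#'
#' @param profile A \code{subject_profile}.
#' @param freqs Frequencies in Hz.
#' @param timepoint,condition Cell selector.
#' @param eye_state \code{"EO"} or \code{"EC"} (EC multiplies the alpha
#'   amplitude by \code{ec_alpha_gain}).
#' @return Numeric vector of PSD values.
#' @export
target_psd <- function(profile, freqs, timepoint = "t1", condition = "NT",
                       eye_state = "EO") {
  amp_a <- profile$alpha_amp_cells[timepoint, condition] *
    if (eye_state == "EC") profile$ec_alpha_gain else 1
  amp_d <- profile$delta_amp_cells[timepoint, condition]
  bg <- ifelse(freqs > 0, profile$background_level / pmax(freqs, 1e-6)^profile$background_exponent, 0)
  bg + amp_a^2 * exp(-(freqs - profile$iaf_true)^2 / (2 * profile$alpha_bump_sigma^2)) +
    amp_d^2 * exp(-(freqs - profile$delta_bump_center)^2 / (2 * profile$delta_bump_sigma^2))
}
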