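# Behavioral score tables: subject baselines + timepoint effects +
# correlated noise.  The correlation between each subject's trained
# alpha-band change and the TQ change is induced through a shared latent
# Gaussian, which gives exact control of the target correlation before
# range clipping.

#' Generate a long behavioral score table
#'
#' Produces one row per subject x timepoint (t1-t4) x outcome
#' (THI, TQ, loudness).  Scores are
#' \code{baseline_i + (mu_t - mu_1) + residual}; for TQ the t1/t2 residual
#' pair is constructed so that the cohort correlation between
#' \code{DeltaTQ = TQ_t2 - TQ_t1} and the subject's trained alpha-band change
#' (\code{profile$alpha_change_db}) equals \code{effects$tq_alpha_corr} in
#' expectation.  Values are clipped to the instrument ranges
#' (THI 0-100, TQ 0-84, loudness 1-100).
#'
#' @param profiles List of \code{subject_profile}s.
#' @param effects An \code{\link{effect_config}}.
#' @param seed Optional seed.
#' @return Data frame with columns \code{subject}, \code{timepoint},
#'   \code{outcome}, \code{value}.
#' @export
generate_behavior <- function(profiles, effects = effect_config(), seed = NULL) {
  if (!length(profiles)) stop_input("profiles must be non-empty")
  if (!is.null(seed)) return(with_seed(seed, generate_behavior(profiles, effects)))

  nsub <- length(profiles)
  outcomes <- rownames(effects$means)
  rho <- effects$tq_alpha_corr

  # standardized latent alpha change (population standardization so the
  # construction is exact regardless of the realized cohort)
  dalpha <- vapply(profiles, `[[`, 0, "alpha_change_db")
  sd_da <- stats::sd(dalpha)
  z <- if (nsub > 1 && sd_da > 0) (dalpha - mean(dalpha)) / sd_da else rep(0, nsub)

  rows <- vector("list", nsub * length(outcomes))
  k <- 0
  for (i in seq_len(nsub)) {
    p <- profiles[[i]]
    for (oc in outcomes) {
      j <- match(oc, outcomes)
      mu <- effects$means[j, ]
      sw <- effects$sd_within[j]
      base <- p$behavioral_baseline[[oc]]
      eps <- stats::rnorm(4, 0, sw)
      if (oc == "tq" && sw > 0) {
        u <- stats::rnorm(1)
        v <- stats::rnorm(1)
        d <- rho * z[i] + sqrt(1 - rho^2) * u
        eps[1] <- sw * (v - d) / sqrt(2)
        eps[2] <- sw * (v + d) / sqrt(2)
      }
      vals <- base + (mu - mu[1]) + eps
      vals <- pmin(pmax(vals, effects$ranges[j, 1]), effects$ranges[j, 2])
      k <- k + 1
      rows[[k]] <- data.frame(subject = p$subject_id,
                              timepoint = paste0("t", 1:4),
                              outcome = oc, value = unname(vals),
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
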