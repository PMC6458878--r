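# Effect-size conversion, difference-score correlations, Benjamini-Hochberg
# adjustment and within-subject (Cousineau-Morey) standard errors.

#' Effect size r from a t statistic
#'
#' Converts a contrast t value with its degrees of freedom to the effect
#' size \eqn{r = \sqrt{t^2 / (t^2 + df)}}.  The conversion is symmetric in
#' the sign of t, strictly increasing in |t| at fixed df and strictly
#' decreasing in df at fixed |t|; r lies in [0, 1).
#'
#' @param t t statistic (vectorized).
#' @param df Degrees of freedom.
#' @return Effect size r.
#' @export
effect_size_r <- function(t, df) {
  if (any(df <= 0)) stop_input("df must be positive")
  sqrt(t^2 / (t^2 + df))
}

#' Pearson correlation of difference scores
#'
#' Correlates per-subject difference scores (e.g. behavioral change vs
#' EEG band-power change, t2 - t1) and reports the one-tailed t test on
#' n - 2 degrees of freedom.
#'
#' @param behavior_delta,eeg_delta Paired numeric vectors (complete cases
#'   required, n >= 3).
#' @param alternative \code{"less"} (hypothesized negative relation,
#'   default), \code{"greater"}, or \code{"two.sided"}.
#' @return List: \code{r}, \code{df}, \code{p}, \code{alternative},
#'   \code{label} (e.g. \code{"r(22)"}).
#' @export
diff_corr <- function(behavior_delta, eeg_delta,
                      alternative = c("less", "greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(behavior_delta) != length(eeg_delta))
    stop_input("difference-score vectors must be paired")
  ok <- stats::complete.cases(behavior_delta, eeg_delta)
  x <- behavior_delta[ok]; y <- eeg_delta[ok]
  if (length(x) < 3) stop_input("need at least 3 complete pairs")
  ct <- stats::cor.test(x, y, alternative = alternative, method = "pearson")
  df <- length(x) - 2L
  list(r = unname(ct$estimate), df = df, p = ct$p.value,
       alternative = alternative, label = sprintf("r(%d)", df))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement
#' (delegates to \code{stats::p.adjust(method = "BH")}).
#'
#' @param p_values Numeric vector of p values.
#' @return Adjusted p values.
#' @export
bh_adjust <- function(p_values) stats::p.adjust(p_values, method = "BH")

#' Within-subject standard errors (Cousineau-Morey)
#'
#' Per-timepoint standard errors for repeated-measure designs: values are
#' subject-centered (subject mean removed, grand mean added) and the
#' resulting per-timepoint standard errors are multiplied by the Morey
#' bias-correction factor \eqn{\sqrt{T/(T-1)}}.  Additive subject offsets
#' therefore do not inflate the error bars.
#'
#' @param table Long outcome table (balanced).
#' @param outcome Outcome name.
#' @return Named numeric vector of standard errors, one per timepoint.
#' @export
morey_within_se <- function(table, outcome) {
  d <- .check_outcome_table(table, outcome)
  subj_mean <- tapply(d$value, d$subject, mean)
  grand <- mean(d$value)
  centered <- d$value - subj_mean[d$subject] + grand
  tt <- nlevels(d$timepoint)
  se <- tapply(centered, d$timepoint, function(v) stats::sd(v) / sqrt(length(v)))
  correction <- sqrt(tt / (tt - 1))
  stats::setNames(as.numeric(se) * correction, levels(d$timepoint))
}
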