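# Repeated-measure mixed-model analysis of the long outcome tables:
# random-intercept-per-subject models with a fixed timepoint factor,
# maximum-likelihood likelihood-ratio chi^2 for the time effect, a priori
# baseline contrasts with Bonferroni-corrected one-tailed p values, and
# single-step (Tukey) post hoc comparisons.
#
# Degrees-of-freedom convention: the contrast t statistics use the
# within-subject residual df, N_obs - N_subjects - (T - 1), i.e. 69 for 24
# subjects x 4 timepoints and 46 for 24 subjects x 3 timepoints.  nlme's
# innermost-level denominator df reproduces this exactly.

.check_outcome_table <- function(table, outcome) {
  need <- c("subject", "timepoint", "outcome", "value")
  if (!all(need %in% names(table)))
    stop_input("outcome table needs columns %s", paste(need, collapse = ", "))
  d <- table[table$outcome == outcome, , drop = FALSE]
  if (!nrow(d)) stop_input("no rows for outcome '%s'", outcome)
  tab <- base::table(d$subject, d$timepoint)
  if (any(tab != 1))
    stop_input("unbalanced table for outcome '%s': every subject needs every timepoint exactly once", outcome)
  d$subject <- factor(d$subject)
  d$timepoint <- factor(d$timepoint)
  d
}

#' Fit the repeated-measure time-course model for one outcome
#'
#' Fits the random-intercept model \code{value ~ timepoint, random = ~1 |
#' subject} to the balanced long table of one outcome, by REML (used for
#' contrasts and post hoc tests) and by ML together with the
#' intercept-only null (used for the likelihood-ratio chi^2 of the time
#' effect).
#'
#' @param table Long data frame with columns \code{subject},
#'   \code{timepoint}, \code{outcome}, \code{value}; must be balanced.
#' @param outcome Outcome name to analyse.
#' @return Object of class \code{"timecourse_fit"} with components
#'   \code{model} (REML \code{lme}), \code{anova}
#'   (\code{\link{fit_time_anova}} result), \code{timepoints},
#'   \code{n_subjects}, \code{df_resid}.
#' @export
fit_timecourse <- function(table, outcome) {
  d <- .check_outcome_table(table, outcome)
  tps <- levels(d$timepoint)
  if (stats::var(d$value) < 1e-12) {
    # degenerate constant outcome: no time effect by construction
    anova_res <- structure(list(chi_sq = 0, df = length(tps) - 1, p = 1,
                                outcome = outcome), class = "anova_time")
    return(structure(list(model = NULL, anova = anova_res, data = d,
                          outcome = outcome, timepoints = tps,
                          n_subjects = nlevels(d$subject),
                          df_resid = nrow(d) - nlevels(d$subject) -
                            (length(tps) - 1)),
                     class = "timecourse_fit"))
  }
  m_reml <- nlme::lme(value ~ timepoint, random = ~1 | subject, data = d,
                      method = "REML")
  m_ml <- nlme::lme(value ~ timepoint, random = ~1 | subject, data = d,
                    method = "ML")
  m_null <- nlme::lme(value ~ 1, random = ~1 | subject, data = d,
                      method = "ML")
  tps <- levels(d$timepoint)
  nsub <- nlevels(d$subject)
  df_resid <- nrow(d) - nsub - (length(tps) - 1)
  chi <- max(0, 2 * (stats::logLik(m_ml) - stats::logLik(m_null)))
  df_chi <- length(tps) - 1
  anova_res <- structure(list(chi_sq = as.numeric(chi), df = df_chi,
                              p = stats::pchisq(as.numeric(chi), df_chi,
                                                lower.tail = FALSE),
                              outcome = outcome),
                         class = "anova_time")
  structure(list(model = m_reml, model_ml = m_ml, model_null = m_null,
                 anova = anova_res, data = d, outcome = outcome,
                 timepoints = tps, n_subjects = nsub, df_resid = df_resid),
            class = "timecourse_fit")
}

#' @export
print.timecourse_fit <- function(x, ...) {
  cat(sprintf("<timecourse_fit '%s': %d subjects x %d timepoints, residual df %d>\n",
              x$outcome, x$n_subjects, length(x$timepoints), x$df_resid))
  print(x$anova)
  invisible(x)
}

#' @export
print.anova_time <- function(x, ...) {
  cat(sprintf("time effect: chi^2(%d) = %.2f, p = %.3f\n", x$df, x$chi_sq, x$p))
  invisible(x)
}

#' @export
coef.timecourse_fit <- function(object, ...) nlme::fixef(object$model)

#' @export
residuals.timecourse_fit <- function(object, ...) stats::residuals(object$model)

#' @export
summary.timecourse_fit <- function(object, ...) {
  list(anova = object$anova, tTable = summary(object$model)$tTable)
}

#' Repeated-measure mixed-model ANOVA for the time effect
#'
#' Likelihood-ratio chi^2 (ML fit of the timepoint model vs the
#' intercept-only null) with T - 1 degrees of freedom.
#'
#' @param table Long outcome table (or a \code{timecourse_fit}).
#' @param outcome Outcome name.
#' @return Object of class \code{"anova_time"}: \code{chi_sq}, \code{df},
#'   \code{p}.
#' @export
fit_time_anova <- function(table, outcome) {
  if (inherits(table, "timecourse_fit")) return(table$anova)
  fit_timecourse(table, outcome)$anova
}

#' A priori baseline contrasts
#'
#' One contrast per post-baseline timepoint (t1 vs t2, t1 vs t3, ...),
#' taken from the fitted model's timepoint coefficients.  Reported p values
#' are one-tailed (half the two-tailed p of the observed t) and Bonferroni
#' multiplied by the number of contrasts, capped at 1.  The hypothesized
#' direction must be stated; whether each observed contrast lies in that
#' direction is returned alongside.  Effect sizes use
#' \code{\link{effect_size_r}}.
#'
#' @param fit A \code{\link{fit_timecourse}} result.
#' @param direction \code{"decrease"} or \code{"increase"}: hypothesized
#'   change from baseline.
#' @param baseline Baseline level (default first timepoint).
#' @return Data frame of class \code{"contrast_result"}: \code{label},
#'   \code{estimate}, \code{t}, \code{df}, \code{p_one_tailed_bonf},
#'   \code{p_two_tailed}, \code{r}, \code{direction_consistent}.
#' @export
apriori_contrasts <- function(fit, direction, baseline = NULL) {
  if (missing(direction))
    stop_input("the hypothesized direction ('decrease' or 'increase') must be specified")
  direction <- match.arg(direction, c("decrease", "increase"))
  baseline <- baseline %||% fit$timepoints[1]
  if (baseline != fit$timepoints[1])
    stop_input("model is coded with baseline %s", fit$timepoints[1])
  tt <- summary(fit$model)$tTable
  rows <- grep("^timepoint", rownames(tt))
  m <- length(rows)
  t_val <- tt[rows, "t-value"]
  df <- as.integer(tt[rows, "DF"])
  stopifnot(all(df == fit$df_resid))
  p1 <- pmin(1, m * stats::pt(-abs(t_val), df))
  res <- data.frame(
    label = paste0(baseline, "-", sub("^timepoint", "", rownames(tt)[rows])),
    estimate = tt[rows, "Value"],
    t = t_val, df = df,
    p_one_tailed_bonf = p1,
    p_two_tailed = 2 * stats::pt(-abs(t_val), df),
    r = effect_size_r(t_val, df),
    direction_consistent = if (direction == "decrease") t_val <= 0 else t_val >= 0,
    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("contrast_result", "data.frame")
  attr(res, "direction") <- direction
  res
}

#' Baseline vs mean-of-follow-ups contrast
#'
#' Tests the contrast with weights (+1, -1/3, -1/3, -1/3): the baseline
#' value against the average of all later timepoints, with the model-based
#' standard error and the within-subject residual df.  The p value is
#' one-tailed and uncorrected.  The sign of the reported t follows the
#' direction of change from baseline (a decrease gives a negative t).
#'
#' @param table Long outcome table or \code{timecourse_fit}.
#' @param outcome Outcome name (ignored when a fit is supplied).
#' @param direction Hypothesized direction of the change from baseline.
#' @return One-row data frame: \code{label}, \code{estimate}, \code{t},
#'   \code{df}, \code{p_one_tailed}, \code{r}, \code{weights}.
#' @export
mean_followup_contrast <- function(table, outcome = NULL, direction = "decrease") {
  direction <- match.arg(direction, c("decrease", "increase"))
  fit <- if (inherits(table, "timecourse_fit")) table else
    fit_timecourse(table, outcome)
  beta <- nlme::fixef(fit$model)
  V <- stats::vcov(fit$model)
  k <- length(fit$timepoints) - 1
  # mean(mu_2..mu_T) - mu_1 = mean(beta_2..beta_T) under treatment coding;
  # reported so that a decrease from baseline carries a negative sign
  L <- c(0, rep(1 / k, k))
  est <- sum(L * beta)
  se <- sqrt(drop(t(L) %*% V %*% L))
  t_val <- est / se
  df <- fit$df_resid
  p1 <- stats::pt(-abs(t_val), df)
  out <- data.frame(label = sprintf("%s-mean(%s)", fit$timepoints[1],
                                    paste(fit$timepoints[-1], collapse = ",")),
                    estimate = est, t = t_val, df = df, p_one_tailed = p1,
                    r = effect_size_r(t_val, df),
                    direction_consistent = if (direction == "decrease") t_val <= 0 else t_val >= 0,
                    stringsAsFactors = FALSE)
  attr(out, "weights") <- c(1, rep(-1 / k, k))
  out
}

#' Tukey post hoc comparisons of all timepoints
#'
#' All pairwise timepoint comparisons from the fitted model with
#' single-step multivariate-t adjusted p values (the Tukey family), using
#' the within-subject residual df.  Internally integrates the multivariate
#' t distribution with a fixed quasi-Monte-Carlo seed so results are
#' reproducible.
#'
#' @param fit A \code{\link{fit_timecourse}} result.
#' @return Data frame: \code{label}, \code{estimate}, \code{t}, \code{df},
#'   \code{p_unadjusted}, \code{p_adjusted}.
#' @export
tukey_posthoc <- function(fit) {
  beta <- nlme::fixef(fit$model)
  V <- stats::vcov(fit$model)
  tps <- fit$timepoints
  tt <- length(tps)
  pairs <- utils::combn(tt, 2)
  K <- matrix(0, ncol(pairs), length(beta))
  lab <- character(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    if (a > 1) K[j, a] <- -1       # coefficient index = level index (treatment coding)
    if (b > 1) K[j, b] <- 1
    lab[j] <- paste0(tps[a], "-", tps[b])
  }
  est <- drop(K %*% beta)
  cv <- K %*% V %*% t(K)
  se <- sqrt(diag(cv))
  t_val <- est / se
  R <- stats::cov2cor(cv)
  df <- fit$df_resid
  p_adj <- vapply(seq_along(t_val), function(j) {
    with_seed(20240101, {
      1 - mvtnorm::pmvt(lower = rep(-abs(t_val[j]), length(t_val)),
                        upper = rep(abs(t_val[j]), length(t_val)),
                        corr = R, df = df,
                        algorithm = mvtnorm::GenzBretz(abseps = 1e-7))[1]
    })
  }, 0)
  p_un <- 2 * stats::pt(-abs(t_val), df)
  data.frame(label = lab, estimate = est, t = t_val, df = df,
             p_unadjusted = p_un,
             p_adjusted = pmin(1, pmax(p_adj, p_un)),
             stringsAsFactors = FALSE)
}

#' Age median-split control analysis
#'
#' Splits the cohort at the median age (ties assigned to the young group),
#' adds the group factor and its interaction with time to the
#' repeated-measure model, and reports the ML likelihood-ratio test of the
#' extended model against the time-only model.
#'
#' @param table Long outcome table.
#' @param ages Named numeric vector of ages (names = subject ids).
#' @param outcome Outcome name.
#' @return List: \code{median}, \code{groups} (factor per subject),
#'   \code{group_sizes}, \code{chi_sq}, \code{df}, \code{p}.
#' @export
age_median_split_control <- function(table, ages, outcome) {
  d <- .check_outcome_table(table, outcome)
  subs <- levels(d$subject)
  if (!all(subs %in% names(ages)))
    stop_input("ages must be named for every subject")
  med <- stats::median(ages[subs])
  grp <- factor(ifelse(ages[subs] <= med, "young", "old"),
                levels = c("young", "old"))
  d$group <- grp[match(d$subject, subs)]
  m_time <- nlme::lme(value ~ timepoint, random = ~1 | subject, data = d,
                      method = "ML")
  m_int <- nlme::lme(value ~ timepoint * group, random = ~1 | subject,
                     data = d, method = "ML")
  chi <- max(0, 2 * (stats::logLik(m_int) - stats::logLik(m_time)))
  df <- length(nlme::fixef(m_int)) - length(nlme::fixef(m_time))
  list(median = med, groups = stats::setNames(grp, subs),
       group_sizes = base::table(grp), chi_sq = as.numeric(chi), df = df,
       p = stats::pchisq(as.numeric(chi), df, lower.tail = FALSE))
}
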