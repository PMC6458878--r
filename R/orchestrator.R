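# End-to-end study runner: cohort generation -> neurofeedback sessions ->
# preprocessing -> spectral quantification -> statistics -> report.

#' Study configuration
#'
#' Validated configuration for \code{\link{run_study}}.  Unknown arguments
#' are rejected.  The default simulation scale (120 s resting recordings at
#' 250 Hz, 120 s neurofeedback sessions) keeps a full 24-subject study run
#' inexpensive; the statistical structure of the cohort is carried by the
#' generator configuration, not by the recording length.
#'
#' @param n Number of subjects.
#' @param seed Master seed for the whole run.
#' @param cohort A \code{\link{cohort_config}} (its \code{n} is overridden).
#' @param rest_duration_s,rest_srate,rest_block_s Resting-state recording
#'   scale.
#' @param nfb_sessions,nfb_session_s Neurofeedback session count and length.
#' @param preprocess \code{"light"} (filters, referencing, segmentation) or
#'   \code{"full"} (adds bad-channel/ICA stages).
#' @param artifacts An \code{\link{artifact_config}} applied to every
#'   resting recording (default: none).
#' @param iaf_source Eye state used for IAF determination (default
#'   \code{"EC"}).
#' @param run_nfb Simulate the weekly neurofeedback sessions (logged;
#'   the cohort's training effect itself is carried by the generator).
#' @param ... Unused; presence raises an error (schema validation).
#' @return Object of class \code{"study_config"}.
#' @export
study_config <- function(n = 24, seed = 1, cohort = cohort_config(),
                         rest_duration_s = 120, rest_srate = 250,
                         rest_block_s = 30,
                         nfb_sessions = 15, nfb_session_s = 120,
                         preprocess = c("light", "full"),
                         artifacts = artifact_config(),
                         iaf_source = c("EC", "EO"),
                         run_nfb = FALSE, ...) {
  extra <- list(...)
  if (length(extra))
    stop_input("unknown study_config field(s): %s",
               paste(names(extra), collapse = ", "))
  preprocess <- match.arg(preprocess)
  iaf_source <- match.arg(iaf_source)
  if (!inherits(cohort, "cohort_config")) stop_input("cohort must be a cohort_config")
  if (!inherits(artifacts, "artifact_config")) stop_input("artifacts must be an artifact_config")
  cohort$n <- n
  structure(list(n = n, seed = seed, cohort = cohort,
                 rest_duration_s = rest_duration_s, rest_srate = rest_srate,
                 rest_block_s = rest_block_s,
                 nfb_sessions = nfb_sessions, nfb_session_s = nfb_session_s,
                 preprocess = preprocess, artifacts = artifacts,
                 iaf_source = iaf_source, run_nfb = run_nfb),
            class = "study_config")
}

.eeg_outcomes <- function(cond) {
  stats::setNames(paste0(c("ratio_", "alpha_", "delta_"), cond),
                  c("ratio", "alpha", "delta"))
}

#' Run a complete simulated study
#'
#' Generates a synthetic cohort, optionally simulates the weekly
#' neurofeedback sessions, synthesizes and preprocesses the t1-t3
#' resting-state recordings for both conditions (NT/WT), quantifies the
#' individualized alpha band, the 3-4 Hz delta band and their ratio on the
#' eyes-open spectra of the four training electrodes, and runs the
#' statistical chain (time ANOVAs, a priori contrasts with effect sizes,
#' Tukey post hoc tests, baseline-vs-follow-up contrast for TQ,
#' difference-score correlations, age median-split control).  Fully
#' reproducible given the configuration seed.
#'
#' @param config A \code{\link{study_config}}.
#' @return Object of class \code{"study_result"}: \code{behavior} and
#'   \code{eeg} long tables, \code{iaf} per subject, \code{stats} (per
#'   outcome), \code{correlations}, \code{config} echo.
#' @export
run_study <- function(config = study_config()) {
  seeds <- child_seeds(config$seed, 6)
  profiles <- generate_cohort_profiles(config$cohort, seed = seeds[1])
  behavior <- generate_behavior(profiles, config$cohort$behavior,
                                seed = seeds[2])
  ids <- vapply(profiles, `[[`, "", "subject_id")

  # --- individual alpha peak from a 30 s training-montage baseline ------
  iaf_spec <- recording_spec(duration_s = 30, srate = 250,
                             channels = training_channels(),
                             reference = "linked-earlobes",
                             eye_pattern = paste0(config$iaf_source, "_only"))
  iaf_seeds <- child_seeds(seeds[3], config$n)
  iaf <- stats::setNames(numeric(config$n), ids)
  for (i in seq_len(config$n)) {
    rec <- synthesize_recording(profiles[[i]], "t1", "NT", iaf_spec,
                                seed = iaf_seeds[i])
    iaf[i] <- estimate_iaf(rec)$iaf
  }

  # --- neurofeedback sessions (logged summary only) ---------------------
  nfb_summary <- NULL
  if (config$run_nfb) {
    nfb_seeds <- child_seeds(seeds[4], config$n)
    gains <- stats::setNames(numeric(config$n), ids)
    for (i in seq_len(config$n)) {
      lrn <- learner_state(alpha_gain = 1, learning_rate = 0.02)
      pspec <- protocol_spec(iaf = iaf[i], session_s = config$nfb_session_s)
      s_seeds <- child_seeds(nfb_seeds[i], config$nfb_sessions)
      for (s in seq_len(config$nfb_sessions)) {
        out <- simulate_session(profiles[[i]], lrn, pspec, seed = s_seeds[s])
        lrn <- out$learner
      }
      gains[i] <- lrn$alpha_gain
    }
    nfb_summary <- gains
  }

  # --- resting-state recordings -> band powers --------------------------
  rest_spec <- recording_spec(duration_s = config$rest_duration_s,
                              srate = config$rest_srate,
                              channels = montage_channels(include_ref = FALSE),
                              block_s = config$rest_block_s)
  rec_seeds <- matrix(child_seeds(seeds[5], config$n * 6), nrow = config$n)
  eeg_rows <- list()
  for (i in seq_len(config$n)) {
    reward <- reward_band(iaf[i])
    cell <- 0
    for (tp in c("t1", "t2", "t3")) for (cond in c("NT", "WT")) {
      cell <- cell + 1
      rec <- synthesize_recording(profiles[[i]], tp, cond, rest_spec,
                                  seed = rec_seeds[i, cell])
      rec <- inject_artifacts(rec, config$artifacts)
      segs <- preprocess_recording(rec, condition = cond,
                                   mode = config$preprocess,
                                   ica_seed = rec_seeds[i, cell])
      psd <- compute_psd(segs$EO)
      a_db <- band_power(psd, reward, training_channels())
      d_db <- band_power(psd, inhibit_band(), training_channels())
      ratio <- alpha_delta_ratio(psd, reward)
      oc <- .eeg_outcomes(cond)
      eeg_rows[[length(eeg_rows) + 1]] <- data.frame(
        subject = ids[i], timepoint = tp,
        outcome = unname(oc), value = c(ratio, a_db, d_db),
        stringsAsFactors = FALSE)
    }
  }
  eeg <- do.call(rbind, eeg_rows)

  # --- statistics -------------------------------------------------------
  ages <- stats::setNames(vapply(profiles, `[[`, 0, "age"), ids)
  stats_out <- list()
  for (oc in c("thi", "tq", "loudness")) {
    fit <- fit_timecourse(behavior, oc)
    stats_out[[oc]] <- list(
      anova = fit$anova,
      contrasts = apriori_contrasts(fit, direction = "decrease"),
      tukey = tukey_posthoc(fit),
      morey_se = morey_within_se(behavior, oc),
      age_control = age_median_split_control(behavior, ages, oc))
  }
  stats_out$tq$mean_followup <- mean_followup_contrast(behavior, "tq")
  for (cond in c("NT", "WT")) {
    oc <- .eeg_outcomes(cond)
    for (k in names(oc)) {
      fit <- fit_timecourse(eeg, oc[[k]])
      dirn <- if (k == "delta") "decrease" else "increase"
      stats_out[[oc[[k]]]] <- list(
        anova = fit$anova,
        contrasts = apriori_contrasts(fit, direction = dirn),
        tukey = tukey_posthoc(fit),
        morey_se = morey_within_se(eeg, oc[[k]]))
    }
  }

  # --- difference-score correlations (t2 - t1) --------------------------
  delta_of <- function(tab, oc) {
    d <- tab[tab$outcome == oc, ]
    v1 <- d$value[match(paste(ids, "t1"), paste(d$subject, d$timepoint))]
    v2 <- d$value[match(paste(ids, "t2"), paste(d$subject, d$timepoint))]
    v2 - v1
  }
  correlations <- list()
  for (cond in c("NT", "WT")) {
    oc <- .eeg_outcomes(cond)
    for (k in names(oc)) for (beh in c("thi", "tq", "loudness")) {
      key <- sprintf("%s_vs_%s", oc[[k]], beh)
      alt <- if (k == "delta") "greater" else "less"
      correlations[[key]] <- diff_corr(delta_of(behavior, beh),
                                       delta_of(eeg, oc[[k]]),
                                       alternative = alt)
    }
  }

  structure(list(behavior = behavior, eeg = eeg, iaf = iaf,
                 profiles = profiles, nfb_gains = nfb_summary,
                 stats = stats_out, correlations = correlations,
                 config = config),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result: n = %d, seed = %d>\n", x$config$n, x$config$seed))
  for (oc in c("thi", "tq", "loudness", "ratio_NT", "ratio_WT")) {
    a <- x$stats[[oc]]$anova
    cat(sprintf("  %-9s chi^2(%d) = %5.2f, p = %.3f\n", oc, a$df, a$chi_sq, a$p))
  }
  invisible(x)
}

#' Serialize study results to JSON
#'
#' Flattens the statistical results into a deterministic JSON document
#' (tables of means, ANOVA chi-squares, contrasts, correlations).
#'
#' @param result A \code{\link{run_study}} result.
#' @param path Optional output file.
#' @return JSON string (invisibly when written to a file).
#' @export
study_results_json <- function(result, path = NULL) {
  means_of <- function(tab) {
    ocs <- unique(tab$outcome)
    out <- list()
    for (oc in ocs) {
      d <- tab[tab$outcome == oc, ]
      out[[oc]] <- as.list(round(tapply(d$value, d$timepoint, mean), 6))
    }
    out
  }
  st <- lapply(result$stats, function(s) {
    o <- list(anova = list(chi_sq = round(s$anova$chi_sq, 6),
                           df = s$anova$df, p = round(s$anova$p, 6)),
              contrasts = lapply(seq_len(nrow(s$contrasts)), function(j)
                list(label = s$contrasts$label[j],
                     t = round(s$contrasts$t[j], 6),
                     df = s$contrasts$df[j],
                     p_one_tailed_bonf = round(s$contrasts$p_one_tailed_bonf[j], 6),
                     r = round(s$contrasts$r[j], 6))))
    if (!is.null(s$morey_se)) o$morey_se <- as.list(round(s$morey_se, 6))
    if (!is.null(s$age_control))
      o$age_control <- list(chi_sq = round(s$age_control$chi_sq, 6),
                            df = s$age_control$df,
                            p = round(s$age_control$p, 6))
    o
  })
  doc <- list(n_subjects = result$config$n, seed = result$config$seed,
              means = c(means_of(result$behavior), means_of(result$eeg)),
              iaf = as.list(round(result$iaf, 2)),
              stats = st,
              correlations = lapply(result$correlations, function(cc)
                list(r = round(cc$r, 6), df = cc$df, p = round(cc$p, 6))))
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Write a human-readable report
#'
#' Writes summary tables (CSV), bar plots with within-subject error bars
#' and difference-score scatterplots for a study result.
#'
#' @param result A \code{\link{run_study}} result.
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written.
#' @export
make_report <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  add <- function(f) files <<- c(files, f)

  js <- file.path(dir, "results.json")
  study_results_json(result, js); add(js)

  tab3 <- do.call(rbind, lapply(unique(result$behavior$outcome), function(oc) {
    d <- result$behavior[result$behavior$outcome == oc, ]
    data.frame(outcome = oc, timepoint = sort(unique(d$timepoint)),
               mean = as.numeric(tapply(d$value, d$timepoint, mean)),
               sd = as.numeric(tapply(d$value, d$timepoint, stats::sd)))
  }))
  f <- file.path(dir, "outcome_means.csv")
  utils::write.csv(tab3, f, row.names = FALSE); add(f)

  contr <- do.call(rbind, lapply(names(result$stats), function(oc) {
    s <- result$stats[[oc]]$contrasts
    if (is.null(s)) return(NULL)
    cbind(outcome = oc, s)
  }))
  f <- file.path(dir, "contrasts.csv")
  utils::write.csv(contr, f, row.names = FALSE); add(f)

  for (oc in unique(result$behavior$outcome)) {
    f <- file.path(dir, sprintf("bar_%s.png", oc))
    grDevices::png(f, width = 600, height = 450)
    d <- result$behavior[result$behavior$outcome == oc, ]
    m <- tapply(d$value, d$timepoint, mean)
    se <- result$stats[[oc]]$morey_se
    bp <- graphics::barplot(m, ylim = c(0, max(m + 2 * se) * 1.15),
                            main = oc, ylab = "score")
    graphics::arrows(bp, m - se, bp, m + se, angle = 90, code = 3,
                     length = 0.06)
    grDevices::dev.off(); add(f)
  }
  ids <- names(result$iaf)
  delta_of <- function(tab, oc) {
    d <- tab[tab$outcome == oc, ]
    d$value[match(paste(ids, "t2"), paste(d$subject, d$timepoint))] -
      d$value[match(paste(ids, "t1"), paste(d$subject, d$timepoint))]
  }
  for (cond in c("NT", "WT")) {
    f <- file.path(dir, sprintf("scatter_ratio_%s_tq.png", cond))
    grDevices::png(f, width = 500, height = 450)
    x <- delta_of(result$eeg, paste0("ratio_", cond))
    y <- delta_of(result$behavior, "tq")
    graphics::plot(x, y, xlab = sprintf("ratio change (%s)", cond),
                   ylab = "TQ change", main = "difference scores (t2-t1)")
    graphics::abline(stats::lm(y ~ x), lty = 2)
    grDevices::dev.off(); add(f)
  }
  files
}
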