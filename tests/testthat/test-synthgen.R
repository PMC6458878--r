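# Synthetic cohort generator: population draws, spectral content of the
# synthesized EEG, artifact injection and behavioral tables.

test_that("profile sampling follows the configured population distributions", {
  cfg <- cohort_config()
  profiles <- lapply(seq_len(1000), generate_subject_profile, config = cfg,
                     solve_spectra = FALSE)
  ages <- vapply(profiles, `[[`, 0, "age")
  expect_within(mean(ages), 46.29 - 3, 46.29 + 3)
  expect_within(min(ages), 24, 71)
  expect_within(max(ages), 24, 71)
  iafs <- vapply(profiles, `[[`, 0, "iaf_true")
  expect_within(min(iafs), 7.5, 12.5)
  expect_within(max(iafs), 7.5, 12.5)
  expect_true(all(vapply(profiles, `[[`, 0, "ec_alpha_gain") >= 1))
})

test_that("truncated sampling respects hard bounds at scale", {
  # brute-force check of the draw machinery behind iaf_true
  draws <- vapply(1:10000, function(i)
    generate_subject_profile(i, cohort_config(iaf_sd = 3),
                             solve_spectra = FALSE)$iaf_true, 0)
  expect_within(min(draws), 7.5, 12.5)
  expect_within(max(draws), 7.5, 12.5)
})

test_that("zero-variance config degenerates to identical profiles", {
  cfg <- cohort_config(age_sd = 0, iaf_sd = 0, background_exponent_sd = 0,
                       ec_alpha_gain_sd = 0, alpha_sd_between = 0,
                       delta_sd_between = 0, alpha_sd_within = 0,
                       delta_sd_within = 0,
                       behavior = effect_config(sd_between = c(thi = 0, tq = 0,
                                                               loudness = 0)))
  p1 <- generate_subject_profile(1, cfg)
  p2 <- generate_subject_profile(99, cfg)
  p2$subject_id <- p1$subject_id
  expect_equal(p1, p2)
  expect_equal(p1$age, 46.29)
  expect_equal(p1$iaf_true, 10)
})

test_that("identical seeds give bit-identical cohorts", {
  cfg <- cohort_config(n = 4)
  expect_identical(generate_cohort_profiles(cfg, seed = 7),
                   generate_cohort_profiles(cfg, seed = 7))
  pr <- generate_cohort_profiles(cfg, seed = 7)
  expect_identical(generate_behavior(pr, seed = 3),
                   generate_behavior(pr, seed = 3))
  sp <- training_spec(30)
  expect_identical(synthesize_recording(pr[[1]], spec = sp, seed = 5),
                   synthesize_recording(pr[[1]], spec = sp, seed = 5))
})

test_that("synthesized spectra carry the profile's alpha peak", {
  p <- generate_subject_profile(11, cohort_config(iaf_sd = 0, iaf_mean = 10))
  rec <- synthesize_recording(p, spec = training_spec(120), seed = 2)
  psd <- compute_psd(eeg_segments(list(rec$samples), rec$srate,
                                  rec$channel_names, eye_state = "EO"))
  sel <- psd$freqs >= 7 & psd$freqs <= 13
  pk <- psd$freqs[sel][which.max(colMeans(psd$power_db)[sel])]
  expect_lte(abs(pk - 10), 0.5)
})

test_that("null oscillation profiles give a pure 1/f spectrum", {
  p <- generate_subject_profile(11, cohort_config())
  p$alpha_amp_cells[] <- 0
  p$delta_amp_cells[] <- 0
  rec <- synthesize_recording(p, spec = training_spec(120), seed = 2)
  psd <- compute_psd(eeg_segments(list(rec$samples), rec$srate,
                                  rec$channel_names, eye_state = "EO"))
  sel <- psd$freqs >= 3 & psd$freqs <= 13
  bg_db <- 10 * log10(target_psd(p, psd$freqs[sel])) -
    10 * log10(exp(1)) * 0.5772157
  dev <- colMeans(psd$power_db)[sel] - bg_db
  # no oscillatory bump: nothing rises above the aperiodic background
  expect_lt(max(dev), 1.5)
})

test_that("eyes-closed alpha gain appears as the predicted dB increase", {
  cfg <- cohort_config(ec_alpha_gain_mean = 2, ec_alpha_gain_sd = 0,
                       bump_prominence_db = 15)
  p <- generate_subject_profile(21, cfg)
  sp <- recording_spec(duration_s = 240, srate = 250,
                       channels = training_channels(),
                       reference = "linked-earlobes", block_s = 30,
                       channel_db_jitter_sd = 0)
  rec <- synthesize_recording(p, spec = sp, seed = 4)
  segs <- segment_eo_ec(rec)
  rb <- band(round(p$iaf_true * 2) / 2 - 2, round(p$iaf_true * 2) / 2 + 2)
  d_eo <- band_power(compute_psd(segs$EO), rb)
  d_ec <- band_power(compute_psd(segs$EC), rb)
  freqs <- seq(rb[["low"]], rb[["high"]], by = 0.5)
  oracle <- mean(10 * log10(target_psd(p, freqs, eye_state = "EC"))) -
    mean(10 * log10(target_psd(p, freqs, eye_state = "EO")))
  expect_gt(oracle, 4.5)              # 20*log10(2) less the background share
  expect_lte(abs((d_ec - d_eo) - oracle), 1)
})

test_that("band power of the oscillatory target is recovered within 1 dB", {
  p <- generate_subject_profile(31, cohort_config())
  rec <- synthesize_recording(p, spec = training_spec(480), seed = 6)
  psd <- compute_psd(eeg_segments(list(rec$samples), rec$srate,
                                  rec$channel_names, eye_state = "EO"))
  iafg <- round(p$iaf_true * 2) / 2
  a <- band_power(psd, band(iafg - 2, iafg + 2))
  d <- band_power(psd, inhibit_band())
  expect_lte(abs(a - p$alpha_band_db["t1", "NT"]), 1)
  expect_lte(abs(d - p$delta_band_db["t1", "NT"]), 1)
})

test_that("recordings shorter than one EO/EC cycle are rejected", {
  p <- generate_subject_profile(1, cohort_config())
  sp <- recording_spec(duration_s = 45, block_s = 30, srate = 250,
                       channels = training_channels())
  expect_error(synthesize_recording(p, spec = sp), "cycle")
})

test_that("artifact injection is the identity at zero rates", {
  p <- generate_subject_profile(1, cohort_config())
  rec <- synthesize_recording(p, spec = training_spec(30), seed = 1)
  expect_identical(inject_artifacts(rec, artifact_config()), rec)
})

test_that("50 Hz bin power rises monotonically with line-noise amplitude", {
  p <- generate_subject_profile(1, cohort_config())
  rec <- synthesize_recording(p, spec = training_spec(60), seed = 1)
  s <- stats::sd(rec$samples[1, ])
  p50 <- vapply(c(0, 1, 3) * s, function(a) {
    r <- inject_artifacts(rec, artifact_config(line_amp = a, seed = 2))
    psd <- compute_psd(eeg_segments(list(r$samples), r$srate,
                                    r$channel_names, eye_state = "EO"))
    band_power(psd, band(50, 50))
  }, 0)
  expect_true(all(diff(p50) > 0))
})

test_that("artifact annotations describe every injected event", {
  p <- generate_subject_profile(1, cohort_config())
  rec <- synthesize_recording(p, spec = training_spec(60), seed = 1)
  art <- inject_artifacts(rec, artifact_config(blink_rate = 6, n_dead = 1,
                                               line_amp = 1, seed = 3))
  expect_setequal(unique(art$artifacts$type), c("blink", "line_noise", "dead"))
  expect_equal(sum(art$artifacts$type == "blink"), 6)
})

test_that("behavioral scores are constant when effects and noise are zero", {
  eff <- effect_config(means = rbind(thi = rep(29, 4), tq = rep(23, 4),
                                     loudness = rep(53, 4)),
                       sd_within = c(thi = 0, tq = 0, loudness = 0))
  pr <- lapply(1:5, function(i) stub_profile(sprintf("S%02d", i), 0))
  beh <- generate_behavior(pr, eff, seed = 1)
  spread <- tapply(beh$value, paste(beh$subject, beh$outcome),
                   function(v) diff(range(v)))
  expect_true(all(spread == 0))
})

test_that("default cohort reproduces the baseline THI level", {
  pr <- generate_cohort_profiles(cohort_config(n = 24), seed = 123,
                                 solve_spectra = FALSE)
  beh <- generate_behavior(pr, seed = 5)
  t1 <- beh$value[beh$outcome == "thi" & beh$timepoint == "t1"]
  expect_lte(abs(mean(t1) - 29.33), 2 * 14.70 / sqrt(24))
})

test_that("behavior values always stay inside the instrument ranges", {
  eff <- effect_config(sd_between = c(thi = 40, tq = 40, loudness = 40),
                       sd_within = c(thi = 30, tq = 30, loudness = 30))
  pr <- generate_cohort_profiles(cohort_config(n = 30, behavior = eff),
                                 seed = 2, solve_spectra = FALSE)
  beh <- generate_behavior(pr, eff, seed = 3)
  rng <- list(thi = c(0, 100), tq = c(0, 84), loudness = c(1, 100))
  for (oc in names(rng)) {
    v <- beh$value[beh$outcome == oc]
    expect_within(min(v), rng[[oc]][1], rng[[oc]][2])
    expect_within(max(v), rng[[oc]][1], rng[[oc]][2])
  }
})

test_that("the configured alpha/TQ coupling is recovered across cohorts", {
  set.seed(77)
  r_emp <- vapply(seq_len(100), function(rep) {
    dalpha <- rnorm(24, 0.2, 0.71)
    pr <- lapply(seq_len(24), function(i)
      stub_profile(sprintf("S%02d", i), dalpha[i]))
    beh <- generate_behavior(pr, effect_config(tq_alpha_corr = -0.4))
    tq <- beh[beh$outcome == "tq", ]
    dtq <- tq$value[tq$timepoint == "t2"] - tq$value[tq$timepoint == "t1"]
    cor(dalpha, dtq)
  }, 0)
  expect_within(mean(r_emp), -0.5, -0.3)
})

test_that("an infeasible correlation target is rejected", {
  expect_error(effect_config(tq_alpha_corr = -1.5), "correlation")
})
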