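# Spectral quantification: PSD grid, band power, IAF estimation, reward
# band construction and the alpha/delta ratio.

# hand-built spectrum object for exact-arithmetic checks
psd_stub <- function(power_db, channels, srate = 250) {
  nf <- ncol(power_db)
  structure(list(freqs = seq(0, by = 0.5, length.out = nf),
                 power_db = power_db, n_windows = 1,
                 channel_names = channels, eye_state = "EO",
                 condition = "NT"),
            class = "eeg_psd")
}

test_that("2 s windows give a 0.5 Hz frequency grid at both sampling rates", {
  for (fs in c(250, 1000)) {
    set.seed(1)
    rec <- eeg_recording(matrix(rnorm(fs * 10), 1), fs, "A")
    psd <- compute_psd(rec)
    expect_equal(unique(round(diff(psd$freqs), 9)), 0.5)
  }
})

test_that("a pure tone localizes at its own bin", {
  fs <- 1000
  t <- seq_len(fs * 20) / fs
  rec <- eeg_recording(matrix(sin(2 * pi * 10 * t), 1), fs, "A")
  psd <- compute_psd(rec)
  expect_equal(psd$freqs[which.max(psd$power_db[1, ])], 10)
})

test_that("white-noise spectra are flat across the analysis range", {
  set.seed(3)
  fs <- 250
  segs <- eeg_segments(list(matrix(rnorm(4 * fs * 201), 4)), fs,
                       paste0("c", 1:4), eye_state = "EO")
  psd <- compute_psd(segs)
  expect_gte(psd$n_windows, 200)
  sel <- psd$freqs >= 1 & psd$freqs <= 80
  m <- colMeans(psd$power_db)[sel]
  expect_lt(max(abs(m - mean(m))), 1.5)
})

test_that("windows shorter than the data raise an error", {
  rec <- eeg_recording(matrix(rnorm(100), 1), 250, "A")
  expect_error(compute_psd(rec), "window")
})

test_that("band power is the mean over inclusive band bins and channels", {
  pd <- matrix(7, 2, 101)                 # constant 7 dB everywhere
  psd <- psd_stub(pd, c("A", "B"))
  expect_equal(band_power(psd, band(3, 4)), 7)
  expect_equal(band_power(psd, band(0.5, 45)), 7)
  # trained delta band has exactly three bins: 3.0, 3.5, 4.0
  sel <- psd$freqs >= 3 & psd$freqs <= 4
  expect_equal(sum(sel), 3)
  expect_error(band_power(psd, band(50.2, 50.3)), "bins")
  expect_error(band_power(psd, band(3, 4), "NOPE"), "unknown")
})

test_that("band power matches integration of the generator's target spectrum", {
  p <- generate_subject_profile(9, cohort_config())
  rec <- synthesize_recording(p, spec = training_spec(300), seed = 2)
  psd <- compute_psd(eeg_segments(list(rec$samples), rec$srate,
                                  rec$channel_names, eye_state = "EO"))
  iafg <- round(p$iaf_true * 2) / 2
  freqs <- seq(iafg - 2, iafg + 2, by = 0.5)
  oracle <- mean(10 * log10(target_psd(p, freqs))) -
    10 * log10(exp(1)) * 0.5772157   # log-then-average estimation bias
  expect_lte(abs(band_power(psd, band(iafg - 2, iafg + 2)) - oracle), 0.5)
})

test_that("the standard band table matches the printed scheme", {
  sb <- standard_bands()
  expect_equal(sb$low[sb$band == "delta"], 0.5)
  expect_equal(sb$high[sb$band == "delta"], 4.0)
  expect_equal(sb$low[sb$band == "alpha"], 8.5)
  expect_equal(sb$high[sb$band == "gamma"], 45)
  # adjacent standard bands do not share bins on the 0.5 Hz grid
  expect_true(all(sb$low[match(c("theta", "beta1"), sb$band)] -
                    sb$high[match(c("delta", "alpha"), sb$band)] == 0.5))
})

test_that("IAF estimation recovers a strong synthetic peak", {
  cfg <- cohort_config(iaf_mean = 10.5, iaf_sd = 0)
  p <- generate_subject_profile(4, cfg)
  rec <- synthesize_recording(p, "t1", "NT",
                              training_spec(30, eye_pattern = "EC_only"),
                              seed = 11)
  est <- estimate_iaf(rec)
  expect_equal(est$iaf, 10.5)
  expect_equal(est$method, "peak-mean")
})

test_that("a noise-free grid-aligned peak is estimated exactly", {
  fs <- 250
  t <- seq_len(fs * 30) / fs
  x <- sin(2 * pi * 10 * t) + 0.1 * sin(2 * pi * 3 * t)
  rec <- eeg_recording(rbind(x, x), fs, c("a", "b"))
  est <- estimate_iaf(rec)
  expect_identical(est$iaf, 10)
})

test_that("peakless spectra fall back to the center of gravity", {
  p <- generate_subject_profile(4, cohort_config())
  p$alpha_amp_cells[] <- 0
  rec <- synthesize_recording(p, spec = training_spec(30, "EC_only"),
                              seed = 3)
  est <- estimate_iaf(rec)
  expect_equal(est$method, "gravity-fallback")
  expect_within(est$iaf, 7, 13)
})

test_that("the reward band is +/-2 Hz around the alpha peak", {
  rb <- reward_band(10)
  expect_equal(unname(rb[["low"]]), 8)
  expect_equal(unname(rb[["high"]]), 12)
  rb2 <- reward_band(7.5)
  expect_equal(as.numeric(rb2), c(5.5, 9.5))
  for (iaf in seq(7.5, 12.5, by = 0.5))
    expect_equal(diff(as.numeric(reward_band(iaf))), 4)
  # a reward band that would touch the inhibit range is refused
  expect_error(reward_band(5.9), "inhibit")
})

test_that("the ratio is ratio-then-average over channels", {
  pd <- rbind(c(rep(50, 7), rep(40, 95)),     # heterogeneous channels
              c(rep(55, 7), rep(60, 95)))
  pd[1, 17:25] <- 48; pd[2, 17:25] <- 66      # 8-12 Hz bins
  psd <- psd_stub(pd, c("A", "B"))
  r_impl <- alpha_delta_ratio(psd, band(8, 12), channels = c("A", "B"))
  a1 <- band_power(psd, band(8, 12), "A"); d1 <- band_power(psd, band(3, 4), "A")
  a2 <- band_power(psd, band(8, 12), "B"); d2 <- band_power(psd, band(3, 4), "B")
  oracle_rta <- mean(c(a1 / d1, a2 / d2))
  oracle_atr <- mean(c(a1, a2)) / mean(c(d1, d2))
  expect_identical(r_impl, oracle_rta)
  expect_false(isTRUE(all.equal(oracle_rta, oracle_atr)))
})

test_that("equal band powers give a ratio of exactly 1", {
  pd <- matrix(52, 4, 101)
  psd <- psd_stub(pd, training_channels())
  expect_equal(alpha_delta_ratio(psd, band(8, 12)), 1)
})

test_that("a non-positive denominator names the offending channel", {
  pd <- matrix(52, 4, 101)
  pd[2, 7:9] <- -1                             # 3-4 Hz bins of FC2
  psd <- psd_stub(pd, training_channels())
  expect_error(alpha_delta_ratio(psd, band(8, 12)), "FC2")
})

test_that("a constant dB offset shifts the ratio as (A+c)/(D+c)", {
  pd <- matrix(50, 4, 101)
  pd[, 17:25] <- 48                            # alpha bins
  psd <- psd_stub(pd, training_channels())
  r0 <- alpha_delta_ratio(psd, band(8, 12))
  psd_c <- psd; psd_c$power_db <- psd$power_db + 10
  r1 <- alpha_delta_ratio(psd_c, band(8, 12))
  expect_equal(r1, (48 + 10) / (50 + 10))
  expect_false(isTRUE(all.equal(r0, r1)))      # the absolute calibration matters
})

test_that("stronger alpha increases reward-band power and the ratio", {
  cfg_lo <- cohort_config(iaf_sd = 0)
  cfg_hi <- cohort_config(iaf_sd = 0,
                          alpha_db = cohort_config()$alpha_db + 3)
  p_lo <- generate_subject_profile(6, cfg_lo)
  p_hi <- generate_subject_profile(6, cfg_hi)
  sp <- training_spec(120)
  psd_lo <- compute_psd(eeg_segments(list(synthesize_recording(p_lo, spec = sp, seed = 2)$samples),
                                     250, training_channels(), eye_state = "EO"))
  psd_hi <- compute_psd(eeg_segments(list(synthesize_recording(p_hi, spec = sp, seed = 2)$samples),
                                     250, training_channels(), eye_state = "EO"))
  rb <- reward_band(10)
  expect_gt(band_power(psd_hi, rb), band_power(psd_lo, rb))
  expect_gt(alpha_delta_ratio(psd_hi, rb), alpha_delta_ratio(psd_lo, rb))
})

test_that("IAF recovery holds across a synthetic cohort", {
  profiles <- lapply(1:30, generate_subject_profile, config = cohort_config())
  hits <- vapply(seq_along(profiles), function(i) {
    rec <- synthesize_recording(profiles[[i]], "t1", "NT",
                                training_spec(30, "EC_only"), seed = 1000 + i)
    abs(estimate_iaf(rec)$iaf - profiles[[i]]$iaf_true) <= 0.5
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})
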