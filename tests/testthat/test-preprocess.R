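# Bad channels, spherical-spline interpolation, average referencing,
# EO/EC segmentation and the ICA stage.

base_rec <- function(duration_s = 60, channels = fixture_channels(),
                     seed = 4, block_s = 30) {
  p <- generate_subject_profile(3, cohort_config())
  synthesize_recording(p, spec = recording_spec(
    duration_s = duration_s, srate = 250, channels = channels,
    block_s = block_s, channel_db_jitter_sd = 0.3), seed = seed)
}

test_that("clean recordings yield no bad channels", {
  rec <- base_rec(channels = montage_channels(include_ref = FALSE))
  expect_length(detect_bad_channels(rec), 0)
})

test_that("injected dead and jump channels are recovered without false positives", {
  rec <- base_rec(channels = montage_channels(include_ref = FALSE))
  art <- inject_artifacts(rec, artifact_config(n_dead = 3, n_jump = 2,
                                               seed = 5))
  truth <- art$artifacts$channel
  found <- detect_bad_channels(art)
  expect_gte(sum(found %in% truth), 4)
  expect_equal(sum(!found %in% truth), 0)
})

test_that("more than ten bad channels reject the dataset", {
  rec <- base_rec(channels = montage_channels(include_ref = FALSE))
  art <- inject_artifacts(rec, artifact_config(n_dead = 11, seed = 5))
  expect_error(detect_bad_channels(art), "rejected")
})

test_that("bad-channel statistics require a minimum duration", {
  rec <- base_rec(duration_s = 30, block_s = 15)
  expect_error(detect_bad_channels(rec), "60 s")
})

test_that("spherical splines reconstruct a smooth topography", {
  chans <- montage_channels(include_ref = FALSE)
  pos <- electrode_positions(chans)
  set.seed(8)
  s1 <- rnorm(2000); s2 <- rnorm(2000)
  # smooth topographic field: two low-order spatial patterns
  x <- outer(pos[, "x"], s1) + outer(pos[, "z"], s2)
  rec <- eeg_recording(x, 250, chans)
  out <- interpolate_channels(rec, "Cz")
  expect_gt(cor(out$samples["Cz", ], x[match("Cz", chans), ]), 0.9)
  # non-interpolated channels untouched
  expect_identical(out$samples["Fp1", ], rec$samples["Fp1", ])
  # empty list is the identity
  expect_identical(interpolate_channels(rec, character()), rec)
})

test_that("interpolated channels stay within the neighbors' scale", {
  rec <- base_rec(channels = montage_channels(include_ref = FALSE))
  for (ch in c("Cz", "P3", "F4")) {
    out <- interpolate_channels(rec, ch)
    v_int <- stats::var(out$samples[ch, ])
    v_others <- apply(rec$samples[setdiff(rownames(rec$samples), ch), ], 1,
                      stats::var)
    expect_lte(v_int, max(v_others) * 1.5)
  }
  expect_error(interpolate_channels(rec, "NOPE"), "unknown")
})

test_that("average referencing reintroduces FCz and zeroes column means", {
  rec <- base_rec(channels = montage_channels(include_ref = FALSE))
  out <- rereference_average(rec)
  expect_length(out$channel_names, 65)
  expect_true("FCz" %in% out$channel_names)
  expect_lt(max(abs(colMeans(out$samples))), 1e-10)
  # idempotence
  out2 <- rereference_average(out)
  expect_equal(out2$samples, out$samples, tolerance = 1e-12)
  expect_length(out2$channel_names, 65)
})

test_that("EO/EC segmentation follows the markers", {
  rec <- base_rec(duration_s = 120)
  segs <- segment_eo_ec(rec)
  expect_equal(sum(vapply(segs$EO$segments, ncol, 0L)) / 250, 60)
  expect_equal(sum(vapply(segs$EC$segments, ncol, 0L)) / 250, 60)
  total <- sum(vapply(c(segs$EO$segments, segs$EC$segments), ncol, 0L))
  expect_lte(total, ncol(rec$samples))   # no overlap, nothing counted twice

  no_ev <- rec; no_ev$events <- data.frame(sample = integer(),
                                           label = character())
  expect_error(segment_eo_ec(no_ev), "marker")
})

test_that("span rejection drops stretches above threshold", {
  rec <- base_rec()
  spike <- rec
  spike$samples[1, 5000:5010] <- spike$samples[1, 5000:5010] +
    50 * stats::sd(rec$samples[1, ])
  rej <- reject_spans(spike)
  expect_gte(rej$n_rejected, 1)
  expect_false(all(rej$keep))
  expect_true(all(reject_spans(rec)$keep))
})

test_that("ICA separates independent sources and inverts exactly", {
  set.seed(5)
  n <- 5000; tt <- (1:n) / 250
  s <- rbind(sin(2 * pi * 7 * tt), sign(sin(2 * pi * 3.1 * tt)),
             runif(n, -1, 1))
  A <- matrix(rnorm(30), 10, 3)
  x <- A %*% s + matrix(rnorm(10 * n, 0, 0.01), 10)
  rec <- eeg_recording(x, 250, paste0("ch", 1:10))
  ica <- decompose_ica(rec, n_comp = 3, seed = 2, max_iter = 200)
  cors <- abs(cor(t(ica$activations), t(s)))
  expect_true(all(apply(cors, 2, max) > 0.95))
  # mixing o unmixing reconstructs the (rank-reduced) data
  recon <- ica$mixing %*% ica$activations + ica$center
  expect_lt(max(abs(recon - x)) / stats::sd(x), 0.05)
  # determinism
  ica2 <- decompose_ica(rec, n_comp = 3, seed = 2, max_iter = 200)
  expect_identical(ica$unmixing, ica2$unmixing)
  # rank limits are enforced
  expect_error(decompose_ica(rec, n_comp = 11), "rank")
})

test_that("removing no components is the identity", {
  rec <- base_rec(channels = fixture_channels())
  ica <- decompose_ica(rec, seed = 1, max_iter = 30)
  expect_identical(remove_components(rec, ica, integer()), rec)
  expect_error(remove_components(rec, ica, 999), "range")
})

test_that("blink components are flagged and their removal cleans Fp channels", {
  rec <- base_rec(channels = fixture_channels())
  amp <- 10 * stats::median(apply(rec$samples, 1, stats::sd))
  art <- inject_artifacts(rec, artifact_config(blink_rate = 15,
                                               blink_amp = amp, seed = 8))
  ica <- decompose_ica(art, seed = 2, max_iter = 150)
  flagged <- classify_artifact_components(ica, art)
  expect_gte(length(flagged), 1)
  cleaned <- remove_components(art, ica, flagged)
  blinks <- art$artifacts[art$artifacts$type == "blink", ]
  idx <- unlist(mapply(function(s, d) s:(s + d - 1), blinks$start_sample,
                       blinks$duration_samples))
  resid_before <- art$samples["Fp1", idx] - rec$samples["Fp1", idx]
  resid_after <- cleaned$samples["Fp1", idx] - rec$samples["Fp1", idx]
  expect_gte(1 - stats::sd(resid_after) / stats::sd(resid_before), 0.8)
  # removing true artifact components never pumps energy into a channel
  en_ratio <- rowSums(cleaned$samples^2) / rowSums(art$samples^2)
  expect_lte(max(en_ratio), 1.05)
})

test_that("artifact-free recordings are left alone by the classifier", {
  rec <- base_rec(channels = fixture_channels())
  ica <- decompose_ica(rec, seed = 2, max_iter = 60)
  expect_length(classify_artifact_components(ica, rec), 0)
})

test_that("the full chain cleans line noise without losing alpha power", {
  rec <- base_rec(duration_s = 120,
                  channels = montage_channels(include_ref = FALSE))
  art <- inject_artifacts(rec, artifact_config(
    line_amp = 2 * stats::sd(rec$samples[1, ]), seed = 9))
  segs_dirty <- segment_eo_ec(rereference_average(art), condition = "NT")
  segs_clean <- preprocess_recording(art, condition = "NT", mode = "light")
  p_dirty <- compute_psd(segs_dirty$EO)
  p_clean <- compute_psd(segs_clean$EO)
  expect_lt(band_power(p_clean, band(50, 50)) -
              band_power(p_dirty, band(50, 50)), -20)
  alpha_shift <- band_power(p_clean, band(8.5, 12)) -
    band_power(p_dirty, band(8.5, 12))
  expect_lt(abs(alpha_shift), 1)
  expect_equal(length(segs_clean$EO$channel_names), 65)
  expect_true(all(c("bad_channels", "removed_components", "interpolated",
                    "rejected_spans") %in% names(segs_clean$EO$provenance)))
})
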