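# Fixtures are generated in code; nothing is stored on disk.

# small multi-channel montage subset with parseable 5/10 labels
fixture_channels <- function() {
  c("Fp1", "Fp2", "AF3", "AF4", "F3", "F4", "FC1", "FC2",
    "Cz", "Pz", "O1", "O2", "C3", "C4", "P3", "P4")
}

# short 4-channel training-montage recording spec
training_spec <- function(duration_s = 60, eye_pattern = "EO_only") {
  recording_spec(duration_s = duration_s, srate = 250,
                 channels = training_channels(),
                 reference = "linked-earlobes", eye_pattern = eye_pattern,
                 channel_db_jitter_sd = 0)
}

# balanced long table: n subjects x T timepoints, subject offsets +
# timepoint shifts + residual noise
fixture_table <- function(n = 24, shifts = c(0, 0, 0, 0), sd_sub = 5,
                          sd_res = 1, outcome = "y", seed = 1) {
  tt <- length(shifts)
  set.seed(seed)
  sub <- sprintf("S%02d", seq_len(n))
  off <- rnorm(n, 0, sd_sub)
  rows <- expand.grid(subject = sub, timepoint = paste0("t", seq_len(tt)),
                      stringsAsFactors = FALSE)
  rows$outcome <- outcome
  rows$value <- off[match(rows$subject, sub)] +
    shifts[match(rows$timepoint, paste0("t", seq_len(tt)))] +
    rnorm(nrow(rows), 0, sd_res)
  rows
}

# minimal profile stub for behavioral Monte-Carlo (no spectral fields)
stub_profile <- function(id, alpha_change_db) {
  structure(list(subject_id = id, alpha_change_db = alpha_change_db,
                 behavioral_baseline = c(thi = 29.33, tq = 23.75,
                                         loudness = 53.25)),
            class = "subject_profile")
}

expect_within <- function(x, lo, hi) {
  expect_gte(x, lo); expect_lte(x, hi)
}
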