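---
title: "Individualized alpha/delta neurofeedback analysis: models and methods"
author: "alphadelta package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized alpha/delta neurofeedback analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphadelta)
```

## The scientific setting

Chronic subjective tinnitus is associated with a characteristic resting-state
EEG pattern: elevated delta-band power and reduced alpha-band power over
auditory areas.  Alpha/delta neurofeedback targets this pattern directly —
participants receive rewarding feedback when alpha power rises and inhibiting
feedback when 3–4 Hz delta power rises.  Because the frequency of the
dominant alpha peak (the individual alpha frequency, IAF) varies considerably
between people, a fixed 8–12 Hz reward band misrepresents alpha power for
many participants; the protocol analysed here instead determines each
participant's IAF from 30 s of resting EEG and rewards the individualized
band IAF ± 2 Hz.

The package implements the full analysis chain of such a study — synthetic
cohort generation, resting-state preprocessing, spectral quantification,
closed-loop session simulation and the repeated-measure statistics — as
testable R functions.  A design point worth stating up front: patient EEG
from such trials is not publicly deposited, so the synthetic-data generator
is a first-class, tested component, and every quantitative claim the test
suite makes is a claim about the pipeline's behavior on data with a known
ground truth.

## The synthetic EEG model

A subject's resting EEG is modelled in the spectral domain as

$$
P(f) \;=\; \frac{c_{\mathrm{bg}}}{f^{\chi}}
  \;+\; A_\alpha^2\, e^{-(f-\mathrm{IAF})^2 / 2\sigma_\alpha^2}
  \;+\; A_\delta^2\, e^{-(f-f_\delta)^2 / 2\sigma_\delta^2}
  \qquad [\mu V^2/\mathrm{Hz}],
$$

a 1/f^χ aperiodic background plus Gaussian alpha and delta bumps.  Signals
are synthesized by inverse FFT of this target amplitude spectrum with
independent random phases per channel and per eyes-open/eyes-closed block
(eyes-closed blocks multiply the alpha amplitude by the subject's
`ec_alpha_gain` ≥ 1).  Spectral synthesis rather than a neural-mass model
was chosen deliberately: the pipeline under test is spectral, and this
construction makes every band power analytically checkable
(`target_psd()` is the oracle the tests integrate directly).

Population defaults (`cohort_config()`):

* IAF ~ Normal(10, 1) truncated to [7.5, 12.5] Hz; background exponent
  χ ~ Normal(1.2, 0.15); eyes-closed alpha gain ~ Normal(1.7, 0.3)
  truncated at 1; age ~ Normal(46.29, 12.22) truncated to [24, 71] years.
* Band-power trajectories are parameterized directly in measured dB: each
  subject draws a target for the individualized alpha band and the 3–4 Hz
  delta band per timepoint (t1–t3) and condition (NT = no task, WT = with
  the instruction to attend to the tinnitus), as cohort mean + a
  between-subject offset (SD 1.5 / 1.86 dB) + a within-subject residual
  (SD 0.5 / 0.95 dB).  The cohort means encode a trained alpha/delta-ratio
  increase from ≈0.96 to ≈0.98 between t1 and t2 in the WT condition,
  with delta near 51–52 dB.
* The absolute calibration — background level such that trained-band dB
  values land near 51 dB — is an explicit constant of the generator, not a
  physiological claim; commercial analysis software applies an arbitrary
  absolute scale, and only ratios and differences carry meaning here.

Two technical constants matter for calibration accuracy.  First, the
analysis logarithmizes each 2 s window before averaging, and the log of a
χ²₂-distributed periodogram underestimates the true PSD by
10·log₁₀(e)·γ ≈ 2.51 dB; the generator adds this bias to its synthesis
targets so that *measured* band power equals the drawn target.  Second,
Hamming-window leakage smears steep spectral slopes slightly into
neighboring bands (≈0.2–0.4 dB in the 3–4 Hz band); this residual bias is
accepted and covered by the ±1 dB ground-truth recovery tolerance.

Behavioral scores (THI 0–100, TQ 0–84, loudness 1–100) follow
`subject baseline + timepoint effect + residual`, with marginal means and
variance components chosen to represent a mild-to-slight distress cohort
whose distress decreases after training and stays low, while loudness
reverts by the 6-month follow-up.  The correlation between each subject's
trained alpha-band change (t2−t1, dB) and TQ change is induced through a
shared latent Gaussian, which gives exact control of the target correlation
(default −0.4) before range clipping.

What the generator does **not** emulate: realistic scalp topographies of
oscillatory sources (channels are spectrally homogeneous up to a small gain
jitter; only blink artifacts carry a topographic gradient), non-stationarity
within blocks, pulse artifacts as a separate class, and any biophysical
tinnitus mechanism.  Passing tests therefore demonstrate that the pipeline
recovers known spectral and statistical structure — not that it would be
robust to every pathology of clinical EEG.

## Preprocessing

The chain mirrors standard resting-state practice:

* **Filtering.** Zero-phase (forward–backward) Butterworth filters:
  band-pass 0.1–80 Hz with 24 dB/octave at the low and 48 dB/octave at the
  high edge (single-pass orders 4 and 8 at 6 dB/octave/order), and a 50 Hz
  band-rejection filter of 1 Hz width, 24 dB/octave.  Slopes are specified
  per pass; the zero-phase application doubles the attenuation.  The
  high/low-pass cascade is implemented as second-order sections (analog
  prototype poles, bilinear transform per conjugate pair) because the
  expanded polynomial form of an order-4 high-pass at 0.1 Hz/1000 Hz is
  numerically ill-conditioned; the sections keep the filter linear to
  ~10⁻⁸ relative, which the suite asserts.
* **Bad channels.** Automated surrogate for visual inspection: dead
  channels (variance floor), noisy channels (robust z of log-variance > 5)
  and jump channels (sliding-median step > 20 × the MAD of the channel
  derivative).  More than ten flagged channels reject the dataset, the
  pre-defined exclusion rule.
* **ICA.** Restricted Infomax: PCA whitening to the numerical rank of the
  retained channels, then extended-Infomax natural-gradient unmixing (the
  kurtosis-sign extension is required to separate sub-Gaussian sources; a
  plain logistic nonlinearity cannot).  Unmixing is estimated on an evenly
  subsampled stretch (default cap 30 000 samples) and applied to all data.
  Component classification is automated: blink components by correlation
  with a low-passed frontal template plus a frontal-dominant topography,
  muscle components by a rising high/low spectral ratio, line components by
  45–55 Hz dominance.
* **Interpolation.** Spherical-spline (Perrin-type) interpolation of bad
  channels on idealized spherical 5/10 positions generated from the label
  grammar; m = 4, 20 Legendre terms, ridge 10⁻⁵.
* **Span rejection.** The visual rejection of residual artifacts is
  replaced by a deterministic amplitude rule on 1 s spans.  Because the
  generator's absolute calibration makes signal RMS ~10³ µV, the default
  threshold is expressed in robust-sigma units (8 × median channel MAD);
  an absolute µV threshold remains available.
* **Referencing and segmentation.** The implicit recording reference (FCz)
  is reintroduced as a zero channel before average referencing (64 → 65
  channels, column means exactly zero, idempotent), and the data are split
  into eyes-open/eyes-closed segments at the event markers; eyes-open
  segments are the analysis default.  Trailing spans shorter than one 2 s
  analysis window are dropped.

## Spectral quantification

Power spectra use 2 s Hamming windows with 1 s overlap; each window's FFT
power (one-sided PSD, µV²/Hz) is converted to dB and the dB values are
averaged across windows — the log-then-average order, preserved deliberately
because it is *not* equivalent to averaging linear power.  The grid is
exactly 0.5 Hz.  Band power is the mean dB over a band's bins, inclusive at
both edges; adjacent standard bands (delta 0.5–4, theta 4.5–8, …,
gamma 35.5–45 Hz) therefore share no bins, and the trained 3–4 Hz inhibit
band contains exactly three bins.

**IAF estimation** follows the protocol's "average alpha peaks over 30 s"
rule, interpreted per analysis window: each 2 s window contributes the
frequency of the local maximum of its channel-mean spectrum within
7–13 Hz.  Two numerical guards make this robust: the window spectrum is
smoothed over 3 bins and a peak must rise ≥ 2.5 dB above the chord between
the search-range endpoints, because raw χ² estimation noise would otherwise
produce a spurious "local maximum" in nearly every window of a peakless 1/f
spectrum.  The per-window peaks are combined by their median — near the
search-range edges the peak distribution is truncated and the arithmetic
mean is biased toward the center (`average = "mean"` remains available).
If more than half of the windows yield no qualifying peak, the estimate
falls back to the spectral center of gravity over the search range and is
tagged `gravity-fallback`.  The estimate is reported on the 0.5 Hz grid.

The **reward band** is IAF ± 2 Hz (always 4 Hz wide, not clipped at the
standard alpha borders); a reward band that would touch the 3–4 Hz inhibit
range raises an error rather than being silently adjusted.  The
**alpha/delta ratio** divides reward-band dB by inhibit-band dB per channel
and then averages over the four training electrodes (FC1, FC2, F3, F4) —
ratio-then-average, which differs measurably from average-then-ratio on
heterogeneous channels, and which the tests pin against a two-path oracle.
Because the ratio is formed on the dB scale, it is *not* invariant under a
constant dB offset; this sensitivity is asserted by the suite and is the
reason the generator's absolute calibration is part of the study
conditions.

## The closed-loop simulator

The training montage is FC1, FC2, F3, F4 against linked earlobes at
250 Hz.  The online loop uses 0.5 s chunks with a 0.25 s hop (the
commercial loop's timing is unpublished; both are configurable); chunks
shorter than 1 s are zero-padded to a 1 Hz grid so that the 3–4 Hz inhibit
band always contains bins.  Feedback is a bounded monotone map: ship speed
is a logistic of (reward-band dB − rolling baseline), autopilot accuracy a
decreasing logistic of the inhibit band, with the baseline accumulated as
an exponentially weighted average over the first 30 s and then frozen — a
causal normalization that uses no future data.  An artifact gate excludes
chunks whose peak-to-peak amplitude or 45–55 Hz power (total linear band
power, so empty bins cannot mask a line component) exceeds thresholds
calibrated from the session start; gated chunks emit no band-power values
and freeze the displayed feedback.

The learner is deliberately minimal — no learning model is claimed by the
protocol: its alpha amplitude gain drifts upward in proportion to the
time-averaged speed feedback, bounded to [0.1, 10] to keep the positive
feedback loop stable.  This suffices for the properties the suite checks:
zero learning rate changes nothing, a fully gated session changes nothing,
and a reward band matched to the learner's alpha peak produces
systematically more gain drift than a mis-set band.

## Statistics

All outcome tables are balanced long tables (subject × timepoint ×
outcome).  The core model is a random-intercept-per-subject linear mixed
model with a fixed timepoint factor, fitted by `nlme::lme`:

* **Time ANOVA.** χ² is the maximum-likelihood likelihood-ratio statistic
  against the intercept-only null, with T − 1 degrees of freedom (REML is
  not used for the LRT).
* **A priori contrasts.** One contrast per post-baseline timepoint, taken
  from the REML fit's timepoint coefficients.  The residual df convention
  is N_obs − N_subjects − (T − 1): 69 for 24 subjects × 4 timepoints and
  46 for 24 subjects × 3 — `nlme`'s innermost-level denominator df
  reproduces this exactly.  Reported p values are one-tailed (half the
  two-tailed p of the observed t) and Bonferroni-multiplied by the number
  of contrasts, capped at 1.  The hypothesized direction must be declared
  and is reported as a consistency flag; the p value itself follows the
  observed tail, the convention under which the published significant
  contrasts reproduce at three decimals.
* **Effect sizes.** r = √(t²/(t²+df)); strictly increasing in |t|,
  strictly decreasing in df, symmetric in the sign of t.
* **Baseline vs mean follow-up.** The (+1, −⅓, −⅓, −⅓) contrast with
  model-based standard error and the same df convention; the sign is
  reported in the direction of change from baseline (a decrease is
  negative).
* **Tukey post hoc.** All pairwise timepoint comparisons with single-step
  multivariate-t adjustment (`mvtnorm::pmvt` on the contrast correlation
  matrix, residual df, fixed quasi-Monte-Carlo seed for reproducibility);
  for two timepoints the family collapses to the unadjusted test.
* **Difference-score correlations.** Pearson r of per-subject (t2 − t1)
  changes with an n − 2 df t test, one-tailed, reported in `r(df)` form.
* **Benjamini–Hochberg** adjustment (`stats::p.adjust`) for the
  questionnaire correlation matrix context; the difference-score
  correlations are reported one-tailed without BH.
* **Within-subject error bars.** Cousineau subject-centering followed by
  the Morey correction √(T/(T−1)).
* **Age control.** Median split (ties to the young group, so a
  median-aged subject is "young"), time × group interaction added to the
  mixed model, ML likelihood-ratio test against the time-only model
  (df = (T − 1) + 1).

Degenerate inputs are handled explicitly: a constant outcome yields
χ² = 0, p = 1 without attempting a singular fit; unbalanced tables are
rejected with an informative error.

## The study runner and simulation scale

`run_study()` chains all stages: cohort generation, optional weekly
neurofeedback sessions, per-subject IAF determination from a 30 s
eyes-closed training-montage baseline, synthesis and preprocessing of the
t1–t3 resting recordings in both conditions, eyes-open spectral
quantification of the individualized alpha band, the 3–4 Hz delta band and
their ratio over the training electrodes, and the statistical chain.  A
single seed drives every random draw; two runs with the same configuration
produce byte-identical results JSON.

The bundled runner defaults to 64-channel recordings of 120 s at 250 Hz
(four 30 s EO/EC blocks) and 120 s sessions, with the `light`
preprocessing chain (filters, span rejection, referencing, segmentation) on
artifact-free synthetic recordings; the `full` chain (bad channels, ICA,
interpolation) is exercised on artifact-injected fixtures in the unit
tests.  These sizes are the package's choice of simulation scale: the
statistical structure of the cohort lives in the generator's band-power
draws, and longer recordings only shrink the spectral estimation noise
(~0.2 dB per band at 120 s) that is already far below the between-subject
variation.  The per-recording specification retains the full protocol
defaults (8 min at 1000 Hz, 65-channel montage) for users who want them.

## Known limitations

* EO/EC block durations are not prescribed by the protocol; 30 s is a
  configurable default.
* Whether IAF determination and the ratio analysis used eyes-open or
  eyes-closed data is not fully specified; the defaults are eyes-closed
  for IAF (stronger peak) and eyes-open for the ratio (the stated primary
  outcome condition), both configurable.
* The ICA component rejection emulates an originally visual step; only the
  automated thresholds documented here are normative for this package.
* The alpha/delta ratio of log-powers inherits the arbitrary absolute dB
  calibration; comparisons are meaningful within a calibration only.
* The learner model is a one-parameter abstraction; it supports sign- and
  ordering-level claims about closed-loop training, nothing quantitative
  about human learning curves.
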