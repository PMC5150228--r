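# eeglifespan

Population-scale spectral analysis of four-channel consumer EEG across
adulthood.

Consumer EEG headbands (channels TP9, AF7, AF8, TP10, sampled at 220 Hz)
make it possible to record thousands of people outside the laboratory and
ask how resting EEG changes year by year across the adult lifespan: band
power in δ (0–2 Hz), θ (3–7 Hz), α (8–13 Hz) and β (14–30 Hz); the peak
alpha frequency (PAF), which slows gradually with age; and frontal /
temporoparietal alpha asymmetry. This package is a tested, reusable
implementation of that analysis for researchers who have such cohorts — or
who want to study the estimators themselves on synthetic cohorts with known
ground truth, since the large consumer databases are proprietary.

## What it computes

**Preprocessing** (`clean_session`, `preprocess_cohort`): 50/60 Hz notch and
2–36 Hz zero-phase Butterworth filtering, division into 256-sample epochs
(1.16 s at 220 Hz), rejection of any epoch whose mean squared amplitude
exceeds 275 µV² on any channel, exclusion of sessions losing >10% of epochs
on any channel (a rejected calibration or neurofeedback recording excludes
its partner), and retention of at most the first five clean sessions per
user and task.

**Spectral features** (`compute_psd`, `band_power`, `alpha_peak`,
`alpha_asymmetry`): averaged 220-sample rectangular-window periodograms give
exact 1-Hz bins satisfying Parseval's identity; band powers are inclusive
bin sums, log10-transformed; PAF is the 8–13 Hz argmax, reported only when
it is a strict local maximum; asymmetry is log10(right α) − log10(left α).

**Population model** (`fit_age_trend`): weighted least squares on per-(age,
sex) cell means, weights equal to cell counts, with age centred at 42 years
(a = age − 42; sex s: male = 0, female = 1):

    y = b0 + b1·a + b2·a² + b3·s + b4·a·s + b5·a²·s + ε

The coefficients are algebraically identical to ordinary least squares on
the individual-level data; only R² differs. When the sex interactions are
jointly significant, separate per-sex age models are refitted. Supporting
statistics: pooled sex t-tests, within- vs between-age variance
decomposition, cross-feature correlation, Tukey-style distribution
summaries.

**Synthetic cohorts** (`sample_cohort`, `render_session`, `write_cohort`,
`simulate_user_features`): seeded cohorts whose raw sessions are inverse-FFT
renders of a parametric 1/f-plus-Gaussian-alpha-bump spectrum with known
age/sex trends (defaults follow a published 6029-user reference population),
plus injected high-amplitude artifact bursts with recorded ground truth.

`run_pipeline()` chains synth → preprocess → features → model into one
file-backed, bit-reproducible run.

## Worked example

```r
library(eeglifespan)

# a small synthetic cohort with the default generative trends
cfg <- run_config(
  cohort = cohort_config(n_users = 150, sessions_per_user = c(1, 2),
                         session_duration = c(CAL = 30, NFB = 60), seed = 1),
  artifact = artifact_model(epoch_rate = 0.02),
  measures = "alpha_peak", seed = 1)
out <- run_pipeline(cfg, "run1")

subset(out$coefficients,
       measure == "alpha_peak" & channel == "TP10" & task == "NFB",
       select = c(intercept, age, sex, r_squared))
#>  intercept         age        sex r_squared
#>   9.303385 -0.01756543 -0.1121101 0.2401186
```

The generative model slows the alpha bump by 0.01891 Hz/year from
9.54 Hz at age 42; the pipeline recovers the slope (−0.0176, within
sampling error at 150 users) after filtering, artifact rejection and
integer-Hz peak detection. The intercept sits ~0.2 Hz below the generative
centre because the 1/f background tilts the integer-bin argmax slightly
toward lower frequencies — a property of the printed-resolution estimator
itself, discussed in the vignette.

```r
fit <- out$fits[["alpha_peak.TP10.NFB"]]
summary(fit)   # coefficient table with stars, per-sex refits if triggered
plot(fit)      # cell means sized by user count, fitted curves per sex
```

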