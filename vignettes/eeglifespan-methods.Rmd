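---
title: "Methods: population EEG spectral trends and their synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population EEG spectral trends and their synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eeglifespan)
```

This vignette is the package's account of its science: the cleaning chain
and spectral estimators, the weighted age-trend regression, the generative
model behind the synthetic cohorts, and the numerical and design decisions
taken where the procedure left room for choice.

## The measurement problem

Four-channel consumer headbands (TP9, AF7, AF8, TP10 referenced near Fpz,
220 Hz) record EEG at home, unattended. Such data are plentiful but noisy:
motion, electrode pops and electromyographic bursts contaminate epochs, and
individual sessions are short. The analysis therefore has three layers:
an artifact gate that discards contaminated epochs and sessions wholesale;
robust, low-resolution spectral summaries (1-Hz bins, integer-Hz band
edges) that average away what survives; and a population regression that
models per-age means rather than individuals, exploiting the fact that a
cohort has many users at every age of adulthood.

## Artifact gating

Each raw session is notch-filtered at its regional line frequency (50 or
60 Hz; the line frequency must be stated — the package refuses to guess)
and band-passed to 2–36 Hz. Both filters are zero-phase Butterworth
designs applied forward and backward (`signal::filtfilt`): the notch is an
order-2 band-stop at f0 ± 1 Hz (measured attenuation at f0 exceeds
100 dB; passband ripple in 2–36 Hz is below 0.01 dB), and the band-pass is
a cascade of an order-2 high-pass at 2 Hz with an order-5 low-pass at
36 Hz. The cascade was chosen over a single band-pass section for
numerical robustness at the very low normalized corner (2/110) and to meet
an explicit attenuation contract: at least 20 dB at 45 Hz and above, DC
removed exactly, 5–30 Hz within 1 dB. Measured: −25 dB at 45 Hz, −62 dB at
60 Hz, −0.98 dB at 30 Hz. The filter family is a means to these measured
contracts, which the test suite asserts tone by tone; any compliant design
could be substituted.

The filtered signal is cut into consecutive non-overlapping 256-sample
epochs (1.16 s at 220 Hz; a trailing remainder is discarded). An epoch's
*overall power* is its mean squared amplitude in µV². Mean — rather than
sum — makes the quantity duration-invariant, so the 275 µV² rejection
threshold has the same meaning for any epoch length. An epoch is rejected
when its power *strictly exceeds* 275 µV² on any channel ("exceeding":
exactly 275 is kept); rejected epochs are dropped from *all* channels so
left and right channels stay time-aligned for asymmetry, but rejection
fractions are tracked per channel. A session is excluded when any
channel's rejected fraction strictly exceeds 10%, and exclusion of either
member of a calibration/neurofeedback (CAL/NFB) pair — keyed by (user,
session order) — excludes both. Per user and task, only the first five
*clean* sessions are retained; sessions with fewer than 10 surviving
epochs are flagged `too_short` and excluded (a guard against degenerate
spectra; the procedure as published is silent on very short sessions).

Because both thresholds are strict inequalities, the boundary behaviour is
exact and testable: epoch powers {274, 275, 276} → keep, keep, reject;
channel fractions {0.100, 0.101} → keep, reject.

## Spectra and derived features

The retained epochs are concatenated and tiled with non-overlapping
**220-sample rectangular windows**; per-window periodograms are averaged
and folded one-sided onto integer frequencies 0–110 Hz. The 220-sample
window is a deliberate reconciliation: 256-sample epochs at 220 Hz cannot
give exact 1-Hz bins, and the published description asks for both ("256
samples" and "frequency resolution of 1 Hz"). Using the sampling rate as
the window length makes the 1-Hz grid exact without zero-padding or
interpolation, at the cost of decoupling the spectral windows from the
artifact epochs. The choice is isolated inside `compute_psd`. Rectangular
windows keep Parseval's identity exact — the bin sum equals the mean
squared amplitude of the analysed samples — which the tests assert to
1 × 10⁻¹⁰ against a naive O(n²) discrete-Fourier-transform oracle and to
1% on full cleaned synthetic sessions.

Band powers are inclusive integer-bin sums (δ 0–2, θ 3–7, α 8–13, β 14–30,
lower α 8–10, upper α 11–13, total 0–30 Hz), so lower α + upper α = α
*exactly*. Powers are log10-transformed; a zero band power yields an
absent feature (NA), never −∞. Peak alpha frequency is the argmax over
the 8–13 Hz bins, reported only when it strictly exceeds both neighbouring
bins (neighbours taken from the full grid, so 8 and 13 Hz are judged
against 7 and 14 Hz); ties break to the lower frequency. This local-maximum
rule operationalizes "visible alpha peak": a monotone 1/f spectrum has no
peak, which is why frontal channels — where the bump is weak — show far
lower peak prevalence than temporoparietal ones. Alpha asymmetry is
log10(right α) − log10(left α) per region (AF8−AF7, TP10−TP9); negative
values mean stronger left alpha.

Per user and task, features are averaged over the retained sessions
(at most five). Averaging operates on the log scale
(transform-then-average), matching the order in which the transform is
introduced in the source procedure; the alternative (average power, then
log) differs by Jensen's inequality but was not adopted. Peak alpha is
averaged over the sessions where a peak was present, with the count
recorded so regression weights can reflect it.

## The weighted age-trend model

For one feature, one channel and one task, user-level values are collapsed
to (age, sex) cell means with weights equal to cell counts, and the model

y = b₀ + b₁·a + b₂·a² + b₃·s + b₄·a·s + b₅·a²·s,  a = age − 42, s ∈ {0, 1}

is fitted by weighted least squares. Cells are (age × sex), not age alone:
with sex in the model, only sex-separated cells preserve the identity that
the weighted cell-level coefficients equal ordinary least squares on the
raw user-level rows. That identity is exact linear algebra, not an
approximation, and the acceptance suite checks it to 1 × 10⁻⁸ against a
normal-equations oracle at cohort sizes 50, 500 and 2000. Centring at 42
years makes the intercept the predicted value for a male at 42 (asserted
exactly via `predict`), and the sex coefficient the female−male difference
there. R² from the cell-level fit is reported; it always dominates the
user-level R² because averaging removes within-age variance — both are
computed in the tests.

Coefficient p-values use the **cell-level residual degrees of freedom**
(the weighted residuals √nᵢ(ȳᵢ − ŷᵢ) are i.i.d. normal under the model, so
the cell-level t- and F-statistics are exact); the convention is recorded
in the run metadata. Significance markers follow the four-threshold star
convention (0.05, 0.01, 0.001, 0.0001) and are a pure function of p. No
multiple-testing correction is applied, matching the uncorrected reporting
style the tables mirror.

**Per-sex refits.** When the sex interactions matter, separate age + age²
models are refitted for males and females. The trigger is a *joint F-test*
of (b₄, b₅) at α = 0.05. The more literal reading — refit when *either*
interaction coefficient is individually significant — is available as
`refit_trigger = "either"`, but it is a union of two roughly independent
5%-level tests and therefore fires on ≈ 9.7% of null data; the joint test
has exact 5% size at the cell level, which the acceptance suite verifies
over 1000 null cohorts (binomial band 3.5–6.5%). A sex with fewer than
four cells is skipped with a warning.

Supporting statistics: pooled two-sample sex t-tests (df = n − 2);
within-age versus between-age variance decomposition with ages ≥ 78 pooled
into one bin (population thins to ≤ 2 users per year there; sexes pooled
by default, `split_sex = TRUE` separates); Pearson cross-feature
correlation with a simple-regression slope; and five-number summaries with
Tukey fences. Quartiles are medians of the lower and upper halves of the
sorted sample with the middle value excluded for odd n (so 1..7 gives
Q1 = 2, Q3 = 6); adjacent values are the most extreme observations inside
Q1 − 1.5·IQR and Q3 + 1.5·IQR.

## The synthetic cohort generator

Real consumer-EEG databases are proprietary, so every downstream stage is
tested against seeded synthetic cohorts with known generative truth. A
subject's one-sided target spectral density is

S(f) = g_ch · 10^(s·Δ) · [ c·f^(−β) + plateaus(f) + h·b·exp(−(f − μ)² / 2σ²) ]

with an aperiodic 1/f^β background (held flat below 1 Hz so low-frequency
energy stays bounded, zero at DC), optional per-band plateaus, and a
Gaussian alpha bump whose centre follows the quadratic age trend
μ = μ₀ + μ₁(age − 42) + μ₂(age − 42)² plus a per-subject deviation. The
Gaussian shape is a conventional parameterization chosen to make the true
peak analytically known; nothing downstream depends on it.

Defaults, chosen once as the package's study conditions:

| parameter | default | rationale |
|---|---|---|
| cohort size / age / sex | 6029 users, 18–88 y, 27.4% female | reference population's Table of user counts, expanded uniformly within decade bins |
| μ₀, μ₁, μ₂ | 9.54145 Hz, −0.01891 Hz/y, 0 | reference TP10 peak-frequency regression row, used as generative truth |
| background c, β | 2 µV²/Hz, 1.0 | EEG-typical aperiodic slope; with the bump height below, log α power at TP10 ≈ 0.46, matching the reference intercept magnitude |
| bump h, σ | 0.5 µV²/Hz, 1.5 Hz | visible temporoparietal peak over the background |
| channel gains | TP 1.0, AF 0.35; bump gain AF 0.25 | temporoparietal power exceeds frontal; weak frontal bumps reproduce the much lower frontal peak prevalence |
| sex offset Δ | 0.05 log10 units | a ~12% power excess in females; at the reference cohort size this yields a pooled t near the reported magnitude |
| per-subject variability | alpha-centre SD 0.75 Hz (truncated to keep the bump in 8.25–12.75 Hz), lognormal bump scale (sdlog 0.5) | within-age spread dominates between-age spread, as in real cohorts; also dithers the integer-Hz peak quantization so the age regression is unbiased |
| feature noise | 0.3 log10 units (band power), 0.8 Hz (peak) | residual SDs for the feature-level simulator |
| sessions | 1–7 recorded per user; CAL 60 s, NFB 180 s | reference task durations; tests and the acceptance script use shorter renders (30/60 s) and smaller cohorts, stated below |
| artifacts | Bernoulli rate 0.05 per 256-sample window; 25 Hz sinusoid at 100 µV, same windows on all channels | epoch power 5000 µV² ≫ 275 and inside the passband, so ground truth is recoverable; a broadband spike would be attenuated below threshold by the band-pass |

Sessions are rendered by inverse FFT with deterministic spectral
amplitudes and i.i.d. uniform phases. Consequences: the signal's mean
square equals the integral of the target density *exactly* (asserted to
1 × 10⁻¹⁰), and the averaged periodogram converges to the target spectrum
(asserted bin-wise within 20% over 2–36 Hz on a 300-s render). Phase
randomization yields stationary, Gaussian-like signals.

**What the generator does not emulate.** Real EEG is nonstationary, has
physiologically structured artifacts (blinks, EMG with 1/f-ish spectra,
electrode drift), narrowband line harmonics, and session-level noise
heterogeneity — the reference population lost 47% of sessions to the >10%
rule, which a homogeneous Bernoulli burst rate cannot reproduce. Passing
tests therefore demonstrate that the *estimators* are correct and that the
pipeline recovers known trends through filtering, rejection and
quantization; they do not certify performance on real recordings.

One estimator property the synthetic cohorts expose deliberately: with a
1/f background, the integer-Hz argmax sits slightly below the true bump
centre (the background tilts adjacent bins), so the end-to-end intercept
lands ~0.2 Hz under the generative 9.54 Hz while the *slope* — the
scientific quantity — is recovered without bias once per-subject
variability dithers the grid. This is a property of printed-resolution
peak pickers generally, not of the implementation.

## Problem sizes and numerical tolerances

The test suite and acceptance script size their simulations for one CPU:
end-to-end raw-signal runs use 150-user cohorts with 30/60-s sessions
(slope-sign and magnitude recovery); the WLS≡OLS identity is checked at
n ∈ {50, 500, 2000} (tolerance 1 × 10⁻⁸); parameter recovery uses 100
feature-level cohorts of 2000 users (the fitted age coefficient must lie
within 3 standard errors of the generative −0.01891 in ≥ 95 of 100); refit
calibration uses 1000 cohorts of 300 users. Feature-level simulation is
used for the statistical suites because the recovery claims concern the
regression layer, for which rendering raw signal adds cost but no
information; raw-signal recovery is exercised separately end to end.

Degenerate inputs are handled explicitly: empty cohorts and manifests,
sessions shorter than one epoch (`too_short`), zero band power (absent
feature), spectra without a local alpha maximum (absent peak), all-NA
cells (dropped, weights adjusted), rank-deficient designs (error naming
the collinear terms), and a missing line frequency (error, never a silent
default).

## Known limitations

- The cleaning chain is a batch reconstruction; the headset's real-time
  signal-quality classifier and feedback logic are out of scope.
- Repeated sessions per user are averaged, not modelled; no longitudinal
  or mixed-effects structure.
- The generator's defaults are illustrative study conditions, not
  estimates fitted to any real cohort's spectra.
- Coefficient p-values use cell-level df; with thousands of users the
  practical difference from user-level df is negligible for the
  coefficients, but the convention matters for small synthetic cohorts and
  is therefore stamped into the run metadata.
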