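---
title: "Methods: timing variability, midfrontal rhythms, and the statistical chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: timing variability, midfrontal rhythms, and the statistical chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timefront)
```

## The scientific problem

In a time-production task, a participant reads an interval instruction
("short" = 3 s, "long" = 7 s), watches for an imperative "Go" cue, and
presses the spacebar when they judge the target interval to have elapsed.
The keypress time is the behavioral readout; its per-subject coefficient of
variation (CV = sd / mean) indexes timing *precision* independently of
accuracy. In Parkinson's disease (PD), mean keypress times are typically
near-normal while the CV is elevated, and the elevation tracks cognitive
impairment as screened by the Montreal Cognitive Assessment (MOCA, 0--30,
lower = worse).

On the neural side, the imperative cue evokes a brief midfrontal
low-frequency burst (delta, 1--4 Hz, maximal a few hundred ms post-cue at
the vertex electrode Cz) that is attenuated in PD. `timefront` implements
the full analysis chain that links these three levels — trial-wise EEG
power, timing precision, and cognition — together with a calibrated
synthetic-data generator so that every stage of the chain can be exercised,
tested, and power-checked without access to patient data.

## The synthetic generator

`synthetic_profile()` collects every generative constant;
`profile_paper_default()` is the calibrated study profile used throughout
the tests.

**Behavior.** Subject $i$ in group $G$ has a latent variability factor
$\lambda_i$ with group mean 1. Keypress times for interval $I$ are drawn as

$$R_{it} \sim \mathcal N\!\big(\mu_{G,I},\; \lambda_i\,\sigma_{G,I}\big),
\qquad R_{it} > 0.2\ \mathrm s,$$

with $\mu_{G,I}$ and $\sigma_{G,I}$ set so the group-level means and CVs are
3.2/6.1/3.2/6.4 s and 0.19/0.15/0.23/0.22 (control-3s/control-7s/PD-3s/
PD-7s). The truncation at 0.2 s only rules out nonphysical presses; at
these parameters it essentially never binds. A single $\lambda_i$ drives
both intervals, which also reproduces the strong empirical correlation
between 3-s and 7-s CVs.

In the PD arm, $\lambda_i$ is tilted linearly in the centred MOCA score
(slope `cv_moca_link`, expressed in CV units per MOCA point at the 7-s
interval) and multiplied by lognormal subject noise with
`cv_subject_sdlog` = 0.32. The lognormal scale follows from the reported
between-subject spread of the CV (a standard error of about 0.01 at
n = 71 implies a subject sd near 0.084, i.e. a relative spread of ~0.38);
the link slope (−0.0094) was then calibrated once, by bisection over
simulated cohorts, so that the median PD Spearman correlation between MOCA
and the measured 7-s CV at n = 71 is approximately −0.39. Both constants
were frozen before the recovery tests were written and are not tuned
afterwards.

MOCA is drawn per group (control 26.6 ± 1.9, PD 24.3 ± 3.6, integer,
clipped to 0--30); the PD motor score (mUPDRS) is 13.4 ± 7.2, clipped to
0--56. The motor score is generated independently of the CV: the profile
deliberately contains no motor-variability link, so analyses that regress
CV on mUPDRS see, by design, only whatever spurious association a finite
cohort produces. Attrition at the 3-s interval is emulated through
`n_complete`: 31 controls and 52 PD patients receive the full 40 trials,
the remainder 12 (below the "more than 20 trials" inclusion filter), so
filtered 3-s cohorts have the study's sizes.

**EEG.** Cue-locked epochs are 1/f ("pink") background noise (RMS 20 µV)
plus a Gaussian-windowed sinusoidal burst:

$$x_t = \mathrm{pink}_t + g_{it}\,\mathrm{RMS}\cdot
  e^{-(t-t_0)^2/2w^2}\cos\!\big(2\pi f_b (t - t_0) + \phi_{it}\big)$$

with carrier $f_b$ = 2.5 Hz (the centre of the delta band; no generative
frequency is dictated by the phenomenon itself), envelope centre
$t_0$ = 350 ms and sd $w$ = 50 ms so the burst fills the canonical
300--400 ms analysis window. A fraction `phase_locking_frac` = 0.6 of
trials share $\phi = 0$; the rest get uniform phases — enough partial
locking that inter-trial phase clustering (ITPC) is clearly detectable at
40 trials. The subject gain derives from the group gain (tilted by MOCA,
lognormal subject noise, sdlog 0.3); the control group gain (0.73) was
calibrated once by bisection against the package's own spectral pipeline so
that the measured control-group delta tf-ROI is ~0.7 dB, and the PD gain is
fixed at 0.15 × control, which measures near 0.0 dB after baseline
normalization. Trial-to-trial, the gain is jittered (relative sd 0.2) and
negatively correlated with the trial's absolute keypress error: the
`trial_coupling` parameter (default 0.3) is the magnitude of that
correlation. A correlation — rather than a raw regression slope — is the
natural parameterisation because keypress times are generated before the
epochs, so the generator can only shape the joint distribution; a slope in
seconds per gain unit would depend on each subject's error spread and
would not be comparable across groups.

**What the generator does *not* emulate.** Real EEG artifacts (blinks,
muscle), channel-specific noise topographies, drug ON/OFF state, theta as a
separate oscillator (theta-band energy is spillover from the broadband
delta burst), and any mUPDRS--CV coupling. Passing recovery tests therefore
demonstrate that the *pipeline* is correct and well-calibrated, not that
the generator reproduces every property of patient recordings.

## Spectral analysis

`morlet_bank()` builds 50 complex Morlet wavelets, log-spaced 1--50 Hz,
with cycles increasing linearly over the frequency *index* from 3 to 10
(the natural reading of "3 to 10 cycles between 1 and 50 Hz" on a
log-spaced bank) and $\sigma = c/(2\pi f)$. Kernels are sampled over
±4σ and normalized to unit area under the Gaussian envelope times a factor
2, the analytic-signal convention under which a real sinusoid of amplitude
$A$ at the wavelet's frequency returns magnitude ≈ $A$.

`morlet_tfr()` convolves each trial with every wavelet by FFT
multiplication on a power-of-two zero-padded grid; this is *exactly* linear
time-domain convolution, and the test suite asserts agreement with a
brute-force convolution oracle to a relative error below 1e-9. Power is
the squared magnitude; phase the argument. Epochs carry a margin beyond any
analysed window (the 1 Hz/3-cycle wavelet spans roughly ±1.4 s), so the
zero-padding edge never touches the baseline or ROI.

`db_normalize()` divides trial-averaged power by the mean power in the
−300..−200 ms pre-cue baseline, per frequency, and converts to decibels
(10·log10). The baseline is computed from trial-averaged power
(condition-average baseline); single-trial dB values for trial-wise models
use the same per-frequency baseline (`db_normalize_trials()`,
`tf_roi_trials()`), so a trial's dB value is comparable across trials.
Baseline and ROI windows are inclusive at both ends on the 500 Hz grid,
with half-a-sample tolerance so floating-point round-off cannot drop an
endpoint pixel. The canonical regions are `roi_delta()` (1--4 Hz ×
300--400 ms) and `roi_theta()` (4--7 Hz, same window).

`itpc()` is the magnitude of the trial-averaged unit phasor; under uniform
phases its expectation is $\sqrt{\pi}/(2\sqrt{n})$ (≈ 0.089 at n = 100),
which the tests verify by Monte-Carlo. No baseline correction is applied to
ITPC; it is reported as-is.

`cluster_ttest()` runs a pooled two-sample t test at every
(frequency × sample) pixel, thresholds at p < 0.05, forms 4-connected
clusters, and discards clusters under 500 pixels. A pixel is one frequency
step × one sample; 4-connectivity and the pixel definition are documented
conventions. With this extent threshold, label permutations of
identical-distribution groups essentially never yield a surviving cluster,
which the acceptance suite checks coarsely with 200 permutations.

**Preprocessing.** `epoch()` cuts `round((t1−t0)·fs)` samples per event and
drops (with a warning count) events whose window leaves the recording.
`average_reference()` subtracts the per-sample channel mean.
`detect_bad_channels()` is a deliberately simplified robust detector (the
full FASTER algorithm is out of scope): robust z-scores (median/MAD) of
pooled log-variance and of mean inter-channel correlation, threshold 3.
Because MAD-based z-scores diverge when channels are nearly identical, a
flag additionally requires a material absolute deviation (variance ratio
≥ 2, or a correlation drop ≥ 0.1); flagged channels are replaced by the
mean of the unflagged ones. All statistics in this package read a single
midfrontal channel (default "Cz").

## ERP features

`erp_average()` averages trials and low-passes at 20 Hz with a zero-phase
(forward-backward) 4th-order Butterworth filter; odd-reflection padding
suppresses the filter's edge transients. `peak_to_trough()` implements the
canonical morphological measure max(peak window) − min(trough window); the
default search windows used by the pipeline (P2 150--300 ms, N2
200--350 ms cue-locked; ERN 0--150 ms response-locked) are configuration
defaults, not empirically fitted values. `cnv_amplitude()` is the mean
amplitude over 500--3000 ms (3-s trials) or 500--7000 ms (7-s trials)
after the cue. No group-level ERP claims are part of the acceptance
surface: the phenomenon of interest lives in the time-frequency domain.

## The statistical chain

* `group_ttest()` — Student's pooled-variance t (df = n1 + n2 − 2, the
  convention implied by the printed degrees of freedom) with Cohen's d.
* `spearman_cor()` — average-rank Spearman rho; p from the t
  approximation on n − 2 df (cross-checked against `cor.test` in the
  tests).
* `fisher_rz_compare()` — z = (atanh r1 − atanh r2) /
  sqrt(1/(n1−3) + 1/(n2−3)).
* `hierarchical_regression()` — `cv ~ mupdrs` then `cv ~ mupdrs + moca`,
  compared by ANOVA: does cognition explain timing variability beyond
  motor impairment?
* `mediation_boot()` — linear product-of-paths mediation
  (power → CV → MOCA): ACME = a·b, ADE the direct effect, total =
  ACME + ADE (exact in the linear no-interaction model, asserted to 1e-6).
  Inference by case bootstrap (default 1000 resamples) with percentile
  intervals; the bootstrap seed is exposed. The implementation is
  self-contained and validated against simulated systems with known paths.
* `lmm_trialwise()` — `keypress ~ delta * group * moca * interval +
  (1 | subject)`, maximum likelihood (not REML) so AIC comparisons across
  fixed-effect structures are valid; type-III F tests with Satterthwaite
  denominator df. The original analyses' denominator df come from a
  different software default and are not matched — df conventions are
  documented rather than imitated. Four single-covariate models
  (delta/group/MOCA/interval only) are fitted for AIC comparison; interval
  dominates keypress, so the full model always beats the delta-only model
  by a wide AIC margin, mirroring the reported ordering.
* `subject_slopes()` — per-subject OLS slope of keypress on single-trial
  delta dB (≥ 5 trials, non-constant power), the individual-level
  companion to the LMM.

No multiple-testing correction is applied anywhere, mirroring the original
analysis strategy; this is a documented property, not an oversight.

## Numerical and design choices

* **Seeds.** Every stochastic function takes a seed (defaulting to the
  profile seed plus a stage offset, kept below 2^31) and is bit-identical
  under a fixed seed; random streams are isolated with `withr::with_seed`
  so library calls never perturb the user's RNG state.
* **Degenerate inputs.** Zero pooled variance, constant correlation
  inputs, |r| = 1 in Fisher's transform, single-channel re-referencing,
  empty ROIs, sub-Nyquist sampling, and aliased LMM terms all raise
  informative errors; summaries with fewer than two trials are flagged
  rather than dropped silently.
* **Problem sizes.** The test and acceptance runs use desk-scale sizes
  chosen as the package's own defaults: full cohorts (37 + 71) for
  behavioral recovery; 30 subjects × 40 trials for the null spectral
  calibration (epochs −2..+3 s, sufficient because the dB statistic reads
  only −0.3..+0.4 s and the background is stationary); 12 + 12 subjects ×
  20 trials for the directional end-to-end EEG check; 20 seeds for the
  correlation recovery and 50 for LMM coverage.
* **Monte-Carlo tolerances.** A single 40-trial subject's null ROI dB
  scatters with sd ≈ 0.5 dB, so subject-mean checks are run at n where the
  standard error sits well inside the asserted band; behavioral recovery
  checks average five seeds because a single cohort's group-mean CV
  fluctuates with sd ≈ 0.01 — the same magnitude as the tolerance.
* **Pipeline.** `run_pipeline()` chains simulate → behavior → spectral →
  erp → stats → report, writes every table as CSV and a JSON manifest with
  MD5 hashes, the seed and package version; statistics that a tiny demo
  cohort cannot support (mediation needs ≥ 20 complete cases) are skipped
  with a recorded note rather than failing the run.

## Known limitations

The generator's EEG model is intentionally minimal: one oscillatory
component, stationary 1/f background, no artifacts, a single effective
channel. The ITPC statistic is implemented without baseline normalization,
as one reasonable interpretation of a phase-locking analysis whose exact
formula is underdetermined. The bad-channel detector is a simplified
stand-in for full automated artifact rejection and is suitable for the
synthetic data and for coarse quality control only. Inferential statistics
on synthetic cohorts recover *directions* and *calibrated magnitudes*; they
do not reproduce patient-level F or p values, which depend on the real
cohort.
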