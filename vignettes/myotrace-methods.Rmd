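---
title: "Quantifying detrusor smooth muscle contractility with myotrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying detrusor smooth muscle contractility with myotrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myotrace)
```

## The measurement problem

Isometric organ-bath recordings from detrusor smooth muscle (DSM) strips mix
several signals on one tension channel: a slowly drifting basal tone,
quasi-periodic spontaneous contractions during "filling-phase" conditions,
large evoked contractions (a 60 mM KCl contracture used as the per-strip
reference, and electric-field-stimulation (EFS) responses), and transient
tension shifts caused by drug application. `myotrace` turns such a recording
plus a small annotation sidecar (KCl window, EFS trains, drug windows) into
the standard summary quantities of the field:

* **A_SC** — spontaneous contraction amplitude, expressed as % of the same
  strip's KCl contraction (normalization removes strip-size dependence);
* **f_SC** — spontaneous contraction frequency (Hz), with period
  T_SC = 1/f_SC;
* **A_EFS** — EFS contraction amplitude (% of KCl) as a function of train
  duration, and its atropine-blockable (cholinergic) versus
  atropine-resistant (mainly purinergic) components;
* drug effects — the baseline-tension shift (% of KCl) and post/pre fold
  changes of A_SC, f_SC and A_EFS across a drug window;
* control-versus-cancer cohort contrasts by unpaired t-test.

Because no public raw traces exist for this preparation, the package pairs
every estimator with a forward generator of synthetic recordings
(`simulate_strip()`, `simulate_cohort()`) whose defaults are the published
group values for control and carcinogen-induced bladder-cancer rats. Every
stage of the pipeline is therefore testable by parameter recovery: simulate
with known ground truth, estimate, compare.

## Estimating A_SC: the two-Gaussian amplitude histogram

Within a stationary segment, the distribution of tension values is
dominated by two dwell modes: samples near basal tension (between events
and on event shoulders) and samples near the event peaks. The analysis
scheme fits the sum of two Gaussians to the amplitude histogram and takes
the distance between their means as A_SC, normalized to the KCl amplitude.

Two numerical points deserve attention:

* **The inter-modal density is not Gaussian.** The dwell-time density of a
  smooth contraction waveform diverges at its turning points and has a
  bathtub-shaped floor in between. A plain 6-parameter least-squares fit
  absorbs that floor by widening both Gaussians, dragging the means inward
  (up to 30% underestimate in our simulations). `fit_two_gaussians()`
  therefore runs the global fit first and then refines each mean with a
  local Gaussian-plus-linear-background fit anchored at the corresponding
  histogram mode and clipped at the inter-modal valley — operationally,
  "the best fit of the near-baseline and near-maximal amplitude regions".
* **Noise smears the dwell modes asymmetrically.** Measurement noise
  convolves the one-sided dwell densities and shifts both modes toward each
  other. Since dwells last seconds, the segment is pre-smoothed with a
  0.5 s boxcar before histogramming (`smooth_s` in
  `quantify_spontaneous()`), which suppresses the shift without distorting
  event amplitudes. The same 0.5 s smoothing is used when reading contraction
  peaks (KCl, EFS), where it removes the upward bias of a raw max statistic.

Bins are equal-width over the segment range; the count follows
Freedman-Diaconis with a floor of one bin per 75 samples (dwell-spiked
distributions are far spikier than the densities FD assumes), clamped to
30-200. Bimodality is decided on the histogram itself: a second mode must
clear 2% of the main peak and be separated from it by a valley dipping
below 75% of the smaller peak. Unimodal histograms report A_SC = 0 with a
flag — a strip without detectable spontaneous activity is a valid
observation, not an error. At the defaults this happens when the true event
amplitude approaches the noise floor (about 0.2 mN at 0.05 mN noise), which
is a genuine detection limit of the histogram method, not an implementation
artifact.

## Estimating f_SC: the spectral main harmonic

f_SC is the frequency of maximal power of a linearly detrended,
split-cosine-tapered averaged (Welch) periodogram within a search band of
0.005-0.5 Hz, which brackets reported detrusor rhythms (0.027-0.047 Hz)
with wide margin; the peak is refined by parabolic interpolation over its
three bins. Sub-segments are sized so the resolution is at least one fifth
of the band's lower edge (1000 s at the default band), which is why
`quantify_spontaneous()` requires long stationary segments. The PSD is
normalized so its band integral equals the signal variance (Parseval; exact
for an untapered, mean-removed single segment).

A peak counts as a "dominant rhythm" only if it exceeds both 4x the band
median power and the 99th percentile of the band *maximum* expected under a
flat spectrum (computed from the gamma distribution of an average of K
periodogram bins). The second guard matters: the maximum of a white-noise
periodogram over hundreds of bins is routinely 5-10x the median, so a fixed
multiple of the median alone would hand back a noise fluctuation for every
rhythm-free strip. Genuine spontaneous rhythms at the defaults exceed the
threshold by orders of magnitude.

## Stationary-segment selection

Published analyses select "parts of the recording with no change in basal
tension" by eye; `select_stationary_segment()` is a reproducible surrogate.
The trace is scanned with 60 s windows stepped by 10 s; each window's
baseline is its 10th percentile (a lower envelope, so spontaneous bumps are
not mistaken for drift); windows overlapping the KCl window (+180 s
washout), EFS response windows, or foreign drug windows are ineligible. A
window is stationary when the local envelope slope is below 1% of the KCl
amplitude per minute, and the accepted segment is additionally required to
keep its envelope inside a band of 2% of the KCl amplitude — a slow
monotone transient tail can pass every local slope test while accumulating
a unit of drift, and the cumulative band is what actually protects the
histogram.

## EFS quantification and the cholinergic dissection

For each annotated train, A_EFS = (response-window peak − median of the
10 s pre-stimulus baseline) / KCl amplitude x 100, with the response window
extending 30 s past train end to capture the slow cholinergic peak, and
negative differences clamped to zero. The atropine-blockable fraction at
each duration is (A_pre − A_ATR)/A_pre, clamped to [0, 1]; the plateau
fraction is its mean over durations >= 4 s, computed per strip and then
averaged (the experiment is a paired, within-strip design). Whether the
published plateau was computed per strip or from group means is not stated;
per-strip-then-average is this package's choice. Peak-minus-baseline (not
area under curve) is used for "amplitude" throughout, consistent with the
term.

## Drug-response quantification

Drug "tension" effects are shifts of basal tension under superimposed
spikes, so `baseline_tension_change()` reads them from a sliding
10th-percentile envelope (30 s windows, EFS windows masked) and reports the
peak shift inside the drug window relative to the pre-drug envelope —
transient agonists report their peak effect, relaxants come out negative.
`pre_post_spontaneous()` reruns the full spontaneous analysis independently
before drug onset and inside the window (after a 90 s settling margin;
stationary-segment selection inside the window then avoids the remaining
transient) and reports post/pre ratios, which cancels any static estimator
bias. `pre_post_efs()` is the analogous ratio of mean normalized EFS
amplitudes. Protocol layouts matter: spontaneous-fold experiments need
>1000 s of stationary trace on each side of drug onset, while EFS-fold
experiments interleave trains every 3 min and leave no such stretch — the
two effects are measured on the protocols that support them, as in the
original experiments, and `drug_effect()` flags what a bundle cannot
provide.

## The synthetic generator

`simulate_strip()` builds tension as

baseline + drift + KCl contracture + spontaneous events + EFS responses +
drug transients + white noise.

Spontaneous events are a renewal process (gamma inter-event intervals,
mean period 1/f_SC, CV `period_cv`) of raised-cosine bumps of height
`asc_true` x KCl/100 and width `event_duty`/f_SC, with onsets snapped to the
sampling grid so noiseless amplitudes are realized exactly. EFS trains
contribute A(D) = Amax(1 − e^(−D/tau_D)) split into a fast non-cholinergic
kernel (0.5 s rise) and a slow cholinergic kernel (2 s rise) whose envelopes
share a plateau, so the peak equals the component sum exactly; the
cholinergic share is zero below a 1.6 s train duration and saturates to
`chol_fraction_plateau` above ~4 s. An atropine window removes the
cholinergic component. Drug transients are alpha functions
(t/tau)e^(1−t/tau); within a drug window the configured folds multiply the
event height, event rate and EFS amplitude. Evoked contractions (KCl, EFS)
suppress spontaneous events that would collide with them, standing in for
the activity reset a strong contraction causes.

Key defaults and their provenance:

| parameter | default | source |
|---|---|---|
| A_SC, f_SC (control) | 4.6% KCl, 0.047 Hz | published control means |
| A_SC, f_SC (cancer) | 2.8% KCl, 0.027 Hz | published cancer means |
| strip-level CVs | printed SD/mean ratios (e.g. 2.9/4.6) | published SDs |
| cholinergic plateau (control) | 0.52 | published plateau fraction |
| cancer EFS components | control chol./3.54, non-chol./1.38 | published folds |
| GSK1016790A | tension 7% (intact) / 4.5% (denuded) KCl; A_SC fold 2.2 / 1.3; cancer 1.3; f_SC fold 1 | published values |
| preload | 5 mN | published protocol |
| EFS trains | 0.5 ms pulses, 100 V, 10 Hz, every 3 min; durations 0.4-10 s | published protocol |
| KCl amplitude | 20 mN | typical rat DSM strip scale (not printed) |
| EFS Amax, tau_D | 60% KCl, 1.3 s | chosen so saturation is reached by ~4 s |
| event shape, duty, period CV | raised cosine, 0.4, 0.2 | morphology-motivated, not printed |
| noise SD | 0.05 mN | plausible transducer + micro-activity noise |
| drug transient taus | GSK 180 s; TEA/CAP 60 s; CBD 120 s | transient time scales, not printed |

Unprinted values were fixed once at what we consider realistic for this
preparation and are all config-overridable; none encode measured results.

`simulate_cohort()` draws strip-level multipliers for A_SC, f_SC and the
KCl amplitude from mean-one lognormal distributions with the printed
between-strip CVs, using stratified (one draw per probability stratum,
randomly permuted) sampling recentred to mean exactly one. A cohort of nine
strips then represents the between-strip distribution and its population
mean faithfully, so cohort-level parameter recovery measures estimator
error rather than sampling luck; the per-strip spread still matches the
printed CVs, which is what the cohort t-tests see.

**What the generator does not emulate:** burst sub-structure and waveform
asymmetry of real spontaneous contractions, slow rhythm drift, fatigue
across repeated EFS trains, desensitization kinetics (the purinergic share
is bookkeeping only), temperature/oxygenation artifacts, and any cellular
mechanism (membrane potential, calcium). Passing recovery tests therefore
shows the estimators are correct for signals with the stated structure —
not that they are robust to every pathology of real recordings.

## Statistical treatment

Cohort metrics are summarized as mean ± sample SD with n = strips, and
control versus cancer contrasts use the classical pooled-variance unpaired
t-test at P < 0.05 (`var_equal = FALSE` switches to Welch); no
multiple-testing correction is applied, matching the original analysis.
Strips are the unit of analysis, pooled across animals — a
pseudo-replication caveat of the original design that the package
reproduces rather than corrects. Note that at the printed group SDs the
n = 9 A_SC contrast has modest analytic power (~0.33 by `power.t.test`);
the package's own test suite checks its t-test against that closed form
rather than asserting that significance is guaranteed.

## Problem sizes and runtime

The test suite and the acceptance script use the study's own scales:
cohorts of 9-10 strips, 1800 s spontaneous recordings at 10 Hz, 3600 s
duration-series protocols, 4200 s drug protocols, plus one 200-strip cohort
for the bias property. Everything runs in well under a minute on a single
CPU; the sizes were chosen to mirror the experiments, not to strain them.

## Known limitations

* A_SC retains a small negative bias (-2% control, up to -6% for the
  smaller cancer events) from noise smearing of the dwell modes; the
  pre-smoothing reduces but cannot eliminate it. Fold changes are immune
  (the bias cancels in ratios).
* The spectral peak of a renewal process sits slightly above 1/mean-period
  (about +2% at CV 0.2); this is a property of the estimand, not a bug.
* Strips whose event amplitude is near the noise floor report A_SC = 0
  (flagged); ensemble means over cohorts that include such strips inherit a
  downward tilt, exactly as manual histogram reading would.
* Auto-binning makes A_SC gain-invariant only up to one bin-count flip
  (relative changes ~1e-3); pass `n_bins` for strict invariance.
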