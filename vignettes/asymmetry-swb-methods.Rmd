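---
title: "EEG band-power asymmetry and short-term subjective well-being: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG band-power asymmetry and short-term subjective well-being: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asymswb)
```

## The scientific question

Hemispheric lateralization of EEG band power — most famously frontal alpha
asymmetry (FAA) — has long been linked to affect and well-being. This
package implements an analysis that asks a broader version of that
question on short time scales: when a person rates their subjective
well-being (SWB) on a 1–10 scale every 30 seconds during a recording,
which contralateral channel pairs (or scalp quadrants) and which frequency
bands show a *linear* relationship between the per-epoch log power
asymmetry and the concurrent rating?

The unit of analysis is the 10-second epoch ending at each report. For a
right-hemisphere channel $ch_1$ and a left-hemisphere channel $ch_2$, the
asymmetry in a band is

$$\mathrm{Asym}_{band}(ch_1, ch_2)
  = \operatorname{mean}\left[\ln \mathrm{pow}_{band}(ch_1)
  - \ln \mathrm{pow}_{band}(ch_2)\right],$$

where $\mathrm{pow}_{band}$ is the Welch power spectral density of the
band-filtered epoch and the mean runs over the frequency bins inside the
band. Positive values mean relatively more band power on the right.

## The montage and the bands

The montage is the 14-channel consumer-headset subset of the 10–20 system
(AF3, F7, F3, FC5, T7, P7, O1, O2, P8, T8, FC6, F4, F8, AF4) sampled at
128 Hz. Bands are delta 0.5–3 Hz, theta 4–7 Hz, alpha 8–13 Hz, beta
14–30 Hz, gamma 31–100 Hz, and an unfiltered control band "non"
(0.5–100 Hz) that guards against artifacts of the filtering step itself.
Band edges above $0.95 \times$ Nyquist (60.8 Hz at 128 Hz) are clipped at
filter-design time: the nominal 100 Hz upper bound of the gamma and non
bands is unreachable at this sampling rate, and the headset's own
recording bandwidth tops out near 43 Hz anyway.

Contralateral test families are enumerated per region: the 16 anterior
pairs (right {AF4, F4, F8, FC6} × left {AF3, F3, F7, FC5}), the 9
posterior pairs (right {T8, P8, O2} × left {T7, P7, O1}), or the 2
quadrant pairs built from sample-wise averages of each quadrant's non-bad
channels. Anterior–posterior cross pairs are deliberately not tested:
the well-known general anterior–posterior power difference would swamp
the lateralization signal.

## Preprocessing

Preprocessing is deliberately minimal and fully reproducible:

* **Detrending.** Each channel has its least-squares line removed
  (idempotent; exact for constants and ramps).
* **Bad-channel detection, run twice.** Each channel is scored by the
  negative mean log-likelihood of its samples under a kernel density fit
  to its own amplitude distribution — an improbability score that rises
  for spiky, heavy-tailed, or grossly over-dispersed channels. Scores are
  z-scored across channels and |z| > 3 is flagged; flat (zero-variance)
  channels are always flagged; the pass is repeated once more on the
  survivors so a gross outlier cannot mask a milder one. Scoring uses a
  deterministic 4096-sample subsample per channel. With 14 channels the
  z-score of a single outlier is algebraically capped at
  $(n-1)/\sqrt{n} \approx 3.47$, so the threshold 3 sits close to the
  ceiling; detection is correspondingly conservative.
* **Re-referencing (optional).** The posterior sensors (T7, P7, O1, O2,
  P8, T8) sit close to the headset's native CMS/DRL reference at P3/P4,
  which can distort posterior asymmetries; the pipeline can subtract a
  frontal channel (AF3 or F3) from the posterior subset before analysis.
  The operation is linear, not idempotent, and preserves pairwise
  differences within the subset.
* **Epoching.** Half-open windows $[t-10\,\mathrm{s}, t)$ before each
  report; sample indices by `round(t * fs)`. Reports whose window does
  not fit inside the run are skipped with a warning rather than
  zero-padded — padding would bias the PSD.

Wavelet-ICA and classifier-based artifact rejection are outside this
package's scope: they depend on externally trained components, and the
synthetic data the pipeline is validated on is generated artifact-free
(with an optional bad-channel injector to exercise detection). A real
recording cleaned by an external pipeline can be supplied through the same
dataset interface.

## Spectral estimation choices

* The band-pass is a 4th-order Butterworth applied forward–backward
  (zero phase). By default its squared magnitude response is applied on
  the DFT grid of the signal, which is the same transfer function as
  time-domain filtfilt with circular rather than reflective boundary
  handling; `method = "filtfilt"` is available and the two agree away
  from the signal edges. The asymmetry statistic is largely insensitive
  to this choice because an identical filter gain multiplies both
  channels' densities and cancels in the log ratio.
* Welch PSD: 256-sample (2 s) Hanning segments at 50% overlap, giving a
  0.5 Hz grid so even the delta band contains 6 bins, and 9 segments per
  10 s epoch. Densities are normalized so the one-sided density
  integrates to the signal's mean squared amplitude (Parseval), which the
  tests verify against sine and white-noise oracles.
* The band mean in the asymmetry is taken over frequency bins of the
  per-bin log-density difference, with band-edge bins included (closed
  interval on the discrete grid). The alternative reading — averaging
  scalar band-power log ratios over time segments — coincides with this
  one for flat in-band spectra; the per-bin reading is stable for narrow
  bands and matches the per-frequency character of a power spectrum.
  Bins with exactly zero density in either channel are excluded from the
  mean (an all-zero band is a degenerate-epoch error).

## The group inference

Per participant and per (pair, band) test:

1. **SWB-class filtering.** Ratings reported fewer than 3 times are
   dropped (3 points is the minimum a class needs to be interpolated),
   and a participant with fewer than 3 distinct surviving ratings is
   excluded from that test — a line through two rating levels is not a
   meaningful trend.
2. **SMOTE balancing.** Ratings are reported very unevenly (mostly 6–8),
   which would let a plain regression overfit the frequent ratings.
   Every minority rating class is oversampled to the majority count by
   interpolating between a random class member and one of its k = 5 (or
   class size − 1, if smaller) nearest same-class neighbours in the
   one-dimensional asymmetry feature space. SMOTE is implemented in the
   package so that behaviour is fully specified and every draw flows
   from one seed.
3. **Repeated regression.** Because SMOTE is stochastic, balancing and
   an ordinary least-squares regression of SWB on asymmetry are repeated
   10 times with derived seeds and the slopes and intercepts averaged.
   The regression orientation (SWB as response) is a single convention
   switch; the group test only asks whether the slope differs from zero,
   and the sign of the slope is shared by both orientations.
4. **Group test.** A one-sample two-sided t-test of the participant
   slopes against zero with a 95% t confidence interval.
5. **FDR control.** Benjamini–Yekutieli adjustment at level 0.1 across
   the family of all (pair, band) tests sharing one universe and one
   reference scheme. BY is valid under arbitrary dependence — important
   because tests sharing a channel are strongly dependent — at the price
   of the harmonic-sum correction $c(m)=\sum_{i\le m} 1/i$. Tests with
   fewer than 2 surviving participants are reported as
   `insufficient_data` and never enter the family.

Participants are excluded globally if left-handed (handedness interacts
with lateralization in ways this group model does not represent) or if
their pooled reports fail the diversity rule above.

## The synthetic-data generator

Because the underlying study data are not publicly deposited, the package
ships a generator that emulates the study design: up to 6 runs of 9
minutes per participant, one 1–10 rating every 30 s drawn i.i.d. from an
imbalanced distribution (default mass 0.74 on ratings 6–8, fully
configurable), 14 channels at 128 Hz. Each channel is a sum over bands of
independent band-limited Gaussian noise — sampled directly in the
frequency domain as a complex-Gaussian spectrum shaped by the band-pass
gain, which is distributionally identical to filtering white noise — with
per-band RMS amplitudes (defaults 20/10/15/8/5 µV for
delta/theta/alpha/beta/gamma, a plausible resting-EEG profile).

A coupling $(ch_1, ch_2, band, \gamma)$ injects a known asymmetry–SWB
relationship: within each 30 s segment ending at a report with rating
$s$, the band component of $ch_1$ is scaled by $e^{+(\gamma s + e)/4}$
and that of $ch_2$ by $e^{-(\gamma s + e)/4}$, with
$e \sim N(0, \sigma_{asym})$, so the expected epoch asymmetry of the pair
is exactly $\gamma s + e$. The scaling is split symmetrically across the
two coupled channels rather than applied to one side only: a one-sided
scaling would hand the identical expected asymmetry to *every* pair
containing the scaled channel, making the injected pair unidentifiable
within its family; under the symmetric split, pairs sharing just one
coupled channel inherit half the slope, and the injected pair is the
unique maximum. The scaling spans the full inter-report segment so the
10 s analysis window is guaranteed to see the intended ratio.

What the generator does *not* emulate: 1/f background spectra, volume
conduction and the resulting cross-channel correlation, ocular/muscle
artifacts, non-stationarity within segments, and any dependence of the
rating sequence on the EEG. Passing recovery tests on this data therefore
demonstrates correctness of the estimators and the inference chain — not
that real EEG satisfies the model.

All randomness flows from one master seed; per-participant, per-run, and
per-repeat child seeds are derived deterministically (multiplicative
mixing, kept below $2^{31}$), so a dataset or analysis is reproducible
bit-for-bit from its seed.

## Numerical and design notes

* Epoch extraction uses half-open sample windows; at the default 30 s
  cadence windows never overlap.
* The EDF writer quantizes to 16 bits against a per-channel physical
  range printed into the 8-character header field and re-parsed, so the
  written range and the encoding agree exactly and the round-trip error
  is bounded by the declared quantization step. The CSV dialect writes
  full `%.17g` precision and round-trips bit-exactly.
* `smote_balance` errors on classes of size 1 (nothing to interpolate);
  repeats whose balanced asymmetry values are constant are skipped with a
  warning, and a participant with no usable repeat is dropped for that
  test.
* p-values from a t distribution are never exactly 0; no epsilon flooring
  is applied anywhere.
* A test family's rejection flags are `p_adjusted <= 0.1`; the family
  size counts only rows with status `ok`.

## Validation study sizes

The package's calibration and recovery studies (run by the test suite and
`scripts/acceptance.R`) use deliberately scaled-down designs chosen to
exercise the full pipeline in minutes on one CPU:

* **Null calibration** — 200 replicates of 8 participants × 2 runs × 18
  epochs with no coupling, posterior universe × {theta, alpha}: the
  fraction of raw group-test p-values below 0.05 is checked against the
  exact binomial 95% acceptance interval around 0.05. Tests within one
  replicate share channels and are therefore positively dependent, so
  the observed count is slightly over-dispersed relative to the binomial
  reference; the check is still a meaningful guard against gross
  miscalibration.
* **Recovery** — 50 replicates of 27 right-handed participants × 1 run,
  $\gamma = 0.3$ on (AF4, F7, alpha) with $\sigma_{asym} = 0.05$,
  anterior universe × {theta, alpha}: the injected test must rank first
  by adjusted p with a positive mean slope in at least 90% of
  replicates, and with $\sigma_{asym} = 0$ the epoch-level regression
  must recover $\gamma$ within ±10%.

## Known limitations

* The asymmetry estimator's per-epoch noise is driven by the Welch
  estimator's variance (9 overlapping segments), which puts a floor on
  the per-participant slope error at around 0.05 asymmetry units per
  SWB unit under the default synthetic conditions.
* With 14 channels, the bad-channel z-score ceiling of 3.47 means the
  default threshold 3 can only catch strong single-channel pathologies;
  subtler artifacts are out of reach of this criterion by construction.
* The group model treats participants as exchangeable and their averaged
  slopes as the unit of inference; no mixed-effects pooling across
  epochs is attempted.
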