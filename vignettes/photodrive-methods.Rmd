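---
title: "Methods: photic driving analysis and the synthetic MEG model"
author: "photodrive"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: photic driving analysis and the synthetic MEG model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photodrive)
```

## The scientific problem

Intermittent photic stimulation (IPS) — trains of periodic light
flashes — can drive rhythmic activity in the visual cortex. Two
phenomena are of interest: *frequency entrainment*, where the
free-running posterior alpha rhythm locks to the stimulation frequency,
and *resonance*, where the response amplitude is enlarged when
stimulating at or near the individual alpha frequency $\alpha$ or its
subharmonic $\alpha/2$. Under scotopic (rod-dominated) viewing, flicker
perception fuses at roughly 15 Hz: above the fusion threshold the
stimulus is perceived as steady light, no oscillation is driven, and
only transient on-/off-responses appear at stimulus onset and offset.

`photodrive` implements the complete analysis chain for such
experiments on 306-channel whole-head MEG (102 magnetometers in fT, 204
planar gradiometers in fT/cm, arranged in 102 triplets), together with
a synthetic session generator that produces ground-truth-labelled
recordings with the same protocol: 20 stimulation frequencies at
multiples 0.40–2.30 of $\alpha$, each presented as 30 trains of 40
flashes with 4 s inter-train rest, preceded by a 60 s resting segment,
sampled at 1000 Hz.

## Analysis stages

**Preprocessing.** The continuous recording is bandpass filtered 2–30 Hz
with a 4th-order Butterworth applied forward and backward (zero phase;
the effective magnitude is the squared single-pass response). Edges are
handled by odd-symmetric reflection padding of three filter lengths.
Filtering precedes epoching so that filter transients never coincide
with epoch boundaries. Each train is epoched from 500 ms before its
first flash to 3 s after the end of its last flash period — windows are
anchored at the recorded *event* times, so the fractional-sample drift
of non-divisor stimulation frequencies (e.g. 10.58 Hz at 1000 Hz) never
accumulates — and averaged sample by sample. Per channel a least-squares
line over the block is removed and the mean of the 500 ms pre-onset
baseline subtracted.

**Frequency domain.** Amplitude spectra are plain (rectangular-taper)
FFTs over the interval from the first flash to the end of the 40th
flash period, zero-padded to the next power of two, with the convention
$A(f) = 2\lvert X(f)\rvert / N$ so that a unit sinusoid has amplitude
one regardless of window length; spectra are averaged over the 24
occipital gradiometers. The individual alpha frequency is the most
prominent spectral local maximum of the resting segment in 7–13 Hz; a
peak is accepted only if it exceeds twice the median 2–30 Hz amplitude,
otherwise the estimate is flagged rather than silently extrapolated.
The *alpha peak ratio* divides the alpha-band peak amplitude during
stimulation by the resting alpha peak (rest window matched in length to
the $1.00\,\alpha$ stimulation window). Entrainment uses two rules: the
highest peak within $\pm 2$ Hz of the stimulation frequency must (i) lie
within one non-padded frequency bin of $k f_{stim}$, $k \in \{1,2,3\}$,
and (ii) exceed 20% of the maximum peak found across the whole cohort.
Per multiplier, one-sample t-tests of the ratios against $\mu = 1$
report both one-sided alternatives; pairwise paired t-tests are
Holm-corrected.

**Topographic Matching Pursuit (TMP).** One multichannel Gabor atom is
fitted per stimulation period (window = one period, anchored at each
flash onset) and per each of the 10 periods after the last flash. The
dictionary holds atoms $g(t) \propto e^{-\pi((t-u)/s)^2} e^{i\xi(t-u)}$
with unit-$\ell_2$ Gaussian envelopes, dyadic scales, quarter-scale
translation lattices and modulations 2–30 Hz in 0.5 Hz steps. The
selected atom maximizes the total energy captured across channels by
the orthogonal projection of each channel onto the real span
$\{e \cos \xi(t-u),\; e \sin \xi(t-u)\}$; per channel the amplitude and
phase of the projected waveform are stored (phase at the envelope
centre). This projection criterion, rather than the raw squared complex
inner product, is used deliberately: for real-valued signals the raw
criterion is biased toward quasi-unmodulated atoms (whose real
projection does not carry the factor $\tfrac12$), to the point of
mis-selecting against an exactly planted mid-frequency atom. With the
projection criterion, planted dictionary atoms are recovered exactly.
Exactly one atom is extracted per window (no residual iteration); ties
break deterministically toward the lowest modulation, then smallest
scale, then smallest translation.

The *reference atom* of a subject averages the 40 stimulus-period atoms
of the $1.00\,\alpha$ block: arithmetic means of scale, translation and
modulation, per-channel arithmetic amplitude means and circular phase
means. *Correlation-coefficient sequences* (40 + 10 values per channel)
take, per channel and period, the maximum over all lags of the absolute
normalized cross-correlation between the reconstructed real waveforms of
the period's atom and the reference atom — a similarity in $[0,1]$.
Among the possible readings of the "maximum" reduction, per-channel
lag-maximum is the default because it preserves per-channel sequences;
the absolute value maps correlations to $[0,1]$.

One identifiability caveat: when the analysis window holds less than
about one carrier cycle under the envelope, the modulation of a Gabor
atom is nearly unidentifiable — the cos/sin projection span barely
depends on $\xi$, and near-tied criteria can scatter fitted modulations
widely while reconstructing near-identical waveforms. Correlation
sequences and classification are unaffected; modulation-stability
statements are only meaningful for windows holding several cycles.

**Phase segmentation.** The engagement / plateau / disengagement
structure of a channel-mean sequence is found by an exhaustive
three-segment least-squares fit (line, constant, line; the
disengagement breakpoint restricted to the post-stimulation periods; 50
periods make the search trivially enumerable). Phases count as detected
when the rise amplitude (plateau minus the mean of the first two
periods) and the fall amplitude (plateau minus the disengagement-segment
mean) both exceed 0.15 of the plateau level, engagement completes by
period 15, and the piecewise fit removes at least half the variance
left by a flat fit. The fit-gain floor of 0.5 was calibrated on a null
study of 500 white-noise sequences (99th percentile of the null fit
gain: 0.32; planted three-phase sequences reach about 0.95) — the
published plateau-variance threshold separates *good* (variance below
0.004) from *moderate* responses among detected sequences; undetected
sequences are *weak*. Two estimator robustness choices matter: (i)
segment-mean amplitude estimators replaced fitted-line endpoints
because a single spurious coefficient at the sequence edge could
otherwise erase a genuine disengagement; (ii) the engagement end uses a
parsimony tie-break — among engagement ends whose best SSE lies within
a noise-scaled tolerance of the optimum (ten times a
successive-difference estimate of the coefficient noise over the
mid-stimulus periods), the earliest is chosen — because a rise *line*
absorbs tilted plateau noise almost as well as the plateau constant,
letting the raw argmin drift past the detection limit. The tolerance
vanishes for noiseless sequences, preserving exact breakpoint recovery
and shift equivariance.

**Time domain.** The square root of mean global field power is the
spatial RMS over one channel type. The block envelope is the magnitude
of the per-channel analytic signal (frequency-domain Hilbert
transform), averaged over all channels after dividing each channel type
by its median envelope — fT and fT/cm cannot be averaged raw. The
on-response is the first qualifying local maximum of the envelope after
stimulation onset, the off-response the first after the end of the last
flash period. A qualifying peak must (i) exceed the pre-onset baseline
mean plus 3 baseline SDs, (ii) be *outstanding*: rise above its
immediately preceding envelope minimum by more than 3 baseline SDs, so
ripples riding on the elevated, slowly decaying preserved response are
not transients, and (iii) reach at least half of the maximal envelope
in its search window, so minor foothills — e.g. the band-edge filter
ringing that precedes a large transient — are not picked as the "first"
peak. The first and last 100 ms of the envelope and a 100 ms guard
after each reference event are excluded (analytic-signal edge effects;
latency strictly positive). Off-occurrence is compared between the low
(multiplier $\le 1.10$) and high ($\ge 1.30$) frequency groups with a
one-sided paired t-test on per-subject occurrence proportions; on-top a
per-multiplier one-way ANOVA of on-latency and amplitude.

## The synthetic generator

The generator is a phase-oscillator source model projected through
fixed dipolar topographies onto an idealized geodesic layout (sunflower
lattice on the unit disk; only channel type, region tag and 2-D
coordinates are consumed downstream). Magnetometer and gradiometer
weights are scaled separately (fT vs fT/cm); the posterior (driven
alpha) and anterior (background) topographies have equal per-type
$\ell_2$ norms so that source amplitudes compete fairly in the
multichannel atom selection.

Inside the entrainment band (multipliers 0.40–1.10) the *driven
component* is stimulus-locked: it oscillates at exactly the stimulation
frequency, ramps up quadratically over 7 engagement periods, holds
through 1–3 preservation periods after the last flash (drawn per
block), then decays with a 0.8-period time constant. Its amplitude gain
follows a double-Gaussian resonance profile over a base gain of 1.3,
peaking at 3.5 for $1.00\,\alpha$ and 2.5 for $0.50\,\alpha$ — chosen
so that the weakest in-band response still clears the cohort 20%
amplitude rule (ratio $1.3/3.5 \approx 0.37$) and the relative power of
the 0.40–0.80 multipliers against the $1.00\,\alpha$ maximum matches
the reported magnitudes. At and above the fusion threshold (1.30) no
oscillation is driven; a transient Gabor (Gaussian FWHM 50 ms, 10 Hz
carrier) appears 200 ms after train onset and a smaller one 150 ms
after the end of the last flash period, with per-subject latency jitter
of SD 18 ms; the free alpha is suppressed to half amplitude
(event-related desynchronization), developing over a 300 ms ramp — an
instantaneous amplitude step would ring through the 2 Hz band edge and
plant spurious envelope peaks.

Two *incoherent* components run continuously: the free alpha rhythm
(frequency wandering $\pm 0.4$ Hz on an 11 s cycle; amplitude shaped by
the stimulation state, recovering over 2.5 s after each train) and an
anterior beta-range background oscillator (22 Hz wandering $\pm 1.5$
Hz, amplitude 2.2 with 25% slow modulation). Because the driven
response is stimulus-locked while these are not, train averaging keeps
the former intact and attenuates the latter by $1/\sqrt{n_{trains}}$.
This is the mechanism behind the engagement/plateau/disengagement
shape of the correlation sequences: early periods of the averaged data
are dominated by the background residual, whose frequency is far from
the $1.00\,\alpha$ reference atom (a same-frequency residual would
correlate near 1 under the lag-maximum, which is why the background
sits in the beta range and the free alpha is strongly recruited during
entrained trains), the plateau by the locked response, and the
post-stimulation decay hands dominance back to the residuals. Sensor
noise is independent Gaussian per channel with SD equal to the per-type
RMS topography weight divided by `snr`.

The generator emulates: the protocol structure, resonance and
entrainment phenomenology, flicker fusion with on/off transients,
preservation, dipolar topographies, channel-type units, and
stimulus-locked vs incoherent dynamics under averaging. It does **not**
emulate: realistic sensor geometry or lead fields, 1/f brain noise,
artifacts (blinks, cardiac), inter-trial variability of the driven
response, or latency variation across blocks within a subject. Passing
recovery experiments therefore demonstrates internal consistency of the
analysis chain under the modelled phenomenology, not performance on
real MEG.

An *averaged-block fast path* (`simulate_averaged_block()`) emits a
single-train recording with incoherent components and sensor noise
pre-scaled by $1/\sqrt{n_{trains}}$ — distributionally equivalent to
simulating and averaging all trains for the linear preprocessing chain,
at a fraction of the cost; cohort-level noise experiments use it.

## Numerical choices and degenerate inputs

* Period windows for non-integer sample periods use
  `round(sfreq / f_stim)` samples anchored at true event times.
* All-zero atom-fit windows return a zero-amplitude atom flagged
  degenerate; zero-energy waveforms get correlation coefficient 0.
* Zero-variance ratio sets, all-zero difference vectors in the paired
  occurrence test and all-equal phase variances are flagged degenerate
  (t undefined, p = 1 where a decision is required) instead of erroring.
* Resting alpha estimation refuses segments shorter than 10 s and flags
  spectra without a prominent in-band local maximum.
* The one-shot resting alpha estimate defines both the stimulation
  frequencies and the oscillator centre for the simulated session,
  mirroring the experiment's calibration step.
* The alpha-ratio resolution precondition is enforced at
  $1.00\,\alpha$ (where rest and stimulation windows match by
  construction) and relaxed for other multipliers, whose windows span
  40 of their own periods; the amplitude convention is window-invariant
  so the ratio stays well defined.

## Validation experiments and problem sizes

The packaged experiments (`experiment_entrainment_recovery()`,
`experiment_latency_recovery()`, `experiment_off_occurrence()`) and the
test suite run at reduced problem sizes chosen to keep the full
validation cycle interactive: 250 Hz sampling (the 2–30 Hz analysis
band needs nothing more), 6–12 sensor triplets for cohort experiments
(the spectral classifier uses the occipital gradiometer subset; the
topographic contrast needs posterior and anterior sites, not 102), 12
subjects for classifier-recovery cohorts, 200 trials for recovery
rates, and 200 simulated cohorts of 6 subjects and 12 multipliers for
the type-I calibration of the occurrence test (a t-test's null
calibration does not depend on those sizes). The response-model
defaults — the emulated study conditions — are identical at every
problem size.

With fusion and driving disabled (`null = TRUE`), every block contains
only the exchangeable free-alpha and background activity, so the
high-vs-low occurrence test's null hypothesis holds exactly and its
rejection rate measures the type-I error; measured rates sit near the
nominal 5%.

## Known limitations

* The spatiotemporal good/moderate boundary depends on the plateau
  variance of channel-mean sequences; per-channel classification is
  available but not the default.
* Sub-cycle analysis windows (stimulation above ~20 Hz at low sampling
  rates) make the fitted modulation parameter unstable by
  construction — conclusions there should rest on the correlation
  sequences, not on $\xi$ itself.
* The generator's two-oscillator background is smoother than real MEG
  residual noise; detection thresholds calibrated here (3 SD, 0.5
  relative height) should be re-examined on real recordings.

## Example

```{r example, eval = FALSE}
proto <- stim_protocol(10.6, sfreq_hz = 250)
layout <- meg_layout(12)
params <- response_model_params(snr = 2, seed = 7)

rec <- simulate_block(1.00, proto, layout, params)
blk <- detrend_baseline(epoch_and_average(bandpass(rec), proto))
spec <- compute_spectrum(blk)
atoms <- atom_sequence(blk)
ref <- reference_atom(atoms[1:40])
classify_response(correlation_sequence(ref, atoms, blk$period_samples))

# or end to end over a cohort:
report <- run_pipeline(list(
  cohort = list(n_subjects = 4),
  protocol = list(sfreq_hz = 250, trains_per_block = 10),
  layout = list(n_triplets = 12),
  seed = 7))
```
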