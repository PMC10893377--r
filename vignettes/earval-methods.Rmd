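---
title: "Methods: validating ear-EEG hardware without subjects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating ear-EEG hardware without subjects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earval)
```

## Scope and model of the data

`earval` is an offline engine for characterizing ear-level EEG sensors at
two levels: the *neural* level, through nine standard acquisition
paradigms (resting state, alpha block, 40 Hz auditory steady-state
response, 10 Hz steady-state visual evoked potential, transient auditory
and visual evoked potentials, auditory and visual oddballs, and
electrooculography), and the *hardware* level, through a conductive ear
phantom bench (mixture recipes, conductivity, contact impedance, noise
floor, and playback of a known signal). Because both levels are about
*measurement validity* rather than neuroscience per se, every analysis in
the package can be exercised end to end on synthetic data with known
ground truth; the generator is first-class, tested code, not a fixture.

A recording is a channels-by-samples matrix in microvolts on a uniform
grid at a nominal sampling rate (500 Hz for sessions, 250 Hz for the
phantom amplifier), together with a marker stream of timestamped string
labels. On disk a session is a plain-text directory (`meta.json`,
`data.csv`, `events.csv`); irregular stored timestamps are regularized
by mapping the first and last timestamps linearly onto a uniform grid at
the nominal rate and interpolating each channel, which is how offline
consumers of streamed EEG commonly treat jittered timestamps. Marker
clocks may carry a constant offset relative to the recording clock; the
offset is applied on read and exposed explicitly (`clock_offset`) rather
than guessed from file metadata.

## The processing chain

All paradigms share one chain: zero-phase filtering, optional
re-referencing, marker-locked epoching with trigger-latency correction,
and baseline correction.

**Filters.** High-pass and low-pass are 4th-order Butterworth filters,
the notch a second-order IIR biquad (RBJ design, default Q = 35 at
50 Hz), applied in the order high-pass, notch, low-pass. Each stage is
run forward-backward (`filtfilt`), making the chain zero phase. Whether
to use zero-phase filtering is a genuine design choice: causal IIR
filtering shifts ERP component latencies by a frequency-dependent group
delay, which would corrupt exactly the latency metrics this toolkit is
meant to produce, so the zero-phase variant is used and the effective
attenuation is doubled. Default bands are 1-100 Hz for spectral
paradigms, 1-20 Hz for transient responses, and 0.2-3 Hz to isolate
blinks.

**Re-referencing** subtracts a chosen channel from all channels; the
reference channel becomes identically zero and all pairwise channel
differences are preserved exactly. The default scheme is Cz; `"none"`
analyses the data against whatever reference it was recorded with. The
reference-comparison tool re-runs a spectral analysis under a list of
schemes (scalp Cz/T8, within-ear, between-ear) and ranks them.

**Epoching.** The corrected onset is the marker time plus the measured
trigger latency of the stimulus chain, rounded to the *nearest* sample
with ties rounding up — a fixed, documented rule so that epoch indices
are reproducible across platforms. Defaults are 0 ms for the auditory
chain and 21 ms for the visual chain; both are per-system quantities and
configurable. Trials whose window would leave the recording are dropped
and counted, so that kept + dropped always equals the number of matching
markers. Baseline correction subtracts the per-trial, per-channel mean
over the 100 ms pre-stimulus interval.

## Spectral estimation and narrowband SNR

Power spectral densities use Welch's method: Hann-windowed,
mean-removed segments of 8 s with 50% overlap (0.125 Hz resolution),
averaged as one-sided densities in uV^2/Hz. Spectrograms use the same
periodogram core with a 2 s window and 50% overlap (1 s hop, 0.5 Hz
resolution). Per-segment powers are retained because the peak
significance test needs them.

The steady-state metric is the narrowband SNR: the power at the bin
nearest the target frequency divided by the mean power over the other
bins of the surrounding band (35-45 Hz around the 40 Hz ASSR, 5-15 Hz
around the 10 Hz SSVEP and the phantom playback). Exactly one bin — the
target bin — is excluded from the neighbor average; with 0.125 Hz
resolution this is the most literal reading of the ratio and is easy to
cross-check by explicit bin enumeration, which the test suite does on
random spectra. All ratio metrics are reported as `10*log10(ratio)` dB
(power convention).

**Peak significance.** A one-way ANOVA compares the per-segment powers
at the target bin against the per-segment powers at the neighbor bins.
Raw periodogram ordinates are approximately scaled chi-squared with two
degrees of freedom; an ANOVA on the raw values is visibly
anti-conservative (about 4% type-I error at a nominal 1% in our
calibration runs, driven by the skew and the small target-bin group).
The package therefore runs the ANOVA on log powers, the standard
variance-stabilizing transform for spectra, after which measured type-I
error is at or below nominal. A peak is flagged *significant* only when
three conditions hold: the ANOVA p-value is below the level, the SNR
exceeds 1 (a peak must exceed its surround, not merely differ from it),
and the target bin lies above a numerical detectability floor of 1e-12
of the spectrum maximum. The floor exists because bins that are exact
Fourier zeros of a deterministic signal (the even harmonics of an ideal
square wave) contain only double-precision rounding dust, on which any
variance-based test is meaningless. The harmonic scanner applies this
machinery at every multiple of a fundamental with a +-5 Hz neighbor
band; for an ideal 10 Hz square wave it reports significant peaks at 10,
30, 50, ... Hz and nothing at the even harmonics.

**Alpha modulation** is the ratio of mean 8-12 Hz power during
eyes-closed intervals to eyes-open intervals, from the spectrogram.
Condition intervals are derived from block markers; the first 2 s after
each transition are discarded (settling, configurable) and only frames
fully contained in an interval are used, so no frame mixes conditions.
Swapping the conditions negates the dB value exactly.

## ERP statistics

Trial averages carry a per-timepoint one-sample two-tailed t-test
against zero at alpha = 0.05, explicitly uncorrected for multiple
comparisons — the mask is descriptive, marking where the average departs
from zero, not a confirmatory family-wise claim. Zero-variance
timepoints take the limit of the t statistic: significant when the mean
is nonzero, not significant when it is zero.

Oddball difference waves subtract the average of the standards that
*immediately precede* a deviant in trial order from the average of the
deviant trials; other standards are excluded, which matches the
standards' adaptation state to the deviants'. The selection rule is
deliberately trivial to brute-force and is tested against a literal
sequence scan. Significance on the difference wave uses a per-timepoint
two-sample two-tailed Welch t-test at alpha = 0.05, uncorrected; a
two-sample test was chosen over a one-sample test on the difference
because the two trial groups have different sizes and variances by
construction.

Component metrics take the signed extremum of the stated polarity
within a search window (P1 0.03-0.08 s, N1 0.08-0.15 s, P2 0.15-0.3 s,
MMN 0.1-0.3 s, P300 0.25-0.5 s; all configurable), with ties broken to
the earliest sample. Peak-to-peak amplitudes (e.g. N1-P2) are absolute
differences of component amplitudes. Grand averages across recordings
are unweighted means of per-recording means.

EOG blinks are quantified as the mean over trials of the within-window
peak-to-peak amplitude after 0.2-3 Hz filtering, for intentional
("hard") versus regular ("soft") blinks, and their ratio; the ratio is
invariant to any common gain or linear filter because both conditions
share the waveform shape. Saccade profiles are per-direction averages
evaluated at 200 ms post-stimulus, where horizontal direction
separation is greatest; separation is the absolute amplitude difference
between opposing directions.

## Phantom bench mathematics

Mixture calculators solve the weight-fraction system exactly: for base
mass `w` and target percentages `p_i`, total mass is
`w / (1 - sum(p_i)/100)` and each component is its percentage of that
total. At the defaults this reduces to closed forms — agar `8w/191` and
salt `w/191` (4% / 0.5%), gelatin `15w/77` and salt `8w/77` (15% / 8%),
and carbon fiber `CF = S * X/(100 - X)` of the silicone mass
`S = volume x 1.11 g/mL` (`S/199` at 0.5%, `S/99` at 1.0%). Rounding is
a policy, not arithmetic: agar rounds up (never under-dose the gelling
agent), carbon fiber rounds to nearest, gelatin is left exact by
default. Fiber loadings above 1.0% warn: such mixtures become too dense
to mold. Conductivity follows the two-wire strip measurement,
`sigma = L / (R * A)`, with the 30 x 10 x 2 mm strip geometry as
default (`L` = 0.03 m, `A` = 2e-5 m^2).

Impedance QC maps kOhm readings to four classes — good (< 10),
acceptable (10-20), poor (20-50), no contact (>= 50 or a saturated
meter). The two anchors are practice-driven: under 10 kOhm is reliably
acceptable for EEG, and at the 50 kOhm meter ceiling contact is absent;
the 20 kOhm split is this package's own intermediate boundary,
configurable. Boundary values take the worse class, and the classes
partition the non-negative axis. Noise floor is per-channel RMS after a
0.3-100 Hz band-pass of a no-input acquisition (wet contacts are
expected close to or under 1 uVrms, failed dry contacts read hundreds).
The playback metric applies the narrowband SNR at 10 Hz with a 5-15 Hz
band at the 1% level; the level is exposed because "1% confidence" is a
protocol convention, not a law. Integrity trends report day-to-day
deltas and percent change from day 1 for phantom mass and played-back
amplitude, without interpolation.

## The synthetic generator: what it emulates, and what it does not

`generate_session()` builds one session per paradigm at 500 Hz on a
12-channel scalp plus 2 x 8 ear montage: 4-minute continuous blocks for
resting, alpha (1-minute alternating eyes open/closed), ASSR and SSVEP;
200 trials with uniform ISIs for the transient paradigms (AEP 200 ms
stimuli, ISI 1.2-1.8 s; VEP 500 ms, ISI 0.5 s; auditory oddball 100 ms,
ISI 1.2-1.8 s; visual oddball 500 ms, ISI 0.6-0.7 s); and 80
dot-movement trials (ISI 1.0-1.6 s) for EOG. These trial counts,
durations and ISI laws are the package's standard test battery and are
individually overridable. The oddball deviant probability is 0.2 with
no two consecutive deviants (the realized count is recorded in the
ground truth). Blinks are generated as separate cued blocks (20 hard,
20 soft) paced 3.5-4.5 s apart so that the 3 s blink analysis window
contains a single blink; at the saccade ISI, adjacent multi-millivolt
blinks would bleed into neighboring windows.

Effects are injected over independent per-channel pink noise whose
one-sided density is `c/f` above 1 Hz (flat below), with
`c = rms^2/ln(100)` so the 1-100 Hz band RMS equals the `noise_rms`
parameter (default 10 uV, a realistic broadband scalp floor). Defaults:
30 uV eyes-closed alpha suppressed 4x in power when open; 1.5 uV
steady-state amplitudes (yielding roughly 5-11 dB narrowband SNRs over
the default floor, the range seen on real caps); Gaussian-sum ERP
templates (auditory N1-P2 peak-to-peak 8.9 uV, visual P2 15 uV, MMN
-2 uV at 200 ms, P300 +6 uV at 280 ms); 8 mV / 1.5 mV hard/soft blinks
and +-5 uV / +-1 uV horizontal/vertical saccade steps. Cortical signals
carry a fixed non-degenerate scalp topography (fronto-central maximum
for auditory paradigms, occipito-parietal for visual) — without it a
common reference like Cz would cancel the signal identically, which no
real cap does — and reach ear channels at 0.3x gain; ocular signals
reach the ear at 1.5x with left/right polarity inversion. These gains
are explicitly arbitrary emulation constants. Markers lead the physical
stimulus by a normally distributed trigger latency (auditory
0 +- 2.2 ms, visual 21 +- 2.8 ms by default), which the analysis chain
corrects by the mean.

The phantom generator plays a phase-defined square wave (exact 50% duty
cycle, so even harmonics vanish identically, as for a function
generator) scaled per electrode by contact quality and by a positional
gain (sensors 1-8 span 0.5-1.5x, emulating increasing distance from the
within-ear reference); bad contacts get 0.1x signal and a 300 uVrms
noise floor against 1 uVrms for good ones. The latency bench generator
schedules step pulses after normally distributed delays at 10 kHz, as a
bench audio/photo-diode capture would be sampled; onset detection
refines the threshold crossing by linear interpolation between
bracketing samples, which removes the half-sample bias of
sample-and-hold detection.

What the generator does *not* emulate: volume conduction or any forward
model (channel topographies are fixed gain vectors, not dipole
projections), artifacts (no line transients, electrode pops, drift or
movement), non-stationary noise, alpha waxing-and-waning (the alpha
rhythm is a constant-amplitude sinusoid per block), or overlapping
neural responses. Passing the recovery suite therefore demonstrates
that the *analysis chain is correct and calibrated* — filters, epoching
arithmetic, spectral scaling, statistics — not that the pipeline is
robust to real-world artifacts, and real recordings will show broader
variability than the simulated conditions.

## Verification design and numerical choices

Analytic expectations close the loop between generator and analyzer.
For a Hann-windowed, bin-aligned sinusoid of amplitude `a`, the Welch
peak density is `a^2 L / (3 fs)` with a quarter of that leaking into
each adjacent bin; adding the pink-noise density model gives a
closed-form expected SNR (`expected_snr_db()`), and the band-mean
construction gives the expected alpha ratio (`expected_alpha_ram_db()`).
The recovery checks run full-length sessions (4-minute spectral
sessions, 200-trial ERP sessions, 1000-event latency benches) and
require: alpha modulation within +-1 dB of the injected ratio,
steady-state SNR within +-1.5 dB of the analytic expectation, ERP
average within `3 sigma / sqrt(n)` of the template, blink ratio within
5%, and latency mean/jitter within +-0.3 ms. The ERP comparison is made
against the template *passed through the same deterministic pipeline*
(zero-phase 1-20 Hz filter and baseline operator, realized as a
noiseless twin of the session), so the error budget is purely the
stochastic term; comparing against the raw template would conflate the
filter's deterministic shaping of sustained components with estimation
error. Null calibration is checked directly: label-shuffled oddball
difference waves must show a significant-timepoint fraction near the
nominal 5%, and pure-noise phantom recordings must be non-significant
at the 1% level in at least 98 of 100 seeds.

Numerical rules are fixed and documented rather than
platform-dependent: sample rounding is nearest-with-ties-up throughout;
component tie-breaks go to the earliest sample; zero-variance t-tests
take their limit values; the F-test has explicit degenerate branches
(identical groups give F = 0, p = 1; separated constant groups give
F = Inf, p = 0); periodogram logs are regularized by the detectability
floor; and noise synthesis runs its FFT on 5-smooth padded lengths
(R's mixed-radix FFT degrades to quadratic cost at large prime
lengths) before truncating to the requested duration, which leaves the
spectrum of the stationary series unchanged.

## Known limitations

Only single-channel reference schemes are implemented (no average or
REST reference). The session format is the package's own text dialect;
binary stream containers are not parsed. The spectral engine is
Welch/STFT only — no multitaper or wavelet estimates — and the
difference-wave statistics are uncorrected pointwise tests, not
cluster-based permutation inference. The phantom model treats contact
quality as a two-class gain/noise switch rather than an electrochemical
impedance model. The resting-state paradigm has no effect model beyond
background noise; its analysis is limited to band-power summaries.
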