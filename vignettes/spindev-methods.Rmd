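---
title: "Methods: spindle-band oscillations and developmental trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spindle-band oscillations and developmental trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindev)
```

## Scope

`spindev` implements an analysis pipeline for developmental
electrophysiology: multichannel neonatal rodent LFP and infant scalp EEG
during sleep, where the dominant transient pattern is a spindle-band
(8--25 Hz) oscillation — spindle bursts / delta brushes in the immature
brain, sleep spindles after maturation. The pipeline covers EMG-based
state scoring, wavelet spectral analysis, detection and characterization
of spindle-band events, amplitude--amplitude cross-frequency coupling,
multi-unit spiking statistics, and regression/bootstrap machinery that
localizes an interior extremum ("nadir") of feature trajectories across
age. Because raw clinical and animal recordings of this kind are access
restricted, the package ships a first-class synthetic-data module whose
generators have exact ground truth; every stage is validated against it.

## Signal model and units

Voltages are microvolts throughout; time is seconds; intervals are
half-open `[start, end)`; sample indices are 0-based in all event tables.
Recordings are channels x samples matrices with per-channel metadata
(position, layer zone, functional flag). Binary I/O uses frame-major
interleaved int16 with a JSON sidecar holding channel order, rate and
gain, matching common acquisition systems; the ADC gain is a required
sidecar field because it is amplifier specific. EDF I/O covers the subset
of EDF/EDF+ produced by clinical amplifiers (single rate, int16 records);
when no channel is requested explicitly, a parietal electrode (P3, then
P4) is preferred and a central one (C3/C4) used as a flagged fallback,
matching the clinical convention of reading somatosensory cortex.

## State scoring

The EMG is high-pass filtered at 300 Hz, rectified, and smoothed with a
100 ms moving RMS to obtain a tone envelope. The tone threshold is
`mean + k * SD` of the envelope with `k` restricted to 1.5--3.5. The
multiplier is calibrated per recording: an Otsu split of the log envelope
into low- and high-tone classes supplies the threshold when the two
classes are well separated (standardized separation >= 3), and the
conservative end of the range (3.5) is used when the envelope is
unimodal, i.e. when the recording contains little or no high tone. The
published range is respected by clipping; a fixed multiplier can be set
in configuration.

Scoring rules: supra-threshold runs >= 1.5 s are wake; shorter
supra-threshold bursts on an atonia background are twitches (a 50 ms
minimum keeps single-sample noise excursions out); sub-threshold runs
>= 2 s are atonia. Brief sub-threshold dips (< 0.3 s) inside a high-tone
period are closed before the duration rules are applied, so a sustained
wake bout with momentary envelope dips scores as one run. Within each
atonia bout, twitch-free stretches >= 10 s are quiet sleep and the
remainder of a twitch-containing bout is active sleep. Runs failing both
duration rules are merged into the flanking state when the flanks agree,
otherwise left unlabeled. Behavioral quiescence from video is replaced by
EMG silence alone (an optional external mask can be supplied), a
documented deviation from video-assisted scoring.

## Spectral analysis

The time-frequency workhorse is an analytic Gabor (Morlet) wavelet
implemented in the frequency domain, normalised so a unit-amplitude
sinusoid at the wavelet's center frequency has magnitude 1. Spectrograms
default to 5 cycles on a 53-point log grid over 1--100 Hz; AR(1)
whitening (`x[t] - phi * x[t-1]` with the lag-1 coefficient estimated
from the data) is available to flatten the 1/f background before
visualization.

Oscillatory-epoch continuity thresholds the lightly smoothed (25 ms)
rectified amplitude at the 99th percentile of the wideband noise floor,
estimated from the quietest decile of 1-s windows. Supra-threshold runs
are merged across gaps < 100 ms and runs < 200 ms discarded; the longer
minimum keeps brief noise excursions (which survive percentile
thresholding by construction) from counting as activity. The threshold is
amplitude-equivariant: scaling the signal scales it identically.

Twitch-triggered spectrograms z-score each frequency row within the
window before averaging and zero lags within +-50 ms of the twitch, since
movement artifact is temporally coincident with the twitch itself. The
twitch-event cross-correlogram derives pointwise 95% bands from uniform
re-draws of the event times over the record span.

The aperiodic (1/f) exponent is the negative slope of a robust (Huber)
log-log fit over 2--40 Hz, with narrowband peaks masked by a first-pass
fit (residuals > 2.5 robust SD removed) — deliberately a simplified
aperiodic fit, not a joint periodic + aperiodic spectral model.

## Spindle-band event detection (PAR)

Detection uses the power-asymmetry ratio
`PAR = (Pspi - (Plow + Phigh)) / (Pspi + Plow + Phigh)`, where the three
band powers are mean squared wavelet magnitudes over 8--25 Hz, 1--5 Hz
(2--6 Hz for infants younger than 40 post-gestational weeks, where delta
brush slow waves sit higher), and 30--80 Hz, each lightly smoothed
(50 ms). The detection wavelets use 4 cycles — shorter than the 5-cycle
spectrogram default — because the wavelet's temporal footprint is what
smears event boundaries; 4 cycles keep the mean boundary error near
80 ms on the reference synthetic conditions (including 300 ms events)
while leaking little enough across bands that a pure in-band tone still
reaches PAR ~0.98. Fewer cycles sharpen boundaries further but push
tone PAR below 0.9. Candidate events are runs with `PAR > -0.1` lasting 0.3--5 s
whose PAR peak exceeds 0; within the run, spindle-band power must exceed
a threshold of 3 MAD-scale units (`median(|Pspi|)/0.6745`) above the
median spindle power inside the sleep mask. Event boundaries are the full
PAR run. Both the statistic and the threshold scale with the signal, so
detection is invariant to amplitude rescaling. On the default synthetic
conditions (events at 5x the background RMS) recall and precision exceed
0.9 with mean boundary error well under 100 ms.

## Event characterization

*Power* is the median of the 8--25 Hz Hilbert envelope over the event.
*Spatial extent* is the fraction of functional channels carrying a
co-occurring event (interval intersection > 300 ms and midpoint
separation <= 50 ms), counting the reference channel in the numerator.
*Waveform asymmetry* (ESR) locates peaks and troughs between
zero-crossings of the 5--30 Hz filtered trace (peaks between rising and
falling crossings, troughs between falling and rising — the only reading
that yields minima), reads sharpness from the raw data at +-8 ms around
each extremum, and reports the ratio of mean peak to mean trough
sharpness. The 8 ms offset is retained as published even though it does
not correspond to a half-period across the whole 5--30 Hz band; it is
configurable.

## Synthetic data

Backgrounds are `1/f^beta` noise (spectral shaping of white noise,
default beta 1.5, RMS 25 uV) — the value typical of cortical LFP — and
events are amplitude-windowed (Tukey, 20% taper) oscillations at 10--20
Hz, 0.5--2 s, with default amplitude 5x the background RMS. Waveform skew
is produced by a second harmonic phased to sharpen peaks and blunt
troughs, `sin(phi) - a*cos(2*phi)` (peak-normalised). A phase-warp of the
form `sin(phi + a*sin(phi))` was evaluated first and rejected: it skews
the waveform horizontally (fast rise, slow fall) while leaving peak and
trough curvature mirror-symmetric, so its measured ESR stays at 1 for any
skew level and it cannot emulate the peak-sharpness asymmetry of
immature oscillations. The second-harmonic skew raises ESR monotonically
for `a` in [0, 0.2]; beyond `a = 0.25` the trough flattens and splits, so
generators map their unitless asymmetry level into [0, 0.2]. Waveform
shape properties (ESR calibration) are probed at 10x background
amplitude: the extremum picker chooses the noisiest sample near each
extremum, which biases both sharpnesses upward and compresses ESR toward
1 at low SNR — at 5x background the Spearman correlation between skew
level and ESR drops to ~0.88, at 10x it is ~0.96. High-amplitude events
are the natural regime for waveform questions (immature spindle bursts
are high power).

Amplitude--amplitude gamma coupling shares the spindle event's envelope
with a gamma carrier on the same channels (mixing coefficient in [0, 1]);
EMG traces are broadband > 300 Hz noise whose amplitude follows a bout
plan (wake factor 8, twitch factor 10 over atonia, 50 ms ramps); spikes
are piecewise-homogeneous Poisson trains (rate multiplied by an event
gain inside events) with optional von Mises phase preference implemented
by repositioning event spikes to the exact ground-truth phase; high-band
fixtures inject a 0.6 ms biphasic template at a stated multiple of the
MAD noise floor. Phase-recovery fixtures set the refractory period to
zero: a refractory filter preferentially deletes spike pairs at the dense
preferred phase, thinning the von Mises peak of the *ground-truth* draw
itself (measured drop from kappa 5 to ~4.4 at a 2 ms refractory), which
would confound estimator validation with a generator interaction. Cohorts draw per-animal feature values from a polynomial
mean trajectory of age plus Gaussian noise; the default emulates 7
animals per day over postnatal days 5--14 with a quadratic vertex at age
8.5 and noise SD equal to 30% of the trajectory's range. Every generator
is a pure function of (spec, seed).

What the generators do *not* emulate: volume conduction and electrode
geometry, non-stationary background spectra, artifacts other than line
noise, spike waveform diversity, and state-dependent background changes.
Passing tests therefore demonstrate algorithmic correctness and
calibration, not robustness to every pathology of real recordings.

## Cross-frequency coupling

Comodulograms correlate log wavelet magnitudes across a 40-point log grid
(1--100 Hz, rows within 2 Hz of 60 Hz dropped), pooled over 4 s windows
around event centers. Magnitudes are smoothed with a Gaussian matched to
the row frequency (sigma = 2 cycles). The comodulogram wavelet uses 10
cycles — sharper in frequency than the spectrogram default — because
correlation is scale-free and inherits the full wavelet bandwidth:
broader wavelets smear genuine single-band coupling across neighbours.
Significance uses correlation t-tests with an effective sample size
derived from the Gaussian-equivalent temporal scale of each pair of rows
(the nominal sample count overstates degrees of freedom by orders of
magnitude at low frequencies), Holm-corrected across the upper triangle.

The coupling curve sums the spindle-band (10--20 Hz) columns, by default
over the Holm-significant entries only; without this gating, sampling
noise at low frequencies (few effective samples after frequency-matched
smoothing) produces spurious prominent bumps. Rows inside 8--25 Hz are
excluded from the peak search (self-coupling block, including its
wavelet-bandwidth shoulders). Peaks are local maxima with topographic
prominence > 0.75 and a width rule; the printed rule `width < 1/f_c`
would reject essentially everything at gamma frequencies (sub-0.1 Hz
widths), so the default reads it as a relative rule `width < f_c`
(quality factor > 1) with the literal reading available in
configuration. Retained peak centers are refined off-grid by parabolic
interpolation in log frequency, and the coupling index is
`value * prominence / width`. Band AUC is a trapezoidal integral (default
25--35 Hz, the band used for infant gamma coupling).

## Spiking statistics

Spikes are negative threshold crossings (4x the MAD noise floor,
`median(|x|)/0.6745`) of the 250--2500 Hz band. Detections coincident
within +-0.5 ms across channels more than 300 um apart are treated as
non-physiological and removed everywhere; within-zone detections < 2 ms
apart collapse to the first. Autocorrelograms use 10 ms bins over
+-0.5 s with the zero-lag bin excluded; the expected count per bin is the
correlogram convolved with a hollow Gaussian kernel (sigma = 2 bins, zero
center), and 95% bands are Poisson quantiles of that expectation. Burst
excess sums counts above the upper band below 50 ms; suppression excess
sums the deficit below the lower band over 50--500 ms. Event-triggered
rates normalize by the rate in a [-1.0, -0.2] s pre-onset baseline with
bands from uniform spike-time shuffles.

Phase locking decimates the LFP to ~125 Hz, band-passes 9--16 Hz, and
takes the analytic-signal phase (0 at the band-passed peak, +-pi at the
trough). The analytic signal is interpolated at the exact spike times: at
125 Hz the nearest-sample phase is quantised by ~0.6 rad at spindle
frequencies, which alone would bias the concentration estimate downward
by ~10%. Concentration is the maximum-likelihood von Mises kappa
(piecewise inversion of `I1/I0`), and significance requires kappa > 0.1
together with circular-uniformity p < 0.05. The Rayleigh test is the
default (the alternative of interest is unimodal locking); the Kuiper
test is available in configuration. Phase histograms use pi/24 bins.

## Developmental trajectories

Features are modeled per animal as polynomials of age, degrees 1--5.
Degree selection uses leave-one-out cross-validation at the animal level
with the one-standard-error rule: the smallest degree whose LOOCV MSE is
within one SE of the minimum. The bare minimum-MSE rule is available in
configuration, but selection noise alone promotes a spurious higher
degree on truly linear data in roughly a third of cohorts at these sample
sizes, defeating the purpose of cross-validating — the parsimony rule is
the standard remedy. The linear fit's mean residual per age is reported
as a lack-of-fit diagnostic.

The nadir bootstrap resamples animals with replacement within each age,
jitters ages uniformly over a total window of 0.5 age units, refits the
selected degree (10,000 resamples by default; 2,000 in the bundled
pipeline configuration for run-time, with identical behavior), and
records the age of the first interior extremum — the smallest age at
which the fitted derivative changes sign strictly inside the observed
range, with an explicit "no interior extremum" category. The null
distribution repeats the procedure with feature values resampled with
replacement across the whole cohort, decoupling value from age; this is
the reading of an "across-ages" resampling null that yields a flat
trajectory against which the within-age mass can be compared. Results
report per-age-bin probability masses, the mode (midpoint of the
maximal-mass 1-unit bin), and the ratio of within to null mass at the
mode.

The combinatorial maturation metric combines asymmetry (A), spatial
extent (S) and power (P) per animal. The published figure does not state
its formula, so the default rule is declared and carried in the output:
the mean of `z(S)`, `-z(A)` and `-z(P)` (within-cohort z-scores), which
rises in the mature direction of each feature and is invariant to
per-feature affine rescaling. Product and first-principal-component
alternatives are selectable; conclusions in the tests refer only to the
default rule. The maturity classifier is a depth-limited (<= 4 splits)
decision tree on spatial extent and ESR with stratified 5-fold
cross-validated accuracy and per-class marginal feature distributions.

## Numerical choices and degenerate inputs

Zero-phase 4th-order Butterworth filters (`filtfilt`) stand behind every
band-pass; corner frequencies are clipped just below Nyquist. Constant
signals make the AR(1) coefficient undefined and raise an error, as do
all-zero signals in PAR (flagged degenerate), empty sleep masks, empty
envelope vectors, intervals shorter than one cycle of the band's lower
edge in event power, and single-class inputs to the classifier.
Trajectory refits center and scale ages internally before solving the
polynomial normal equations and map coefficients back to raw age, keeping
degree-5 designs well conditioned. Bootstrap and pipeline runs are pure
functions of their seed; the pipeline writes no timestamps so reruns are
byte-identical.

## Problem sizes used in validation

The bundled validation exercises 100 injected events over a 6-minute
single-channel recording for detector recovery; 20 seeded runs of 2-minute
recordings for coupling calibration (and 20 uncoupled runs for the false
positive rate); 10 Poisson trains of 1,000 spikes for autocorrelogram
coverage; 1,000 uniform draws of 100 phases for the Rayleigh type-I rate;
a 4-minute recording with 40 events for kappa recovery; 20 cohorts of 70
animals with 2,000 bootstrap resamples each for nadir recovery; and 20 + 20
cohorts for model selection. These sizes give stable pass/fail behavior
for each property while keeping a full validation run on a single CPU
within minutes.

## Known limitations

The EDF subset has one sampling rate across signals and no annotation
parsing. The aperiodic fit is a masked robust line, not a joint
periodic/aperiodic model, and will under-mask very broad spectral peaks.
The comodulogram's effective-sample-size correction assumes approximately
Gaussian temporal autocorrelation of the magnitude series. ESR is
attenuated toward 1 at low SNR by extremum-picking noise; comparisons
across conditions should hold amplitude roughly constant. Human sleep
staging is taken as given; the scorer addresses rodent EMG only.
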