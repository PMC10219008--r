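---
title: "Simulated psychophysics and neurophysiology of AM sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated psychophysics and neurophysiology of AM sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(modsense)
```

## The question the package addresses

Human sensitivity to amplitude modulation (AM) — measured psychophysically
as the temporal modulation transfer function (TMTF), the smallest detectable
AM depth as a function of AM rate — takes strikingly different shapes
depending on the stimulus: low-pass for broadband noise carriers, high-pass
for narrowband carriers. One hypothesis is that these shapes are not wired
in but emerge when an auditory system is optimized to recognize natural
sounds, whose categories differ in their modulation statistics. modsense
implements the full computational experiment needed to test that idea at
desk scale:

1. optimize a layered dilated-convolution network to classify sounds whose
   categories differ in AM statistics and carrier spectra;
2. freeze it and run the same forced-choice AM-detection experiments that
   humans performed, layer by layer, yielding per-layer TMTFs;
3. quantify the similarity of model TMTFs to a human reference;
4. degrade the training sounds (envelope/fine-structure chimeras) to ask
   which acoustic structure the emergent sensitivity depends on;
5. probe single units with modulated noise, as in animal neurophysiology,
   and map layers onto auditory brain regions by the similarity of their
   AM-tuning distributions.

## The model

Each layer is a one-dimensional dilated convolution along time followed by
an exponential linear unit (ELU, `alpha = 1`); a classification layer
(convolution of filter size one) sits on top. The network is fully
convolutional and unpadded ("valid"), so one output time step sees exactly
`1 + sum((k_i - 1) d_i)` input samples — the receptive field — which is
constrained not to exceed the 0.2 s input window. Architectures are sampled
randomly under that constraint (filter sizes 2–8; layer counts 7/9/11/13 at
full scale; units per layer from {32, 64, 128, 256, 512}).

Training minimizes softmax cross-entropy computed at a single output time
step per example (one randomly positioned receptive-field-length window per
clip per epoch) with Adam at learning rate `1e-4` by default. Per-clip
amplitude jitter (uniform ±6 dB) during training keeps overall level
uninformative. Early stopping monitors clip-level accuracy on a held-out
split; the best-epoch parameters are returned and the model is frozen —
the simulated experiments only ever read activations.

Choices the description of the procedure left open, fixed here once:

* weight initialization: fan-in-scaled uniform, biases zero;
* batch size 16, an epoch is one pass over the update split;
* the two-step architecture search trains each candidate with patience 32,
  ranks layer counts by the mean accuracy of the four best candidates,
  then continues training the winning group with patience 96.

The whole network, backpropagation and Adam are implemented in plain R on
BLAS matrix products; at the package's problem sizes (tens of thousands of
parameters, second-long clips) this is entirely adequate and keeps the
implementation transparent.

## The synthetic corpus

The corpus generator stands in for natural-sound datasets. Each category is
defined by a modulation spectrum concentrated in a Gaussian bump on the
log-rate axis (center rate, bandwidth in octaves, depth) and by a carrier
spectral tilt in dB/octave; every clip draws a fresh modulator and carrier,
so within-category variability is real and classification non-trivial. The
defaults — 10 categories × 40 clips of 1 s at 16 kHz, modulation centers
log-spaced 4–128 Hz, tilts −6..+6 dB/octave, modulation depth 0.8, a −40 dB
noise floor, 0.6/0.2/0.2 update/early-stop/validation splits — are the
package's standing corpus conditions. Clips are high-pass filtered at
20 Hz, given 10 ms raised-cosine ramps, and normalized to unit RMS
(amplitude is in arbitrary units throughout; unit RMS keeps first-layer
pre-activations well scaled).

What the generator emulates: category-discriminative modulation statistics
and spectral envelopes, the two cue families the recognition task is meant
to reward. What it does not emulate: harmonic structure, transients,
semantic content, phoneme sequences, or recording-channel variability.
Passing tests on this corpus therefore show that the pipeline's machinery
behaves as specified and that AM statistics suffice to drive the emergence
of modulation-sensitive features — they do not show that any particular
natural dataset would produce a particular TMTF.

The end-to-end tests use a reduced 3-category variant (3 layers × 32
units, 8 kHz, 0.5 s clips, modulation centers 4/32/256 Hz, tilts
−15/0/+15 dB/octave, depth 1.0, bump width 0.35 octaves, learning rate
`1e-3`) chosen so that training converges in minutes on one CPU; these
problem sizes are the package's own test-scale conditions, stated here
once and reused everywhere.

## Stimuli and the six conditions

Detection stimuli are sinusoidally amplitude-modulated Gaussian noise:
`C(t) (1 + 10^(m/20) sin(2 pi f t + phi))`, with depth `m` in dB (0 dB is
full modulation) and an independent carrier per stimulus. The six built-in
conditions differ in carrier bandwidth (2/3/31/314 Hz narrowband, or
broadband), duration (0.5–2 s), AM starting phase (fixed at zero or drawn
per stimulus), whether RMS equalization is applied before or after
modulation, and whether narrowband filtering (a brick-wall digital Fourier
transform filter) is applied before or after modulation. Depth grids span
−60..0 dB for the 2 Hz-bandwidth condition and −40..0 dB otherwise, in
4 dB steps; each condition tests 8 AM rates evenly spaced on a log scale.

Two stimulus parameters are not fixed by the sources the conditions mirror
and are therefore plain editable columns: the per-condition AM rate ranges
(defaults span the ranges typical of the respective study designs) and the
narrowband carrier center frequency (default 5 kHz). Nothing in the
package's checks depends on these defaults.

## The two simulated observers

**Time-average + logistic readout.** Each stimulus is reduced to the time
average of one layer's unit activities. An L2-regularized logistic
regression is trained to classify modulated vs unmodulated stimuli; trials
are scored in an outer 4-fold cross-validation (with 128 trials: 96
training, 32 held-out per fold), and the ridge penalty is chosen by an
inner 4-fold cross-validation over 13 penalties log-spaced 1e-3..1e3, ties
resolved toward stronger regularization. The response in a held-out trial
is the interval with the highest modulated-probability; exact ties are
broken uniformly at random (seeded). Class weights are not rebalanced
across the (x−1):1 interval label imbalance.

**Template correlation.** A template is the mean unit activity over 128
fully modulated stimuli minus the mean over 128 unmodulated ones; each
interval is scored by the non-normalized correlation (dot product over
units and time) with the template.

## Psychometric fitting

Proportion correct against depth is fitted by least squares with a
Richards-type asymmetric sigmoid,
`psi(m) = gamma + (1 - gamma) (1 + exp(-(m - alpha)/beta))^(-lambda)`,
with the guess rate pinned at `1/x` and `beta, lambda > 0` enforced by a
log parameterization; `nlminb` runs from a 4 × 3 × 3 multi-start grid. The
threshold is the depth where the fitted curve crosses 70.7% correct
(bisection). When the curve never crosses inside the tested depth range the
threshold is clipped to the range minimum (curve entirely above) or maximum
(curve entirely below) and flagged — clipped thresholds stay in the data
rather than being dropped, so pooled similarity statistics are not
flattered by removing hard conditions.

## Comparing with human TMTFs

Reference TMTFs are subject-level tables (condition, subject, rate,
threshold). Subjects are averaged after linear interpolation along
log2(rate); no extrapolation — target rates outside a subject's span are
clamped to the nearest endpoint and flagged. Model and reference thresholds
pooled over all conditions and rates yield three indices: pattern
similarity (Pearson r; shape), discrepancy (RMS deviation in dB; absolute
mismatch) and net difference (signed mean, positive = model less sensitive
than the reference). `discrepancy^2 = net_difference^2 + var(differences)`
holds as an algebraic identity. Pooling is unweighted, following the index
definitions.

The package ships no measured human thresholds. `synthetic_human_reference()`
generates a clearly-labeled stand-in with the qualitative shapes (low-pass
broadband, high-pass narrowband, three pseudo-subjects); real values can be
supplied as CSV in the same schema.

## Simulated neurophysiology

Units are probed with fully modulated broadband noise (default 10 carriers
per rate). Two tuning curves summarize each unit: rate coding (the
time-averaged activity per rate) and synchrony coding (vector strength of
the activity at the modulation rate, `|sum a(t) e^(-2 i pi f t)| / sum a(t)`
with the trace shifted to be nonnegative, since ELU activities can dip
below zero). The best rate is the argmax (ties to the lowest rate); the
upper cutoff is the highest rate at which the baseline-shifted curve still
holds 0.707 of its peak — the conventional −3 dB point — log-interpolated
between probe rates. Curves whose relative range `(max − min)/max(|v|)`
falls below 1/6 (equivalent to a 1.2 peak-to-floor ratio for positive
curves) count as untuned and are excluded. Both the −3 dB rule and the
validity criterion are conventions chosen here; the original procedure
defers to prior work and does not pin them down.

Layer–region similarity is `1 − D` where `D` is the two-sample
Kolmogorov–Smirnov distance between a layer's distribution of a tuning
characteristic and a brain region's, computed over log rate and averaged
over the available characteristics (rate/synchrony × best/cutoff).
`synthetic_region_reference()` provides a synthetic stand-in for the
literature's single-unit samples across AN → CN → SOC → NLL → IC → MGB →
AC with the qualitative periphery-to-center trend (synchrony tuned to high
rates peripherally, low rates centrally); real literature samples can be
supplied as CSV.

## Numerical choices and degenerate inputs

* Hilbert analytic signals are computed on whole clips by FFT one-siding;
  edge effects are real and excluded from envelope-correlation checks
  (5 ramp lengths per end).
* The "linear bandpass filter bank" is realized as non-overlapping
  brick-wall FFT partitions with edges at ERB-scale midpoints, first edge
  0 Hz and last at Nyquist, so sub-bands sum exactly to the input — the
  property the multiband chimera definitions require. The filter *shape*
  is a package choice; only ERB spacing is given.
* ERB scale: Glasberg–Moore, `ERB-number(f) = 21.4 log10(4.37 f/1000 + 1)`;
  one-ERB spacing from 20 Hz reproduces 42 bands at a 22.05 kHz Nyquist
  and 33 at 8 kHz.
* Flattening a *broadband* signal's envelope cannot survive the real-part
  projection exactly: `Re(FlatEnv · e^(i TFS))` keeps a residual envelope
  fluctuation (CV ≈ 0.3 for white-noise-like clips). The exact invariant —
  constant analytic magnitude before projection — holds to machine
  precision and is what the tests assert, alongside strong relative
  flattening.
* An all-zero clip has RMS 0; scaling it to a nonzero target is an error,
  while flattening its envelope returns zeros.
* All stochastic operations take an explicit seed; corpus-, experiment- and
  pipeline-level seeds fan out to children through a fixed integer hash
  (`derive_seed()`), so any stage can be re-run standalone and byte-identical.

## Known limitations

* Pure-R training is adequate at desk scale but not for 44.1 kHz
  multi-thousand-clip corpora; the architecture search at full published
  budgets (20 candidates × 4 layer counts, patience 32/96) is implemented
  and tested at toy scale only.
* The synthetic corpus lacks the higher-order structure of natural audio;
  conclusions about real datasets require the optional WAV-directory
  loaders and real data.
* The template observer is the plain dot-product correlator; no
  internal-noise injection is provided (the model is deterministic apart
  from carrier and phase sampling).
* Reference data for humans and brain regions are synthetic stand-ins
  unless the user supplies literature tables.
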