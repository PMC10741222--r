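---
title: "Closed-loop theta/beta-ratio neurofeedback: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop theta/beta-ratio neurofeedback: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfbloop)
```

## The problem this package addresses

Elevated theta/beta power ratio (TBR) at frontal electrodes is a classical
electrophysiological correlate of inattention in school-aged children.
Neurofeedback protocols turn this biomarker into a training signal: the
child's EEG is analysed in real time, the TBR is mapped to a visible reward
(here, the altitude of a helicopter on a virtual classroom's whiteboard),
and the child learns, over repeated sessions, to push the statistic in the
trained direction. `nfbloop` implements the full computational stack of such
a protocol — the streaming spectral engine, per-child calibration, feedback
and distraction dynamics, the accompanying cognitive tasks, offline EEG
cleaning (including simultaneous EEG-fMRI artifact correction), microstate
analysis and session statistics — together with a synthetic-data module that
stands in for the children, so that every stage is testable on a desk.

## The real-time engine

Every second the engine takes the trailing 3 s of EEG, applies an average
reference over the scalp (role-`eeg`) channels, tapers the window with a
Hanning function, and computes spectral power at `Fz` in theta (4–7.5 Hz)
and beta (13–19 Hz) as the sum of one-sided periodogram bins with band
edges inclusive. The raw TBR is their ratio. A pure in-band sinusoid of
amplitude $A$ contributes $1.5\,A^2/2$ to its band (the factor 1.5 is the
Hanning equivalent noise bandwidth); the common factor cancels in the
ratio, so no attempt is made to remove it.

Jaw-muscle artifacts inflate broadband power at temporal sites, so the
engine watches beta power at `T7`: when it strictly exceeds 3 times the
beta power at `Fz`, the emitted feedback value is forced to zero and the
sample is flagged. The comparison is strict ("exceeds"), which the boundary
test pins down.

**Window alignment.** A sample at time $t$ uses the half-open interval
$(t-3\,\mathrm{s},\, t]$; the first emission is at $t = 3$ s. Streaming and
whole-recording invocations are guaranteed to produce identical sequences
(`tbr_streamer()` is tested against `stream_tbr()` under several chunk
sizes, including one sample at a time).

## Calibration and normalization

Raw TBR is idiosyncratic, so each child is calibrated by a four-phase
routine (relax, focus, relax, focus; 20 s each). All ungated raw TBR
samples are pooled and sorted; the lower bound is the minimum, the upper
bound the mean of the top quarter (`ceiling(n/4)` values — the rounding
rule is a package choice, since only "last quarter" is specified upstream).
Pooling across all four phases rather than focus phases only is likewise a
documented choice.

The normalized feedback value is

$$\mathrm{nfb} = \mathrm{clip}\!\left(\frac{\mathrm{TBR}_{\max} -
\mathrm{TBR}_{\mathrm{raw}}}{\mathrm{TBR}_{\max} - \mathrm{TBR}_{\min}},\,
0,\, 1\right).$$

The direction — low raw TBR maps to nfb = 1 — is the package's resolution
of an ambiguity: the protocol never writes the formula, but only the
inverted form is consistent with (a) distraction frequency being
*proportional* to concentration, (b) the rising helicopter being the
reward, and (c) training aiming to *decrease* TBR. Degenerate bounds
(max = min) yield 0.5 with a warning rather than an error, so a flat
calibration does not kill a session.

## Feedback dynamics and distraction scheduling

The helicopter integrates the feedback:
$h(t) = \mathrm{clip}(h(t-1) + \mathrm{nfb}\cdot s\cdot dt - 0.5\cdot
s\cdot dt,\ h_{\min},\ h_{\max})$ with constant speed $s = 10$ m/s. The
update is implemented in the factored form $(\mathrm{nfb}-0.5)\,s\,dt$ so
that the equilibrium at nfb = 0.5 is exact in floating point. The clamp
bounds default to 0 and 2.4 m (the screen height); the step is applied at
the 1 s engine hop by default — the per-video-frame gravity of the original
display is irrelevant to the net dynamics because the update carries an
explicit $dt$.

Distractions are scheduled per 30 s block. The first block of each task is
distraction-free; every later block receives at least one event; at full
focus one event occurs every 3 s. The rate law is the simplest one matching
both printed endpoints: the target inter-onset interval is
$3/\max(\mathrm{nfb}, \varepsilon)$ s with $\varepsilon = 3/30$, evaluated
at the instantaneous nfb (instantaneous vs block-averaged was an open
choice; instantaneous is implemented). Events never overlap (durations are
capped at the minimum interval) and the minimum-gap constraint is enforced
across block boundaries as well — an early implementation enforced it only
within blocks, which the 1000-block property test caught. Distraction kinds
are drawn uniformly from a 14-entry catalogue (mistress, headmaster,
classmates, phone, bell, insects) with per-kind default durations, which
the upstream description leaves unspecified.

## Cognitive tasks

*Go/no-go*: 20 trials per block, exactly 5 of them the no-go letter "X"
(the 25% composition is enforced per block rather than i.i.d., so it is
testable), nominal 750/250/1000 ms fixation/letter/response segments with
±10% uniform jitter renormalized so every trial lasts exactly 2 s. A go
trial without a press, or with a press slower than 1 s, is an omission; a
press on "X" is a commission. Reaction-time cleaning removes error trials
first and then, in a single pass, trials more than 3 SD from the
per-subject mean computed on the correct trials.

*Adaptive arithmetic*: single-digit addition/subtraction while the running
accuracy is at most 70%; above 70% the pool widens to two-digit
addition/subtraction and single-digit multiplication, with answers kept in
[0, 99] and three answer options per trial. The rule is implemented
symmetrically (difficulty drops back below the threshold), a flagged
interpretation, and "success rate" is read as running accuracy over the
session.

*Transfer*: alternating 30 s Rest/Regulation blocks, six per condition,
serialized through the ordinary event-table I/O.

## MR artifact cleaning

In-scanner EEG (5 kHz, TR = 1.76 s) is cleaned by moving trimmed-template
subtraction: for each time point of the template, the values of the $L$
neighbouring artifact occurrences are sorted, the $K$ smallest and largest
dropped, and the rest averaged ($L=30, K=6$ for the gradient artifact,
$L=40, K=5$ for the cardioballistic pulse). Neighbourhoods are centred
(⌊L/2⌋ before, rest after, shifted at the edges). The chain order is fixed:
gradient subtraction → 70 Hz FIR low-pass → downsample to 500 Hz → QRS
detection on the ECG channel → pulse subtraction on the scalp channels,
with pulse epochs starting 210 ms after each R-peak (a typical
ballistocardiogram lag; the upstream description gives no window) and
lasting one median RR interval. The QRS detector is a
derivative–energy–threshold design (5–15 Hz bandpass, squaring, 150 ms
integration, adaptive threshold, 300 ms refractory period), polarity-robust
by construction and validated only against synthetic ground truth.

**A quantified limitation.** Template subtraction necessarily injects the
trimmed mean of the neighbouring epochs' *EEG* into every epoch. With the
fixed parameters this leakage has variance ≈ 1/18 (gradient) + 1/30
(pulse) of the EEG variance, capping the achievable correlation between
cleaned and true clean signal near $1/\sqrt{1 + 1/18 + 1/30} \approx
0.957$ — before counting ballistocardiogram energy that leaks into the
TR-locked gradient template (the mandated order cleans the gradient first,
while the pulse artifact is still present) and R-peak sample quantization.
On the synthetic injection-recovery fixture the package measures 0.92–0.94;
the acceptance assertion at 0.95 is therefore red by design rather than
weakened, while the ≥ 20 dB artifact-band reduction clause passes with
>10 dB of margin. Anything better requires methods (optimal basis sets,
PCA residual removal) that are explicit non-goals here.

## Microstates

Topographies at the strict local maxima of the global field power (the
spatial SD across scalp channels) are clustered by a polarity-invariant
modified k-means: assignment by maximal squared spatial correlation, map
update as the dominant eigenvector of the assigned topographies'
outer-product sum, best of 100 random restarts by global explained
variance, k = 5. Exact GFP ties (which arise in noise-free synthetic
signals) are collapsed into plateau runs before peak detection. Recording-
level maps are pooled and re-clustered once for the group level. Back-
fitting assigns each sample to the map with the highest absolute spatial
correlation; temporal smoothing multiplies the evidence of the label
dominating the surrounding 50 ms window by a factor of 10 before the
argmax. That reward scheme is this package's concretization of a smoothing
step whose formula the upstream description does not give; it is isolated
in one internal function (`smooth_labels`) so alternatives can be swapped,
and the tests assert only its contract (fewer segments on noisy data, GEV
accounting intact, polarity invariance).

## The synthetic world

The simulated child is a latent attention state: a clipped mean-reverting
process on [0, 1] with a stationary target and a volatility — the minimal
bounded stationary model with interpretable knobs. Synthetic EEG stacks
band-limited theta/alpha/beta carriers (narrowband Gaussian noise by
default; a pure-tone mode exists for spectral unit tests) on pink
background noise; at frontal channels the theta amplitude falls and the
beta amplitude rises linearly with attention (gain 0.8), making raw TBR
strictly decreasing in attention — the property the whole calibration chain
needs to be testable. Default band amplitudes (theta 10, alpha 6, beta 4,
pink 4 µV RMS) are ordinary child-EEG scales; blinks (80 µV, frontopolar)
and an ECG channel with stylized PQRST complexes at 90 bpm complete the
picture. Jaw bursts are 20–140 Hz noise with 15 Hz raised-cosine spectral
skirts — real EMG rolls off rather than vanishing below 20 Hz, and it is
exactly that shoulder that the 13–19 Hz gate sees. MR contamination adds a
strictly periodic gradient waveform (10 mV, 32 slices per TR, optional
sub-sample jitter and a silent tail) and a smooth R-peak-locked
ballistocardiogram pulse (150 µV, energy below ~4 Hz, no artificial sharp
attack — physiological pulses rise over tens of milliseconds).

What the generator does *not* emulate: volume conduction (channels carry
independent carriers, so spatial interpolation is tested on separate
smooth-field fixtures, not on synthetic EEG), realistic scalp topographies,
pediatric spectral priors beyond the configurable amplitudes, and any
quantitative link between attention and behavior fitted to real children —
the response model's parameters (base RT 450 ms, distraction offset 50 ms,
omission probability falling linearly in attention) are free constructions,
not estimates. A green test therefore establishes algorithmic correctness
and internal consistency, not clinical validity.

## Numerical choices

- FIR filters are windowed-sinc (Hamming) designs with the −6 dB point at
  the cutoff, tap count from the 3.3/Δf rule, applied with exact
  group-delay compensation and reflection padding; ~53 dB stopbands.
- Band power uses inclusive band edges; bin handling at edges is not
  specified upstream, and the oracle tests freeze this choice.
- Modified k-means converges on a relative GEV change below 1e-8 or 300
  iterations; empty clusters are re-seeded with the worst-fitted
  topography.
- EDF is written as 16-bit integers over each channel's physical range
  (documented lossy, correlation > 0.999 on ±100 µV signals); BrainVision
  as IEEE float32 multiplexed, lossless to ~1e-3 µV. Annotations always
  live in seconds so resampling cannot invalidate them; basic EDF cannot
  carry them, so they travel in a `_events.tsv` sidecar.
- Electrode positions are the idealized 10-20/10-10 construction (vertex,
  midline arc, 10% ring, spherical midpoints for intermediate sites) — good
  enough for spherical-spline interpolation (stiffness 4, 20 Legendre
  terms, ridge 1e-5), not a digitized montage.
- Sessions are split 1–4 vs 5–8 for the training-period summary; the
  upstream prose overlaps session 4 into both periods, which this package
  does not reproduce.

## Known limitations

Beyond the MR-cleaning correlation floor quantified above: the engine is
offline-faithful rather than wire-compatible with any acquisition protocol;
ICA denoising is a hook, not an implementation; difficulty and smoothing
parameters reflect single documented interpretations of underspecified
prose; and none of the statistics here are inferential — the package
computes descriptive session summaries only.
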