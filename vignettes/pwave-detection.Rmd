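---
title: "Wavelet P-wave delineation: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet P-wave delineation: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwaver)
```

## The detection model

`pwaver` delineates single-lead ECG with the modulus-extremum machinery of
the translation-invariant (à trous) dyadic wavelet transform.  The
quadratic-spline derivative-of-smoothing wavelet makes each coefficient
series `W_j x` behave like the derivative of a smoothed signal, so an
upright wave of width comparable to scale `2^j` produces a
maximum-then-minimum pair of coefficients whose **zero crossing falls at
the wave crest**.  This single primitive drives both detectors:

* QRS complexes are sharp and large, so their pairs stand out at the fine
  scales 2^1–2^3 simultaneously; requiring cross-scale co-occurrence above
  an adaptive threshold (0.3 x a 2 s running RMS) separates them from the
  smooth P and T waves, whose fine-scale content is negligible.
* P (and T) waves are read at scale 2^4.  Within the pre-QRS search
  segment, extrema are screened by two adaptive amplitude gates — the
  positive gate is 2/5 of the mean of the (up to) ten largest positive
  extremum amplitudes in the segment, the negative gate 1/3 of the mean of
  the ten most negative — and by a pairing window of 100 ms.  The strongest
  surviving pair localizes the P peak at its zero crossing.

The transform is linear, annihilates constants, and is made zero-phase by
averaging the two integer shifts around the spline filters' half-sample
group delay; tests assert linearity, shift covariance and exact crest
localization on analytic bumps.

### Assumptions

The pair screen assumes an *upright* P wave: only maximum-then-minimum
adjacencies are accepted, because a minimum-first adjacency straddles a
valley, and in noise it tends to pair a pre-P dip with the P's own maximum
and mislocalize the crest by tens of milliseconds.  Biphasic or inverted P
morphology is out of scope.  Amplitude units cancel everywhere (all gates
are ratios), so delineation is invariant to lead gain; there is, however,
no absolute voltage floor, so a record containing *only* noise and no
usable P population cannot be vetoed on amplitude grounds alone.

## Search geometry and the secondary scan

The P search segment ahead of beat *i* is
`[S_Q - min(0.45 s, 0.9 RR_{i-1}), S_Q - 0.03 s]`, clipped behind the
previous QRS offset and — when one was found — the previous **T offset**,
since at short coupling intervals the previous T wave would otherwise be
the strongest pair in the segment and pose as a P.  At most one P is
reported per segment.

Nonconducted P waves (dropped beats, complete AV dissociation) have no
anchoring QRS, so a secondary whole-record scan runs on the
QRS-T-cancelled signal: a per-sample **median** template of the beat
window `[R - 0.15 s, R + 0.50 s]` (edge-anchored baseline, cosine-tapered,
subtracted at the best integer-plus-fractional lag) removes the
ventricular waves, leaving atrial activity visible even inside QRS-T
complexes.  The median across beats keeps the minority of windows that a
neighbouring ectopic or dissociated P strays into from biasing the
template; the fractional-lag refinement suppresses the derivative-sized
residual spikes that sub-sample beat jitter would otherwise leave at the
R peak.

Segment-relative thresholds cannot, by construction, reject noise in a
segment that holds no P at all — some noise extrema always clear a gate
defined as a fraction of the segment's own largest extrema.  Two
record-level verification layers therefore follow the screen:

* a **strength floor**: candidates weaker than 0.5 x the median primary
  pair strength are demoted to absent-P;
* **template verification**: every candidate must correlate with the
  record's own average P (detrended, +/- 60 ms window) at >= 0.5 for
  anchored candidates and >= 0.8 for unanchored (secondary) candidates.
  The stricter unanchored gate rejects cancellation residuals near R,
  which never exceed ~0.7 correlation, while genuine dissociated P waves
  sit above 0.87.

With fewer than five primary P waves no template can be built and
verification is skipped; such records (very short, or with no conducted
beats at all) get best-effort output.

## Boundary placement and features

The wavelet response at scale 2^4 is much wider than the P wave itself, so
the 5% coefficient-decay points bracket the wave generously rather than
delimit it.  Final onsets and offsets are refined in the signal domain:
inside the wavelet bracket, the boundary is placed where the
baseline-corrected amplitude falls below 1% of the peak amplitude (floored
at 3 x the high-frequency noise level) for two consecutive samples, on the
cancelled signal for P and on the reconstructed template contribution for
the QRS onset (which is noise-free by construction).  On noiseless sinus
records with a scripted PR of 160 ms the measured mean PR lands within
4 ms and P duration within 2 ms of the analytic truth.

Features follow the standard definitions, all intervals in milliseconds
and amplitudes in mV with 0-based sample indices: PR interval
`(S_Q - S_P)/fs` flagged normal inside the inclusive 120–200 ms range; P
duration `(E_P - S_P)/fs`, strictly < 120 ms; baseline-corrected P
amplitude (PR-segment median 40–10 ms before S_Q), strictly < 0.25 mV;
P-wave dispersion `Pm - Pn` across leads, < 40 ms normal and >= 50 ms
suggesting heterogeneous atrial conduction (the published criterion for
the in-between band is garbled in the literature this implements; the
50 ms reading is recorded as an interpretation); heart rate
`60 / mean(interval)` from PP or RR.  A duration printed as onset *minus*
offset in some sources is implemented as offset minus onset — durations
are nonnegative by definition.  The printed slope criterion for extremum
pairs is typographically degenerate (identical numerator and denominator);
it is implemented as amplitude difference over time difference and ships
disabled (`slope_min = 0`), available as a config knob.

## Rhythm rules

All rule constants are config keys, not code: a PAC is a P arriving >= 20%
earlier than the running median PP with PR > 120 ms followed by an
incomplete compensatory pause (coupling + pause < 2 x median PP); a
nonconducted P has no QRS onset within 300 ms; AV dissociation requires
circular variance of the P-to-next-QRS phases above 0.5 *and* atrial rate
above ventricular rate; sinus bradycardia is 1:1 conduction below 60 bpm.
The dropped-QRS pattern is labelled neutrally `intermittent_block`
(clinically it is described as a type I / Mobitz-like atrioventricular
block).  The circular variance is computed over *uncapped* P-to-next-QRS
intervals mapped to phases of the ventricular cycle: coupling concentrates
the phases, dissociation spreads them uniformly.

## The synthetic generator

Beats are sums of five Gaussians (P, Q, R, S, T), which keeps ground truth
analytic: peaks at the Gaussian centers, boundaries at 1% of each peak.
The normal preset keeps the P inside textbook limits (0.15 mV, ~108 ms);
the PAC preset is wider and taller on purpose.  Default sampling rate is
250 Hz; scripts state rhythm kind, lattice intervals, PR delay, conduction
pattern, duration, noise and seed, and the seed fully determines the
output while truth never depends on noise.

Scripted conditions mirror the rhythms the detector is meant to handle:
complete AV dissociation uses independent lattices at 0.6818 s (88 bpm)
and 2.0 s (30 bpm); the dropped-QRS script omits the QRS-T after every
5th P at a 0.9677 s lattice (62 bpm); PACs replace every 8th beat at 25%
prematurity with the post-ectopic interval `2 PP - coupling - 0.1 PP` (an
incomplete compensatory pause); noise is white Gaussian at a scripted SNR
plus sinusoidal baseline wander and optional powerline.  The benchmark
classes pool PAC + dissociation (ventricular-arrhythmia-like) and sinus +
bradycardia (atrial) records, ~2,000 annotated beats per class at 20 dB
SNR with 0.1 mV wander over ten seeds — sizes chosen so the whole
benchmark runs in a few minutes on one core.

The default dissociation phase offset (first P 0.45 s after the first R)
lets the 88/30 configuration drift through the ventricular cycle, so some
P waves do fall inside QRS-T complexes; the cancellation path is what
recovers them.  What the generator does *not* emulate: real P-wave
morphology variation, respiratory modulation, fibrillatory f waves
(P-wave dispersion is exercised by scripted inter-lead width jitter
instead), muscle artifact, or electrode motion.  Passing the benchmark
therefore demonstrates the algorithm's mechanics — thresholds, pairing,
cancellation, scoring — under controlled conditions, not clinical-grade
performance on Holter data.

## Evaluation conventions

Detections are matched to truth greedily one-to-one in order of increasing
time error within +/- 75 ms (the common delineation tolerance;
configurable).  On dense random tracks the greedy matching sits within a
documented 1–2 matches of the optimal-assignment oracle.  `Se`, `Pp` are
the usual sensitivity and positive predictivity; the failed-detection rate
is `Er = 100 (FP + FN)/(TP + FN)` with the alternative denominator
`TP + FP + FN` available by config.  Sample-size helpers
(`N = Z^2 P (1-P)/E^2`, `n = Z^2 sigma^2 / d^2`) round up with a floor of
one.

## Numerical choices and degenerate inputs

Zero crossings interpolate linearly between samples and round to the
nearest sample; when several crossings lie between a pair the one nearest
the pair midpoint is taken.  Ties in pair strength resolve to the first
maximum.  Segments shorter than 40 ms are treated as degenerate (absent
P); empty records delineate to an empty fiducial table; flat-line records
yield an empty QRS list with a warning; a missing polarity in a search
segment produces sentinel thresholds that reject every pair.  Records are
refused on NaN cells rather than imputed.

## Known limitations

Single-lead logic only (multi-lead records are delineated per lead and
fused at the feature level); upright-P assumption; no absolute amplitude
floor without a P population to calibrate against; atrial-fibrillation f
waves and biphasic P subtyping are out of scope.
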