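---
title: "Methods: state-resolved power, theta-gamma coupling and ripple detection in hippolfp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: state-resolved power, theta-gamma coupling and ripple detection in hippolfp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippolfp)
```

# Scope

`hippolfp` analyzes laminar hippocampal CA1 local field potential (LFP)
recordings from freely moving rodents together with overhead tracking of
the animal. The pipeline has five stages:

1. **Behavior** — classify every video frame into exploration, grooming or
   wake immobility from tracking speed, collapse frames into epochs,
   drop grooming and sub-second epochs, and map epochs onto LFP sample
   indices through shared TTL pulses.
2. **Spectral** — Welch power spectra per behavioral state, band power for
   the canonical bands, normalization by total 0.5–250 Hz power, and a
   top-3-channel summary per subject.
3. **PAC** — theta–gamma phase-amplitude coupling via the
   envelope-normalized mean-vector-length modulation index (MI):
   comodulograms over 1-Hz bins and time-resolved PAC (tPAC) on 1-s
   windows.
4. **SWR** — sharp wave–ripple detection: a 120–250 Hz ripple power signal
   with dual-threshold event detection on the pyramidal-layer channel,
   sharp-wave co-detection on the stratum radiatum channel, event
   features, and an exploration/immobility occurrence-rate ratio.
5. **Stats** — PCA/Hotelling T² outlier masking, random-intercept linear
   mixed models over genotype × state × trial, an interaction-dropping
   refit rule for two-factor analyses, and Welch-t post hocs with
   Benjamini–Hochberg FDR.

A synthetic session generator produces multichannel LFP, tracking and
ground truth with the statistical structure the analysis assumes, so
every stage is testable without recorded data.

# Behavioral segmentation

Frame speed is `||pos[i] − pos[i−1]|| × frame rate`, with the first frame
copying the second so every frame has a defined label. Thresholds follow
the conventional open-field scheme: exploration above 0.05 m/s, wake
immobility at zero, grooming in between. A literal "zero" is numerically
fragile under tracker jitter, so immobility is defined by a zero-tolerance
parameter (`zeroTol`, default 1e-3 m/s). Maximal runs of one label become
half-open epochs `[start, end)`; grooming epochs are removed outright and
any epoch shorter than 1 s is dropped without merging its neighbors.

Camera and LFP clocks are aligned by an affine map fitted to matched TTL
pulse times: one shared pulse gives a pure offset, two or more also
estimate linear drift by least squares. With two pulses bracketing a
20-minute session and 10 ppm drift the mapping residual is below 1 ms
(asserted in the test suite). Sample indices are 0-based and half-open
everywhere.

# Spectral analysis

Welch spectra use 1-s Hann windows with 50% overlap, per-segment constant
detrend and one-sided density scaling, so the rectangle-rule integral of
the density equals the mean power of the detrended segments. Epochs of a
state are pooled by averaging segment periodograms with equal weight
across all epochs of that state. Band power is a rectangle-rule integral
over the half-open band; normalized band power divides by the total
0.5–250 Hz power and is exactly invariant to amplitude rescaling. The
canonical band table is delta 0.4–4, theta-low 5–8, theta-high 8–12,
slow-gamma 30–45, fast-gamma 60–120 and HFO 120–250 Hz. (The delta band
opens at 0.4 Hz while total power starts at 0.5 Hz; on a 1-Hz analysis
grid both resolve to the same bins, so the table is kept as printed.)

**Parseval and 1/f signals.** A spectrum on a 1-Hz grid cannot represent
power below its resolution; for 1/f-type signals a substantial share of
the variance lives in slow drift that per-segment detrending removes. The
PSD object therefore carries `segPower`, the mean power of the analyzed
detrended segments, and Parseval checks compare the spectral integral
against that quantity (for tones and white noise it coincides with the
signal variance).

**Top-channel summary.** The "three channels with the highest power" are
ranked per band on normalized power pooled across states, so the channel
set is fixed across the state comparison within a subject; the average of
the top three is reported per state.

**Operating rate.** Spectral and PAC stages run at the recording rate;
the ripple stage resamples to 1200 Hz (below). The default test-scale
recording rate is 2500 Hz — high enough to carry a 250 Hz band
comfortably — with 25 kHz acquisition supported by configuration.

# Phase–amplitude coupling

All filters are Butterworth band-passes applied forward–backward
(zero phase, doubled order; order 4 per pass by default). For analysis
bands the design corners are pre-warped by an iterative calibration so
that the −3 dB corners of the combined two-pass response land on the
requested edges within 0.5 Hz. Phase and envelope come from the FFT
analytic signal; a per-side transient span (propagated as an attribute)
is excluded before any statistic.

The modulation index is the envelope-normalized mean vector length

$$MI = \frac{\left|\langle A(t)\,e^{i\phi(t)}\rangle\right|}{\langle A(t)\rangle},$$

which is bounded in [0, 1], zero in expectation when envelope and phase
are uncoupled, invariant to rescaling either signal, and equal to 0.5 in
the continuous limit for a fully modulated sinusoidal envelope
$A \propto 1+\cos\phi$. For the generator's modulation law with depth
$d$, the closed form is $MI = d/(4-2d)$, which the estimator reproduces
to three decimals on clean fixtures. An 18-bin Kullback–Leibler MI is
provided as an independent cross-check estimator; the pipeline itself
uses the mean-vector-length form throughout because its normalization
makes subject-level comparisons amplitude-independent.

**Comodulogram.** Phase bins are 1-Hz-spaced centers over 5–12 Hz with a
2-Hz filter bandwidth; amplitude bins cover 30–120 Hz with bandwidth
twice the phase frequency, wide enough to pass both modulation sidebands.
The amplitude design corners are padded ~5% per side: a Butterworth
response is already −3 dB at its corners, and without the pad a bin that
passes one sideband against a partially attenuated carrier shows spurious
beat modulation that can out-score the true bin under envelope
normalization. With the pad, a single injected 8 Hz → 70 Hz coupling
localizes to within one bin, and a dual coupling (8 → 40 and 8 → 70)
produces two separated local maxima. MI is computed per epoch and
averaged across epochs; group comodulograms average subject matrices.

**tPAC.** Each epoch is cut into non-overlapping 1-s windows (remainder
discarded), MI is computed per window, and the subject summary is the
arithmetic mean. At a 6.5-Hz phase band a 1-s window holds only ~7 theta
cycles, so single-window MI is noisy; the per-window spread is reported
and shrinks as $1/\sqrt{n}$ for stationary coupling. Default band pairs
for state comparisons: 6.5–10 / 55–90 Hz and 6.5–9 / 35–45 Hz during
exploration, 6.5–9 / 60–90 Hz during wake immobility. Significance
statements use 200 circular time-shift surrogates of the envelope with a
minimum 1-s shift.

# Sharp wave–ripple detection

The pyramidal-layer signal is band-passed 120–250 Hz, resampled to
1200 Hz by Fourier resampling (spectrum truncation at the new Nyquist —
inherently anti-aliased, and exact for band-limited content; the
2500→1200 ratio is not an integer decimation), segmented by behavioral
epochs, z-scored per segment, rectified and smoothed with a centered 8-ms
rectangular window, yielding the ripple power signal. Constant segments
are flagged degenerate by inspecting the raw input (filter edge
transients leave numerical residue after band-passing a constant).

Candidate ripples are maximal runs with at least one sample above
mean + 3 SD of the segment's power signal, expanded bidirectionally to
the last contiguous sample above mean + 2 SD; expanded runs that touch
are merged. Events shorter than 30 ms or with a peak spectral frequency
below 140 Hz (periodogram maximum within 120–250 Hz, zero-padded to 1-Hz
resolution) are discarded. Segment SDs are pooled within state for
segments shorter than 5 s. Sharp waves are detected on the radiatum
channel band-passed 0.5–40 Hz (a high-pass/low-pass cascade — a direct
transfer-function band-pass with a lower corner at 1/2400 of the
sampling rate is numerically fragile), thresholding |filtered| at
2.5 SD — polarity-agnostic, since referencing can flip the conventional
negative deflection — and keeping crossings lasting 20–400 ms. Only
ripples whose interval intersects a sharp-wave interval are retained (no
tolerance window). Event features: duration, peak spectral frequency,
120–250 Hz band power, slow-gamma (30–45 Hz) power and peak frequency
over the event window (extended symmetrically to 100 ms when shorter, so
the band is resolvable), and the behavioral state of the segment. The
occurrence-rate ratio divides the exploration event rate by the
immobility event rate, canceling electrode-placement effects common to
both.

Note the duration a threshold detector reports is the span of the
mean + 2 SD crossing, which for any smoothly enveloped burst is shorter
than the burst's nominal extent; the generator's flat-core envelope
(below) keeps this gap within a few milliseconds.

# Statistical layer

Outliers are masked per genotype × state × trial cell: measures are
standardized, projected onto the principal components explaining ≥ 95%
of variance, Hotelling T² is computed per point, and points above the
F-distribution bound $k(n-1)/(n-k)\,F_{k,n-k,0.95}$ are flagged. Singular
covariance falls back to a univariate z-rule with a warning. The mask is
returned, never silently applied.

Mixed models are fit by REML via `lmerTest` with a per-subject random
intercept, treatment coding with WT / exploration / trial-1 reference
levels, and type-III F tests with Satterthwaite degrees of freedom (the
package's fit surface owns coding and effect extraction; the optimizer is
delegated). A singular fit — zero estimated intercept variance — is a
valid boundary solution and is not treated as non-convergence. A constant
response returns a flagged degenerate result rather than an error. For
the two-factor genotype × trial analyses (PAC, occurrence ratio,
whole-trial behavior), a non-significant interaction (p ≥ 0.05) triggers
an additive refit whose main-effect p-values are reported.

Post hocs are pairwise Welch t-tests on subject-level values (chosen over
the pooled-variance form because group sizes of ~5 make the equal
variance assumption untestable), corrected by Benjamini–Hochberg within
one measure family: $q_{(i)} = \min_{j \ge i} m\,p_{(j)}/j$, capped at 1.
The implementation is the step-up definition itself and is verified in
tests against a literal double-loop oracle and `p.adjust`. A
null-simulation test of the full procedure (fit → interaction rule →
post hoc → FDR, 500 replicates of 5 + 5 subjects × 2 trials) confirms the
false-rejection rate stays within Monte-Carlo error of the nominal 5%.

# The synthetic session generator

`simSession()` sums, per channel: Gaussian 1/f^α background (spectral
shaping of white noise; α = 1 by default, the standard LFP
approximation), state-gated theta (amplitude per behavioral state),
gamma whose envelope follows
$A(t) = a_g\,[1-d+d\,(1+\cos\phi_\theta)/2]$ with depth $d$ set per
state, and an injected SWR train. Theta and gamma are concentrated on
the channels flanking the pyramidal layer (gain 1 there, 0.25
elsewhere), ripples go to the pyramidal channel and sharp waves to the
radiatum channel. Tracking follows the same bout schedule with constant
within-state speeds strictly inside each class (0.2, 0.03, 0 m/s), a
smooth random-turning path reflecting off the arena walls, and TTL
pulses at session start and end on both clocks; camera-clock offset and
drift are configurable. Everything is reproducible from one integer
seed.

Design choices worth restating:

- **Ripple burst envelope.** Bursts are sinusoids under a tapered-cosine
  (Tukey, 25% taper) envelope rather than a fully bell-shaped one. A
  bell-shaped envelope keeps only about half its nominal duration above
  the 2-SD expansion threshold at moderate SNR, so no threshold detector
  could score well against its nominal extent; the flat core makes the
  injected duration physically meaningful to the detector while the
  cosine ramps avoid spectral splatter.
- **Sharp-wave shape.** A negative Gaussian deflection of configurable
  width (default 80 ms), which the 0.5–40 Hz / 20–400 ms detector sees as
  a single crossing.
- **Event placement.** Poisson per state at the state's rate (or exact
  counts for benchmarks), with start times resampled on collision so
  ground truth is unambiguous; ripple-only and sharp-wave-only
  distractors exercise the co-occurrence filter in the fail direction.
- **Default conditions.** 16 channels, 2500 Hz (desk-scale; 25 kHz by
  configuration), noise SD 20 μV, theta 50/30/15 μV across
  exploration/grooming/immobility, gamma 15 μV with coupling depth
  0.8/0.4/0.3, SWR rates 0.05/0/0.3 events/s, ripple 180 Hz × 60 ms,
  arena 1 m at 30 fps. Amplitudes and SNRs are chosen for detector
  exercisability — the source recordings report no amplitude or SNR
  figures — and benchmark ripple amplitude is set relative to the
  measured in-band background SD so SNR is controlled exactly.

**What passing tests do and do not show.** The generator produces
stationary rhythms with fixed frequencies, Gaussian background, isolated
stereotyped events and noiseless tracking. Real recordings add
non-stationary rhythms, movement and chewing artifacts, electrode drift,
overlapping events and tracker dropouts. Green tests certify that the
implementations compute their definitions correctly and recover known
structure under the stated model — not that thresholds are optimal for
any particular recording system.

# Numerical choices and degenerate inputs

- Filters: Butterworth order 4 per pass, forward–backward; corner
  pre-warp by iterative calibration (analysis bands) or design corners at
  the bin edges with ~5% padding (comodulogram bins). Bands whose upper
  edge falls below 1% of the sampling rate (e.g., theta at 2.5–25 kHz)
  are filtered at a decimated working rate — Fourier resample down,
  filter where the transfer function is well-conditioned, resample
  back; every step zero-phase — because clustered poles near z = 1 make
  the direct form numerically unstable. The 0.5–40 Hz sharp-wave band
  uses a high-pass/low-pass cascade for the same reason.
- Analytic signal by FFT; transient spans discarded at signal ends only
  (filtering is continuous across epoch interiors).
- Problem sizes in the test and acceptance runs: 10–30 s PAC fixtures at
  600–1000 Hz, a 360-s two-channel SWR benchmark at 2500 Hz, a 20-minute
  two-channel occurrence-ratio session, 500-replicate null simulation —
  sizes at which every property is measurable with comfortable margins.
- Degenerate inputs error informatively (`invalid-argument` style) or
  return flagged results: constant signals in phase/envelope extraction,
  zero mean envelope in MI, zero total power in normalization, constant
  responses in the LMM, zero-duration states in the occurrence ratio.
- Ties in the comodulogram argmax are broken by the first bin in
  column-major order; local maxima require strict dominance over the
  8-neighborhood.

# Known limitations

- The mean-vector-length MI, under envelope normalization, can be
  inflated in narrow amplitude bins that straddle a spectral line; the
  comodulogram's padded filters mitigate this for line-like fixtures, and
  broadband gamma in real data blunts it further, but isolated spectral
  peaks adjacent to the gamma range (e.g., line noise harmonics) should
  be notched before PAC analysis.
- Sharp-wave detection on |filtered| accepts rebound lobes of large slow
  transients as separate events; the co-occurrence requirement removes
  most of these, but artifact-heavy segments should be excluded upstream.
- The occurrence ratio is undefined without immobility exposure and
  infinite without immobility events; both cases are flagged rather than
  imputed.
- T² outlier masking with ~5 subjects per cell has low power and the
  F-bound is approximate at such n; the mask is returned for inspection
  rather than silently applied for exactly this reason.
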