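---
title: "Quantifying mechanically gated currents on pillar arrays: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mechanically gated currents on pillar arrays: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechanopillar)
```

# The measurement problem

Chondrocytes, the cells of articular cartilage, convert mechanical load
into ionic current through mechanically gated channels (PIEZO1 and
TRPV4). A clean way to deliver a calibrated mechanical stimulus at a
cell-substrate contact is to culture the cells on an array of
elastomeric pili and deflect a single pilus beneath a patch-clamped
cell. Quantification then runs through a chain of steps, each of which
this package implements and tests:

1. **Stimulus size.** A bright-field image is taken before, during and
   after the stimulus. Each pilus images as a bright spot; its center is
   localized by a 2D Gaussian fit, and the center displacement between
   the before and during frames, in nm, is the stimulus magnitude.
2. **Stimulus force.** A pilus is a bent elastic cylinder, i.e. a
   spring: `k = (3/4) * pi * E * r^4 / L^3`, and the restoring force is
   Hooke's law `F = k d`.
3. **Current kinetics.** Whole-cell currents sampled at 10 kHz (3 kHz
   low-pass) are summarized by latency (stimulus onset to current
   onset), a mono-exponential activation constant tau1, a
   mono-exponential decay constant tau2, and peak amplitude. Latencies
   under 5 ms (and activation faster than 1 ms) are the accepted
   signature of direct mechanical gating, as opposed to second-messenger
   activation.
4. **Population statistics.** Per cell, amplitudes are binned by
   stimulus size (bins 0-10, 10-50, 50-100, 100-250, 250-500, 500-1000
   nm), averaged within bins, then across cells; a cell is a *responder*
   if at least one stimulus in (0, 1000] nm gated a current, and its
   *threshold* is the smallest gating deflection.
5. **Membrane stretch.** High-speed pressure clamp (HSPC) applies
   pressure steps (10-150 mmHg in 20 mmHg increments) to membrane
   patches; per-patch normalized peak currents follow a Boltzmann
   relation whose midpoint P50 summarizes stretch sensitivity.
6. **Calcium imaging.** dF/F = (F - F0)/F0 with F0 the mean of the
   first 10 frames; agonist epochs (ATP viability test, Yoda1 for
   PIEZO1, GSK1016790A for TRPV4) are scored as responses when the peak
   dF/F exceeds a threshold.
7. **Inference.** Categorical contrasts use Fisher's exact test, skewed
   continuous summaries the Mann-Whitney U test, and spread contrasts
   the variance-ratio F test; all three are implemented here with
   enumeration/exact tails so small-sample p-values are auditable.

No recordings are distributed with the package; a seeded synthetic
module generates all four input classes with the statistical structure
the analyses expect, which is what makes every downstream stage testable
end to end.

# Units

One unit identity does all the work in the mechanics module: 1 MPa is
exactly 1 pN/nm^2. With the elastomer modulus in MPa and the pillar
dimensions converted from um to nm, the beam formula returns pN/nm
directly. The default calibration (E 2.1 MPa, r 1.79 um, L 5.87 um)
gives:

```{r}
k <- springConstant(PillarGeometry())
k
deflectionToForce(252, k)   # nN at the mean chondrocyte threshold
```

# Pillar localization

Spots are modeled and fitted as isotropic 2D Gaussians on a constant
background, `A exp(-((x-x0)^2 + (y-y0)^2) / (2 s^2)) + B`; the pili act
as light guides and their exact optical profile is not specified by the
imaging model, so the simplest profile consistent with the fitting model
is used for synthesis (an anisotropic fit is available behind a flag).
Coordinates are 0-based with the pixel-center convention, and every
nm conversion goes through a single pixel-size constant (default 161
nm/px, a 40x objective with a 6.45 um camera pixel). Fits are
initialized from the background-subtracted intensity centroid; a fit
that does not converge or whose center leaves the ROI is flagged, never
silently reported.

Default synthetic imaging conditions: spot sigma 600 nm, grid pitch
4.16 um (chosen so neighboring spots do not overlap within 3 sigma —
the real inter-pillar spacing is not part of the imaging model), peak
2000 counts over a 200-count background, Gaussian read noise sd 15
counts. Under these conditions the deflection RMSE over seeded
before/during pairs is about 1.3 nm, comfortably inside the 7 nm error
budget quoted for the method.

Rigid stage drift between frames can be removed by measuring the median
displacement of non-stimulated reference pillars; this correction is
off by default (the three-frame protocol does not describe it) and
exercised in the drift tests.

# Current kinetics

The synthetic event waveform rises as `A (1 - exp(-t/tau1))` for five
activation constants and decays as `A exp(-t/tau2)`; inward currents
are negative at negative holding potentials. The whole trace passes
through a causal 4-pole Bessel low-pass at 3 kHz — the standard
acquisition filter family in patch-clamp hardware — designed in-package
from the reverse Bessel polynomial with a prewarped bilinear transform
(order configurable).

Extraction decisions, each the package's own operational definition
(the measurement chain does not pin them down) and configurable:

- **Onset detector:** first deviation from the baseline mean by more
  than 5 baseline SDs sustained for 0.3 ms, searched after stimulus
  onset; baseline statistics come from the 20 ms before the stimulus.
- **Sub-sample latency:** at 10 kHz one sample is 0.1 ms, i.e. ~3% of a
  3.6 ms latency, so the detector's onset is refined by a free-onset
  fit of the activation model, and the group delay of the recorded
  acquisition filter (~0.08 ms at 3 kHz/10 kHz, computed from the
  filter's impulse-response centroid) is subtracted. Samples within
  0.3 ms of the detected onset are excluded from the rise fit — the
  filter reshapes the waveform front over its settling time — while
  1 ms of pre-onset baseline anchors the free onset under noise.
- **Peak and decay window:** the peak is located on a 1 ms
  boxcar-smoothed deviation trace (the raw argmax rides the largest
  noise excursion); amplitude is read from the raw trace at that
  position. The decay fit `A exp(-t/tau2) + C` starts 0.5 ms after the
  peak and ends where the smoothed deviation falls below 2% of the
  peak, or at the trace end.
- **Unfittable currents** (rise windows under 5 samples, optimizer
  failure) keep their latency and amplitude and carry NA time
  constants, mirroring how sparse knockout currents are reported rather
  than discarded.

With these choices, noiseless synthetic events are recovered to well
under 1% in latency, tau1 and tau2 at the published parameter sets, and
at a signal-to-noise ratio of 20 the median relative error of both time
constants stays below 5%.

# Stimulus-response statistics

Bins are implemented contiguously as {0, 10, 50, 100, 250, 500, 1000}
nm with half-open intervals (lower, upper]; the bin list in the source
methods omits 50-100 nm while the figures use it, which is treated as a
typo in the methods list. Averaging is two-stage — within cell per bin,
then across cells — and a bin's across-cell mean uses only the cells
that contributed a measurement to it. Non-responding sweeps count as
amplitude 0 in their deflection bin; whether the original analysis did
the same is not stated outright, but its source data mark bins where
"all measurements were zero", which is only possible if zero-amplitude
sweeps are binned. Both conventions are therefore implemented as stated
here and flagged as an assumption.

# Pressure-clamp analysis

Each patch's peak currents are divided by the family maximum and fitted
with `y(P) = A / (1 + exp((P50 - P) / slope))`, slope constrained
positive. The amplitude scale A (close to 1) is needed because
max-normalization pins the curve to 1 at the largest *applied* pressure
(150 mmHg), where a Boltzmann with P50 near 87 mmHg has only reached
~97% of saturation; without A the fitted P50 would be biased low by
over 1 mmHg even on noiseless data. The group P50 is the mean of
per-patch P50s, not a pooled fit. Non-responding (all-zero) and
non-converging patches are excluded and listed rather than guessed at.
Cell-attached protocols use negative pressures of the same magnitudes;
analysis operates on |P| throughout.

The generator's default slope is 10 mmHg. The source experiments report
P50s (87.1 mmHg in wild-type chondrocytes) but no slope; Boltzmann
slopes for stretch-activated channels in patch recordings typically sit
around 8-15 mmHg, and the steeper end of that range is what makes P50
recoverable to ~2 mmHg from an 8-step protocol at realistic noise.

# Exact tests

- **Fisher's exact test** sums hypergeometric point probabilities not
  exceeding the observed one (relative tolerance 1e-12 on the
  comparison); the doubled-one-sided variant is available behind a
  flag. The point-probability rule reproduces the published responder
  contrasts: p = 0.040 for 6/12 vs 19/22 and p = 0.00025 for 2/11 vs
  19/22.
- **Mann-Whitney U** enumerates all group assignments up to a pooled
  size of 12 and otherwise uses a normal approximation with midranks,
  tie-corrected variance, continuity correction and an Edgeworth
  kurtosis term. The kurtosis term matters: without it the
  approximation can disagree with enumeration by more than 0.015 right
  at the enumeration cutoff; with it the two modes agree to better
  than 0.002.
- **Variance-ratio F test** takes the larger variance over the smaller
  and doubles the upper tail.

All three hold their nominal type-I error within [0.03, 0.07] at
alpha 0.05 in the simulation checks (2000 null replicates each).

# What the synthetic generators do and do not emulate

The generators reproduce the *statistical structure* the analyses
consume: Gaussian spot images with read/shot noise, event waveforms
with log-normally distributed kinetics (kinetic source data are
right-skewed and strictly positive), Bernoulli responder status,
Boltzmann pressure dependence, and step-plus-decay calcium transients.
Parameter defaults are taken from the published group statistics:
latency 3.6 ms and tau1 1.7 ms for chondrocytes (3.1/1.4 ms for
dedifferentiated cells), tau2 12.2 ms, responder fractions 24/27 and
15/17, thresholds 252 vs 59 nm, HSPC P50 87.1 mmHg and peak currents
72.8 vs 4.1 pA for the knockdown contrast. Event-level kinetic spreads
are recovered from the reported s.e.m. and n (sd = sem * sqrt(n)).

Two generator choices deserve emphasis:

- **Thresholds are drawn from a log-normal truncated to (0, 1000] nm**
  whose *truncated* moments match the published mean. A responder is,
  by definition, a cell whose threshold lies inside the probed range,
  and the published threshold statistics are computed from such
  range-limited observations. The per-cell spread is set to CV 0.5
  (126 nm for chondrocytes, 29.5 nm for dedifferentiated cells): the
  sem-derived spread (333 nm) cannot coexist with a 252 nm mean on a
  (0, 1000] support for any unimodal family — it forces mass onto both
  support ends, which would contradict both the convergence of the
  observed threshold mean to the published value and the clear
  group separation the published contrast shows.
- **Each cell's stimulus series includes its threshold crossing**: the
  experiment ramps stimulus size until the channel gates and records
  that deflection, so the generator's observed smallest gating
  deflection equals the drawn threshold rather than the next point of
  a fixed probe grid.

Features of real recordings deliberately *not* modeled: optical
diffraction and cell-body shading in images, single-channel (Markov)
gating noise, leak/seal drift and series-resistance artifacts,
pressure-clamp hardware dynamics, and dye bleaching. Passing tests
therefore demonstrate that the analysis chain is correct and
well-conditioned under the declared statistical structure — not that it
is robust to every artifact of real data.

# Reproducibility and problem sizes

Every generator takes an explicit seed and restores the caller's RNG
state; the pipeline fans one global seed out to per-stage child seeds
by a fixed affine scheme, so stages are independently reproducible and
a full run is byte-identical per seed. The test suite sizes its
simulations to keep a full run in the tens of seconds while leaving
clear statistical margins: 60 image pairs for the localization error
check (the acceptance script uses 200), 500 noisy events for kinetic
recovery, 100 patches for P50 recovery, 200 replicates per power
property, 2000 replicates per type-I check, and 10 000 cells for the
law-of-large-numbers checks.

# Known limitations

- The mono-exponential activation/decay model is the summary the
  measurement chain defines; genuinely multi-exponential decays will
  fold into an effective tau2.
- Latency compensation assumes the acquisition filter recorded in the
  trace metadata is the filter that shaped the data; traces of unknown
  provenance get no compensation (and their latency carries the
  filter's group delay, ~0.1 ms).
- Sub-millisecond activation constants approach the 3 kHz filter's
  settling time; recovery degrades gracefully (~1% bias at tau1 = 0.55
  ms) but the filter, not the fitter, sets the floor.
- The Fisher p-value printed as 0.03 for the 6/13 vs 24/27 responder
  contrast in the source material is not reproduced by any standard
  two-sided rule (enumeration gives 0.0065); the package reports the
  enumerated value.
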