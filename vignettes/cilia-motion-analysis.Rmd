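---
title: "Measuring passive renal cilium motion: model, estimators, and their limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring passive renal cilium motion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliamotion)
```

## Setting

In the proximal tubule of a live, anesthetized mouse, GFP-labelled primary
cilia are bent nearly flat along the tubule wall by filtrate flow, pivot
about a fixed point just above their base, and — when flow is pulsatile —
oscillate through an arc of about 106° at about 4.6 Hz, dwelling most of
each cycle near the wall. The field oscillates in unison; motion stops at
death and the cilia relax to perpendicular. `ciliamotion` implements the
measurement chain for such movies (projection → arc fit → kymograph →
tip-angle trace → statistics) and a synthetic generator of the same
kinematics so the chain can be validated end to end without real data.

## The kinematic model and its assumptions

The cilium is reduced to a rigid distal segment of length `distal_length`
pivoting about a hinge `hinge_height` pixels above its base. This is
deliberately phenomenological: in vivo observations locate a regular,
specific bend point and the analysis concerns only the tip path, so an
elastic-cantilever model would add parameters (flexural rigidity, drag
profile) that nothing downstream can identify. The tip angle follows

$$\theta(t) = \theta_{\min} + S\,u(t)^p,\qquad
  u(t) = \tfrac12\bigl(1 + \sin(2\pi f t + \phi)\bigr),$$

a sinusoidal drive passed through a power-law saturation. The single shape
parameter $p$ controls wall-biased dwell. Because $u$ is arcsine-distributed
over a cycle, the fraction of time spent in the lowest tenth of the arc has
the closed form

$$F_1(p) = \tfrac12 + \tfrac{1}{\pi}\,\mathrm{asin}\bigl(2\cdot 0.1^{1/p} - 1\bigr),$$

which exceeds $1/2$ only for $p > \log_2 10 \approx 3.32$. The observation
the generator must emulate is that the cilium spends the *majority* of each
cycle in the wall-proximal tenth of its path, so the default is $p = 4$
($F_1 = 0.540$); $p = 3$, for comparison, yields $F_1 = 0.477$ and fails
the majority criterion — a point worth noting because saturating-dwell
exponents near 3 look superficially adequate.

Reversal events (a cilium flipping to the mirrored posture, occasionally
seen under steady flow) are a Poisson process of rate `reversal_rate` with
exponentially distributed durations, implemented as $\theta \to 180° -
\theta$. Phase jitter across the field is Gaussian per cilium and frozen
over the movie: the field moves in unison up to small static offsets.

Three presets state the three observed regimes: `renal_anesthetized`
($f = 4.58$ Hz, $S = 106°$, $\theta_{\min} = 4°$, $p = 4$, 26 fps, 40 s),
`death` (no drive, rest at 90°), and `steady_flow` (rest at 15°, reversal
rate 0.02/s).

## Generator parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `drive_frequency` | 4.58 | Hz | reported oscillation frequency |
| `sweep_span` | 106 | deg | reported arc |
| `wall_angle_min` | 4 | deg | closest wall approach; not reported, chosen small but nonzero |
| `dwell_exponent` | 4 | — | smallest integer exponent giving majority wall-proximal dwell (see above) |
| `fps`, `duration` | 26, 40 | 1/s, s | reported acquisition settings |
| `hinge_height` | 4 | px | bend point just above the base, desk-scale |
| `distal_length` | 20 | px | tip-path radius, desk-scale |
| `psf_sigma` | 1.5 | px | typical widefield PSF at this sampling |
| `photons_per_unit_length` | 120 | photons/px/frame | moderate-SNR intravital GFP; peak filament signal ≈ 3× background |
| `background` | 10 | photons/px | tissue autofluorescence floor |
| `phase_offsets`, `phase_jitter_sd` | −90, 0 | deg | drive starts wall-parallel; jitter off unless studied |
| `cilia_per_cell` | 1 | — | dilution divisor: per-cilium budget = per-cell budget / N |
| `bit_depth`, `seed` | 16, 1 | — | quantization; reproducibility |

These values are fixed once: they are the stated world every test and
acceptance run measures against, not tuning knobs.

Rendering: each filament polyline is sampled at ≤ 0.25 px steps; each
sample deposits an isotropic Gaussian (integral = per-cilium budget /
number of samples), so expected signal is independent of angle; mass
falling outside the frame is clipped silently. Poisson sampling is applied
per pixel per frame, then quantization; saturated counts are tallied and
reported, never wrapped.

## What the generator does not emulate

Two-dimensional projection only (no out-of-plane bending), a single rigid
segment (no curvature along the filament), structureless uniform
background (real lamina propria autofluorescence is textured), no motion
blur within a frame, no drift, no heart-rate variability in the drive, and
one cilium per region of interest (no crossing filaments). A green test
therefore establishes that the estimators recover the stated kinematics
under Poisson noise and PSF blur — not that they are robust to occlusion,
texture, or focal drift in real tissue.

## Numerical and algorithmic choices

**Frequency.** Mean-subtracted, Hann-windowed FFT; the peak is searched
above $\max(0.2\ \mathrm{Hz}, 2/T)$ and refined by parabolic interpolation
of log power, honestly beating the raw $1/T$ resolution (0.025 Hz at 40 s)
for off-grid tones. Validity requires: SNR ≥ 5 against the median non-DC
power (an invented but necessary guard against reporting noise peaks);
at least two cycles in the record; and a *sustained* peak — the four
quarters of the record must peak at the same frequency within their own
resolution. The sustainment check exists because a single posture reversal
is a boxcar whose spectrum is a high-SNR low-frequency lobe; no global SNR
threshold separates it from a genuine oscillation, but quarter-wise
consistency does. Peaks within two resolution steps of Nyquist set an
`aliasing_possible` flag. A reported "±0.2 Hz" spread can mean spectral
width, within-record variability, or across-movie spread; the package
reports resolution, SNR, and (in its tests) across-seed SD separately
rather than conflating them.

**Arc fitting.** The mask is the temporal-mean image above median + 5 MAD.
Motion is attested by pixels whose temporal variance exceeds twice the
Poisson expectation (`var > 2(mean + 1)`); a static filament — noiseless or
shot-noise-limited — has none and raises the insufficient-motion error, as
does an angular span below 5°. The hinge is initialized at the
low-variance mask pixel nearest the moving region's centroid (the base is
the only stationary filament point) and, when the movie is available,
refined to sub-pixel accuracy as the weighted least-squares intersection of
per-frame total-least-squares filament line fits: every frame's filament
line passes through the pivot. The refinement matters — a 1.5 px hinge
error alone produces ~4° tip-angle bias at this geometry. The scan radius
is 0.9 × the intensity-weighted 99.9th-percentile mask distance from the
hinge; a plain maximum would be dragged outward by the faint PSF halo
whenever noise is low enough to unmask it. The sector is the smallest
wrap-aware angular window holding 99% of annulus mask pixels, so arcs may
straddle the ±180° seam after rotation.

**Tip angle.** Per kymograph column: background = median, scale = MAD,
qualifying bins exceed background + 3 MAD, and the angle is the
background-subtracted intensity centroid of the *contiguous* qualifying run
containing the brightest bin — the tip crosses the scan circle once, so
isolated supra-threshold noise bins elsewhere must not pull the centroid.
The symmetric PSF makes the centroid unbiased, with sub-bin precision that
an argmax lacks. Frames with no qualifying bin are flagged `low_signal`,
linearly interpolated, and retained as flags; more than 50% of them aborts.

**Dwell.** The observed min–max span is cut into equal-angle bins (equal
angle = equal arc length on a circle, making "each tenth of the path"
well defined); fractions are computed over quality-ok frames on the whole
record. Occupancy per cycle was considered and rejected: at 26 fps a
4.6 Hz cycle holds ~5.7 frames, far too few for ten bins.

**Synchrony.** Each trace is band-passed around the field's consensus peak
and the instantaneous phase extracted by the analytic-signal method; pairs
are summarized by the phase-locking value and circular-mean phase
difference. The pass band is $\pm\max(2/T, 0.15 f_0)$: a band of only two
resolution steps leaves roughly $2BT \approx 8$ independent phase samples
in a 40 s record, inflating the null PLV of independent signals to ~0.4,
whereas the proportional band keeps the null near
$1/\sqrt{2BT} \lesssim 0.1$. The widened band is a deliberate deviation
from a fixed two-bin band, chosen on this small-sample argument.

**Classification.** `oscillating` requires a valid (SNR-, cycle-, and
sustainment-checked) frequency and ≥ 10° sweep; otherwise the circular-mean
angle decides `static_perpendicular` (70–110°) versus `static_bent`. The
70–110° window is generous on purpose: a dead field's cilia are *nearly*
perpendicular.

**Degenerate inputs.** Constant traces return an invalid estimate with
reason "no spectral peak" (never an error); zero angular span makes dwell
fractions undefined (error); single-frame movies are readable but flagged
unusable; RGB TIFFs, missing sidecar frame rates, and truncated files fail
with structured errors naming the offending frame or field.

## File-format choices

Movies are uncompressed little-endian grayscale multi-page TIFF written
and read by a minimal built-in codec (no TIFF package is available in the
supported dependency set); the frame rate travels in a JSON sidecar because
TIFF frame-interval tags are dialect-ridden — explicit beats inferred.
Configurations are JSON (the schema mirrors the scenario constructor;
unknown keys are rejected, defaults are recorded for provenance); traces
and kymographs are CSV; reports are versioned JSON.

## Known limitations

Multi-cilium fields require user-supplied regions of interest (no instance
segmentation); the path model is a circular arc about a fixed pivot, so a
translating or flexing filament will fit poorly; frequency validity is
tuned for records of tens of seconds (the quarter-wise sustainment check
loses power below ~2 s); and the phase-locking null depends on record
length — PLV values from records much shorter than 40 s at 26 fps should be
compared against a matched surrogate null rather than the ~0.2 rule of
thumb used in the tests.
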