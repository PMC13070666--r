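---
title: "Posture, mobility and pressure-time exposure from continuous pressure monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Posture, mobility and pressure-time exposure from continuous pressure monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(presmat)
library(dplyr)
```

`presmat` analyses continuous pressure-mat recordings — the interface
pressure between a lying body and its support surface, sampled on a sensel
grid — to quantify how often a patient changes posture and how much
pressure-time exposure their buttock region accumulates between changes.
This vignette is the package's account of the underlying methods: the
models, the parameters that matter, what the synthetic-data generator does
and does not emulate, and the numerical choices made where the design was
genuinely open.

## The recording model

A recording is a time-ordered stack of 2-D pressure frames on a fixed
`mat_geometry()`: `n_rows` sensels across the mat width, `n_cols` along the
long (head-to-foot) axis, an inter-sensel pitch in mm, and a sampling rate.
The default `geometry_profile("foresite_pt")` describes a full-body bed
sensing array: 15.9 mm pitch, 1 Hz, and a 48 × 118 grid covering
762 × 1880 mm. (The vendor quotes 5556 cells, which no integer grid at that
pitch yields; 48 × 118 = 5664 is what the stated dimensions imply. Grid
dimensions are therefore always explicit configuration, never a hard-coded
count.) Conventions, declared once and used everywhere: sensel indices are
0-based, rows across the width; the physical centre of sensel $(r, c)$ is
$((r + 0.5)\,p, (c + 0.5)\,p)$ for pitch $p$; timestamps are seconds from
the first frame; all intervals are half-open $[start, end)$.

Sequences round-trip exactly through a plain-text long-format CSV
(`t_s,row,col,pressure_mmHg`) with a JSON sidecar carrying geometry and
session metadata. `validate_sequence()` reports — rather than silently
repairs — negative or non-finite pressures and sampling jitter beyond ±10 %
of the nominal interval.

## Posture-change detection

Three per-frame channels summarise the load distribution: the COP in each
planar axis (pressure-weighted centroid of cells above a 5 mmHg floor) and
the contact area (cells above 20 mmHg × cell area). The floor keeps noise
on unloaded sensels from dragging the centroid and is deliberately distinct
from the 20 mmHg contact threshold, which defines meaningful tissue
contact.

Each channel is smoothed (centred moving average, default 11 s),
differentiated by central differences, and robust z-scored using the
median and MAD over the whole recording. The channels have incommensurable
units (sensels vs cm²), so scale-free standardisation is what makes them
combinable; the per-frame movement signal is the Euclidean norm of the
three z-scored derivatives. Postural changes are contiguous
supra-threshold runs of this signal above `median + 6·MAD`, each reduced to
its peak frame, accepted greedily by amplitude (ties to the earlier time)
under a 60 s minimum separation.

Numerical choices worth stating:

- *Zero-MAD channels.* An idle channel's derivative is zero almost
  everywhere, so its MAD is 0 even when real events are present. Such
  channels fall back to SD scaling; only a channel whose variation sits at
  or below a numerical floor (10⁻⁹ of the channel magnitude — orders above
  double-rounding dust, orders below any real movement) is treated as
  constant and contributes nothing.
- *Smoothing by direct convolution.* A cumsum-difference moving average
  leaves ~10⁻¹³ rounding residue on constant channels, which scale-free
  z-scoring happily amplifies into phantom events; `stats::filter`
  convolution makes constant stretches exactly constant.
- *Debouncing.* A genuine change, smeared by the 11 s window plus the turn
  itself, stays above threshold for ~10–20 s; supra-threshold runs shorter
  than `min_event_width_s` (default 3 s) are rejected as spikes.
- *Degenerate inputs.* Recordings shorter than twice the smoothing window
  are rejected with an error rather than segmented.

The change times partition $[0, T)$ into static postures; segment durations
sum to $T$ by construction. Movement features follow: posture count,
`frequency_per_hour`, intervals between changes, and the fraction of time
in postures longer than 2 h. The published per-patient frequency extremes
are reproduced by dividing the *posture count* (not the change count) by
monitoring hours, although the accompanying text describes the latter; both
definitions are available via `frequency_basis`, with "postures" the
default because it matches the printed values. Quartiles throughout use
linear interpolation at positions $1 + (n-1)q$ (R type 7) — the one
convention that reproduces all three internally consistent IQRs in the
packaged movement table; one printed IQR (13 for the pre-intervention
lengths, where the table gives 20) is irreproducible under any standard
convention and is treated as an erratum, not a target.

## Buttock ROI and pressure signatures

For each posture, a 30 × 20-sensel window (47.7 × 31.8 cm at 15.9 mm
pitch; 30 along the body axis) is centred on the segment's median COP —
median, not mean, so brief transition frames cannot displace it — rounded
to the nearest sensel, with even extents spanning
$c - \lfloor e/2\rfloor \dots c + \lceil e/2\rceil - 1$, and shifted
minimally (flagged `clipped`) when the window would leave the grid. The ROI
is fixed per posture: a stable patch avoids gradient artefacts from a
window that tracks every micro-movement.

Within the window, per frame:

- **peak** — maximum pressure (mmHg);
- **PPI** — mean of the 10 highest pressures (mmHg), a peak estimate
  robust to single-sensel spikes;
- **PPG** — maximum $|p_a - p_b|$ over diagonally adjacent sensel pairs,
  divided by the diagonal spacing $\sqrt{2}\,p$ (2.2486 cm at default
  pitch), in mmHg/cm. Both diagonal orientations enter the maximum: the
  field definition speaks of "a diagonal direction", but the symmetric
  maximum is never smaller and does not depend on which diagonal a body
  happens to align with. (A checkerboard pattern has PPG 0 — diagonal
  neighbours share parity — which documents the direction sensitivity of
  any diagonal definition.)

Per posture, each series reduces to mean ± sample SD (n−1), with at least
2 frames required. All three signatures are homogeneous of degree 1 in
pressure and satisfy peak ≥ PPI ≥ ROI mean on every frame; the test suite
checks them against brute-force oracles on a thousand random windows.

## Sigmoid pressure-time exposure

Tissue tolerates high pressure briefly and only lower pressure for long;
injury-threshold experiments motivate a sigmoid boundary in the
(duration, pressure) plane. Three curves with shared shape,

$$B_k(t) = F_k + \frac{S_k - F_k}{1 + e^{\alpha (t - t_0)}},$$

separate four ordered exposure categories (low, moderate, high, very
high). The starting pressures $S_k$ are 25/35/45 mmHg/cm for PPG and
70/90/110 mmHg for PPI — interpreted as the short-exposure boundary values.
The PPG triple is printed in mmHg in some sources, but the quantity's unit
is mmHg/cm and that is how it is treated here. The decay shape is not
published anywhere: floor fraction $F_k/S_k = 0.4$, steepness
$\alpha = 2\,\mathrm{h^{-1}}$ and inflection $t_0 = 2$ h are package
defaults chosen so tolerable pressure roughly halves between brief and
several-hour loading, and every parameter is exposed in
`sigmoid_thresholds()`. No physiological validity is claimed for the
defaults; all downstream checks of this module are property-based
(ordering, monotonicity, conservation, inverse-function identities), not
value-matching.

A posture is categorised at its (duration, mean magnitude) point by
counting the curves it exceeds — mirroring one marker per posture on an
exposure chart. That is the default attribution (`mode = "posture"`). The
alternative reading — that exposure accrues over a posture's own timeline,
crossing into higher categories as the boundaries decay — is
`mode = "resolved"`: the timeline is split analytically at
`crossing_time()` (the closed-form inverse of $B_k$), and the tests verify
the split against a 1-second brute-force scan. Both modes conserve time:
category fractions sum to 1.

## The synthetic generator

No raw recordings of this kind are publicly available, so validation rests
on a generator whose ground truth is known by construction. A posture is a
set of Gaussian loading sites (head, scapulae, sacrum/buttocks, heels)
with documented fixed amplitudes — pelvic load dominant at 80–100 mmHg,
heels 45, scapulae ≤ 40, head 35 — not fitted to any subject. A session is
a schedule of postures with per-posture whole-body offsets, plus:

- *micro-movement*: a mean-reverting AR(1) wander of all site centres with
  stationary SD `jitter_sd_sensels` (default 0.2) and a 60 s relaxation
  time. A pure random walk was rejected: at 0.2 sensels/frame it drifts
  ~19 sensels over a 2.5 h posture, which no lying body does, and it
  floods the detector with spurious events precisely in the long-posture
  regime the analysis targets;
- *sensor noise*: i.i.d. Gaussian, SD 2 mmHg by default, truncated at 0
  because pressures are non-negative (the truncation biases near-zero
  cells slightly upward — at SD 2 the bias on an unloaded cell is
  ~0.8 mmHg, well under the 5 mmHg COP floor);
- *transitions*: 10 s linear cross-fades between postures, so the detector
  sees a finite-width pulse as in real turning; transition samples belong
  to the following posture (half-open convention), and the ground-truth
  change time is the fade's first sample;
- *optional alternating-mattress modulation*: columns of opposite parity
  multiplied by $1 \pm d\sin(2\pi t/\mathrm{period})$ (defaults 600 s,
  depth 0.15) — stripes chosen to stress the detector the way an active
  air surface can, not to model any product.

Noise and movement statistics of real devices are unpublished; the
defaults are stress-test choices. The generator does **not** emulate shear
forces, tissue mechanics, sensor drift/hysteresis, or real anatomical
pressure distributions — so passing recovery tests demonstrates that the
algorithm recovers the structure this model shares with real data (abrupt
redistribution events between quasi-stationary loading patterns), not
clinical performance.

Determinism: one integer seed drives all randomness; identical configs and
seeds give bit-identical sessions (the RNG state is restored afterwards).

## Problem sizes and validation scope

The packaged validation uses: 5-posture sessions of 300–600 s per posture
on the full 48 × 118 grid at 1 Hz for detector recovery (20 seeds; the
recovered change count must match truth in ≥ 95 % of runs, every matched
event within half a smoothing window plus one transition of its true
time — measured max error 5 s); an 8-h 4-posture session for the
end-to-end smoke run; and a thousand random windows for the
signature-oracle comparisons. Five-to-ten-minute dwells were chosen as
short enough to keep many events per session while staying well clear of
the 60 s separation floor; they are generator conditions, fixed once.

The cohort module ships transcriptions of the published 17-patient
pre/post tables as checksummed plain-text fixtures. Its summaries
reproduce the printed medians, IQRs, frequency extremes, category counts
and the BMI mean exactly; the handful of printed values that contradict
the tables themselves (a pre-length IQR and maximum, a BMI range endpoint,
one post-phase frequency minimum, one post-phase category count) are
documented errata and deliberately not reproduced. Cohort-level exposure
percentages reported for the original study require its raw recordings,
which are not public; they are out of scope, and nothing in this package
estimates them.

## Known limitations

- Posture *identity* (supine vs lateral) is not classified; the detector
  finds changes, not labels. Seated/wheelchair data are out of scope.
- The ROI is a fixed rectangle anchored at the COP; no anatomical
  recognition is attempted, and for unusual body positions the window may
  cover more than the buttock region (the `clipped` flag marks edge
  cases).
- The sigmoid parameters beyond the starting pressures are package
  defaults, not estimates; conclusions about absolute exposure categories
  inherit that arbitrariness, though orderings and time-in-category
  comparisons across phases do not.
- Active-surface cycling can masquerade as movement; the generator can
  produce it for stress testing. Because the detection threshold is
  relative (`median + 6·MAD` of the combined signal), steady cycling
  inflates the MAD and is largely self-normalising: in the packaged
  simulations a genuine turn is still recovered on a cycling surface with
  no false events. An optional low-pass (`prefilter_window_s`, set to the
  cycling period) is exposed for stronger interference, but it deflates
  the MAD and lets residual contact-area steps through, which can cost
  timing accuracy — it therefore stays off by default.
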