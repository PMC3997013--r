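---
title: "Mapping neurally driven contraction and relaxation in tubular gut preparations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping neurally driven contraction and relaxation in tubular gut preparations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peristalmap)
```

## The problem

Peristaltic propulsion in the colon is driven by polarised enteric reflex
pathways: distension excites the circular muscle orally and inhibits it
anally, so a fluid bolus is squeezed from behind and accommodated in front,
re-creating its own stimulus further along the gut. Testing this
neuromechanical picture requires knowing, at every point of a preparation
and every moment, whether the muscle is *actively* contracting or relaxing
(neural drive) or merely responding passively to fluid displaced from
elsewhere — which neither a diameter map nor a pressure map can tell on its
own. A narrowing with rising local pressure is a contraction; the same
narrowing with falling pressure is elastic recoil. This package implements
the analysis pipeline that makes that distinction, end to end.

## From recordings to maps

Silhouette video is thresholded (a global threshold at a fraction of each
frame's intensity range; the field's silhouettes are back-lit and
high-contrast, so a per-frame adaptive threshold adds little), per-column
widths are converted to millimetres, frames are decimated to 4 Hz by block
averaging (so constant input is a fixed point and temporal aliasing is
suppressed), and pixel columns are averaged into 1 mm axial bins — finer
than the 10 mm manometry pitch, so that the 20 mm propagation rule and the
30 mm flank analyses are well resolved. Pressure records are shifted onto
the video clock by a single constant offset, block-averaged to the same
4 Hz grid, and linearly interpolated along position between sensors;
outside the sensor span the nearest sensor's value is held rather than
extrapolated. The diameter of a column with no silhouette is 0 and flagged,
never interpolated. Positions are measured from the oral end, so anal
(propulsive) propagation has positive speed.

## The quiescence model and trend decoding

Whether a change is "real" is decided in normalised derivative units:
`z_D = (dD/dt)/c_D` and `z_P = (dP/dt)/c_P` with `c_D = 0.4` mm/s and
`c_P = 3` mmHg/s. The conditional probability that the muscle is quiescent
at normalised derivative `z` is the unit-width Gaussian `exp(-z^2/2)` —
equal to 1 at `z = 0`, symmetric, and monotone decreasing in `|z|`.
Derivatives are taken by central differences after a 5-frame (1.25 s)
centred moving average: long enough to suppress frame noise, comfortably
shorter than a typical ~4 s contraction.

Each channel at each position is decoded independently over time by a
three-state hidden Markov chain over {falling, quiescent, rising}. The
quiescent state emits with the quiescence Gaussian; the moving states emit
with the same-width Gaussian shifted to mu = -2 and +2, so the pointwise
decision boundary sits at `|z| = 1` and the Viterbi path upgrades it with
temporal persistence: the self-transition probability (default 0.95 per
0.25 s frame) makes isolated one-frame spikes stay quiescent while
sustained ramps switch cleanly. This is the smallest model that yields
"quiescence to activity" transitions, and small enough that the decoder is
verified exactly against brute-force enumeration of all `3^n` paths. Ties
are broken toward quiescent, then falling, for determinism. No spatial
coupling is imposed — spatial coherence of the decoded maps emerges from
the data, matching the fact that orbit plots are taken at one site.

## Twelve mechanical states

The two decoded trends and an occluded/distended level yield a total
decision table: diameter falling with pressure rising is an auxotonic
contraction, with pressure quiescent an isotonic contraction, with pressure
falling passive shortening; the mirror cases give the relaxations and
passive dilation; and the doubly-diameter-quiescent cases split by level
into the occluded-isometric and distended-isometric states plus the two
quiescences — twelve states exactly, of which three are grouped as active
contraction and two as active relaxation. The level split uses the
per-position 5th/95th percentile diameter range over time with the cut at
its midpoint; robust percentiles resist outliers where the field's
vocabulary only says "near its minimum/maximal diameter". Only the
diameter-quiescent states are level-split; splitting the moving states as
well would yield more than twelve states.

## Separating myogenic from neurogenic activity

Nerve blockade (TTX) leaves only pacemaker-driven (myogenic) activity:
low-amplitude rhythmic diameter ripple with minimal pressure effect. In
orbit coordinates normalised by the quiescence constants (diameter by
`c_D`, pressure by `c_P`), each maximal non-quiescent run at a position
traces an orbit whose polygonal path length measures its excursion.
Myogenic orbits are short and flat; neurogenic contractions trace long
loops. The threshold is the 95% quantile (linear-interpolation convention)
of the nerve-blocked recording's path-length distribution; active cells in
segments at or below it are reassigned to "other", and what remains is
attributed to neurogenic input. The threshold is always recalibrated per
dataset — published values are preparation-specific — and masking changes
only group assignments, never the underlying twelve-state labels, so the
decision is auditable. Segments (not sliding windows) delimit orbits: they
make the quantity well defined without an arbitrary window length, at the
cost that a segment overlapping an event keeps its full path length.

## Events, initiation, boluses

Active-contraction events are 8-connected components of the masked map
(4-connectivity would fragment oblique streaks). An event is propagating
iff its spatial extent is at least 20 mm. Its speed is the least-squares
slope of its per-frame spatial midline, with 10% of frames trimmed at each
end: the leading edge alone overshoots while the active region grows at
onset and freezes while it fades at termination, biasing edge-based fits
low by 10–20% on bands of known speed, whereas the midline is insensitive
to symmetric growth and decay and equals the edge slope on steadily
translating bands. Initiation is the most oral cell of the earliest frame.

The initiation analysis excludes events whose 40 mm oral / 80 mm anal
window would be truncated by the preparation ends. The compared dilation is
the mean increase over the per-position baseline (5th percentile diameter)
within 5 mm of the initiation site over the 2 s before initiation — the
distension *at the site* of initiation, on the scale of the physical bump
that triggered the event; the average over the full 120 mm window is also
reported but dilutes a focal bump roughly threefold. Group comparison uses
the in-package Mann–Whitney U (exact by enumeration up to pooled n = 20,
tie- and continuity-corrected normal approximation above) and Fisher's
exact test on presence of anal inhibition.

Boluses are dilations exceeding 2 mm above the per-position baseline for at
least 0.5 s, with sub-resolution gaps (<= 3 mm) closed before linking,
frame-to-frame linking by largest spatial overlap, and tracks allowed to
coast through two-frame detection dropouts. Speed is the mean of robust
(Theil–Sen) slopes of the smoothed oral and anal edge trajectories,
restricted to the longest run of frames whose centre moves faster than the
0.5 mm/s stationary threshold — a track outlives its propulsion by a few
seconds while the remnant dilation decays through the detection threshold,
and those parked frames otherwise drag the fitted speed down. For tracks
under 10 frames the net centre displacement over the track duration is used
instead, since pairwise slopes on a briefly appearing blob measure its
growth and decay, not translation. Bins are > 7 (fast), 3–7, 0–3 mm/s and
stationary (< 0.5 mm/s in magnitude). State profiles sample the masked map
over a 30 mm oral flank, 21 normalised interior coordinates and a 30 mm
anal flank, per moving frame of each bolus in a speed bin; a random-anchor
control with a fixed 20 mm pseudo-bolus checks that the polarised pattern
is not a sampling artefact. Anal relaxation for the dilation- and
length-relation analyses means any active-relaxation cell in the 30 mm anal
flank at any tracked frame; the length relation is tested with an
uncorrected Pearson chi-squared on the 2x2 table.

## The synthetic preparation generator

The generator emulates the study conditions this pipeline is built for: a
25 cm fluid-filled preparation mapped for 10 min at 4 Hz and 1 mm, resting
just above a 3 mm indwelling catheter, with 60-sensor-style pressure records
at 10 mm pitch. Its components:

* **Catheter floor and resting tone.** The silhouette cannot be narrower
  than the catheter, so the diameter field is clamped at 3 mm; the resting
  gut sits 0.8 mm above it. A consequence the pipeline must (and does)
  handle: squeezing an occluded segment produces *no* diameter signal, only
  a pressure wave — the occluded isometric regime.
* **Propelled boluses** are Gaussian dilation bumps (amplitudes 3–6 mm,
  sigma 10 mm) translating at 6.4 mm/s — the typical propagation speed in
  this field — over 70 mm, with pressure coupled to dilation (2 mmHg/mm).
  They dissipate gradually en route so the tracked dilation ends while
  still moving, without a terminal collapse transient that would masquerade
  as a contraction.
* **Oral contraction bands** ride 40 mm oral of the bolus edge as linear
  squeeze ramps (constant squeeze rate above the quiescence scale across
  the whole flank) with a synchronous pressure wave; **anal relaxation
  bands** are a dilation ramp ahead of the bolus with a small pressure dip,
  attached to the larger boluses (>= 4 mm) to mirror the diameter
  dependence of descending inhibition, fading as the propulsion wanes.
* **Standalone contractions** (stationary Gaussian squeezes with pressure
  pulses, ~4 s per point) provide non-propagating events, optionally
  preceded by a slow pre-dilation bump whose ramps stay below the
  quiescence scale, so it offsets diameter without itself registering as
  activity.
* **Myogenic ripple**: 0.3 mm, 0.25 Hz, 60 mm wavelength, travelling at the
  ripple phase speed, with a second harmonic (pacemaker-driven contractions
  have a sharper contracting phase than a sine) and slow amplitude
  modulation so orbit lengths form a spread distribution rather than a
  single atom. Under TTX the ripple is 4/3 as large — removal of tonic
  neural inhibition modestly disinhibits pacemaker-driven activity — which
  makes the calibrated threshold dominate control myogenic orbits with
  margin instead of sitting exactly at the 95th percentile.
* **Noise** is independent Gaussian per cell (0.05 mm, 0.2 mmHg).

Ground truth is derived from the noiseless field: trends from analytic
derivatives with the same `|z| = 1` boundaries, labels from the same
decision table, per-frame bolus edges from the noiseless 2 mm contour using
the same baseline rule as the detector, and an event-support mask (where
the event components move the field, dilated by the smoothing window and
decoder hysteresis margin) that splits truth-active cells into neurogenic
and pure-myogenic classes.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: spatially correlated noise, gut curvature and
axis misalignment in video, pressure-volume mechanics coupling `D` and `P`
beyond the stated local rules, solid (pellet) boluses, and pre-initiation
accommodation before propelled boluses (the dedicated initiation scenario
seeds pre-dilations explicitly; in the default event set the propagating
events arise with their oral band at depth, so their measured pre-initiation
dilation is small).

## Numerical choices and degenerate inputs

Decimation requires the source rate to be an integer multiple of 4 Hz.
Frames with no contrast, or masks that are all foreground/background, are
flagged rather than fatal; empty axial columns yield diameter 0 with a
flag. A position whose diameter never varies is treated as occluded. The
Viterbi tie-break and the quantile convention (R type 7) are fixed for
reproducibility; the empirical-quantile threshold is inclusive (`<=`) on
the masking side. The container is a single RDS file with a schema-version
tag, so stale files fail cleanly; event and bolus tables export to CSV.

## Problem sizes

The test suite validates the pipeline on preparations of 150–250 mm and
2–12.5 min at the native 4 Hz / 1 mm grid (the decoder is exact-checked on
series up to length 8 against full enumeration, and the small-sample tests
against complete enumeration up to pooled n = 12); the acceptance script
analyses the full default 250 mm x 10 min pair. These sizes exercise every
rule at the same grid resolution as full recordings.

## Known limitations

Per-channel decoding ignores cross-channel evidence (a strong pressure wave
does not make a marginal diameter fall more credible). The 5th-percentile
baseline sits at the ripple trough, so "dilation above baseline" carries a
small positive offset relative to resting tone, and under very dense event
trains it can dip further; the initiation comparison is unaffected (both
groups share the offset) but absolute dilations inherit it. Orbit segments
that span both an event and adjacent ripple keep their full path length, so
a small fraction of ripple cells adjacent to events survives masking.
Stationary-bolus speed is defined only up to the 0.5 mm/s threshold.
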