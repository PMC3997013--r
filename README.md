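# peristalmap

Tools for studying **neural peristalsis** in isolated tubular gut
preparations (e.g. rabbit distal colon) from combined video and
multichannel intraluminal manometry. The package converts silhouette video
and sparse pressure records into aligned spatiotemporal maps of diameter
`D(x,t)` and pressure `P(x,t)`, decodes the *mechanical state* of the
circular muscle at every point in space and time, separates neurogenic from
myogenic activity, and quantifies how peristaltic contractions initiate,
propagate, and couple to the fluid boluses they propel.

It is aimed at motility physiologists who record ex vivo preparations and
want a reproducible, testable pipeline for active-state mapping — and it
ships a fully ground-truthed synthetic preparation generator, so every
stage can be validated without any recordings.

## The method in brief

1. **Maps.** Video frames are thresholded into silhouettes; per-column
   widths give `D(x,t)` on a 1 mm x 0.25 s grid (4 Hz). Pressure sensors at
   10 mm pitch are anti-alias averaged to 4 Hz and linearly interpolated
   between sensors to give `P(x,t)` on the same grid.
2. **Quiescence model and trends.** Time derivatives are normalised by the
   quiescence scale constants `c_P = 3 mmHg/s` and `c_D = 0.4 mm/s`; the
   conditional probability of quiescence at normalised derivative `z` is
   `g(z) = exp(-z²/2)`. A three-state hidden Markov chain
   (falling / quiescent / rising) per channel and position, with `g` as the
   quiescent emission and shifted Gaussians (mu = +-2) for the moving
   states, is decoded by Viterbi.
3. **Twelve mechanical states.** The pair of decoded trends plus an
   occluded/distended split of the diameter yields one of twelve states per
   cell (auxotonic/isotonic/occluded-isometric contraction, the two active
   relaxations, and seven passive states), grouped into *active
   contraction*, *active relaxation* and *other*.
4. **Myogenic threshold.** On a nerve-blocked (TTX) recording, orbit
   path lengths — the cumulative excursion of the normalised
   pressure-diameter trajectory over each activity burst — are collected;
   their 95% quantile is the myogenic threshold. Active states in segments
   below it are reassigned to *other*, leaving neurogenic activity.
5. **Events and boluses.** Active-contraction events are 8-connected
   components (propagating when extending >= 20 mm); initiation windows
   (40 mm oral / 80 mm anal / +-2 s) compare the pre-initiation distension
   of propagating vs non-propagating events (Mann-Whitney, Fisher's exact).
   Boluses are dilations > 2 mm above the minimum occluded diameter lasting
   >= 0.5 s, tracked by overlap, binned by speed (> 7, 3-7, 0-3 mm/s,
   stationary), and profiled for active states over a 30 mm oral flank, the
   normalised interior, and a 30 mm anal flank.

## Worked example

```r
library(peristalmap)

cfg     <- synth_config(seed = 1)          # default study conditions
control <- generate_preparation(cfg)       # 25 cm, 10 min, 12 boluses
ttx     <- generate_ttx(cfg)               # nerve-blocked calibration run

report <- run_full_analysis(control, ttx)
report
```

which prints (numbers from this exact run):

```
Peristalsis analysis report
  myogenic threshold: 3.880 (q = 0.95, 12028 segments)
  events: 44 (12 propagating, 12.0 per 10 min)
  pre-dilation: 1.00 mm (propagating) vs 1.44 mm, Mann-Whitney P = 0.142
  boluses tracked: 55
```

The myogenic threshold is the 95% quantile of the nerve-blocked orbit-length
distribution, in normalised (dimensionless) orbit units; all twelve seeded
propelled boluses are recovered as propagating contraction events (12 per
10 min); and 55 bolus tracks are found (the twelve propelled boluses plus
smaller transient dilations). Individual pieces are available too:

```r
smap  <- classify_dpmap(control$dpmap)        # 12-state map
occ   <- state_occupancy(smap)                # fraction of (x,t) per state
bol   <- lapply(detect_boluses(control$dpmap$diameter), estimate_speed)
prof  <- state_profile(bol, report$states, bin = "mid")
```

A command-line wrapper for the two common operations lives at
`inst/scripts/peristalmap.R` (`simulate` and `run` subcommands).

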