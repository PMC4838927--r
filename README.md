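# microlink

Agent-based simulation of **optical interlink feedback** between two
isolated microalgal populations. Two 25-square micro-aquaria (480 um
squares joined by 90 um passages) are simulated side by side: dish A holds
~400 *Euglena gracilis*-like cells, whose photophobic response to blue
light is to switch from straight swimming to on-site tumbling, and dish B
holds ~1300 *Chlamydomonas reinhardtii*-like cells, which are awakened
from rest by blue light. The dishes exchange no cells - only data. Every
1.47 s feedback cycle, each dish's swimming traces are rasterized into a
binary image and condensed into 25 **trace momentum** (TM) values (trace
pixels per square), and each dish's TM dataset sets the *other* dish's
next illumination pattern.

Two interlink algorithms are implemented:

* **Two-state flipping** - with group-I/II sums TM_I and TM_II, when a
  dish's signed ratio (TM_I − TM_II)/(TM_I + TM_II) crosses a prefixed
  threshold T, the dominant group is illuminated in the counter-dish.
  This closed loop generates an **autonomous cell-density oscillation**
  whose period grows with T (minutes scale), with dish A trailing dish B
  by a fraction of a minute.
* **Ranking** - illuminate in dish B the squares of the 12 lowest TMs of
  dish A, and in dish A the 12 highest TMs of dish B. This **separates
  and clusters** the high cell-density areas: the two dishes settle into
  mirrored illumination patterns agreeing on ~23 of 25 squares.

The package is intended for anyone studying closed-loop optogenetic-style
population control, emergent oscillations in coupled micro-ecologies, or
cell-based soft computing, and provides the chamber geometry, stochastic
run-and-tumble cell models, trace imaging, both feedback algorithms, the
analysis metrics (oscillation period, phase delay, illumination
coincidence, duty ratios, grid clustering, pattern histograms), and
calibration utilities. The per-cycle stepping and rasterization are
implemented in C++ (Rcpp); a full 98-minute experiment (4000 cycles,
1700 cells) simulates in ~20-25 s on one core.

## Worked example

```r
library(microlink)

cfg <- experiment_config(algorithm = "oscillation", threshold = 0.40,
                         seed = 11)
log <- run_experiment(cfg)
log
#> <aq_log> 4000 steps (oscillation mode), 44 flip events, duration 98.0 min

oscillation_period(log)
#> period 6.67 +/- 0.56 min over 10 cycles
phase_delay(log)
#> phase delay 0.38 +/- 0.05 min over 22 flips
```

The period is the mean time between consecutive flips of dish B's
illumination back to group I (each full cycle contains two alternating
flips); the phase delay is the lag from each dish-B flip to the next
dish-A flip, set by how fast the Chlamydomonas population activates. With
the shipped defaults the same run at threshold 0.05 gives a period of
about 1.5-1.8 min. The ranking algorithm:

```r
rlog <- run_experiment(experiment_config("ranking", seed = 11))
co <- coincidence_series(rlog)
mean(co$coincidence[701:3500])      # plateau after the initial transient
#> [1] 23.92286
cluster_count(rlog$patternA[3000, ], "unlit")
#> [1] 4
duty_ratio(rlog, "A")               # per-square lit fraction over feedback
```

The coincidence plateau near 23 means the two dishes' illumination
patterns are almost exact mirrors of the two species' activity
distributions: squares rich in active Chlamydomonas are lit in dish A,
squares poor in Euglena traces are lit in dish B.

A thin command-line front end is installed with the package
(`inst/scripts/microlink`) with `run`, `analyze`, `calibrate` and
`fixtures` subcommands over key-value config files and CSV logs.

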