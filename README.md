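# usv44

Analysis of rat ultrasonic vocalization (USV) repertoires from aversive
conditioning sessions, built around the recently described long,
high-pitched "44-kHz" call type.

## The scientific problem

Rats communicate affective state through two classically recognized USV
families: long (>300 ms), constant-frequency **22-kHz calls** (aversive) and
short (10–150 ms), often frequency-modulated **50-kHz calls** (appetitive),
split at a 32 kHz boundary. Under prolonged fear conditioning a third kind
appears: calls that are *high* like 50-kHz calls but *long* and monotonous
like 22-kHz alarm calls. This package implements, as a tested and reusable
pipeline, the analyses by which such calls are isolated and characterized:

- **Rule-based typing.** A call with peak frequency f (Hz) and duration
  d (s) is classified by a total partition of the (f, d) plane:
  `fortyfour` iff f > 32 000 and d > 0.150; `fifty` iff f > 32 000 and
  d ≤ 0.150; `long22` iff f ≤ 32 000 and d > 0.300; `short22` otherwise.
  Peak frequency is the frequency of the highest power peak in the
  time-averaged spectrum of the entire call.
- **Subtypes.** 44-kHz call contours are segmented into constant-frequency
  *elements* at instantaneous frequency jumps (|Δf| > 4 kHz within ≤ 10 ms);
  a leading/trailing fragment shorter than 1/5 of its neighbor is discounted
  (the affix rule); the element count and order give five subtypes: flat,
  step up, step down, insert, complex. Two-element calls carry a frequency
  ratio near 3:2 (a "perfect fifth") relative to 22-kHz elements.
- **Sequences.** Calls separated by silent gaps < 320 ms form *bouts*;
  first-order transition probabilities P(type_j | type_i) are conditional
  pair frequencies, overall and within bouts.
- **Repertoire clustering.** DBSCAN over standardized (peak frequency,
  duration) with min_pts = 150 and ε from the k-distance-knee heuristic
  (with an ε-maximizing range scan), silhouette-checked; and k-means over
  32-point resampled contours + duration + peak frequency with elbow-chosen
  k ≤ 4.
- **Freezing linkage.** Freezing = runs of ≥ 30 video frames (1 s at
  30 fps) with motion index < 18; sessions are tiled into 10-s bins
  categorized by their call content (exclusively long-22, exclusively
  44-kHz, mixed, call-free) and freezing percentages are compared across
  categories; a call-nested variant scores freezing inside matched call
  windows with reduced minimum runs (3/5/10/15 frames).
- **Synthetic sessions.** A seeded generator emulates the full data
  structure (ITI-dependent emission, Markovian type sequences in bouts,
  frequency drift, 3:2 step ratios, call-locked freezing) with hidden
  ground truth, so every stage is testable without recordings.

## Worked example

```r
library(usv44)
cfg <- pipeline_config(seed = 7,
                       synthetic = synthetic_config(n_rats = 4, seed = 7),
                       min_pts = 40, kmeans_sample = 200)
res <- run_pipeline(cfg)
res$summary$counts
#>    long22   short22     fifty fortyfour   unknown
#>       652        79        43       132         0
round(res$summary$transition_all, 3)
#>            to
#> from        long22 short22 fifty fortyfour
#>   long22     0.949   0.029 0.002     0.020
#>   short22    0.241   0.468 0.215     0.076
#>   fifty      0.093   0.372 0.488     0.047
#>   fortyfour  0.092   0.046 0.008     0.854
res$summary$dbscan$cluster_stats
#>   cluster size mean_peak_frequency mean_duration
#> 1       1   79            25351.50     0.1492566
#> 2       2  652            25950.86     0.8955978
#> 3       3  131            38981.71     0.6890247
res$summary$freezing
#>         category n_bins mean_freezing
#> 1       baseline    120      5.666667
#> 2       no_calls    862     30.835267
#> 3    only_long22     89     43.033708
#> 4 only_fortyfour     13     66.923077
#> 5          mixed     44     57.500000
```

Reading the output: the 4-rat synthetic cohort emits mostly long 22-kHz
calls with a 14.6% share of 44-kHz calls; the estimated self-transition
probabilities (long22 → long22 0.949, fortyfour → fortyfour 0.854) recover
the planted chain (0.95 / 0.85); DBSCAN isolates a high-frequency
(≈39 kHz), long-duration (≈0.69 s) cluster of 131 calls — the 44-kHz group —
from the low-frequency mass; and 10-s bins containing exclusively 44-kHz
calls carry the highest freezing (66.9%), above call-free bins (30.8%), the
planted call–freezing linkage. `write_summary(res, "summary.json")` exports
all of it.

A command-line front end with `simulate`, `classify` and `run` subcommands
is installed at `inst/cli/usv44.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/usv44.R", package="usv44"))')" run --seed 7 --n-rats 4
```

## Layout

- `R/` — typed containers and IO (`calltable.R`, `io.R`), spectral
  measurements (`acoustics.R`), the classifier (`classify.R`), element
  segmentation and subtypes (`subtypes.R`), bouts and transitions
  (`sequences.R`), DBSCAN/k-means clustering (`clustering.R`), freezing
  (`behavior.R`), the generator (`simulate.R`), orchestration
  (`pipeline.R`).
- `vignettes/methods.Rmd` — the model, parameter choices, and what the
  synthetic world does and does not establish.
- `tests/testthat/` — unit and property tests per module plus
  `test-acceptance.R` (one block per acceptance criterion).
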