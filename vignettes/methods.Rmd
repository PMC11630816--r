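---
title: "Methods: models, parameters, and what the synthetic world establishes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and what the synthetic world establishes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usv44)
```

This vignette is the package's own account of its science: the models and
rules it implements, the tunable parameters and why their defaults are what
they are, the design choices made where the procedure was genuinely open,
and the limits of what a green test establishes.

## The call-type partition

Rat ultrasonic vocalizations are typed from two measurements per call: peak
frequency (Hz) — the frequency of the highest power peak in the
time-averaged spectrum of the entire call — and duration (s). The
classifier is a total partition of the positive quadrant:

| region | label |
|---|---|
| f > 32 kHz, d > 150 ms | `fortyfour` |
| f > 32 kHz, d ≤ 150 ms | `fifty` |
| f ≤ 32 kHz, d > 300 ms | `long22` |
| f ≤ 32 kHz, d ≤ 300 ms | `short22` |

Boundary semantics are strict on the high/long side, so a call at exactly
32 kHz or exactly 150/300 ms falls to the low/short class. This is the
literal reading of the defining inequalities; it matters only on a
measure-zero set and is configurable through `class_rules()`. No upper
frequency bound is imposed on `fortyfour`: published 95% ranges are
descriptive, not definitional. The manual spectrogram verification step
that corrected a ~0.2% residue of misassigned calls in the original corpus
is deliberately not automated; an optional contour-flatness veto
(`flatness_veto_khz`) can demote wide-band high calls to `unknown`, but it
is off by default because the published criteria do not formalize
modulation.

Peak frequency itself (`peak_frequency()`) averages *linear* power across
the call's spectrogram frames before locating the maximum. Averaging in dB
would over-weight the noise floor of quiet frames and can move the peak to
the wrong element of a two-element call; averaging linear power is the
physically meaningful "averaged spectrum". Ties break toward the lower
frequency bin — deterministic, and conservative toward the 22-kHz class.
Absolute dB levels are implementation-relative (the acquisition software's
FFT settings are unknown), so only comparisons and the attenuation
correction are meaningful; the default STFT (512-sample Hann window, 75%
overlap at 250 kHz) gives ≈2 ms frames and ≈488 Hz bins, resolving ≥4 kHz
element jumps while keeping a 150 ms call ≈70 frames long.

The attenuation correction reflects directional-microphone physics: at the
≈45° emitter–microphone angle of the reference recording setup,
≈40 kHz sound is attenuated by an estimated (conservative) 10 dB relative
to ≈20 kHz sound. The default profile is exactly the two anchors
(20 kHz, 0 dB), (40 kHz, +10 dB) with linear interpolation and constant
extrapolation; the small sub-20 kHz gain of the real hardware is ignored
(set to 0) to stay conservative.

## Elements, affixes, subtypes

A 44-kHz call's contour is segmented into constant-frequency *elements*
wherever consecutive contour points jump by more than `jump_threshold`
within `max_jump_gap`. The source taxonomy quantifies neither
"instantaneous" nor the jump size; the defaults (4 kHz within 10 ms) sit
clearly above within-element drift and jitter (≤ ~2 kHz) and clearly below
the ≥ 10 kHz jumps of archetypal step calls, and both are configurable.
Element frequency is summarized by the median of its contour points —
robust to onset transients; the summary statistic is unspecified in the
source description, and mean/median differ negligibly for near-constant
elements.

The affix rule discounts a leading (prefix) or trailing (suffix) element
shorter than 1/5 of its neighbor. It is applied exactly once per end, with
both conditions evaluated on the untrimmed sequence: the description speaks
of start and end *portions*, singular, and iterative application could
erode genuine two-element calls. At least one element is always retained.
Subtypes then follow from the trimmed element count: 1 → flat; 2 → step up
or step down by direction; 3 with a differing middle → insert; more than
3 → complex. A 3-element sequence whose middle matches a neighbor is
impossible after segmentation (adjacent elements differ by construction)
and raises an internal-consistency error rather than a silent label.

Two ratio statistics quantify the 3:2 relation: `element_ratio()` (max over
min of the two element medians of a step call, order-invariant) and
`pair_ratio_22_44()` (mean 44-kHz peak frequency over mean long-22 peak
frequency within a transitioning rat).

## Bouts and transitions

The inter-call gap is *silence* — next onset minus previous offset — not
onset-to-onset distance; "time gaps between calls" most naturally means the
former. Calls with gaps strictly under 320 ms share a bout (a gap of
exactly 320 ms splits). Transition probabilities are conditional pair
frequencies pooled across sessions, never across session boundaries;
`unknown`-typed calls break pairs in both directions. Pairs spanning a
shock are counted in the `all` scope (the source is silent; exclusion
windows can be emulated upstream). Counts are pooled across rats directly;
per-session matrices can be computed by filtering the input table.

## Clustering

The density route standardizes (peak frequency, duration) to z-scores and
runs DBSCAN, implemented in-package with the classic core-point /
density-reachability definition (no suitable dependency exists in the
target environment, and the clustering is a headline analysis). min_pts
defaults to 150 — at corpus scale this suppresses incidental
micro-clusters. ε comes from the k-distance heuristic: the knee (maximum
chord deviation, a discrete maximum-curvature proxy) of the sorted
150th-nearest-neighbor distance curve. The published procedure additionally
*maximizes ε among ranges* to select the most relevant cluster count;
`select_eps()` implements this by scanning candidates from 0.7× the knee up
to the top of the k-distance curve and keeping the largest ε that preserves
the modal cluster count. On clean planted blobs this absorbs extreme tail
points that a knee-exact ε would leave as noise, without merging clusters.

The silhouette is computed over clustered points only, excluding noise:
outlier points have no cluster cohesion to score, and including them would
turn a quality measure of the found clusters into a measure of the noise
rate. (Whether the published coefficient included outliers is unstated;
this choice is documented rather than hidden.) The in-package chunked
silhouette is verified against `cluster::silhouette` exactly.

The contour route resamples each call's frequency track to 32 points by
linear interpolation (a DeepSqueak-like granularity; configurable),
z-scores every column, and weights the three feature blocks — contour
shape, duration, peak frequency — so each contributes equal total variance
("equal weights" honored block-wise; the reference software's internal
weighting is opaque). k-means is seeded and restarted `n_init` times for
k = 1..max_k (default 4); k is the largest second forward difference of the
inertia curve — the sharpest elbow — with a degenerate all-identical input
collapsing to k = 1. The optional 2-D embedding is seeded PCA, display-only
by contract: cluster membership never depends on it (the original used
UMAP purely for visualization, and embedding fidelity is out of scope).

## Freezing

A frame freezes iff it lies in a run of at least `min_frames` consecutive
frames with motion index below `motion_threshold` (defaults 30 frames,
threshold 18 — the conditioning-software convention at 30 fps). Frames are
half-open intervals [k/fps, (k+1)/fps); a frame belongs to a window iff its
start does — this resolves fractional-frame edges deterministically and
makes window freezing exactly concatenation-consistent.

`bin_linkage()` tiles the session into 10-s bins. A bin's category comes
from the set of call types with *onset* inside it (consistent with ITI
assignment; the treatment of boundary-spanning calls is otherwise
unspecified): exclusively long-22, exclusively 44-kHz, or mixed. The
baseline category is the first 5 minutes truncated at the first shock
(reference sessions deliver the first shock after ≥10 min, so truncation is
a safety net, not the norm); call-free bins count as `no_calls` only after
the first shock, and silent bins between baseline and first shock belong to
no analysis category. `call_nested_freezing()` evaluates matched
(long-22, 44-kHz) pairs over the shorter call's full span and an
equal-length window centered in the longer call, with the freeze mask
recomputed *globally* at the reduced `min_frames` (3/5/10/15): whether the
original recomputation was global or window-local is unstated, and the
global choice keeps the mask a session-level object with one definition.

## The synthetic world

`synthetic_config()` states the emulated world once; its defaults are the
reference conditions: 46 rats, 52-minute sessions, 10 shocks evenly spaced
after a 600 s pre-period, 30 fps video. Within that world:

- **Class features** are drawn strictly inside class regions with margins
  (≥500 Hz, ≥10 ms) off every label-relevant boundary, so classifier
  agreement with ground truth is exactly 100% — a clean acceptance gate,
  not a claim about real boundary-straddling calls.
- **Emission structure**: per-window expected counts plant the long-22 peak
  at ITI-3 and the late rise of 44-kHz calling (planted share ≈1.2% at
  ITI-1 — matching the reported early-trial share — rising monotonically to
  60% at ITI-9). Types follow a persistent chain: each call repeats the
  previous type with the planted self-transition probability (long22 0.95,
  fortyfour 0.85), else jumps to a type drawn with probability ∝
  share × (1 − self-transition), which makes the per-window equilibrium
  share equal the planted share. The chain continues across window
  boundaries with an ordinary transition, so *every* consecutive pair has
  self-probability exactly as planted and the pooled estimator is unbiased.
  Because the sequence is autocorrelated, per-ITI share estimates lag the
  planted profile by roughly one mean run length and carry
  design-effect-inflated variance; the recovery criterion for the profile
  is therefore *ordering* (monotone rise, rank correlation ≥0.9), not a
  per-ITI binomial band — a deliberate, pre-registered choice documented
  here.
- **Timing** is built sequentially: each next onset is the previous offset
  plus a positive gap (<320 ms with probability 0.75, else 0.5–2.5 s),
  which guarantees non-overlap by construction — chosen over
  rejection-resampling of onsets because it keeps the bout-gap distribution
  exactly as configured and cannot loop.
- **Contours** are sampled every 5 ms: flat calls jitter within ±900 Hz
  (spread < 2 kHz, under the flatness tolerance); step calls hold two
  elements with ratio ~ Normal(1.5, 0.05) and duration fractions in
  0.35–0.65 (safely above the 1/5th affix rule, so the planted subtype is
  recoverable exactly); inserts drop the middle element by 2:3; complex
  calls alternate 4–6 elements; 50-kHz calls are sinusoidally modulated
  ±5 kHz. The 22-kHz frequency drift (24.5 → 27.9 kHz across ITIs) and the
  44-kHz drift (37.8 → 39.6 kHz) are planted as linear trends in the
  per-ITI means.
- **Freezing** is a 1-s-block model: blocks freeze independently with
  probability 0.05 pre-shock, 0.30 after the first shock, 0.45 within ±5 s
  of a long-22 onset and 0.75 within ±5 s of a 44-kHz onset (44-kHz
  precedence). Frozen blocks emit motion ~ U(0, 10), active blocks
  U(25, 100), so runs align with blocks and the 30-frame rule detects them
  crisply. The probabilities are the package's own stated world — chosen
  once to produce baseline ≈5%, call-free ≈30%, long-22 ≈43%, 44-kHz ≈65%
  freezing, the qualitative ordering reported for real sessions — and are
  not tuned further.

What a green test does **not** establish: the generator draws features from
clean unimodal distributions with hard margins; real calls straddle
boundaries (hence the published 0.2% manual correction), real contours
carry detection noise, dropouts and amplitude structure, real freezing is
autocorrelated beyond 1-s blocks, and real emission rates vary by orders of
magnitude across rats. Green acceptance means the *estimators recover what
was planted*, not that the biological effect sizes are reproduced; the
published corpus-scale numbers (e.g. cluster means, silhouette 0.198,
94.4%/83.1% transition probabilities) are data-dependent and are only
mirrored qualitatively here.

## Numerical choices and degenerate inputs

- Onset-sorting of call tables is stable; ties keep file order.
- The native CSV dialect is lossless round-trip; ms/kHz dialects convert on
  read/write. Unknown columns pass through as opaque annotations.
- A flat averaged spectrum (silence) raises "no spectral peak" instead of
  returning an arbitrary bin.
- Zero-variance features refuse to standardize, by name; duplicated-point
  inputs make the ε heuristic fail loudly ("degenerate distances") rather
  than return 0.
- Rows of a transition matrix with no outgoing pairs are NaN, not 0 — "no
  evidence" is distinct from "never follows".
- Empty windows yield NaN freezing percentages; bins are produced by count
  (`ceiling(session_length / bin_length)`), immune to floating-point seq
  fuzz.
- All seeds derived from the master seed stay below 2^31.

## Known limitations

- DBSCAN region queries are exact O(n²) (chunked for memory); fine for
  ~10^4–10^5 calls, not for millions.
- The contour k-means block weighting is a principled reading of "equal
  weights", not a byte-level emulation of the reference software.
- WAV support covers 16-bit mono PCM only.
- The pipeline processes sessions independently; cross-session rat-level
  modeling (beyond pooling) is out of scope.
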