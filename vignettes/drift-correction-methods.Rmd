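---
title: "Correcting vertical drift in reading eye-tracking data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting vertical drift in reading eye-tracking data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driftkit)
```

## The problem

Eye trackers accumulate systematic error — drift — from calibration decay,
head movement and lighting changes. In scene viewing a few pixels of drift
are harmless; in reading experiments they routinely move recorded fixations
onto the wrong word or, worse, the wrong line of text, corrupting every
word-level measure computed downstream. Because the error is predominantly
vertical, correction amounts to *line re-assignment*: deciding, for each
fixation, which line of text it was actually directed at, and snapping its
y coordinate to that line's center. The x coordinate and the duration are
never touched; horizontal repositioning is deliberately out of scope.

All coordinates in this package are screen pixels with the origin at the
top-left and y increasing downward. Line and part indices are 1-based.
AOI containment is half-open (`x <= px < x + width`,
`y <= py < y + height`), so a point on the shared edge of two adjacent
AOIs belongs to exactly one of them, and nearest-line ties resolve to the
smaller line index. These conventions are load-bearing: every module
inherits them, and several tests probe exactly these boundaries.

## The correction algorithms

Thirteen automatic correctors are provided, all with the same contract: a
fixation sequence plus the line geometry in, a line assignment out. They
are reimplementations of published algorithms summarized here:

* **attach** — each fixation independently to its nearest line center.
* **chain** — runs of consecutive fixations within linking thresholds
  (`x_link = 192`, `y_link = 32` px) share the line nearest their mean y.
* **cluster** — k-means on y with as many clusters as lines
  (10 restarts, seed 0); clusters map to lines by ascending mean.
* **merge** — progressive runs fused (closest mean y first) until one run
  per line remains; runs map to lines by ascending mean y.
* **regress** — one regression line per text line, sharing a slope in
  \[-0.1, 0.1\], a vertical offset in \[-50, 50\] px and a Gaussian
  residual SD in \[1, 20\] px; parameters maximize the summed best-line
  log-density (L-BFGS-B from a 3x3 grid of starts), fixations take their
  best line at the optimum.
* **stretch** — the vertical scale in \[0.9, 1.1\] and offset in
  \[-50, 50\] px minimizing total distance to the nearest centers;
  assignment is nearest-line on the transformed y.
* **segment** — cuts at the m-1 largest leftward x jumps (return
  sweeps) and maps segments to lines 1..m chronologically.
* **slice** — like merge, but tuned as a sequential method: runs break on
  leftward jumps or y steps, then fuse to the line count.
* **warp** — dynamic time warping between the chronological fixation
  sequence and the reading-order word-center sequence (Euclidean cost,
  first-to-first / last-to-last boundaries); each fixation takes the mode
  of its matched words' lines, earlier word on ties.
* **warp+attach / +chain / +regress / +stretch** — hybrids: regressive
  fixations are split out, the progressive remainder is warped and
  snapped, the regressions are re-inserted at their original coordinates,
  and the base algorithm runs on the recombined sequence.

The published descriptions of several of these algorithms leave their
tunables open, so every tunable is fixed explicitly here; the defaults
above are part of the package contract and are all overridable through
`params` in `correct_fixations()`.

Two details were genuinely open and are worth recording. First, the
regression-marking rule used by the hybrids: fixation *i* is regressive
when its nearest line lies above the furthest line reached so far, or when
it jumps leftward by more than one word width while staying on the same
nearest line. This captures both between- and within-line regressions as
the synthetic generators produce them, which is what makes the hybrids
testable against generated ground truth. Second, DTW tie-breaking: the
backtrace prefers diagonal, then the previous-fixation step, and a
fixation matched to several words takes the earliest line among the most
frequent — all deterministic, so the algorithms are pure functions.

Positional algorithms (attach and friends) fail once drift approaches half
the line spacing; warp exploits reading order instead of position and
survives offsets of a full line spacing. The test suite pins both facts
down on fixtures, and they are also the reason assisted correction helps:
the human supplies exactly the information position-based suggestions
lack.

## Assisted correction

`start_session()` builds a session that walks fixations chronologically.
At each step the selected algorithm's assignment for the current fixation
is the *suggestion*; the user accepts (`session_accept()`) or intervenes
(`session_override()`, `session_line_up()`/`_down()`,
`session_line_jump()`). The design decisions:

* **Recompute strategy.** After an intervention the full algorithm is
  re-run on a copy of the sequence in which every decided fixation carries
  its decided coordinates; the recomputed assignment replaces suggestions
  for undecided fixations only. Decided fixations are immutable. A full
  re-run is the simplest realization that is faithful to "the algorithm
  updates its internal state"; with sequences of at most a few hundred
  fixations it is computationally negligible.
* **No recompute on accept.** An accepted suggestion came from the
  algorithm, so feeding it back adds no information. Interventions
  (override, line keys) do add information and trigger the recompute.
  Attach is the documented exception among algorithms: it looks at one
  fixation at a time, so its suggestions never change — a property the
  tests assert.
* **Back-navigation** is read-only; actually re-deciding an earlier
  fixation reopens every later decision and triggers a single recompute.
* **Timestamps** come from an injected clock (`make_step_clock()` by
  default), which makes session logs deterministic in tests;
  `active_time()` drops inter-event gaps above a cutoff so breaks do not
  inflate completion time.

The package quantifies the collaboration with a simulated *oracle user*
(`run_oracle_session()`): it accepts a suggestion iff it matches ground
truth and otherwise overrides to the truth. By construction it always ends
at accuracy 1; the interesting quantity is how many overrides it needs.
On a 3-line fixture offset by 35 px (more than half the 60 px line
spacing, so every initial chain suggestion on lines 1-2 is wrong), chain
with `y_link = 40` needs 2 oracle overrides with recompute against 10
without: each correction anchors the rest of its line. The acceptance
script recomputes exactly this pair of numbers.

## Synthetic data and distortions

The generators produce benchmark trials with known ground truth:

* Durations follow `100 + 40 * letters` ms. Letter counts are
  approximated from AOI width divided by a nominal 15 px letter width
  (minimum one letter).
* Word skipping is exponential in length, `p = k * exp(-lambda * L)`
  clamped to \[0, 1\], with defaults `k = 0.95`, `lambda = 0.35` chosen to
  give the familiar shape — near-certain skipping of 1-letter words,
  rare skipping beyond 8 letters. They are approximations, documented and
  overridable, not fitted constants. The skip decision compares a
  uniform(0, 1) draw to the probability — the only draw distribution
  under which the realized skip rate equals the model probability; the
  draw is nonetheless a pluggable choice conceptually, fixed here for
  determinism of the contract.
* Fixations land at the optimal viewing position, realized as
  `x + 0.40 * width` — slightly left of word center, the standard OVP
  finding; the exact fraction is a convention, not an estimate.
* The regression generators insert, after each eligible word with a given
  probability, one revisit to a uniformly chosen earlier word on the same
  line (within-line) or an earlier line (between-line), then resume the
  progressive pass. Word frequency is deliberately ignored throughout.

Four distortion families turn clean trials into benchmarks: per-fixation
Gaussian **noise** (both axes, SD = magnitude), a **slope** growing
linearly with x, a **shift** growing linearly with y, and a uniform
**offset**. Slope and shift are normalized by the observed fixation span
rather than the screen size, so `magnitude` is exactly the maximum
displacement — an interpretable and directly testable definition; the
alternative (anchoring at the screen edge) would make the effective
distortion depend on where the text happens to sit.

The generator emulates the *structure* reading correction algorithms care
about — line membership, reading order, regressions, skipping,
length-dependent durations — on top of rectangular word boxes rendered by
`make_stimulus_fixture()`. It does not emulate saccade dynamics, pupil
size, binocular disparity, word-frequency effects or antialiased
typography. Tests passing on these fixtures therefore certify the
algorithms' geometric and sequential behavior, not their accuracy on any
particular real dataset.

## AOI detection

`detect_aois()` is threshold scanning: binarize (ink = intensity strictly
below 128 by default), group ink rows into line bands wherever a blank-row
run *strictly exceeds* the height threshold (10 px default), then group
ink columns within each band wherever a blank-column run strictly exceeds
the width threshold (2 px for letters, 8 px for words). "Exceeds" is
taken literally — a run equal to the threshold does not split — and the
choice is documented because the source description does not fix it.
Each AOI spans its whole band vertically, with an optional symmetric
`height_pad`. The module's primary correctness property is exact
recovery: on fixture stimuli whose gaps exceed the thresholds, detection
returns the generating boxes pixel-for-pixel, and the AOI count is
non-increasing in the width threshold.

## Filters, metrics, formats

The cleaning filters follow the conventional thresholds (drop above
800 ms, below 80 ms, beyond n SDs from the mean — computed once, not
iteratively — and outside the screen). The merge filter absorbs short
fixations into their nearest close temporal neighbor (previous preferred
on ties), conserving total duration. Boundary inclusivity is fixed by the
tests: the long filter keeps 800 at threshold 800, the short filter keeps
80 at threshold 80.

Gaze duration ends at the first fixation on *any other* AOI or off-AOI —
momentary off-word samples are not bridged; the one-line textbook
definition admits both readings, and the unbridged one is stated and
tested. `TT >= GD >= FFD` holds for every fixated AOI, and total time
plus off-AOI duration conserves the grand total.

The JSON trial dialect requires exactly one key, `"fixations"`, holding
ordered `[x, y, duration]` triples; all other top-level keys round-trip
verbatim, so enriched files need no schema migration. EyeLink ASCII
parsing reads `EFIX`/`ESACC`/`EBLINK` lines, groups trials on a
configurable message regex (default `"TRIALID"`), skips unknown lines
with a count rather than aborting, and selects the first eye seen in
binocular files unless told otherwise.

## Problem sizes and limitations

The test and acceptance workloads use 3-line x 5-word fixtures (line
spacing 60 px) for algorithm and session properties, up to 10,000
simulated words for the Monte-Carlo skip-rate check, instances of at most
8 fixations x 8 words for the exhaustive DTW oracle, and 10,000 fixations
for distortion moment checks — sizes at which every closed-form or
enumerative oracle is exact and the whole suite runs in seconds.

Known limitations: correction is vertical-only by design; `merge` and
`slice` are simplified relative to their original publications (both
reduce to run-building plus fusion, which suffices for their contract
here but will not reproduce those tools' outputs on hard real data); the
skip-model defaults are shape approximations; AOI detection assumes
axis-aligned dark-on-light text and offers no manual AOI editing; and no
claim is made about human correction time or accuracy — those are
empirical questions about users, not software, and nothing in this
package computes them.
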