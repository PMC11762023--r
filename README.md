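# driftkit

Correction of vertical drift in reading eye-tracking data.

In reading experiments, eye-tracker drift — calibration decay, head
movement, lighting changes — shifts recorded fixations vertically, often
onto the wrong line of text. Since most reading measures are word-level,
uncorrected drift silently corrupts them. `driftkit` is a headless toolkit
for researchers who need to clean such data reproducibly: it implements
thirteen automatic line-assignment algorithms, an *assisted* correction
mode in which an algorithm streams per-fixation suggestions that a human
accepts or overrides (with the remaining suggestions recomputed after
every intervention), plus the surrounding machinery — AOI detection from
stimulus bitmaps, synthetic benchmark generation, distortion models,
cleaning filters, reading metrics, and format converters.

## The core model

Drift correction is treated as line assignment: given fixations
$(x_i, y_i, d_i)$ and text line centers $c_1 < \dots < c_m$, each
algorithm produces $\ell_i \in \{1..m\}$ and correction snaps
$y_i \leftarrow c_{\ell_i}$ (x and duration untouched). Algorithms range
from positional (*attach*: $\ell_i = \arg\min_k |y_i - c_k|$) through
relative-positional (*chain*, *cluster*, *merge*, *regress*, *stretch*)
and sequential (*segment*, *slice*) to order-based (*warp*: dynamic time
warping of the fixation sequence against the reading-order word-center
sequence under Euclidean cost) and four warp hybrids that handle
regressions separately. Correction quality against a known ground truth
is the fraction of fixations returned to their original line.

Benchmarks come from the synthetic generators: one fixation per word at
the optimal viewing position, durations $100 + 40\cdot\text{letters}$ ms,
word skipping with probability $k e^{-\lambda L}$ for an $L$-letter word
(defaults $k = 0.95$, $\lambda = 0.35$), optional within- and between-line
regressions, and four parametric distortions (noise, slope, shift,
offset).

## Worked example

```r
library(driftkit)

# A known 3-line stimulus (15 word boxes, line spacing 60 px) and a clean
# reading trial over it, then a severe vertical drift: one full line.
fix     <- make_stimulus_fixture(n_lines = 3, words_per_line = 5, seed = 2)
g       <- gen_basic(fix$aois, dispersion_sd = 3, seed = 7)
drifted <- distort_offset(g$seq, 60)

for (algo in c("attach", "warp")) {
  res <- correct_fixations(drifted, fix$aois, algo)
  cat(sprintf("%-6s accuracy: %.3f\n", algo,
              drift_accuracy(res$assignment, g$truth)))
}
#> attach accuracy: 0.333
#> warp   accuracy: 1.000
```

A whole-line offset defeats the positional corrector — every fixation's
nearest line is its neighbor — while warp, which aligns reading *order*
to word order, restores every fixation. With a drift of 35 px (just over
half the line spacing) an assisted session shows the human–machine
collaboration at work: a simulated perfectly informed user corrects the
first fixation of a mis-assigned line, the chain algorithm re-runs with
that anchor, and the rest of the line snaps into place:

```r
tr     <- trial(distort_offset(g$seq, 35), fix$aois)
oracle <- run_oracle_session(tr, g$truth, "chain", params = list(y_link = 40))
cat(sprintf("oracle user: accuracy %.2f with %d overrides out of %d fixations\n",
            oracle$accuracy, oracle$n_override, length(g$truth)))
#> oracle user: accuracy 1.00 with 2 overrides out of 15 fixations
```

Without recomputation the same user would have had to fix all ten wrong
suggestions by hand. Downstream analysis uses the same AOIs:

```r
head(hit_test(g$seq, fix$aois), 3)
#>      fix_x    fix_y duration aoi_x aoi_y aoi_width aoi_height line part         image
#> 1 104.0617 61.40304      420    50    50       118         20    1    1 synthetic.png
#> 2 212.8097 57.31860      300   188    50        71         20    1    2 synthetic.png
#> 3 324.9171 59.07802      420   279    50       120         20    1    3 synthetic.png
```

`aoi_metrics()` adds first-fixation duration, gaze duration and total
time per word; `detect_aois()` recovers word boxes from a stimulus
bitmap; `read_asc()` / `read_trial_json()` / `read_fixations_csv()`
import real recordings. A command-line wrapper (`exec/driftkit`) exposes
the same operations as subcommands
(`synth`, `distort`, `correct`, `filter`, `aoi`, `report`, `convert`,
`accuracy`) for shell pipelines.

## Package layout

| Where | What |
|---|---|
| `R/core.R` | fixation sequences, AOI sets, line geometry, accuracy |
| `R/algorithms.R` | the 13 correction algorithms |
| `R/assist.R` | assisted-correction sessions, event logs, oracle user |
| `R/synthgen.R` | synthetic trial + stimulus generators |
| `R/distort.R` | noise / slope / shift / offset distortions |
| `R/aoi_detect.R` | threshold-scan AOI detection, AOI CSV I/O |
| `R/filters.R` | duration / outlier / merge / offscreen filters |
| `R/reports.R` | hit-testing, FFD/GD/TT metrics, tabular reports |
| `R/io_formats.R` | EyeLink ASCII, CSV and JSON converters |
| `R/cli.R`, `exec/driftkit` | command-line wrapper |

See `vignettes/drift-correction-methods.Rmd` for the full account of the
models, parameter defaults, and design decisions.
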