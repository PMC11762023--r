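Package: driftkit
Title: Correction of Vertical Drift in Reading Eye-Tracking Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cleaning and correcting fixation data from eye-tracking
    reading experiments. Implements thirteen automatic vertical drift
    correction algorithms (positional, relative-positional, sequential and
    warp-based hybrids) that assign fixations to text lines, a stateful
    assisted-correction session in which an algorithm streams per-fixation
    suggestions that a human accepts or overrides (with suggestions recomputed
    after each intervention), threshold-scan detection of letter-, word- and
    line-level areas of interest from stimulus bitmaps, parametric generators
    of synthetic reading fixation sequences (length-dependent durations,
    exponential word-skipping, within- and between-line regressions) and of
    benchmark distortions (noise, slope, shift, offset), standard data-cleaning
    filters, hit-testing and reading duration metrics (first-fixation duration,
    gaze duration, total time), and converters between EyeLink ASCII exports,
    CSV, and a minimal JSON fixation format.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    png,
    tiff,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
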