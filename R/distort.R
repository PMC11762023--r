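#' Distort a fixation sequence with random noise
#'
#' Displaces every fixation independently in a random direction: per-axis
#' Gaussian displacement with standard deviation `magnitude` on both x and
#' y. Durations and ordering are unchanged.
#'
#' @param seq A [fixation_seq].
#' @param magnitude Per-axis Gaussian SD in pixels (>= 0).
#' @param seed RNG seed.
#' @return A distorted [fixation_seq].
#' @export
distort_noise <- function(seq, magnitude, seed = 1) {
  stopifnot(magnitude >= 0)
  if (nrow(seq) == 0 || magnitude == 0) return(seq)
  with_seed(seed, {
    out <- seq
    out$x <- out$x + stats::rnorm(nrow(seq), 0, magnitude)
    out$y <- out$y + stats::rnorm(nrow(seq), 0, magnitude)
    out
  })
}

#' Distort a fixation sequence with a horizontal-position-dependent slope
#'
#' Emulates a calibration error that grows across the screen: fixations on
#' the left edge of the observed span are unmoved, and the vertical
#' displacement grows linearly with x up to exactly `magnitude` pixels at
#' the rightmost fixation.
#'
#' @inheritParams distort_noise
#' @param magnitude Maximum vertical displacement in pixels (signed).
#' @return A distorted [fixation_seq].
#' @export
distort_slope <- function(seq, magnitude) {
  if (nrow(seq) == 0) return(seq)
  out <- seq
  span <- max(seq$x) - min(seq$x)
  frac <- if (span > 0) (seq$x - min(seq$x)) / span else rep(0, nrow(seq))
  out$y <- out$y + magnitude * frac
  out
}

#' Distort a fixation sequence with a vertical shift gradient
#'
#' Pushes fixations down in proportion to their distance from the topmost
#' fixation: the topmost fixation stays put, the bottommost moves by
#' exactly `magnitude`. A single-fixation sequence is unchanged.
#'
#' @inheritParams distort_slope
#' @return A distorted [fixation_seq].
#' @export
distort_shift <- function(seq, magnitude) {
  if (nrow(seq) == 0) return(seq)
  out <- seq
  span <- max(seq$y) - min(seq$y)
  frac <- if (span > 0) (seq$y - min(seq$y)) / span else rep(0, nrow(seq))
  out$y <- out$y + magnitude * frac
  out
}

#' Distort a fixation sequence with a uniform vertical offset
#'
#' Moves every fixation up or down by the same signed amount — the
#' prototypical vertical drift that line-assignment correction exists to
#' undo.
#'
#' @inheritParams distort_slope
#' @param magnitude Signed vertical offset in pixels.
#' @return A distorted [fixation_seq].
#' @export
distort_offset <- function(seq, magnitude) {
  out <- seq
  out$y <- out$y + magnitude
  out
}

#' Apply a named distortion
#'
#' Dispatch wrapper over the four distortion families.
#'
#' @inheritParams distort_noise
#' @param kind One of `"noise"`, `"slope"`, `"shift"`, `"offset"`.
#' @return A distorted [fixation_seq].
#' @export
distort <- function(seq, kind = c("noise", "slope", "shift", "offset"),
                    magnitude, seed = 1) {
  kind <- match.arg(kind)
  switch(kind,
         noise = distort_noise(seq, magnitude, seed),
         slope = distort_slope(seq, magnitude),
         shift = distort_shift(seq, magnitude),
         offset = distort_offset(seq, magnitude))
}
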