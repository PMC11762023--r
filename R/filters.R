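#' Remove overly long fixations
#'
#' Drops fixations whose duration exceeds the threshold (strictly above);
#' 800 ms is the conventional cutoff for fixations unlikely to reflect
#' lexical processing.
#'
#' @param seq A [fixation_seq].
#' @param threshold_ms Duration threshold in milliseconds (default 800).
#' @return Filtered [fixation_seq].
#' @export
filter_long <- function(seq, threshold_ms = 800) {
  keep_rows(seq, seq$duration <= threshold_ms)
}

#' Remove overly short fixations
#'
#' Drops fixations strictly below the threshold; 80 ms is the conventional
#' lower cutoff.
#'
#' @inheritParams filter_long
#' @param threshold_ms Duration threshold in milliseconds (default 80).
#' @return Filtered [fixation_seq].
#' @export
filter_short <- function(seq, threshold_ms = 80) {
  keep_rows(seq, seq$duration >= threshold_ms)
}

#' Remove duration outliers
#'
#' Single pass: the mean and SD of all durations are computed once, then
#' fixations whose duration deviates from the mean by more than `n_sd`
#' standard deviations are removed. With zero spread nothing is removed.
#'
#' @inheritParams filter_long
#' @param n_sd Number of standard deviations (default 2.5).
#' @return Filtered [fixation_seq].
#' @export
filter_outliers <- function(seq, n_sd = 2.5) {
  if (nrow(seq) == 0) return(seq)
  mu <- mean(seq$duration)
  sigma <- stats::sd(seq$duration)
  if (is.na(sigma) || sigma == 0) return(seq)
  keep_rows(seq, abs(seq$duration - mu) <= n_sd * sigma)
}

#' Merge short fixations into a close larger neighbor
#'
#' Eye trackers sometimes over-segment one fixation into a short and a
#' long one close together. Each fixation with duration at or below
#' `max_dur_ms` whose nearest temporal neighbor (previous preferred, else
#' next) lies within `max_dist_px` (Euclidean) is merged into that
#' neighbor: the neighbor keeps its position and the durations are summed.
#' One left-to-right pass.
#'
#' @inheritParams filter_long
#' @param max_dur_ms Maximum duration (ms) of a fixation eligible for
#'   merging (default 80).
#' @param max_dist_px Maximum Euclidean distance (pixels) to the absorbing
#'   neighbor (default 20).
#' @return Filtered [fixation_seq]; total duration of merged groups is
#'   conserved.
#' @export
filter_merge_short <- function(seq, max_dur_ms = 80, max_dist_px = 20) {
  n <- nrow(seq)
  if (n < 2) return(seq)
  x <- seq$x; y <- seq$y; dur <- seq$duration
  alive <- rep(TRUE, n)
  dist2 <- function(i, j) sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
  for (i in seq_len(n)) {
    if (!alive[i] || dur[i] > max_dur_ms) next
    prv <- { k <- i - 1; while (k >= 1 && !alive[k]) k <- k - 1; if (k >= 1) k else NA }
    nxt <- { k <- i + 1; while (k <= n && !alive[k]) k <- k + 1; if (k <= n) k else NA }
    cand <- c(prv, nxt)
    cand <- cand[!is.na(cand)]
    if (length(cand) == 0) next
    d <- vapply(cand, dist2, numeric(1), i = i)
    j <- cand[which.min(d)]      # previous wins ties (listed first)
    if (min(d) <= max_dist_px) {
      dur[j] <- dur[j] + dur[i]
      alive[i] <- FALSE
    }
  }
  fixation_seq(x[alive], y[alive], dur[alive])
}

#' Remove fixations outside the stimulus
#'
#' Keeps fixations with `0 <= x < screen_width` and
#' `0 <= y < screen_height` (half-open, matching AOI containment).
#'
#' @inheritParams filter_long
#' @param screen_width,screen_height Stimulus dimensions in pixels.
#' @return Filtered [fixation_seq].
#' @export
filter_offscreen <- function(seq, screen_width, screen_height) {
  keep_rows(seq, seq$x >= 0 & seq$x < screen_width &
                 seq$y >= 0 & seq$y < screen_height)
}

keep_rows <- function(seq, keep) {
  if (nrow(seq) == 0) return(seq)
  out <- seq[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(seq)
  out
}
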