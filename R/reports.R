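#' Hit-test fixations against an AOI set
#'
#' Assigns each fixation to the AOI it falls in (half-open containment:
#' `x <= px < x + width`, `y <= py < y + height`), producing one record per
#' fixation in order. Fixations outside every AOI carry NA AOI fields.
#'
#' @param seq A [fixation_seq].
#' @param aois An [aoi_set].
#' @return A data.frame with columns `fix_x`, `fix_y`, `duration`,
#'   `aoi_x`, `aoi_y`, `aoi_width`, `aoi_height`, `line`, `part`, `image`.
#' @examples
#' a <- aoi_set("word", x = 137.5, y = 147, width = 119, height = 44,
#'              line = 1, part = 1, image = "stimulus.png")
#' s <- fixation_seq(168, 166, 300)
#' hit_test(s, a)  # lands on line 1, part 1
#' @export
hit_test <- function(seq, aois) {
  n <- nrow(seq)
  idx <- aoi_index(seq, aois)
  data.frame(
    fix_x = seq$x, fix_y = seq$y, duration = seq$duration,
    aoi_x = ifelse(is.na(idx), NA_real_, aois$x[idx]),
    aoi_y = ifelse(is.na(idx), NA_real_, aois$y[idx]),
    aoi_width = ifelse(is.na(idx), NA_real_, aois$width[idx]),
    aoi_height = ifelse(is.na(idx), NA_real_, aois$height[idx]),
    line = ifelse(is.na(idx), NA_integer_, aois$line[idx]),
    part = ifelse(is.na(idx), NA_integer_, aois$part[idx]),
    image = ifelse(is.na(idx), NA_character_, aois$image[idx]),
    stringsAsFactors = FALSE)
}

# index of the containing AOI for each fixation, NA when none
aoi_index <- function(seq, aois) {
  vapply(seq_len(nrow(seq)), function(i) {
    hit <- which(aois$x <= seq$x[i] & seq$x[i] < aois$x + aois$width &
                 aois$y <= seq$y[i] & seq$y[i] < aois$y + aois$height)
    if (length(hit) == 0) NA_integer_ else hit[1]
  }, integer(1))
}

#' Reading duration metrics per AOI
#'
#' Computes, for every AOI, the fixation count and the three standard
#' word-level reading time measures:
#' \describe{
#'   \item{FFD}{First-fixation duration — the duration of the first
#'     fixation landing on the AOI.}
#'   \item{GD}{Gaze duration — the summed duration of the contiguous
#'     first-pass run starting at that first fixation and ending before
#'     the first fixation on a different AOI (or off any AOI).}
#'   \item{TT}{Total time — the sum of all fixation durations on the AOI,
#'     including regressions.}
#' }
#' Never-fixated AOIs get count 0 and zero durations; fixations outside
#' every AOI contribute to no metric. `TT >= GD >= FFD` always holds for
#' fixated AOIs.
#'
#' @inheritParams hit_test
#' @return A data.frame with one row per AOI: `line`, `part`, `aoi_x`,
#'   `aoi_y`, `aoi_width`, `aoi_height`, `image`, `fixation_count`, `FFD`,
#'   `GD`, `TT`.
#' @export
aoi_metrics <- function(seq, aois) {
  idx <- aoi_index(seq, aois)
  k <- nrow(aois)
  count <- integer(k); ffd <- gd <- tt <- numeric(k)
  for (a in seq_len(k)) {
    on_a <- which(!is.na(idx) & idx == a)
    count[a] <- length(on_a)
    if (count[a] == 0) next
    first <- on_a[1]
    ffd[a] <- seq$duration[first]
    run_end <- first
    while (run_end + 1 <= nrow(seq) &&
           !is.na(idx[run_end + 1]) && idx[run_end + 1] == a)
      run_end <- run_end + 1
    gd[a] <- sum(seq$duration[first:run_end])
    tt[a] <- sum(seq$duration[on_a])
  }
  data.frame(line = aois$line, part = aois$part,
             aoi_x = aois$x, aoi_y = aois$y,
             aoi_width = aois$width, aoi_height = aois$height,
             image = aois$image, fixation_count = count,
             FFD = ffd, GD = gd, TT = tt, stringsAsFactors = FALSE)
}

#' Tabular fixation report
#'
#' Lossless dump of a fixation sequence, one row per fixation with its
#' chronological index.
#'
#' @param seq A [fixation_seq].
#' @return A data.frame with columns `index`, `x`, `y`, `duration`.
#' @export
fixation_report <- function(seq) {
  data.frame(index = seq_len(nrow(seq)), x = seq$x, y = seq$y,
             duration = seq$duration)
}

#' Tabular saccade report
#'
#' Lossless dump of saccade events as parsed from an EyeLink ASCII export
#' (see [read_asc()]).
#'
#' @param events An event data.frame (as in trials from [read_asc()]).
#' @return The saccade rows with columns `timestamp`, `x`, `y`, `duration`,
#'   `amplitude`, `peak_velocity`.
#' @export
saccade_report <- function(events) {
  sac <- events[events$kind == "saccade", , drop = FALSE]
  rownames(sac) <- NULL
  sac[, c("timestamp", "x", "y", "duration", "amplitude", "peak_velocity")]
}
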