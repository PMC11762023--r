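#' Construct a fixation sequence
#'
#' A fixation sequence is the central data structure of the package: an
#' ordered (chronological) table of fixations, each described by its
#' horizontal and vertical position in pixel screen coordinates (origin
#' top-left, y increasing downward) and its duration in milliseconds.
#'
#' @param x,y Numeric vectors of pixel coordinates (finite).
#' @param duration Numeric vector of fixation durations in milliseconds
#'   (strictly positive).
#' @return A `data.frame` of class `fixation_seq` with columns `x`, `y`,
#'   `duration`.
#' @examples
#' fixation_seq(x = c(100, 200), y = c(150, 152), duration = c(220, 180))
#' @export
fixation_seq <- function(x = numeric(), y = numeric(), duration = numeric()) {
  x <- as.numeric(x); y <- as.numeric(y); duration <- as.numeric(duration)
  n <- length(x)
  if (length(y) != n || length(duration) != n)
    stop("x, y and duration must have equal length")
  if (n > 0) {
    if (!all(is.finite(x)) || !all(is.finite(y)))
      stop("fixation coordinates must be finite")
    if (any(!is.finite(duration)) || any(duration <= 0))
      stop("fixation durations must be positive and finite")
  }
  structure(data.frame(x = x, y = y, duration = duration),
            class = c("fixation_seq", "data.frame"))
}

#' @export
print.fixation_seq <- function(x, ...) {
  cat(sprintf("Fixation sequence: %d fixations\n", nrow(x)))
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more\n", nrow(x) - 10))
  invisible(x)
}

as_fixation_seq <- function(df) {
  fixation_seq(df$x, df$y, df$duration)
}

#' Construct a set of areas of interest
#'
#' Areas of interest (AOIs) are axis-aligned rectangles bound to elements of
#' a text stimulus at one granularity (`letter`, `word` or `line`). Each AOI
#' carries a 1-based line index and a 1-based within-line part index.
#' Containment is half-open: a point (px, py) is inside an AOI iff
#' `x <= px < x + width` and `y <= py < y + height`, so a point on the shared
#' edge of two adjacent AOIs belongs to exactly one of them.
#'
#' @param kind Granularity, one of `"letter"`, `"word"`, `"line"`.
#' @param x,y Top-left corners (pixels).
#' @param width,height Extents (pixels, positive).
#' @param line 1-based line indices.
#' @param part 1-based within-line indices.
#' @param image Stimulus identifier (recycled if scalar).
#' @param screen_width,screen_height Optional stimulus dimensions (pixels).
#' @return A `data.frame` of class `aoi_set`, sorted by (line, part), with
#'   attributes `screen_width` and `screen_height`.
#' @export
aoi_set <- function(kind, x, y, width, height, line, part,
                    image = "stimulus", screen_width = NA_real_,
                    screen_height = NA_real_) {
  kind <- match.arg(kind, c("letter", "word", "line"))
  n <- length(x)
  if (any(width <= 0) || any(height <= 0))
    stop("AOI width and height must be positive")
  df <- data.frame(kind = rep_len(kind, n), x = as.numeric(x),
                   y = as.numeric(y), width = as.numeric(width),
                   height = as.numeric(height), line = as.integer(line),
                   part = as.integer(part),
                   image = rep_len(as.character(image), n),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df[, c("line", "part")]))
    stop("(line, part) pairs must be unique within an AOI set")
  df <- df[order(df$line, df$part), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("aoi_set", "data.frame"),
            screen_width = as.numeric(screen_width),
            screen_height = as.numeric(screen_height))
}

#' @export
print.aoi_set <- function(x, ...) {
  cat(sprintf("AOI set: %d %s-level AOIs on %d line(s)\n",
              nrow(x), x$kind[1], length(unique(x$line))))
  print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Line centers of an AOI set
#'
#' Derives the vertical geometry of the text: one center y-value per distinct
#' line, computed as the midpoint (`y + height / 2`) of that line's AOIs,
#' returned in ascending order. This is the target set that every drift
#' correction algorithm maps fixations onto.
#'
#' @param aois An [aoi_set].
#' @return Numeric vector of line center y-values, ascending; names give the
#'   1-based line index.
#' @examples
#' a <- aoi_set("word", x = c(0, 60), y = c(100, 200), width = 50,
#'              height = 20, line = c(1, 2), part = c(1, 1))
#' line_centers(a)  # 110, 210
#' @export
line_centers <- function(aois) {
  if (nrow(aois) == 0) stop("no AOIs")
  mids <- aois$y + aois$height / 2
  centers <- tapply(mids, aois$line, mean)
  centers <- centers[order(as.integer(names(centers)))]
  out <- as.numeric(centers)
  names(out) <- names(centers)
  if (is.unsorted(out, strictly = TRUE))
    stop("line centers are not strictly ascending; check line indices")
  out
}

#' Nearest text line of each y coordinate
#'
#' Maps y values to 1-based line indices by minimum absolute distance to the
#' line centers. A tie between two centers resolves to the smaller index.
#'
#' @param y Numeric vector of y coordinates.
#' @param centers Line centers as returned by [line_centers()].
#' @return Integer vector of 1-based line indices.
#' @export
nearest_line <- function(y, centers) {
  if (length(centers) == 0) stop("no line centers")
  d <- abs(outer(y, centers, "-"))
  # max.col(-d, "first") gives the first (smallest-index) minimum
  as.integer(max.col(-d, ties.method = "first"))
}

#' Snap fixations to assigned line centers
#'
#' Applies a line assignment to a fixation sequence: each fixation's y is
#' replaced by the center of its assigned line; x and duration are untouched.
#' Drift correction in reading data is vertical line re-assignment, so this
#' is the only coordinate change any correction performs.
#'
#' @param seq A [fixation_seq].
#' @param assignment Integer vector of 1-based line indices, one per fixation.
#' @param centers Line centers from [line_centers()].
#' @return A corrected [fixation_seq].
#' @export
apply_assignment <- function(seq, assignment, centers) {
  if (nrow(seq) != length(assignment))
    stop("assignment length must equal number of fixations")
  if (nrow(seq) == 0) return(seq)
  if (any(assignment < 1L) || any(assignment > length(centers)))
    stop("assignment indices out of range")
  out <- seq
  out$y <- as.numeric(centers[assignment])
  out
}

#' Line-assignment accuracy
#'
#' The fraction of fixations whose corrected line equals the true
#' (generating) line — the benchmark metric for drift correction: a fixation
#' counts as correct when it was moved back to its initial line.
#'
#' @param corrected,truth Integer vectors of line assignments, equal length.
#' @return A fraction in \[0, 1\].
#' @export
drift_accuracy <- function(corrected, truth) {
  if (length(corrected) != length(truth))
    stop("assignments must have equal length")
  if (length(corrected) == 0) stop("empty assignments")
  mean(corrected == truth)
}

#' Bundle a fixation sequence with its stimulus
#'
#' A trial ties a fixation sequence to the AOIs of the stimulus it was
#' recorded on, plus free-form metadata (participant id, condition, ...).
#'
#' @param seq A [fixation_seq].
#' @param aois An [aoi_set].
#' @param image Stimulus identifier.
#' @param metadata Named list of extra fields, preserved verbatim by the
#'   JSON writer.
#' @return A list of class `trial`.
#' @export
trial <- function(seq, aois, image = "stimulus", metadata = list()) {
  structure(list(seq = seq, aois = aois, image = image, metadata = metadata),
            class = "trial")
}

#' @export
print.trial <- function(x, ...) {
  cat(sprintf("Trial on '%s': %d fixations, %d AOIs\n",
              x$image, nrow(x$seq), nrow(x$aois)))
  invisible(x)
}
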