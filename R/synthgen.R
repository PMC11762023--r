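#' Synthetic fixation duration from word length
#'
#' Fixation durations on words grow with word length (the length effect).
#' The generator models this linearly: a base duration plus a fixed
#' increment per letter. Defaults: 100 ms base, 40 ms per letter, so a
#' 5-letter word yields 300 ms.
#'
#' @param token_length Number of letters (non-negative integer vector).
#' @param base_ms Intercept duration in milliseconds (default 100).
#' @param per_letter_ms Increment per letter in milliseconds (default 40).
#' @return Durations in milliseconds.
#' @export
synth_duration <- function(token_length, base_ms = 100, per_letter_ms = 40) {
  if (any(token_length < 0)) stop("token_length must be non-negative")
  if (base_ms <= 0 || per_letter_ms <= 0)
    stop("duration model parameters must be positive")
  base_ms + token_length * per_letter_ms
}

#' Approximate word length from AOI width
#'
#' Word AOIs carry no text, so letter counts are approximated from pixel
#' width divided by a nominal letter width, rounded, with a minimum of one
#' letter.
#'
#' @param width AOI widths in pixels.
#' @param letter_width_px Nominal letter width in pixels (default 15).
#' @return Integer letter counts (>= 1).
#' @export
token_length_from_width <- function(width, letter_width_px = 15) {
  if (any(width <= 0)) stop("width must be positive")
  if (letter_width_px <= 0) stop("letter_width_px must be positive")
  pmax(1L, as.integer(round(width / letter_width_px)))
}

#' Word skipping probability as a function of word length
#'
#' Readers skip short words far more often than long ones; the skipping
#' rate decays exponentially with word length:
#' `p(length) = k * exp(-lambda * length)`, clamped to \[0, 1\].
#'
#' @param length Word length in letters (non-negative).
#' @param k Scale constant (default 0.95).
#' @param lambda Decay rate per letter (default 0.35).
#' @return Skip probabilities in \[0, 1\].
#' @export
skip_probability <- function(length, k = 0.95, lambda = 0.35) {
  if (any(length < 0)) stop("length must be non-negative")
  if (k < 0 || lambda < 0) stop("k and lambda must be non-negative")
  pmin(1, pmax(0, k * exp(-lambda * length)))
}

# Optimal viewing position: the preferred landing site within a word,
# slightly left of center. Realized as x + 0.40 * width.
ovp_x <- function(aoi_x, aoi_width) aoi_x + 0.40 * aoi_width

# Word table in reading order with OVP coordinates, lengths, durations.
word_table <- function(aois, letter_width_px = 15,
                       base_ms = 100, per_letter_ms = 40) {
  if (nrow(aois) == 0) stop("empty AOI set")
  centers <- line_centers(aois)
  data.frame(
    line = aois$line, part = aois$part,
    x = ovp_x(aois$x, aois$width),
    y = as.numeric(centers[aois$line]),
    length = token_length_from_width(aois$width, letter_width_px),
    duration = synth_duration(
      token_length_from_width(aois$width, letter_width_px),
      base_ms, per_letter_ms)
  )
}

jitter2 <- function(n, sd) if (sd > 0) stats::rnorm(n, 0, sd) else numeric(n)

finish_gen <- function(wt, idx, dispersion_sd) {
  n <- length(idx)
  sx <- wt$x[idx] + jitter2(n, dispersion_sd)
  sy <- wt$y[idx] + jitter2(n, dispersion_sd)
  list(seq = fixation_seq(sx, sy, wt$duration[idx]),
       truth = wt$line[idx], word = idx)
}

#' Generate a basic synthetic reading trial
#'
#' Places one fixation at the optimal viewing position of each word in
#' reading order, with optional Gaussian positional jitter, and a duration
#' from the word-length model. The generating line of every fixation is
#' returned as ground truth, making the output a benchmark for correction
#' algorithms.
#'
#' @param aois A word-level [aoi_set].
#' @param dispersion_sd Gaussian jitter SD around the placement point
#'   (pixels, default 0).
#' @param seed RNG seed (default 1).
#' @param letter_width_px,base_ms,per_letter_ms Duration/length model
#'   parameters, see [synth_duration()] and [token_length_from_width()].
#' @return A list with `seq` (a [fixation_seq]), `truth` (1-based generating
#'   line per fixation) and `word` (index of the generating word in reading
#'   order).
#' @export
gen_basic <- function(aois, dispersion_sd = 0, seed = 1,
                      letter_width_px = 15, base_ms = 100,
                      per_letter_ms = 40) {
  wt <- word_table(aois, letter_width_px, base_ms, per_letter_ms)
  with_seed(seed, finish_gen(wt, seq_len(nrow(wt)), dispersion_sd))
}

#' Generate a synthetic trial with word skipping
#'
#' As [gen_basic()], but each word is independently skipped with the
#' length-dependent probability of [skip_probability()]: a uniform(0,1)
#' draw below the skip probability drops the word.
#'
#' @inheritParams gen_basic
#' @param k,lambda Skip model constants (see [skip_probability()]).
#' @return As [gen_basic()]; `skipped` additionally gives the indices of
#'   skipped words.
#' @export
gen_with_skips <- function(aois, dispersion_sd = 0, seed = 1,
                           k = 0.95, lambda = 0.35, letter_width_px = 15,
                           base_ms = 100, per_letter_ms = 40) {
  wt <- word_table(aois, letter_width_px, base_ms, per_letter_ms)
  with_seed(seed, {
    p <- skip_probability(wt$length, k, lambda)
    skip <- stats::runif(nrow(wt)) < p
    out <- finish_gen(wt, which(!skip), dispersion_sd)
    out$skipped <- which(skip)
    out
  })
}

# Common machinery for the two regression generators: a progressive pass
# over all words; after each eligible word, with probability regression_prob
# insert one revisit fixation to a uniformly chosen earlier target, then
# resume the progressive pass.
gen_with_regressions <- function(aois, regression_prob, dispersion_sd, seed,
                                 letter_width_px, base_ms, per_letter_ms,
                                 target_pool) {
  if (regression_prob < 0 || regression_prob > 1)
    stop("regression_prob must be in [0, 1]")
  wt <- word_table(aois, letter_width_px, base_ms, per_letter_ms)
  with_seed(seed, {
    idx <- integer(0)
    for (i in seq_len(nrow(wt))) {
      idx <- c(idx, i)
      pool <- target_pool(wt, i)
      if (length(pool) > 0 && stats::runif(1) < regression_prob)
        idx <- c(idx, pool[sample.int(length(pool), 1)])
    }
    finish_gen(wt, idx, dispersion_sd)
  })
}

#' Generate a synthetic trial with within-line regressions
#'
#' A progressive pass over every word; after each word that is not the
#' first of its line, a revisit fixation to a uniformly chosen earlier word
#' on the same line is inserted with probability `regression_prob`. The
#' inserted fixation's ground-truth line is the revisited word's line.
#'
#' @inheritParams gen_basic
#' @param regression_prob Per-opportunity probability of inserting a
#'   regression (0-1).
#' @return As [gen_basic()].
#' @export
gen_within_line_regressions <- function(aois, regression_prob = 0.1,
                                        dispersion_sd = 0, seed = 1,
                                        letter_width_px = 15, base_ms = 100,
                                        per_letter_ms = 40) {
  gen_with_regressions(
    aois, regression_prob, dispersion_sd, seed,
    letter_width_px, base_ms, per_letter_ms,
    target_pool = function(wt, i)
      which(wt$line == wt$line[i] & seq_len(nrow(wt)) < i))
}

#' Generate a synthetic trial with between-line regressions
#'
#' As [gen_within_line_regressions()], but revisit targets are uniformly
#' chosen among words on strictly earlier lines.
#'
#' @inheritParams gen_within_line_regressions
#' @return As [gen_basic()].
#' @export
gen_between_line_regressions <- function(aois, regression_prob = 0.1,
                                         dispersion_sd = 0, seed = 1,
                                         letter_width_px = 15, base_ms = 100,
                                         per_letter_ms = 40) {
  gen_with_regressions(
    aois, regression_prob, dispersion_sd, seed,
    letter_width_px, base_ms, per_letter_ms,
    target_pool = function(wt, i) which(wt$line < wt$line[i]))
}

#' Render a word-box stimulus with known AOIs
#'
#' Builds a synthetic text-like stimulus: black rectangles ("words") on a
#' white background, laid out on a regular grid of lines, together with the
#' exact AOI set used to place them. Word widths can vary randomly between
#' bounds (seeded) so that the word-length and skipping models have
#' something to act on. The pair (image, AOIs) gives every module a fully
#' known ground truth: AOI detection must recover the boxes, generators
#' place fixations into them, and correction accuracy is measurable.
#'
#' @param n_lines Number of text lines.
#' @param words_per_line Words on each line.
#' @param word_height Box height in pixels (default 20).
#' @param word_width_range Min/max box width in pixels (default c(40, 120)).
#' @param word_gap Horizontal gap between boxes (pixels, default 20).
#' @param line_gap Vertical gap between lines (pixels, default 40).
#' @param margin Margin around the text block (pixels, default 50).
#' @param seed RNG seed for the word widths.
#' @param image Stimulus identifier.
#' @return A list with `image` (an integer matrix, rows x cols, grayscale
#'   0-255) and `aois` (the generating word-level [aoi_set]).
#' @export
make_stimulus_fixture <- function(n_lines = 3, words_per_line = 5,
                                  word_height = 20,
                                  word_width_range = c(40, 120),
                                  word_gap = 20, line_gap = 40,
                                  margin = 50, seed = 1,
                                  image = "synthetic.png") {
  stopifnot(n_lines >= 1, words_per_line >= 1)
  widths <- with_seed(seed, matrix(
    sample(seq(word_width_range[1], word_width_range[2]),
           n_lines * words_per_line, replace = TRUE),
    nrow = n_lines))
  xs <- ys <- ws <- ln <- pt <- c()
  for (i in seq_len(n_lines)) {
    x <- margin
    for (j in seq_len(words_per_line)) {
      xs <- c(xs, x); ys <- c(ys, margin + (i - 1) * (word_height + line_gap))
      ws <- c(ws, widths[i, j]); ln <- c(ln, i); pt <- c(pt, j)
      x <- x + widths[i, j] + word_gap
    }
  }
  width_px <- max(xs + ws) + margin
  height_px <- max(ys) + word_height + margin
  img <- matrix(255L, nrow = height_px, ncol = width_px)
  for (b in seq_along(xs)) {
    rows <- (ys[b] + 1):(ys[b] + word_height)
    cols <- (xs[b] + 1):(xs[b] + ws[b])
    img[rows, cols] <- 0L
  }
  aois <- aoi_set("word", x = xs, y = ys, width = ws, height = word_height,
                  line = ln, part = pt, image = image,
                  screen_width = width_px, screen_height = height_px)
  list(image = img, aois = aois)
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards so generators never perturb user RNG flow.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
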