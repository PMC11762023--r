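#' Word centers in reading order
#'
#' Midpoints of the word AOIs, ordered line-major (line, then part) — the
#' target sequence the warp algorithm aligns fixations to.
#'
#' @param aois A word-level [aoi_set].
#' @return A data.frame with columns `x`, `y`, `line` in reading order.
#' @export
word_centers <- function(aois) {
  if (nrow(aois) == 0) stop("empty AOI set")
  data.frame(x = aois$x + aois$width / 2,
             y = aois$y + aois$height / 2,
             line = aois$line)
}

check_algo_input <- function(seq, centers) {
  if (nrow(seq) == 0) stop("empty fixation sequence")
  if (length(centers) == 0) stop("no text lines")
}

#' Attach: nearest-line assignment
#'
#' The simplest positional corrector: each fixation independently goes to
#' the line whose center is vertically closest (ties to the smaller line
#' index).
#'
#' @param seq A [fixation_seq].
#' @param centers Line centers from [line_centers()].
#' @return Integer line assignment, one entry per fixation.
#' @export
algo_attach <- function(seq, centers) {
  check_algo_input(seq, centers)
  nearest_line(seq$y, centers)
}

# Split 1..n into runs: a new run starts at i when new_run[i] is TRUE.
runs_from_breaks <- function(n, new_run) {
  cumsum(c(TRUE, new_run[-1]))
}

#' Chain: assign linked fixation runs to lines
#'
#' Links consecutive fixations whose x and y separations stay within the
#' linking thresholds into chains, then assigns each chain to the line
#' closest to the mean of its y values. Robust to isolated fixations that
#' stray from an otherwise coherent run.
#'
#' @inheritParams algo_attach
#' @param x_link,y_link Maximum |dx| and |dy| (pixels) for two consecutive
#'   fixations to stay in one chain (defaults 192 and 32).
#' @return Integer line assignment.
#' @export
algo_chain <- function(seq, centers, x_link = 192, y_link = 32) {
  check_algo_input(seq, centers)
  n <- nrow(seq)
  brk <- c(FALSE, abs(diff(seq$x)) > x_link | abs(diff(seq$y)) > y_link)
  chain_id <- runs_from_breaks(n, brk)
  mean_y <- tapply(seq$y, chain_id, mean)
  chain_line <- nearest_line(as.numeric(mean_y), centers)
  chain_line[chain_id]
}

#' Cluster: k-means on the y coordinate
#'
#' Groups fixations with similar y values into as many clusters as there
#' are text lines and maps clusters to lines top-to-bottom by cluster mean.
#' Falls back to nearest-line assignment when there are fewer distinct y
#' values than lines.
#'
#' @inheritParams algo_attach
#' @param seed RNG seed for the k-means restarts (default 0).
#' @param nstart Number of k-means restarts (default 10).
#' @return Integer line assignment.
#' @export
algo_cluster <- function(seq, centers, seed = 0, nstart = 10) {
  check_algo_input(seq, centers)
  m <- length(centers)
  if (m == 1) return(rep(1L, nrow(seq)))
  if (length(unique(seq$y)) < m) return(nearest_line(seq$y, centers))
  km <- with_seed(seed, stats::kmeans(seq$y, centers = m, nstart = nstart))
  # clusters sorted by mean y ascending become lines 1..m
  line_of_cluster <- integer(m)
  line_of_cluster[order(km$centers[, 1])] <- seq_len(m)
  line_of_cluster[km$cluster]
}

#' Merge: fuse progressive runs until one per line
#'
#' Builds short progressive runs of consecutive fixations, then repeatedly
#' merges the two runs with the closest mean y until the number of runs
#' equals the number of lines; runs are then mapped to lines in ascending
#' order of mean y. If fewer runs than lines emerge, each run simply takes
#' the line nearest its mean.
#'
#' @inheritParams algo_chain
#' @return Integer line assignment.
#' @export
algo_merge <- function(seq, centers, x_link = 192, y_link = 32) {
  check_algo_input(seq, centers)
  n <- nrow(seq)
  m <- length(centers)
  brk <- c(FALSE, diff(seq$x) < -x_link | abs(diff(seq$y)) > y_link)
  grp <- runs_from_breaks(n, brk)
  # iterative fusion on group mean y
  repeat {
    ids <- unique(grp)
    if (length(ids) <= m) break
    my <- vapply(ids, function(g) mean(seq$y[grp == g]), numeric(1))
    o <- order(my)
    gaps <- diff(my[o])
    j <- which.min(gaps)
    grp[grp == ids[o[j + 1]]] <- ids[o[j]]
  }
  ids <- unique(grp)
  my <- vapply(ids, function(g) mean(seq$y[grp == g]), numeric(1))
  if (length(ids) == m) {
    line_of_grp <- integer(length(ids))
    line_of_grp[order(my)] <- seq_len(m)
  } else {
    line_of_grp <- nearest_line(my, centers)
  }
  names(line_of_grp) <- ids
  as.integer(line_of_grp[as.character(grp)])
}

#' Regress: fit a sheaf of sloped regression lines
#'
#' Treats the fixations as a point cloud and fits one regression line per
#' text line, all sharing a slope, a vertical offset and a residual SD.
#' For candidate parameters, each fixation is scored against its best line
#' under a Gaussian residual model; the parameters maximizing total
#' log-density are found by bounded quasi-Newton search from a small grid
#' of starts. The assignment is each fixation's best line at the optimum.
#'
#' @inheritParams algo_attach
#' @param slope_bounds,offset_bounds,sd_bounds Search bounds for the shared
#'   slope (dimensionless), vertical offset (pixels) and residual SD
#'   (pixels).
#' @return Integer line assignment.
#' @export
algo_regress <- function(seq, centers, slope_bounds = c(-0.1, 0.1),
                         offset_bounds = c(-50, 50), sd_bounds = c(1, 20)) {
  check_algo_input(seq, centers)
  m <- length(centers)
  if (m == 1) return(rep(1L, nrow(seq)))
  x <- seq$x; y <- seq$y
  density_mat <- function(p) {
    # rows fixations, cols lines: residual y - (slope*x + center + offset)
    pred <- outer(p[1] * x + p[2], centers, "+")
    stats::dnorm(y - pred, 0, p[3], log = TRUE)
  }
  negloglik <- function(p) -sum(apply(density_mat(p), 1, max))
  lower <- c(slope_bounds[1], offset_bounds[1], sd_bounds[1])
  upper <- c(slope_bounds[2], offset_bounds[2], sd_bounds[2])
  starts <- expand.grid(slope = c(slope_bounds[1] / 2, 0, slope_bounds[2] / 2),
                        offset = c(offset_bounds[1] / 2, 0, offset_bounds[2] / 2),
                        sd = mean(sd_bounds))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(as.numeric(starts[s, ]), negloglik, method = "L-BFGS-B",
                   lower = lower, upper = upper),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) return(nearest_line(y, centers))
  as.integer(max.col(density_mat(best$par), ties.method = "first"))
}

#' Stretch: optimal vertical scale and offset
#'
#' Searches for the vertical scaling factor and offset that, applied to the
#' fixation y values, minimize the total distance to the nearest line
#' centers; the assignment is nearest-line on the transformed coordinates.
#'
#' @inheritParams algo_attach
#' @param scale_bounds,offset_bounds Search bounds for the scale factor and
#'   vertical offset (pixels).
#' @return Integer line assignment.
#' @export
algo_stretch <- function(seq, centers, scale_bounds = c(0.9, 1.1),
                         offset_bounds = c(-50, 50)) {
  check_algo_input(seq, centers)
  if (length(centers) == 1) return(rep(1L, nrow(seq)))
  y <- seq$y
  cost <- function(p) {
    yt <- p[1] * y + p[2]
    sum(apply(abs(outer(yt, centers, "-")), 1, min))
  }
  starts <- expand.grid(scale = c(scale_bounds[1], 1, scale_bounds[2]),
                        offset = c(offset_bounds[1], 0, offset_bounds[2]))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(as.numeric(starts[s, ]), cost, method = "L-BFGS-B",
                   lower = c(scale_bounds[1], offset_bounds[1]),
                   upper = c(scale_bounds[2], offset_bounds[2])),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) return(nearest_line(y, centers))
  nearest_line(best$par[1] * y + best$par[2], centers)
}

#' Segment: split at the largest return sweeps
#'
#' Cuts the sequence after the m-1 largest leftward x jumps (the return
#' sweeps between lines) and maps the resulting segments to lines 1..m in
#' chronological order. Assumes strictly line-by-line reading.
#'
#' @inheritParams algo_attach
#' @return Integer line assignment.
#' @export
algo_segment <- function(seq, centers) {
  check_algo_input(seq, centers)
  n <- nrow(seq)
  m <- length(centers)
  if (m == 1 || n == 1) return(rep(1L, n))
  dx <- diff(seq$x)
  k <- min(m - 1, n - 1)
  cut_after <- sort(order(dx)[seq_len(k)])   # indices i: break between i, i+1
  new_run <- rep(FALSE, n)
  new_run[cut_after + 1] <- TRUE
  as.integer(runs_from_breaks(n, new_run))
}

#' Slice: sequence runs mapped to lines top to bottom
#'
#' Splits the sequence into runs of fixations that plausibly share a line
#' (a run breaks at a large leftward jump or a large vertical step), fuses
#' the closest runs in y until their number matches the line count, and
#' maps runs to lines by ascending mean y.
#'
#' @inheritParams algo_chain
#' @param y_step Vertical step (pixels) that breaks a run (default 32).
#' @return Integer line assignment.
#' @export
algo_slice <- function(seq, centers, x_link = 192, y_step = 32) {
  check_algo_input(seq, centers)
  algo_merge(seq, centers, x_link = x_link, y_link = y_step)
}

# DTW over fixations (rows) and reading-order word centers (cols) with
# Euclidean cost; boundary matched first-to-first and last-to-last.
# Returns for each fixation the indices of matched words.
dtw_match <- function(fx, fy, wx, wy) {
  n <- length(fx); w <- length(wx)
  cost <- sqrt(outer(fx, wx, "-")^2 + outer(fy, wy, "-")^2)
  D <- matrix(Inf, n + 1, w + 1)
  D[1, 1] <- 0
  for (i in seq_len(n)) for (j in seq_len(w)) {
    D[i + 1, j + 1] <- cost[i, j] + min(D[i, j], D[i, j + 1], D[i + 1, j])
  }
  # backtrace; on ties prefer diagonal, then up (previous fixation), then left
  path_i <- integer(0); path_j <- integer(0)
  i <- n; j <- w
  while (i >= 1 && j >= 1) {
    path_i <- c(i, path_i); path_j <- c(j, path_j)
    if (i == 1 && j == 1) break
    opts <- c(D[i, j], D[i, j + 1], D[i + 1, j])  # diag, up, left
    valid <- c(i > 1 && j > 1, i > 1, j > 1)
    opts[!valid] <- Inf
    step <- which.min(opts)
    if (step == 1) { i <- i - 1; j <- j - 1 }
    else if (step == 2) i <- i - 1
    else j <- j - 1
  }
  split(path_j, path_i)
}

#' Warp: dynamic-time-warp alignment to the word sequence
#'
#' Aligns the chronological fixation sequence to the reading-order word
#' center sequence by dynamic time warping under Euclidean cost, with the
#' first fixation matched to the first word and the last to the last. Each
#' fixation then takes the line of its matched word(s) — the mode of the
#' matched lines, earlier word winning ties. Because the alignment is
#' order-driven rather than position-driven, warp survives distortions as
#' large as a whole line spacing, where purely positional correctors fail.
#'
#' @param seq A [fixation_seq].
#' @param words Word centers from [word_centers()].
#' @return Integer line assignment.
#' @export
algo_warp <- function(seq, words) {
  if (nrow(seq) == 0) stop("empty fixation sequence")
  if (nrow(words) == 0) stop("no words")
  matched <- dtw_match(seq$x, seq$y, words$x, words$y)
  out <- integer(nrow(seq))
  for (i in seq_len(nrow(seq))) {
    lines <- words$line[matched[[as.character(i)]]]
    tab <- table(lines)
    best <- as.integer(names(tab)[tab == max(tab)])
    out[i] <- min(best)  # earlier (smaller) line on tie
  }
  out
}

#' Split a sequence into progressive and regressive fixations
#'
#' Marks fixations that violate monotone reading order: a fixation is
#' regressive when its nearest line (by current y) lies above the furthest
#' line reached so far, or when it jumps leftward by more than one word
#' width while staying on the same nearest line. Hybrid correctors warp
#' the progressive remainder and re-insert the marked fixations.
#'
#' @inheritParams algo_attach
#' @param word_width Typical word width in pixels used for the within-line
#'   leftward-jump test (default 100).
#' @return A list with logical vector `regressive` (length of `seq`) and
#'   integer vector `progressive` (indices of unmarked fixations).
#' @export
split_regressions <- function(seq, centers, word_width = 100) {
  check_algo_input(seq, centers)
  nl <- nearest_line(seq$y, centers)
  n <- nrow(seq)
  reg <- logical(n)
  max_line <- nl[1]
  prev_prog <- 1L
  for (i in seq_len(n)[-1]) {
    if (nl[i] < max_line) {
      reg[i] <- TRUE
    } else if (nl[i] == nl[prev_prog] &&
               seq$x[i] < seq$x[prev_prog] - word_width) {
      reg[i] <- TRUE
    }
    if (!reg[i]) {
      max_line <- max(max_line, nl[i])
      prev_prog <- i
    }
  }
  list(regressive = reg, progressive = which(!reg))
}

#' Hybrid correction: warp the progressive pass, then re-fit
#'
#' Splits out regressive fixations, corrects the progressive remainder with
#' [algo_warp()] and snaps it to its assigned line centers, re-inserts the
#' regressive fixations at their original coordinates, and finally runs a
#' base algorithm on the recombined sequence to produce the full
#' assignment. The snapped progressive fixations anchor the base
#' algorithm, letting it place the regressions correctly.
#'
#' @inheritParams algo_warp
#' @param centers Line centers from [line_centers()].
#' @param base Base corrector: `"attach"`, `"chain"`, `"regress"` or
#'   `"stretch"`.
#' @param word_width Passed to [split_regressions()].
#' @return Integer line assignment.
#' @export
algo_hybrid <- function(seq, centers, words,
                        base = c("attach", "chain", "regress", "stretch"),
                        word_width = NULL) {
  base <- match.arg(base)
  check_algo_input(seq, centers)
  if (is.null(word_width)) word_width <- 100
  sp <- split_regressions(seq, centers, word_width)
  recombined <- seq
  if (length(sp$progressive) > 0) {
    prog <- seq[sp$progressive, , drop = FALSE]
    class(prog) <- class(seq)
    wa <- algo_warp(prog, words)
    recombined$y[sp$progressive] <- as.numeric(centers[wa])
  }
  base_fun <- switch(base, attach = algo_attach, chain = algo_chain,
                     regress = algo_regress, stretch = algo_stretch)
  base_fun(recombined, centers)
}

#' Available drift-correction algorithms
#'
#' @return Character vector of algorithm names accepted by
#'   [correct_fixations()].
#' @export
algorithm_names <- function() {
  c("attach", "chain", "cluster", "merge", "regress", "stretch",
    "segment", "slice", "warp",
    "warp+attach", "warp+chain", "warp+regress", "warp+stretch")
}

#' Correct vertical drift in a fixation sequence
#'
#' Single entry point over the thirteen correction algorithms. Returns the
#' line assignment and, if requested, the snapped sequence.
#'
#' @param seq A [fixation_seq].
#' @param aois The word-level [aoi_set] of the stimulus.
#' @param algorithm One of [algorithm_names()] (hybrids also accepted with
#'   `_` instead of `+`).
#' @param params Named list of per-algorithm tunables (e.g. `x_link`,
#'   `y_link`, `seed`, `slope_bounds`); unset tunables use documented
#'   defaults.
#' @param snap If `TRUE` (default) also return the corrected sequence with
#'   y snapped to assigned line centers.
#' @return A list with `assignment` (integer lines) and, when `snap`,
#'   `seq` (the corrected [fixation_seq]).
#' @examples
#' fix <- make_stimulus_fixture(n_lines = 2, words_per_line = 3)
#' g <- gen_basic(fix$aois, dispersion_sd = 2, seed = 7)
#' res <- correct_fixations(distort_offset(g$seq, 15), fix$aois, "attach")
#' drift_accuracy(res$assignment, g$truth)
#' @export
correct_fixations <- function(seq, aois, algorithm = "attach",
                              params = list(), snap = TRUE) {
  algorithm <- gsub("_", "+", tolower(algorithm))
  centers <- line_centers(aois)
  words <- word_centers(aois)
  p <- function(name, default) if (!is.null(params[[name]])) params[[name]] else default
  asg <- switch(algorithm,
    "attach" = algo_attach(seq, centers),
    "chain" = algo_chain(seq, centers, p("x_link", 192), p("y_link", 32)),
    "cluster" = algo_cluster(seq, centers, p("seed", 0), p("nstart", 10)),
    "merge" = algo_merge(seq, centers, p("x_link", 192), p("y_link", 32)),
    "regress" = algo_regress(seq, centers, p("slope_bounds", c(-0.1, 0.1)),
                             p("offset_bounds", c(-50, 50)),
                             p("sd_bounds", c(1, 20))),
    "stretch" = algo_stretch(seq, centers, p("scale_bounds", c(0.9, 1.1)),
                             p("offset_bounds", c(-50, 50))),
    "segment" = algo_segment(seq, centers),
    "slice" = algo_slice(seq, centers, p("x_link", 192), p("y_step", 32)),
    "warp" = algo_warp(seq, words),
    "warp+attach" = algo_hybrid(seq, centers, words, "attach",
                                p("word_width", mean(aois$width))),
    "warp+chain" = algo_hybrid(seq, centers, words, "chain",
                               p("word_width", mean(aois$width))),
    "warp+regress" = algo_hybrid(seq, centers, words, "regress",
                                 p("word_width", mean(aois$width))),
    "warp+stretch" = algo_hybrid(seq, centers, words, "stretch",
                                 p("word_width", mean(aois$width))),
    stop("unknown algorithm: ", algorithm)
  )
  out <- list(assignment = asg)
  if (snap) out$seq <- apply_assignment(seq, asg, centers)
  out
}
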