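# Shared fixtures and independent oracles for the test suite.

# Standard 3-line reading fixture: word boxes 20 px tall, 40 px line gap,
# so line spacing is 60 px and line centers sit at 60, 120, 180.
std_fixture <- function(n_lines = 3, words_per_line = 5, seed = 2) {
  make_stimulus_fixture(n_lines = n_lines, words_per_line = words_per_line,
                        seed = seed)
}

# Brute-force nearest line: explicit loop, independent of nearest_line().
brute_nearest_line <- function(y, centers) {
  vapply(y, function(yy) {
    d <- abs(yy - centers)
    which(d == min(d))[1]
  }, integer(1))
}

# Exhaustive DTW oracle: enumerates every monotone boundary-matched
# alignment path on small instances and returns the minimal total cost.
brute_dtw_cost <- function(fx, fy, wx, wy) {
  n <- length(fx); w <- length(wx)
  cost <- sqrt(outer(fx, wx, "-")^2 + outer(fy, wy, "-")^2)
  best <- Inf
  recurse <- function(i, j, acc) {
    acc <- acc + cost[i, j]
    if (acc >= best) return()
    if (i == n && j == w) {
      best <<- acc
      return()
    }
    if (i < n && j < w) recurse(i + 1, j + 1, acc)
    if (i < n) recurse(i + 1, j, acc)
    if (j < w) recurse(i, j + 1, acc)
  }
  recurse(1, 1, 0)
  best
}

# Total cost of the path implied by algo_warp's internal matcher.
warp_path_cost <- function(seq, words) {
  matched <- driftkit:::dtw_match(seq$x, seq$y, words$x, words$y)
  total <- 0
  for (i in seq_len(nrow(seq))) {
    js <- matched[[as.character(i)]]
    total <- total + sum(sqrt((seq$x[i] - words$x[js])^2 +
                              (seq$y[i] - words$y[js])^2))
  }
  total
}
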