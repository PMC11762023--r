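# Shared clean fixture: 3 lines x 5 words, line spacing 60 px.
fix3 <- std_fixture()
cen3 <- line_centers(fix3$aois)
words3 <- word_centers(fix3$aois)
clean3 <- gen_basic(fix3$aois, dispersion_sd = 3, seed = 7)

test_that("attach equals brute-force nearest-center on random inputs", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(1:40, 1)
    s <- fixation_seq(runif(n, 0, 800), runif(n, 0, 300), runif(n, 80, 400))
    expect_equal(algo_attach(s, cen3), brute_nearest_line(s$y, cen3))
  }
  # exact center and midway tie cases
  s <- fixation_seq(c(1, 2), c(cen3[2], mean(cen3[1:2])), c(100, 100))
  expect_equal(algo_attach(s, cen3), c(2L, 1L))
})

test_that("chain assigns a stray fixation to its chain's line", {
  # five fixations on line 1 (y = 60), one dipped to y = 92: closer to
  # line 2 (120) than line 1, so attach mis-assigns it, but it stays within
  # the chain's y-link and inherits the chain's line
  s <- fixation_seq(x = c(100, 180, 260, 340, 420),
                    y = c(60, 60, 92, 60, 60),
                    duration = rep(200, 5))
  expect_equal(algo_attach(s, cen3)[3], 2L)
  expect_equal(algo_chain(s, cen3), rep(1L, 5))
})

test_that("chain splits at large x jumps into independently assigned chains", {
  s <- fixation_seq(x = c(100, 180, 600, 680),
                    y = c(62, 58, 121, 119),
                    duration = rep(200, 4))
  expect_equal(algo_chain(s, cen3, x_link = 192), c(1L, 1L, 2L, 2L))
})

test_that("cluster maps well-separated y bands to lines top-to-bottom", {
  set.seed(3)
  y <- c(runif(10, 55, 65), runif(10, 115, 125), runif(10, 175, 185))
  s <- fixation_seq(runif(30, 0, 800), y, runif(30, 80, 300))
  expect_equal(algo_cluster(s, cen3), rep(1:3, each = 10))
  # identical points get identical assignments
  s2 <- fixation_seq(c(1, 2, 3, 4), c(60, 60, 120, 180), rep(100, 4))
  asg <- algo_cluster(s2, cen3)
  expect_equal(asg[1], asg[2])
  # single line
  one <- aoi_set("word", x = 0, y = 50, width = 50, height = 20,
                 line = 1, part = 1)
  expect_equal(algo_cluster(s2, line_centers(one)), rep(1L, 4))
})

test_that("merge fuses progressive runs and orders them by mean y", {
  g <- gen_basic(fix3$aois, dispersion_sd = 2, seed = 12)
  expect_equal(algo_merge(g$seq, cen3), g$truth)
  # single line trivial case
  one <- fixation_seq(c(1, 50), c(10, 12), c(100, 100))
  expect_equal(algo_merge(one, 11), rep(1L, 2))
})

test_that("regress recovers sloped generating lines within bounds", {
  # fixations exactly on lines y = 0.05 x + center
  set.seed(4)
  x <- rep(seq(100, 700, by = 150), 3)
  truth <- rep(1:3, each = 5)
  y <- 0.05 * x + cen3[truth]
  s <- fixation_seq(x, y, rep(200, 15))
  expect_equal(algo_regress(s, cen3), truth)
  # zero-slope clean data agrees with attach
  g <- clean3
  expect_equal(algo_regress(g$seq, cen3), algo_attach(g$seq, cen3))
})

test_that("stretch undoes a uniform offset within its search bounds", {
  d <- distort_offset(clean3$seq, 30)
  expect_equal(algo_stretch(d, cen3), clean3$truth)
  # identity distortion matches attach
  expect_equal(algo_stretch(clean3$seq, cen3), algo_attach(clean3$seq, cen3))
})

test_that("segment cuts at the largest return sweeps", {
  expect_equal(algo_segment(clean3$seq, cen3), clean3$truth)
  # monotone-y sequence of length m maps fixation i to line i
  s <- fixation_seq(c(100, 100, 100), c(50, 110, 190), rep(100, 3))
  expect_equal(algo_segment(s, cen3), 1:3)
})

test_that("slice recovers clean and shifted line-by-line data", {
  expect_equal(algo_slice(clean3$seq, cen3), clean3$truth)
  sh <- distort_shift(clean3$seq, 25)   # shift < line spacing
  expect_equal(algo_slice(sh, cen3), clean3$truth)
})

test_that("warp matches the exhaustive-path DTW oracle on small instances", {
  set.seed(21)
  for (rep in 1:10) {
    nw <- sample(3:8, 1)
    lines <- sort(rep(1:2, length.out = nw))
    parts <- stats::ave(lines, lines, FUN = seq_along)
    a <- aoi_set("word", x = seq(0, by = 80, length.out = nw),
                 y = (lines - 1) * 60, width = 60, height = 20,
                 line = lines, part = parts)
    w <- word_centers(a)
    nf <- sample(2:8, 1)
    s <- fixation_seq(runif(nf, 0, 80 * nw), runif(nf, 0, 120),
                      runif(nf, 80, 300))
    expect_equal(warp_path_cost(s, w), brute_dtw_cost(s$x, s$y, w$x, w$y))
  }
})

test_that("warp aligns one fixation per word in order despite jitter", {
  g <- gen_basic(fix3$aois, dispersion_sd = 4, seed = 5)
  expect_equal(algo_warp(g$seq, words3), g$truth)
  # single fixation, single word
  one_aoi <- aoi_set("word", 0, 40, 50, 20, 1, 1)
  expect_equal(algo_warp(fixation_seq(25, 50, 100), word_centers(one_aoi)), 1L)
})

test_that("warp survives a full line-spacing offset where attach fails", {
  d <- distort_offset(clean3$seq, 60)   # exactly one line spacing
  expect_equal(algo_warp(d, words3), clean3$truth)
  expect_lt(drift_accuracy(algo_attach(d, cen3), clean3$truth), 1)
})

test_that("split_regressions marks exactly the order-violating fixations", {
  g <- gen_basic(fix3$aois, dispersion_sd = 0, seed = 2)
  sp <- split_regressions(g$seq, cen3, word_width = mean(fix3$aois$width))
  expect_equal(sum(sp$regressive), 0)
  # one between-line regression: visit line 1 mid-way through line 2
  s <- fixation_seq(x = c(100, 300, 100, 300, 500),
                    y = c(60, 60, 120, 120, 120),
                    duration = rep(200, 5))
  s$y[4] <- 60; s$x[4] <- 150   # returns to line 1
  sp <- split_regressions(s, cen3, word_width = 80)
  expect_equal(which(sp$regressive), 4L)
  # reversal of the whole second half of a two-line read
  s2 <- fixation_seq(x = c(100, 300, 500, 500, 300, 100),
                     y = c(60, 60, 60, 120, 60, 60),
                     duration = rep(200, 6))
  sp2 <- split_regressions(s2, cen3, word_width = 80)
  expect_equal(which(sp2$regressive), 5:6)
})

test_that("hybrids equal warp when there are no regressions", {
  d <- distort_offset(clean3$seq, 20)
  wa <- algo_warp(d, words3)
  for (base in c("attach", "chain", "regress", "stretch")) {
    expect_equal(
      algo_hybrid(d, cen3, words3, base, word_width = mean(fix3$aois$width)),
      wa, info = base)
  }
})

test_that("warp+attach recovers a between-line regression under offset", {
  g <- gen_between_line_regressions(fix3$aois, 0.3, 0, seed = 8)
  d <- distort_offset(g$seq, 20)
  asg <- correct_fixations(d, fix3$aois, "warp+attach")$assignment
  expect_equal(asg, g$truth)
})

test_that("every algorithm returns in-range, length-preserving assignments", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(2:25, 1)
    s <- fixation_seq(runif(n, 0, 800), runif(n, 0, 240), runif(n, 80, 400))
    for (a in algorithm_names()) {
      asg <- correct_fixations(s, fix3$aois, a, snap = FALSE)$assignment
      expect_length(asg, n)
      expect_true(all(asg >= 1 & asg <= 3), info = a)
    }
  }
})

test_that("on clean regression-free data every algorithm is perfect", {
  g <- gen_basic(fix3$aois, dispersion_sd = 2, seed = 17)
  for (a in algorithm_names()) {
    acc <- drift_accuracy(
      correct_fixations(g$seq, fix3$aois, a, snap = FALSE)$assignment,
      g$truth)
    expect_equal(acc, 1.0, info = a)
  }
})

test_that("algorithms are deterministic with fixed seeds and params", {
  d <- distort_noise(clean3$seq, 10, seed = 3)
  for (a in algorithm_names()) {
    r1 <- correct_fixations(d, fix3$aois, a, snap = FALSE)$assignment
    r2 <- correct_fixations(d, fix3$aois, a, snap = FALSE)$assignment
    expect_identical(r1, r2, info = a)
  }
})
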