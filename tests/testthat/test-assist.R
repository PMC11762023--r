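fixA <- std_fixture()
cenA <- line_centers(fixA$aois)
genA <- gen_basic(fixA$aois, dispersion_sd = 0, seed = 7)

test_that("a session starts with one pending suggestion per fixation", {
  tr <- trial(genA$seq, fixA$aois)
  s <- start_session(tr, "attach")
  expect_equal(length(s$suggestions), nrow(genA$seq))
  expect_equal(session_progress(s), 0)
  expect_equal(s$suggestions, algo_attach(genA$seq, cenA))
  expect_equal(event_log_df(s$log)$action, "start")
  expect_error(start_session(trial(fixation_seq(), fixA$aois)), "no fixations")
  # deterministic suggestion stream
  s2 <- start_session(tr, "attach")
  expect_equal(s2$suggestions, s$suggestions)
})

test_that("accepting all suggestions reproduces the automatic correction", {
  d <- distort_offset(genA$seq, 35)
  tr <- trial(d, fixA$aois)
  for (algo in c("attach", "chain", "warp")) {
    s <- start_session(tr, algo)
    auto <- correct_fixations(d, fixA$aois, algo)
    while (!session_complete(s)) s <- session_accept(s)
    fin <- session_finalize(s)
    expect_equal(fin$assignment, auto$assignment, info = algo)
    expect_equal(fin$seq$y, auto$seq$y, info = algo)
    expect_equal(fin$seq$x, d$x, info = algo)
  }
})

test_that("accept logs the fixation index and completes on the last one", {
  tr <- trial(genA$seq, fixA$aois)
  s <- start_session(tr, "attach")
  s <- session_accept(s)
  log <- event_log_df(s$log)
  expect_equal(log$action[nrow(log)], "accept")
  expect_equal(log$index[nrow(log)], 1L)
  while (!session_complete(s)) s <- session_accept(s)
  expect_true(session_complete(s))
  expect_error(session_accept(s), "complete")
})

test_that("override pins the fixation and recomputes only the undecided", {
  d <- distort_offset(genA$seq, 35)
  tr <- trial(d, fixA$aois)
  s <- start_session(tr, "chain", params = list(y_link = 40))
  # chain mis-suggests line 2 for the first line-1 fixation
  expect_equal(current_suggestion(s), 2L)
  s2 <- session_override(s, d$x[1], cenA[1])
  expect_equal(s2$final_y[1], unname(cenA[1]))
  # the intervention propagates: next suggestion now correct
  expect_equal(current_suggestion(s2), 1L)
  # decided fixation untouched by later recomputes
  s3 <- session_override(s2, d$x[2], cenA[1])
  expect_equal(s3$final_y[1], unname(cenA[1]))
})

test_that("overriding with the suggested position equals accepting", {
  d <- distort_offset(genA$seq, 20)
  tr <- trial(d, fixA$aois)
  s <- start_session(tr, "chain")
  sug_y <- as.numeric(cenA[current_suggestion(s)])
  via_accept <- session_accept(s)
  via_override <- session_override(s, d$x[1], sug_y)
  expect_equal(via_override$suggestions, via_accept$suggestions)
  expect_equal(via_override$final_y, via_accept$final_y)
})

test_that("attach suggestions are invariant under overrides", {
  d <- distort_offset(genA$seq, 20)
  s <- start_session(trial(d, fixA$aois), "attach")
  before <- s$suggestions
  s <- session_override(s, 400, 60)
  expect_equal(s$suggestions[-1], before[-1])
})

test_that("line shortcuts move to the adjacent line and advance", {
  s <- start_session(trial(genA$seq, fixA$aois), "attach")
  # first fixation sits on line 1: line_up is a logged no-op
  n_log <- length(s$log)
  s1 <- session_line_up(s)
  expect_equal(s1$cursor, s$cursor)
  expect_equal(event_log_df(s1$log)$action[n_log + 1], "line_up_noop")
  # line_down pins to line 2 center and advances
  s2 <- session_line_down(s)
  expect_equal(s2$final_y[1], unname(cenA[2]))
  expect_equal(s2$cursor, 2L)
  expect_true(s2$decided[1])
  # line_down equals a manual override to that line
  man <- session_override(s, genA$seq$x[1], cenA[2])
  expect_equal(s2$final_y, man$final_y)
  expect_equal(s2$suggestions, man$suggestions)
})

test_that("line_jump pins to line k and ignores out-of-range keys", {
  s <- start_session(trial(genA$seq, fixA$aois), "attach")
  s1 <- session_line_jump(s, 1)
  expect_equal(s1$final_y[1], unname(cenA[1]))
  s3 <- session_line_jump(s, 3)
  expect_equal(s3$final_y[1], unname(cenA[3]))
  s4 <- session_line_jump(s, 4)   # only 3 lines: no-op, logged
  expect_false(s4$decided[1])
  expect_equal(tail(event_log_df(s4$log)$action, 1), "line_jump_noop")
})

test_that("off-stimulus overrides are accepted with a logged warning", {
  s <- start_session(trial(genA$seq, fixA$aois), "attach")
  s2 <- session_override(s, -40, 60)
  expect_true(s2$decided[1])
  expect_equal(s2$final_x[1], -40)
  expect_true("warn_offscreen" %in% event_log_df(s2$log)$action)
})

test_that("finalize requires all fixations decided and reports them", {
  s <- start_session(trial(genA$seq, fixA$aois), "attach")
  s <- session_accept(s)
  expect_error(session_finalize(s), "undecided fixations: 2")
})

test_that("the event log round-trips through JSON-lines serialization", {
  s <- start_session(trial(genA$seq, fixA$aois), "attach")
  s <- session_accept(s)
  s <- session_override(s, 123.5, 60)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_event_log(s$log, path)
  back <- read_event_log(path)
  expect_equal(back, event_log_df(s$log))
})

test_that("active time sums inter-event gaps below the cutoff", {
  log <- data.frame(time = c(0, 10, 15, 115, 120),
                    action = "accept", index = 1L, x = NA_real_, y = NA_real_)
  expect_equal(active_time(log, Inf), 120)          # last - first
  expect_equal(active_time(log, 50), 20)            # 100 s break dropped
  expect_equal(active_time(log[1, ], Inf), 0)
})

test_that("re-deciding an earlier fixation reopens all later decisions", {
  d <- distort_offset(genA$seq, 20)
  s <- start_session(trial(d, fixA$aois), "attach")
  for (i in 1:5) s <- session_accept(s)
  s <- session_back(s, 2)
  expect_equal(s$cursor, 2L)
  expect_true(all(s$decided[1:5]))      # read-only move
  s <- session_override(s, d$x[2], cenA[3])
  expect_true(s$decided[2])
  expect_false(any(s$decided[3:5]))     # reopened
  expect_true(s$decided[1])             # earlier decision kept
})

test_that("an oracle user always finishes at accuracy 1", {
  set.seed(9)
  for (case in list(
    list(algo = "attach", d = function(s) distort_offset(s, 25)),
    list(algo = "chain", d = function(s) distort_shift(s, 40)),
    list(algo = "warp", d = function(s) distort_noise(s, 12, seed = 2)),
    list(algo = "cluster", d = function(s) distort_offset(s, 70)))) {
    tr <- trial(case$d(genA$seq), fixA$aois)
    res <- run_oracle_session(tr, genA$truth, case$algo)
    expect_equal(res$accuracy, 1.0, info = case$algo)
  }
})

test_that("recompute never increases and can strictly decrease oracle work", {
  # offset slightly above half the line spacing, chain with a y-link wide
  # enough to absorb the residual: one correction per line anchors the rest
  tr <- trial(distort_offset(genA$seq, 35), fixA$aois)
  p <- list(y_link = 40)
  with_rec <- run_oracle_session(tr, genA$truth, "chain", p, recompute = TRUE)
  no_rec <- run_oracle_session(tr, genA$truth, "chain", p, recompute = FALSE)
  expect_lt(with_rec$n_override, no_rec$n_override)
  # across other algorithm/distortion combinations: never more work
  for (case in list(list(algo = "chain", seq = distort_offset(genA$seq, 35)),
                    list(algo = "warp", seq = distort_offset(genA$seq, 60)),
                    list(algo = "attach", seq = distort_offset(genA$seq, 25)))) {
    tr2 <- trial(case$seq, fixA$aois)
    a <- run_oracle_session(tr2, genA$truth, case$algo, recompute = TRUE)
    b <- run_oracle_session(tr2, genA$truth, case$algo, recompute = FALSE)
    expect_lte(a$n_override, b$n_override)
  }
})

test_that("scripted replay drives a session to the same result", {
  d <- distort_offset(genA$seq, 25)
  tr <- trial(d, fixA$aois)
  actions <- c(list(list(action = "line_jump", k = 1)),
               rep(list(list(action = "accept")), nrow(d) - 1))
  s <- replay_actions(start_session(tr, "attach"), actions)
  expect_true(session_complete(s))
  fin <- session_finalize(s)
  expect_equal(fin$assignment[1], 1L)
})
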