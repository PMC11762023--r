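#' Step clock for deterministic session timestamps
#'
#' Sessions timestamp every interaction through an injected clock function.
#' The default is a monotone counter (1, 2, 3, ...) so that replayed
#' sessions are bit-reproducible; pass
#' `function() as.numeric(Sys.time())` for wall-clock timestamps.
#'
#' @param start First timestamp.
#' @param step Increment per call.
#' @return A zero-argument function returning the next timestamp.
#' @export
make_step_clock <- function(start = 0, step = 1) {
  t <- start - step
  function() {
    t <<- t + step
    t
  }
}

log_event <- function(session, action, index = NA_integer_, payload = NULL) {
  rec <- list(time = session$clock(), action = action, index = index,
              payload = payload)
  session$log[[length(session$log) + 1]] <- rec
  session
}

#' Start an assisted-correction session
#'
#' Assisted correction walks the fixations of a trial one at a time in
#' chronological order. At each step the selected automatic algorithm
#' supplies a suggested line for the current fixation; the user accepts it
#' ([session_accept()]) or intervenes ([session_override()],
#' [session_line_up()], [session_line_down()], [session_line_jump()]).
#' After every intervention (but not after an accept, which adds no new
#' information) the algorithm is re-run on a copy of the sequence in which
#' all decided fixations carry their decided coordinates, so the user's
#' corrections propagate into better suggestions for the remaining
#' fixations. Decided fixations are never altered by a recompute.
#'
#' All session operations are pure: they return an updated session.
#'
#' @param tr A [trial()].
#' @param algorithm Algorithm name, see [algorithm_names()].
#' @param params Algorithm tunables, as in [correct_fixations()].
#' @param clock Timestamp source, see [make_step_clock()].
#' @param recompute Re-run the algorithm after interventions (default
#'   TRUE; FALSE gives the static-suggestion ablation).
#' @return A `correction_session` object.
#' @export
start_session <- function(tr, algorithm = "attach", params = list(),
                          clock = make_step_clock(), recompute = TRUE) {
  if (nrow(tr$seq) == 0) stop("trial has no fixations")
  if (nrow(tr$aois) == 0) stop("trial has no AOIs")
  centers <- line_centers(tr$aois)
  session <- structure(list(
    trial = tr, algorithm = algorithm, params = params,
    centers = centers, cursor = 1L,
    decided = rep(FALSE, nrow(tr$seq)),
    final_x = tr$seq$x, final_y = tr$seq$y,
    action = rep(NA_character_, nrow(tr$seq)),
    suggestions = integer(nrow(tr$seq)),
    log = list(), clock = clock, recompute = recompute
  ), class = "correction_session")
  session$suggestions <- run_algo(session)
  log_event(session, "start")
}

#' @export
print.correction_session <- function(x, ...) {
  cat(sprintf("Assisted correction session (%s): %d/%d fixations decided\n",
              x$algorithm, sum(x$decided), length(x$decided)))
  invisible(x)
}

# Run the session's algorithm on the coordinate-substituted sequence:
# decided fixations at their decided coordinates, the rest as recorded.
run_algo <- function(session) {
  seq2 <- session$trial$seq
  seq2$x <- session$final_x
  seq2$y <- session$final_y
  correct_fixations(seq2, session$trial$aois, session$algorithm,
                    session$params, snap = FALSE)$assignment
}

#' Session state accessors
#'
#' @param session A `correction_session`.
#' @return `session_complete()`: logical; `session_progress()`: fraction
#'   of decided fixations; `current_suggestion()`: the suggested 1-based
#'   line for the fixation at the cursor.
#' @export
session_complete <- function(session) all(session$decided)

#' @rdname session_complete
#' @export
session_progress <- function(session) mean(session$decided)

#' @rdname session_complete
#' @export
current_suggestion <- function(session) {
  if (session_complete(session)) stop("session is complete")
  session$suggestions[session$cursor]
}

advance_cursor <- function(session) {
  remaining <- which(!session$decided)
  session$cursor <- if (length(remaining) > 0) remaining[1]
    else length(session$decided)
  session
}

# Pin the current fixation at (x, y), log the given action, advance, and
# recompute suggestions for the undecided remainder if this was an
# intervention and recompute is enabled. Deciding a fixation that sits
# before already-decided ones (after back-navigation) reopens all later
# decisions.
decide_current <- function(session, x, y, action, intervention) {
  if (session_complete(session)) stop("session is complete")
  i <- session$cursor
  later <- which(session$decided & seq_along(session$decided) > i)
  if (length(later) > 0) {     # re-decision: reopen everything after i
    session$decided[later] <- FALSE
    session$final_x[later] <- session$trial$seq$x[later]
    session$final_y[later] <- session$trial$seq$y[later]
    session$action[later] <- NA_character_
  }
  sw <- attr(session$trial$aois, "screen_width")
  sh <- attr(session$trial$aois, "screen_height")
  if (!is.na(sw) && !is.na(sh) &&
      (x < 0 || x >= sw || y < 0 || y >= sh))
    session <- log_event(session, "warn_offscreen", i, list(x = x, y = y))
  session$decided[i] <- TRUE
  session$final_x[i] <- x
  session$final_y[i] <- y
  session$action[i] <- action
  session <- log_event(session, action, i, list(x = x, y = y))
  session <- advance_cursor(session)
  if (intervention && session$recompute && !session_complete(session)) {
    asg <- run_algo(session)
    undecided <- !session$decided
    session$suggestions[undecided] <- asg[undecided]
  }
  session
}

#' Accept the current suggestion
#'
#' Snaps the current fixation to its suggested line center (x unchanged)
#' and advances. No recompute: the suggestion came from the algorithm, so
#' accepting it adds no information.
#'
#' @param session A `correction_session`.
#' @return The updated session.
#' @export
session_accept <- function(session) {
  sug <- current_suggestion(session)
  decide_current(session, session$final_x[session$cursor],
                 as.numeric(session$centers[sug]), "accept",
                 intervention = FALSE)
}

#' Override the current suggestion with a manual position
#'
#' Pins the current fixation at the given coordinates (the drag-and-drop
#' equivalent), advances, and re-runs the algorithm on the corrected
#' sequence so the intervention improves the remaining suggestions.
#' Off-stimulus coordinates are accepted with a logged warning (a margin
#' may be intended).
#'
#' @inheritParams session_accept
#' @param x,y New pixel coordinates of the current fixation.
#' @return The updated session.
#' @export
session_override <- function(session, x, y) {
  if (session_complete(session)) stop("session is complete")
  decide_current(session, x, y, "override", intervention = TRUE)
}

line_step <- function(session, delta, action) {
  if (session_complete(session)) stop("session is complete")
  i <- session$cursor
  cur <- nearest_line(session$final_y[i], session$centers)
  target <- cur + delta
  if (target < 1 || target > length(session$centers))
    return(advance_none(log_event(session, paste0(action, "_noop"), i)))
  decide_current(session, session$final_x[i],
                 as.numeric(session$centers[target]), action,
                 intervention = TRUE)
}

advance_none <- function(session) session  # no-op keeps cursor in place

#' Keyboard line shortcuts
#'
#' `session_line_up()` / `session_line_down()` pin the current fixation to
#' the center of the line immediately above / below its current nearest
#' line (the 'a' / 'z' keys); `session_line_jump()` pins it to line `k`
#' (the 1-9 keys; usable when the trial has at most nine lines). All
#' three apply the correction, advance to the next fixation, and trigger a
#' recompute. When no such line exists the call is a logged no-op.
#'
#' @inheritParams session_accept
#' @param k Target 1-based line number (1-9).
#' @return The updated session.
#' @export
session_line_up <- function(session) line_step(session, -1L, "line_up")

#' @rdname session_line_up
#' @export
session_line_down <- function(session) line_step(session, 1L, "line_down")

#' @rdname session_line_up
#' @export
session_line_jump <- function(session, k) {
  if (session_complete(session)) stop("session is complete")
  i <- session$cursor
  if (k < 1 || k > length(session$centers))
    return(advance_none(log_event(session, "line_jump_noop", i)))
  decide_current(session, session$final_x[i],
                 as.numeric(session$centers[k]), "line_jump",
                 intervention = TRUE)
}

#' Move the cursor back to an earlier fixation
#'
#' Read-only navigation: the decision record is untouched until the user
#' actually re-decides the fixation, at which point all later decisions
#' are reopened and suggestions recomputed once.
#'
#' @inheritParams session_accept
#' @param index 1-based fixation index to move to.
#' @return The updated session.
#' @export
session_back <- function(session, index) {
  if (index < 1 || index > length(session$decided))
    stop("index out of range")
  session$cursor <- as.integer(index)
  log_event(session, "back", index)
}

#' Finalize a session
#'
#' @inheritParams session_accept
#' @return A list with `seq` (the corrected [fixation_seq]), `assignment`
#'   (1-based final line per fixation), and `log` (the event log as a
#'   data.frame, see [event_log_df()]).
#' @export
session_finalize <- function(session) {
  undecided <- which(!session$decided)
  if (length(undecided) > 0)
    stop("undecided fixations: ", paste(undecided, collapse = ", "))
  session <- log_event(session, "finish")
  seq <- fixation_seq(session$final_x, session$final_y,
                      session$trial$seq$duration)
  list(seq = seq,
       assignment = nearest_line(session$final_y, session$centers),
       log = event_log_df(session$log))
}

#' Event log as a data.frame / JSON lines
#'
#' Every interaction is timestamped and appended to the session log. The
#' log converts losslessly to a data.frame and serializes to JSON lines.
#'
#' @param log The `log` field of a session, or a finalized log.
#' @return `event_log_df()`: data.frame with columns `time`, `action`,
#'   `index`, `x`, `y`.
#' @export
event_log_df <- function(log) {
  if (is.data.frame(log)) return(log)
  data.frame(
    time = vapply(log, function(r) r$time, numeric(1)),
    action = vapply(log, function(r) r$action, character(1)),
    index = vapply(log, function(r) as.integer(r$index), integer(1)),
    x = vapply(log, function(r)
      if (is.null(r$payload$x)) NA_real_ else r$payload$x, numeric(1)),
    y = vapply(log, function(r)
      if (is.null(r$payload$y)) NA_real_ else r$payload$y, numeric(1)),
    stringsAsFactors = FALSE)
}

#' @rdname event_log_df
#' @param path Output / input path for JSON-lines serialization.
#' @export
write_event_log <- function(log, path) {
  df <- event_log_df(log)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(df)))
    writeLines(jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE,
                                digits = NA, na = "null"), con)
  invisible(path)
}

#' @rdname event_log_df
#' @export
read_event_log <- function(path) {
  lines <- readLines(path)
  field <- function(obj, name, cast) {
    v <- obj[[name]]
    if (is.null(v)) cast(NA) else cast(v)
  }
  rows <- lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln)
    data.frame(time = field(obj, "time", as.numeric),
               action = field(obj, "action", as.character),
               index = field(obj, "index", as.integer),
               x = field(obj, "x", as.numeric),
               y = field(obj, "y", as.numeric),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Active correction time from an event log
#'
#' Total time between the first and last logged event, excluding
#' inactivity gaps: inter-event intervals strictly longer than
#' `gap_cutoff` are dropped (breaks the user took). With an infinite
#' cutoff this equals last minus first timestamp.
#'
#' @param log Event log (list or data.frame).
#' @param gap_cutoff Inactivity cutoff in the log's time unit (default
#'   `Inf`).
#' @return Active time in the log's time unit.
#' @export
active_time <- function(log, gap_cutoff = Inf) {
  df <- event_log_df(log)
  if (nrow(df) < 2) return(0)
  gaps <- diff(sort(df$time))
  sum(gaps[gaps <= gap_cutoff])
}

#' Replay a scripted action sequence on a session
#'
#' Non-interactive driver used for testing and batch experiments: each
#' action is a list with an `action` field (`"accept"`, `"override"`,
#' `"line_up"`, `"line_down"`, `"line_jump"`, `"back"`) and the fields
#' that action needs (`x`, `y`, `k`, `index`).
#'
#' @param session A `correction_session`.
#' @param actions List of action records.
#' @return The session after all actions.
#' @export
replay_actions <- function(session, actions) {
  for (a in actions) {
    session <- switch(a$action,
      accept = session_accept(session),
      override = session_override(session, a$x, a$y),
      line_up = session_line_up(session),
      line_down = session_line_down(session),
      line_jump = session_line_jump(session, a$k),
      back = session_back(session, a$index),
      stop("unknown action: ", a$action))
  }
  session
}

#' Simulate an oracle user over a whole session
#'
#' The oracle user knows the ground-truth line of every fixation: it
#' accepts a suggestion when it matches the truth and otherwise overrides
#' the fixation to the truth line's center. Running it measures how much
#' manual work an algorithm leaves for a perfectly informed corrector —
#' and, by comparing `recompute = TRUE` against `FALSE`, how much the
#' recompute-on-intervention collaboration saves.
#'
#' @param tr A [trial()].
#' @param truth Ground-truth 1-based line per fixation.
#' @param algorithm,params As in [start_session()].
#' @param recompute Recompute suggestions after interventions.
#' @return A list with `accuracy` (vs truth, always 1 by construction),
#'   `n_override`, `n_accept`, and the finalized `result`.
#' @export
run_oracle_session <- function(tr, truth, algorithm = "attach",
                               params = list(), recompute = TRUE) {
  session <- start_session(tr, algorithm, params, recompute = recompute)
  n_override <- 0L
  while (!session_complete(session)) {
    i <- session$cursor
    if (current_suggestion(session) == truth[i]) {
      session <- session_accept(session)
    } else {
      n_override <- n_override + 1L
      session <- session_override(session, session$final_x[i],
                                  as.numeric(session$centers[truth[i]]))
    }
  }
  res <- session_finalize(session)
  list(accuracy = drift_accuracy(res$assignment, truth),
       n_override = n_override,
       n_accept = length(truth) - n_override,
       result = res)
}
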