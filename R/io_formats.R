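#' Read an EyeLink ASCII (.asc) export
#'
#' Parses fixation (`EFIX`), saccade (`ESACC`) and blink (`EBLINK`) event
#' lines from an EyeLink ASCII export and groups them into trials using a
#' configurable message pattern: a `MSG` line matching `trial_start` opens
#' a trial, which runs until the next match or end of file. Lines that
#' parse as neither an event nor a marker are skipped and counted.
#'
#' `EFIX` lines carry start/end timestamps, duration, x, y and pupil size;
#' `ESACC` lines carry start/end coordinates, amplitude and peak velocity
#' (the end coordinates are reported as the event's x, y); `EBLINK` lines
#' carry timestamps only. In binocular files the `eye` argument selects
#' the eye (default: first eye encountered).
#'
#' @param path Path to the `.asc` file.
#' @param trial_start Regular expression on `MSG` text that opens a trial
#'   (default `"TRIALID"`).
#' @param eye `"auto"` (first eye seen), `"L"` or `"R"`.
#' @return A list of trials; each trial is a list with `id` (the matched
#'   message text) and `events`, a data.frame with columns `timestamp`,
#'   `kind` (fixation/saccade/blink), `x`, `y`, `duration`, `pupil`,
#'   `amplitude`, `peak_velocity`. The attribute `skipped_lines` counts
#'   unparsed non-blank lines.
#' @export
read_asc <- function(path, trial_start = "TRIALID", eye = c("auto", "L", "R")) {
  eye <- match.arg(eye)
  lines <- readLines(path, warn = FALSE)
  trials <- list()
  cur <- NULL
  cur_id <- NULL
  skipped <- 0L
  chosen_eye <- if (eye == "auto") NULL else eye
  flush <- function() {
    if (!is.null(cur_id)) {
      df <- if (length(cur) > 0) do.call(rbind, cur) else empty_events()
      rownames(df) <- NULL
      trials[[length(trials) + 1]] <<- list(id = cur_id, events = df)
    }
    cur <<- list(); cur_id <<- NULL
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "") next
    tok <- strsplit(ln, "[ \t]+")[[1]]
    if (tok[1] == "MSG") {
      msg <- paste(tok[-(1:2)], collapse = " ")
      if (grepl(trial_start, msg)) {
        flush()
        cur_id <- msg
      }
      next
    }
    ev <- parse_asc_event(tok)
    if (is.null(ev)) {
      if (!tok[1] %in% c("SFIX", "SSACC", "SBLINK", "START", "END",
                         "SAMPLES", "EVENTS", "INPUT", "**"))
        skipped <- skipped + 1L
      next
    }
    if (is.null(chosen_eye)) chosen_eye <- ev$eye
    if (ev$eye != chosen_eye) next
    if (!is.null(cur_id)) cur[[length(cur) + 1]] <- ev$row
  }
  flush()
  if (length(trials) == 0)
    stop("no trials found: no MSG line matched pattern '", trial_start, "'")
  attr(trials, "skipped_lines") <- skipped
  trials
}

empty_events <- function() {
  data.frame(timestamp = numeric(0), kind = character(0), x = numeric(0),
             y = numeric(0), duration = numeric(0), pupil = numeric(0),
             amplitude = numeric(0), peak_velocity = numeric(0),
             stringsAsFactors = FALSE)
}

num <- function(s) suppressWarnings(as.numeric(s))

# One EFIX/ESACC/EBLINK line -> list(eye, row) or NULL.
parse_asc_event <- function(tok) {
  make_row <- function(timestamp, kind, x = NA, y = NA, duration = NA,
                       pupil = NA, amplitude = NA, peak_velocity = NA) {
    data.frame(timestamp = timestamp, kind = kind, x = x, y = y,
               duration = duration, pupil = pupil, amplitude = amplitude,
               peak_velocity = peak_velocity, stringsAsFactors = FALSE)
  }
  if (tok[1] == "EFIX" && length(tok) >= 8) {
    row <- make_row(num(tok[3]), "fixation", x = num(tok[6]), y = num(tok[7]),
                    duration = num(tok[5]), pupil = num(tok[8]))
    if (anyNA(row[c("timestamp", "x", "y", "duration")])) return(NULL)
    list(eye = tok[2], row = row)
  } else if (tok[1] == "ESACC" && length(tok) >= 11) {
    row <- make_row(num(tok[3]), "saccade", x = num(tok[8]), y = num(tok[9]),
                    duration = num(tok[5]), amplitude = num(tok[10]),
                    peak_velocity = num(tok[11]))
    if (is.na(row$timestamp)) return(NULL)
    list(eye = tok[2], row = row)
  } else if (tok[1] == "EBLINK" && length(tok) >= 5) {
    row <- make_row(num(tok[3]), "blink", duration = num(tok[5]))
    if (is.na(row$timestamp)) return(NULL)
    list(eye = tok[2], row = row)
  } else NULL
}

#' Convert parsed events to the 8-column CSV dialect
#'
#' Writes (or returns) all events of one trial — fixations, saccades and
#' blinks — with the full information of the ASCII file: timestamp, event
#' kind, x, y, duration, pupil, saccade amplitude and peak velocity.
#'
#' @param events Event data.frame from [read_asc()].
#' @param path Optional output CSV path.
#' @return The data.frame (invisibly if written to `path`).
#' @export
asc_to_csv <- function(events, path = NULL) {
  df <- events[, c("timestamp", "kind", "x", "y", "duration", "pupil",
                   "amplitude", "peak_velocity")]
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Convert parsed events to the minimal JSON trial representation
#'
#' Keeps only fixations, as an ordered list of `[x, y, duration]` triples.
#'
#' @inheritParams asc_to_csv
#' @param path Optional output JSON path.
#' @return A list with element `fixations` (written as JSON if `path`
#'   given).
#' @export
asc_to_json <- function(events, path = NULL) {
  fx <- events[events$kind == "fixation", , drop = FALSE]
  obj <- list(fixations = unname(
    lapply(seq_len(nrow(fx)),
           function(i) c(fx$x[i], fx$y[i], fx$duration[i]))))
  if (!is.null(path)) write_trial_json_obj(obj, path)
  obj
}

#' Read a trial from the minimal JSON dialect
#'
#' The only requirement on the file is a top-level `"fixations"` key
#' holding an ordered list of `[x, y, duration]` triples. Any other
#' top-level keys (participant id, trial number, timestamps, ...) are
#' preserved verbatim and travel through [write_trial_json()] untouched,
#' so enriched files need no schema changes.
#'
#' @param path JSON path.
#' @return A list with `seq` (a [fixation_seq]) and `extra` (named list of
#'   all other top-level keys, unmodified).
#' @export
read_trial_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$fixations))
    stop("missing 'fixations' list in ", path)
  fx <- obj$fixations
  for (i in seq_along(fx)) {
    if (length(fx[[i]]) != 3)
      stop("fixation ", i, " is not an [x, y, duration] triple")
  }
  seq <- fixation_seq(
    vapply(fx, function(t) as.numeric(t[[1]]), numeric(1)),
    vapply(fx, function(t) as.numeric(t[[2]]), numeric(1)),
    vapply(fx, function(t) as.numeric(t[[3]]), numeric(1)))
  list(seq = seq, extra = obj[setdiff(names(obj), "fixations")])
}

#' Write a trial to the minimal JSON dialect
#'
#' @param seq A [fixation_seq].
#' @param path Output path.
#' @param extra Named list of additional top-level keys to carry along
#'   (round-trips from [read_trial_json()]).
#' @return `path`, invisibly.
#' @export
write_trial_json <- function(seq, path, extra = list()) {
  obj <- c(list(fixations = unname(
    lapply(seq_len(nrow(seq)),
           function(i) c(seq$x[i], seq$y[i], seq$duration[i])))),
    extra)
  write_trial_json_obj(obj, path)
}

write_trial_json_obj <- function(obj, path) {
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read / write a fixation sequence as CSV
#'
#' Three-column (`x`, `y`, `duration`) CSV interchange for fixation
#' sequences.
#'
#' @param path CSV path.
#' @return [read_fixations_csv()] returns a [fixation_seq];
#'   [write_fixations_csv()] returns `path` invisibly.
#' @export
read_fixations_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("x", "y", "duration") %in% names(df)))
    stop("fixation CSV must have columns x, y, duration")
  fixation_seq(df$x, df$y, df$duration)
}

#' @rdname read_fixations_csv
#' @param seq A [fixation_seq].
#' @export
write_fixations_csv <- function(seq, path) {
  utils::write.csv(as.data.frame(seq)[, c("x", "y", "duration")], path,
                   row.names = FALSE)
  invisible(path)
}
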