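# JSON-lines serialization of traces and decoded configuration
# sequences.  One event per line; schema:
#   {"event":"step-executed","name":...,"step_id"?,"params":{...}}
#   {"event":"step-skipped","name":...,"condition":...,"value":false}
#   {"event":"measurement","step_id":...,"vessel":...,"quantity":...,
#    "raw":...,"result":...}
#   {"event":"loop-iteration","index":n}
#   {"event":"halt","reason":"completed"|"cap"|"error","message"?}

#' Write an execution trace as JSON lines
#'
#' @param trace an [ExecutionTrace-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [readTrace()]
#' @export
writeTrace <- function(trace, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  for (ev in trace@events)
    writeLines(jsonlite::toJSON(ev, auto_unbox = TRUE, digits = NA,
                                null = "null"), con)
  invisible(path)
}

#' Read an execution trace from JSON lines
#'
#' Inverse of [writeTrace()]: the reloaded trace compares equal to the
#' one written (the status is recovered from the final halt event).
#'
#' @param path path to a JSON-lines trace file.
#' @return an [ExecutionTrace-class].
#' @export
readTrace <- function(path) {
  lines <- readLines(path)
  events <- lapply(lines, function(l)
    jsonlite::fromJSON(l, simplifyVector = FALSE))
  status <- "completed"
  if (length(events)) {
    last <- events[[length(events)]]
    if (identical(last$event, "halt")) status <- last$reason
  }
  new("ExecutionTrace", events = events, status = status)
}

#' Write a decoded configuration sequence as JSON lines
#'
#' One line per iteration: `{"iteration": i, "state": ..., "head": ...,
#' "tape": "01111110"}` with iteration 0 the starting configuration.
#'
#' @param configs a list of [TMConfiguration-class] (e.g. from
#'   [runCompiled()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [readDecoded()]
#' @export
writeDecoded <- function(configs, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  for (i in seq_along(configs)) {
    c <- configs[[i]]
    writeLines(jsonlite::toJSON(
      list(iteration = i - 1L, state = c@state, head = c@head,
           tape = tapeString(c)),
      auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read a decoded configuration sequence from JSON lines
#'
#' @param path path written by [writeDecoded()].
#' @return a list of [TMConfiguration-class] in iteration order.
#' @export
readDecoded <- function(path) {
  lapply(readLines(path), function(l) {
    j <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    tmConfiguration(j$tape, head = j$head, state = j$state)
  })
}
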