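# Reference Turing-machine interpreter: the independent oracle against
# which compiled-and-executed procedures are checked.

.overrunError <- function(head) {
  structure(
    class = c("chemturing_overrun", "error", "condition"),
    list(message = sprintf("tape overrun: head moved to position %d", head),
         call = NULL)
  )
}

#' Construct a Turing machine from a transition table
#'
#' @param table a data.frame (or list of rows) with columns `state`,
#'   `read`, `write`, `move` (`"L"`/`"R"`) and `next`; must be total over
#'   (states minus HALT) x alphabet, with no rules out of `"HALT"`.
#' @param initial the start state.
#' @param blank the blank symbol, default `"0"`.
#' @param states optional explicit state order (`"HALT"` is appended
#'   last if missing); defaults to order of first appearance in the
#'   table, which also fixes the state-vial color coding downstream.
#' @param alphabet optional explicit symbol order (blank first by
#'   default).
#' @return a validated [TuringMachine-class].
#' @examples
#' bb <- busyBeaverMachine()
#' transitionTable(bb)
#' @export
turingMachine <- function(table, initial, blank = "0",
                          states = NULL, alphabet = NULL) {
  if (!is.data.frame(table))
    table <- do.call(rbind, lapply(table, function(r)
      data.frame(state = r$state, read = r$read, write = r$write,
                 move = r$move, "next" = r[["next"]],
                 check.names = FALSE, stringsAsFactors = FALSE)))
  table <- as.data.frame(lapply(table, as.character),
                         check.names = FALSE, stringsAsFactors = FALSE)
  if (is.null(states)) {
    seen <- unique(c(initial, table$state, table[["next"]]))
    states <- c(setdiff(seen, "HALT"), "HALT")
  } else if (!"HALT" %in% states) {
    states <- c(states, "HALT")
  }
  if (is.null(alphabet))
    alphabet <- unique(c(blank, table$read, table$write))
  obj <- new("TuringMachine", states = states, alphabet = alphabet,
             blank = blank, initial = initial, table = table)
  validObject(obj)
  obj
}

#' Construct a tape configuration
#'
#' @param tape a character vector of symbols, or a single string that is
#'   split into single-character symbols (e.g. `"101x0011"`).
#' @param head 1-based head position.
#' @param state current state.
#' @return a validated [TMConfiguration-class].
#' @examples
#' tmConfiguration("101x0011", head = 1, state = "Z1")
#' @export
tmConfiguration <- function(tape, head, state) {
  if (length(tape) == 1L && nchar(tape) > 1L)
    tape <- strsplit(tape, "")[[1L]]
  obj <- new("TMConfiguration", tape = as.character(tape),
             head = as.integer(head), state = as.character(state))
  validObject(obj)
  obj
}

.ruleIndex <- function(machine) {
  tb <- machine@table
  stats::setNames(seq_len(nrow(tb)), paste(tb$state, tb$read, sep = "\x01"))
}

#' Advance a Turing machine by one step
#'
#' Looks up the rule for (current state, symbol under the head), writes
#' the rule's symbol, moves the head one cell left or right, and adopts
#' the next state.  A pure function: the input configuration is
#' unchanged.  Stepping a halted configuration or moving the head off
#' the finite tape is an error.
#'
#' @param machine a [TuringMachine-class].
#' @param config a [TMConfiguration-class] with `state != "HALT"`.
#' @return the successor [TMConfiguration-class].
#' @export
tmStep <- function(machine, config) {
  if (config@state == "HALT")
    stop(.runtimeError("cannot step a halted configuration"))
  idx <- .ruleIndex(machine)
  .tmStepFast(machine@table, idx, config)
}

.tmStepFast <- function(tb, idx, config) {
  key <- paste(config@state, config@tape[config@head], sep = "\x01")
  i <- idx[[key]]
  if (is.null(i) || is.na(i))
    stop(.runtimeError(sprintf("no rule for (state %s, symbol %s)",
                               config@state, config@tape[config@head])))
  tape <- config@tape
  tape[config@head] <- tb$write[i]
  head <- config@head + if (tb$move[i] == "R") 1L else -1L
  if (head < 1L || head > length(tape)) stop(.overrunError(head))
  new("TMConfiguration", tape = tape, head = head, state = tb[["next"]][i])
}

#' Run a Turing machine until it halts or a step budget is spent
#'
#' Iterates [tmStep()] until the state becomes `"HALT"` or `maxSteps`
#' steps have been taken.  Tape overruns propagate as errors.
#'
#' @param machine a [TuringMachine-class].
#' @param config the starting [TMConfiguration-class].
#' @param maxSteps step budget (default 10000).
#' @return a list with `config` (final configuration), `halted`
#'   (logical) and `steps` (count taken).
#' @examples
#' bb <- busyBeaverMachine()
#' res <- tmRun(bb, tmConfiguration(rep("0", 8), head = 3, state = "A"))
#' tapeString(res$config)  # "01111110"
#' @export
tmRun <- function(machine, config, maxSteps = 10000L) {
  stopifnot(maxSteps >= 0L)
  idx <- .ruleIndex(machine)
  steps <- 0L
  while (config@state != "HALT" && steps < maxSteps) {
    config <- .tmStepFast(machine@table, idx, config)
    steps <- steps + 1L
  }
  list(config = config, halted = config@state == "HALT", steps = steps)
}

#' Full trajectory of a bounded run
#'
#' Like [tmRun()] but records every intermediate configuration and
#' reports how the run ended, converting a tape overrun into a status
#' rather than an error — the form needed to compare against a compiled
#' run on the platform.
#'
#' @inheritParams tmRun
#' @return a list with `configs` (list of [TMConfiguration-class],
#'   starting configuration first), `status` (`"halted"`, `"cap"` or
#'   `"overrun"`) and `steps`.
#' @export
tmTrajectory <- function(machine, config, maxSteps = 10000L) {
  idx <- .ruleIndex(machine)
  configs <- vector("list", 16L)
  configs[[1L]] <- config
  n <- 1L
  status <- "cap"
  steps <- 0L
  while (steps < maxSteps) {
    if (config@state == "HALT") { status <- "halted"; break }
    config <- tryCatch(.tmStepFast(machine@table, idx, config),
                       chemturing_overrun = function(e) e)
    if (inherits(config, "chemturing_overrun")) { status <- "overrun"; break }
    steps <- steps + 1L
    n <- n + 1L
    if (n > length(configs)) length(configs) <- 2L * length(configs)
    configs[[n]] <- config
  }
  if (status == "cap" && configs[[n]]@state == "HALT") status <- "halted"
  list(configs = configs[seq_len(n)], status = status, steps = steps)
}

#' Longest run of a symbol on a tape
#'
#' The Busy Beaver score of a halting tape is the longest run of
#' `"1"`-symbols it carries.
#'
#' @param tape a character vector of symbols or a single tape string.
#' @param symbol the symbol to count, default `"1"`.
#' @return integer length of the longest consecutive run.
#' @examples
#' countMaxConsecutive("01111110")  # 6
#' @export
countMaxConsecutive <- function(tape, symbol = "1") {
  if (length(tape) == 1L && nchar(tape) > 1L)
    tape <- strsplit(tape, "")[[1L]]
  stopifnot(length(tape) >= 1L)
  best <- 0L
  run <- 0L
  for (s in tape) {
    if (identical(s, symbol)) {
      run <- run + 1L
      if (run > best) best <- run
    } else run <- 0L
  }
  best
}

#' Read or write a transition table file
#'
#' JSON schema:
#' `{states, alphabet, blank, initial, rules: [{state, read, write,
#' move, next}]}`.
#'
#' @param path path to a JSON transition-table file.
#' @return `readTransitionTable` returns a [TuringMachine-class].
#' @export
readTransitionTable <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  turingMachine(j$rules, initial = j$initial, blank = j$blank,
                states = j$states, alphabet = j$alphabet)
}

#' @rdname readTransitionTable
#' @param machine a [TuringMachine-class] to serialize.
#' @return `writeTransitionTable` returns `path` invisibly.
#' @export
writeTransitionTable <- function(machine, path) {
  out <- list(states = machine@states, alphabet = machine@alphabet,
              blank = machine@blank, initial = machine@initial,
              rules = machine@table)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
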