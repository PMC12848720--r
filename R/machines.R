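# Shipped machines: the 3-state Busy Beaver and the 3-bit binary adder,
# plus a seeded random-machine generator for property sweeps.

.rule <- function(state, read, write, move, nxt) {
  data.frame(state = state, read = read, write = write, move = move,
             "next" = nxt, check.names = FALSE, stringsAsFactors = FALSE)
}

#' The 3-state Busy Beaver machine
#'
#' A 3-state, 2-symbol machine (states A, B, C plus HALT) that, started
#' on a blank 8-cell tape with the head at position 3 in state A, halts
#' after 14 steps with tape `01111110` — six consecutive ones, the
#' classic witness that the Busy Beaver score satisfies Sigma(3) >= 6.
#'
#' @return a [TuringMachine-class].
#' @examples
#' bb <- busyBeaverMachine()
#' res <- tmRun(bb, tmConfiguration(rep("0", 8), head = 3, state = "A"))
#' countMaxConsecutive(res$config@tape)  # 6
#' @export
busyBeaverMachine <- function() {
  tb <- rbind(
    .rule("A", "0", "1", "R", "B"),
    .rule("A", "1", "1", "R", "HALT"),
    .rule("B", "0", "0", "R", "C"),
    .rule("B", "1", "1", "R", "B"),
    .rule("C", "0", "1", "L", "C"),
    .rule("C", "1", "1", "L", "A")
  )
  turingMachine(tb, initial = "A", blank = "0",
                states = c("A", "B", "C", "HALT"), alphabet = c("0", "1"))
}

#' Starting configuration of the Busy Beaver experiment
#'
#' Blank 8-cell tape, head at position 3, state A.
#'
#' @param tapeLength tape length, default 8.
#' @return a [TMConfiguration-class].
#' @export
busyBeaverConfiguration <- function(tapeLength = 8L) {
  tmConfiguration(rep("0", tapeLength), head = 3L, state = "A")
}

#' The 3-bit binary adder machine
#'
#' A machine over the alphabet `{0, 1, x, y}` operating on the fixed
#' 8-cell layout `abc x 0def`: a 3-bit number `abc` in cells 1-3, the
#' separator `x` in cell 4 and a 4-bit accumulator in cells 5-8 holding
#' `0def`.  It repeatedly decrements the left number and increments the
#' accumulator until the left field is zero, then overwrites the
#' separator with `0` and halts, leaving the 4-bit binary sum in cells
#' 5-8 (so `101x0011` becomes `00001000`, i.e. 5 + 3 = 8).
#'
#' Because the layout is fixed, the machine locates the two fields with
#' fixed-offset states rather than marker symbols; the `y` symbol is
#' never written, and its rules (required for a total table) are inert.
#' The start is head position 1 in state `Z1` (the zero-check scan).
#'
#' @return a [TuringMachine-class].
#' @examples
#' add <- binaryAdderMachine()
#' res <- tmRun(add, adderConfiguration(5, 3))
#' tapeString(res$config)  # "00001000"
#' @export
binaryAdderMachine <- function() {
  states <- c("Z1", "Z2", "Z3", "GR", "DEC", "W1", "R1", "R2", "R3",
              "INC", "RET", "L1", "L2", "FIN")
  # inert filler for unreachable (state, symbol) pairs, to keep the
  # table total
  inert <- function(s, a) .rule(s, a, a, "R", "HALT")
  tb <- rbind(
    # Z1..Z3: scan cells 1-3; all zero -> FIN, else decrement
    .rule("Z1", "0", "0", "R", "Z2"), .rule("Z1", "1", "1", "R", "GR"),
    .rule("Z2", "0", "0", "R", "Z3"), .rule("Z2", "1", "1", "R", "GR"),
    .rule("Z3", "0", "0", "R", "FIN"), .rule("Z3", "1", "0", "R", "W1"),
    # GR: walk right to the separator, then step left onto the LSB
    .rule("GR", "0", "0", "R", "GR"), .rule("GR", "1", "1", "R", "GR"),
    .rule("GR", "x", "x", "L", "DEC"),
    # DEC: binary decrement with borrow, moving left
    .rule("DEC", "0", "1", "L", "DEC"), .rule("DEC", "1", "0", "R", "W1"),
    # W1: walk right to the separator, then cross into the accumulator
    .rule("W1", "0", "0", "R", "W1"), .rule("W1", "1", "1", "R", "W1"),
    .rule("W1", "x", "x", "R", "R1"),
    # R1..R3: fixed offsets from the separator to the accumulator LSB
    .rule("R1", "0", "0", "R", "R2"), .rule("R1", "1", "1", "R", "R2"),
    .rule("R2", "0", "0", "R", "R3"), .rule("R2", "1", "1", "R", "R3"),
    .rule("R3", "0", "0", "R", "INC"), .rule("R3", "1", "1", "R", "INC"),
    # INC: binary increment with carry, moving left
    .rule("INC", "0", "1", "L", "RET"), .rule("INC", "1", "0", "L", "INC"),
    # RET: walk left to the separator, then fixed offsets back to cell 1
    .rule("RET", "0", "0", "L", "RET"), .rule("RET", "1", "1", "L", "RET"),
    .rule("RET", "x", "x", "L", "L1"),
    .rule("L1", "0", "0", "L", "L2"), .rule("L1", "1", "1", "L", "L2"),
    .rule("L2", "0", "0", "L", "Z1"), .rule("L2", "1", "1", "L", "Z1"),
    # FIN: left field exhausted; blank the separator and halt
    .rule("FIN", "x", "0", "R", "HALT")
  )
  covered <- paste(tb$state, tb$read, sep = "\x01")
  for (s in states) for (a in c("0", "1", "x", "y")) {
    if (!paste(s, a, sep = "\x01") %in% covered)
      tb <- rbind(tb, inert(s, a))
  }
  turingMachine(tb, initial = "Z1", blank = "0",
                states = c(states, "HALT"), alphabet = c("0", "1", "x", "y"))
}

#' Starting configuration for the binary adder
#'
#' Builds the tape `abc x 0def` for two 3-bit addends.
#'
#' @param a,b integers in 0..7, or 3-character bit strings.
#' @return a [TMConfiguration-class] (head 1, state `Z1`).
#' @export
adderConfiguration <- function(a, b) {
  toBits <- function(v) {
    if (is.character(v)) {
      stopifnot(nchar(v) == 3L, grepl("^[01]{3}$", v))
      strsplit(v, "")[[1L]]
    } else {
      stopifnot(v >= 0, v <= 7)
      rev(as.character(bitwAnd(v %/% c(1L, 2L, 4L), 1L)))
    }
  }
  tmConfiguration(c(toBits(a), "x", "0", toBits(b)), head = 1L, state = "Z1")
}

#' Generate a seed-deterministic random Turing machine
#'
#' Draws a total transition table over `nStates` working states (named
#' A, B, ...) plus HALT and the first `nSymbols` symbols of
#' `c("0","1","x","y")`.  The same seed always yields the same machine;
#' at least one rule targets HALT when `requireHalt` is set (the machine
#' may still fail to halt — sweeps compare bounded traces).  The
#' caller's RNG state is left untouched.
#'
#' @param nStates number of working states, at most 15.
#' @param nSymbols alphabet size, at most 4.
#' @param seed integer seed that fully determines the machine.
#' @param requireHalt force at least one HALT-targeting rule
#'   (default TRUE).
#' @return a [TuringMachine-class].
#' @examples
#' m <- generateMachine(2, 2, seed = 1)
#' identical(transitionTable(m), transitionTable(generateMachine(2, 2, seed = 1)))
#' @export
generateMachine <- function(nStates, nSymbols, seed, requireHalt = TRUE) {
  if (nStates > 15L) stop(.validationError("at most 15 working states"))
  if (nSymbols > 4L) stop(.validationError("at most 4 symbols"))
  stopifnot(nStates >= 1L, nSymbols >= 2L)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  states <- LETTERS[seq_len(nStates)]
  symbols <- c("0", "1", "x", "y")[seq_len(nSymbols)]
  grid <- expand.grid(state = states, read = symbols,
                      stringsAsFactors = FALSE)
  tb <- data.frame(
    state = grid$state, read = grid$read,
    write = sample(symbols, nrow(grid), replace = TRUE),
    move = sample(c("L", "R"), nrow(grid), replace = TRUE),
    "next" = sample(c(states, "HALT"), nrow(grid), replace = TRUE),
    check.names = FALSE, stringsAsFactors = FALSE)
  if (requireHalt && !any(tb[["next"]] == "HALT"))
    tb[["next"]][sample(nrow(tb), 1L)] <- "HALT"
  turingMachine(tb, initial = states[1L], blank = "0",
                states = c(states, "HALT"), alphabet = symbols)
}
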