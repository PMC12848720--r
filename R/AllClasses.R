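#' @import methods
NULL

# Closed color gamut of the platform: "white" denotes an empty vial and is
# never a solution color.
.CHEM_COLORS <- c("white", "orange", "blue", "green")
.SOLUTION_COLORS <- c("orange", "blue", "green")

# Detection threshold of the virtual camera, in microliters.  A vial whose
# total contents fall below this reads "white".
.DETECTION_THRESHOLD_UL <- 100

#' TuringMachine: a finite-state machine over a finite tape alphabet
#'
#' Holds a complete transition table mapping (state, read symbol) to
#' (write symbol, move, next state).  The designated halt state is always
#' called `"HALT"`; it has no outgoing rules and is listed last in
#' `states`.  The blank symbol (default `"0"`) is part of the alphabet.
#'
#' @slot states character vector of state identifiers, `"HALT"` last.
#' @slot alphabet character vector of tape symbols, blank first.
#' @slot blank the blank symbol.
#' @slot initial the start state.
#' @slot table data.frame with columns `state`, `read`, `write`, `move`
#'   (`"L"` or `"R"`) and `next`, one row per rule, total over
#'   (states minus HALT) x alphabet.
#'
#' @seealso [turingMachine()], [tmStep()], [tmRun()]
#' @exportClass TuringMachine
setClass("TuringMachine",
  representation(
    states   = "character",
    alphabet = "character",
    blank    = "character",
    initial  = "character",
    table    = "data.frame"
  )
)

setValidity("TuringMachine", function(object) {
  msg <- character()
  st <- object@states
  ab <- object@alphabet
  tb <- object@table
  if (!"HALT" %in% st) msg <- c(msg, "states must include 'HALT'")
  if (length(st) && st[length(st)] != "HALT")
    msg <- c(msg, "'HALT' must be the last state")
  if (anyDuplicated(st)) msg <- c(msg, "duplicate state identifiers")
  if (anyDuplicated(ab)) msg <- c(msg, "duplicate alphabet symbols")
  if (!object@blank %in% ab) msg <- c(msg, "blank symbol not in alphabet")
  if (!object@initial %in% st) msg <- c(msg, "initial state not in states")
  need <- c("state", "read", "write", "move", "next")
  if (!all(need %in% names(tb))) {
    msg <- c(msg, "table must have columns state, read, write, move, next")
  } else {
    if (any(tb$state == "HALT")) msg <- c(msg, "HALT must have no outgoing rules")
    if (!all(tb$state %in% st)) msg <- c(msg, "rule state not declared")
    if (!all(tb$read %in% ab)) msg <- c(msg, "rule read symbol not in alphabet")
    if (!all(tb$write %in% ab)) msg <- c(msg, "rule write symbol not in alphabet")
    if (!all(tb$move %in% c("L", "R"))) msg <- c(msg, "moves must be 'L' or 'R'")
    if (!all(tb[["next"]] %in% st)) msg <- c(msg, "rule next state not declared")
    key <- paste(tb$state, tb$read, sep = "\x01")
    if (anyDuplicated(key)) msg <- c(msg, "duplicate rule for a (state, read) pair")
    want <- as.vector(outer(setdiff(st, "HALT"), ab, paste, sep = "\x01"))
    if (!all(want %in% key))
      msg <- c(msg, "table is not total over (states \\ HALT) x alphabet")
  }
  if (length(msg)) msg else TRUE
})

#' TMConfiguration: a snapshot of a running Turing machine
#'
#' A finite tape of `N` cells, a 1-based head position and the current
#' state.  Finiteness is deliberate: the physical medium (a row of vials)
#' is finite, and running off either end is a hard error.
#'
#' @slot tape character vector of tape symbols (length N).
#' @slot head integer head position, `1 <= head <= N`.
#' @slot state current state identifier.
#'
#' @seealso [tmConfiguration()], [tmStep()]
#' @exportClass TMConfiguration
setClass("TMConfiguration",
  representation(tape = "character", head = "integer", state = "character")
)

setValidity("TMConfiguration", function(object) {
  msg <- character()
  if (length(object@tape) < 1L) msg <- c(msg, "tape must be nonempty")
  if (length(object@head) != 1L || is.na(object@head) ||
      object@head < 1L || object@head > length(object@tape))
    msg <- c(msg, "head must lie within the tape")
  if (length(object@state) != 1L || is.na(object@state))
    msg <- c(msg, "state must be a single identifier")
  if (length(msg)) msg else TRUE
})

#' PlatformState: the virtual Chemputer
#'
#' Vessels holding colored solutions, reagent stock flasks (one per
#' color), an unbounded waste container, and a liquid-handling backbone
#' of pumps and valves expressed as a reachability graph.  All volumes
#' are kept internally as whole microliters so that conservation of
#' liquid is exact and testable with equality.
#'
#' @slot vessels named list; each element is a list with fields
#'   `capacity` (uL, may be `Inf`), `contents` (named numeric vector of
#'   whole uL keyed by solution id), `temperature` (degrees C) and `pH`.
#' @slot solutions named character vector mapping solution id to its
#'   color label (one of orange, blue, green).
#' @slot stocks named character vector mapping color label to the id of
#'   its stock flask.
#' @slot nodes character vector of non-vessel graph nodes (pumps, valves).
#' @slot edges two-column character matrix of undirected backbone edges.
#' @slot membership named integer vector: connected component of every
#'   vessel and node (transfers require src and dst in one component).
#' @slot counter integer, incremented by every mutating operation.
#'
#' @seealso [virtualPlatform()], [transfer()], [sense()]
#' @exportClass PlatformState
setClass("PlatformState",
  representation(
    vessels    = "list",
    solutions  = "character",
    stocks     = "character",
    nodes      = "character",
    edges      = "matrix",
    membership = "integer",
    counter    = "integer"
  )
)

setValidity("PlatformState", function(object) {
  msg <- character()
  vs <- object@vessels
  if (is.null(names(vs)) || anyDuplicated(names(vs)))
    msg <- c(msg, "vessels must be uniquely named")
  for (id in names(vs)) {
    v <- vs[[id]]
    if (length(v$contents)) {
      if (any(v$contents <= 0))
        msg <- c(msg, sprintf("vessel '%s': content volumes must be > 0", id))
      if (sum(v$contents) > v$capacity)
        msg <- c(msg, sprintf("vessel '%s': contents exceed capacity", id))
      if (!all(names(v$contents) %in% names(object@solutions)))
        msg <- c(msg, sprintf("vessel '%s': unknown solution id", id))
    }
    if (!is.finite(v$temperature))
      msg <- c(msg, sprintf("vessel '%s': temperature must be finite", id))
  }
  if (length(object@solutions) &&
      !all(object@solutions %in% .SOLUTION_COLORS))
    msg <- c(msg, "solution colors must be orange, blue or green")
  for (col in names(object@stocks)) {
    sid <- object@stocks[[col]]
    if (!sid %in% names(vs)) {
      msg <- c(msg, sprintf("stock flask '%s' is not a vessel", sid))
    } else if (length(vs[[sid]]$contents) > 1L) {
      msg <- c(msg, sprintf("stock flask '%s' must hold a single solution", sid))
    }
  }
  if (length(msg)) msg else TRUE
})

#' XDLDocument: a parsed conditional-XDL procedure
#'
#' Reagent and vessel declarations, named blueprints (the XDL analogue of
#' functions) and the main step sequence.  Steps are plain lists with
#' fields `name`, `params`, `condition` (a parsed expression tree or
#' `NULL`), `condition_text`, `step_id` and `children`.
#'
#' @slot reagents data.frame with columns `id` and `color`.
#' @slot vessels character vector of declared vessel ids.
#' @slot blueprints named list; each element has `params` (character
#'   vector of formal parameter names) and `steps` (ordered step list).
#' @slot main ordered list of top-level steps.
#'
#' @seealso [parseXDL()], [executeProcedure()]
#' @exportClass XDLDocument
setClass("XDLDocument",
  representation(
    reagents   = "data.frame",
    vessels    = "character",
    blueprints = "list",
    main       = "list"
  )
)

#' ExecutionTrace: the ordered event log of a procedure run
#'
#' Events are plain lists with an `event` field naming the type
#' (`step-executed`, `step-skipped`, `measurement`, `loop-iteration`,
#' `halt`) plus type-specific fields.  Event order equals execution
#' order; the final event is always a `halt` with a reason
#' (`completed`, `cap` or `error`).
#'
#' @slot events ordered list of events.
#' @slot status one of `"completed"`, `"cap"`, `"error"`.
#'
#' @seealso [executeProcedure()], [writeTrace()], [readTrace()]
#' @exportClass ExecutionTrace
setClass("ExecutionTrace",
  representation(events = "list", status = "character")
)

setValidity("ExecutionTrace", function(object) {
  if (!object@status %in% c("completed", "cap", "error"))
    return("status must be completed, cap or error")
  TRUE
})

#' ColorEncoding: the bridge between machine and platform
#'
#' Maps tape symbols to vial colors (blank is always white/empty) and
#' states to ordered pairs of colors for the two state vials.  Four
#' colors across two vials encode up to 16 states.
#'
#' @slot symbolToColor named character vector, symbol -> color.
#' @slot statePairs character matrix with one row per state (rownames are
#'   the state ids, `"HALT"` last) and two columns, the colors of state
#'   vials 1 and 2.
#' @slot tapeLength integer number of tape cells.
#' @slot headRowLength integer number of head-row vials (equals
#'   `tapeLength`).
#'
#' @seealso [colorEncoding()], [encodeConfiguration()]
#' @exportClass ColorEncoding
setClass("ColorEncoding",
  representation(
    symbolToColor = "character",
    statePairs    = "matrix",
    tapeLength    = "integer",
    headRowLength = "integer"
  )
)

setValidity("ColorEncoding", function(object) {
  msg <- character()
  s2c <- object@symbolToColor
  if (length(s2c) > 4L) msg <- c(msg, "at most 4 symbols are encodable")
  if (anyDuplicated(s2c)) msg <- c(msg, "symbol -> color map must be injective")
  if (!all(s2c %in% .CHEM_COLORS)) msg <- c(msg, "unknown color label")
  sp <- object@statePairs
  if (nrow(sp) > 16L) msg <- c(msg, "at most 16 states are encodable")
  if (!all(sp %in% .CHEM_COLORS)) msg <- c(msg, "unknown state-vial color")
  code <- paste(sp[, 1L], sp[, 2L])
  if (anyDuplicated(code)) msg <- c(msg, "state -> pair map must be injective")
  if (object@headRowLength != object@tapeLength)
    msg <- c(msg, "head row length must equal tape length")
  if (length(msg)) msg else TRUE
})

#' CompiledProgram: a Turing machine lowered to conditional XDL
#'
#' Bundles the emitted document with the machine it came from, the color
#' encoding, the initial configuration and the loop iteration cap, so a
#' run can be set up and decoded without external bookkeeping.
#'
#' @slot document the emitted [XDLDocument-class].
#' @slot encoding the [ColorEncoding-class] used.
#' @slot machine the source [TuringMachine-class].
#' @slot initial the [TMConfiguration-class] the run starts from.
#' @slot cap integer iteration cap of the outer Repeat loop.
#'
#' @seealso [compileMachine()], [runCompiled()]
#' @exportClass CompiledProgram
setClass("CompiledProgram",
  representation(
    document = "XDLDocument",
    encoding = "ColorEncoding",
    machine  = "TuringMachine",
    initial  = "TMConfiguration",
    cap      = "integer"
  )
)
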