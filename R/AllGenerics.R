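#' Tape contents as a single digit string
#'
#' Concatenates the tape symbols of a configuration left to right, the
#' form in which results are usually quoted (e.g. `"01111110"`).
#'
#' @param x a [TMConfiguration-class].
#' @return a single character string.
#' @export
setGeneric("tapeString", function(x) standardGeneric("tapeString"))

#' @describeIn tapeString tape of a configuration as one string
setMethod("tapeString", "TMConfiguration", function(x) {
  paste(x@tape, collapse = "")
})

#' Accessors for Turing-machine objects
#'
#' @param x a [TuringMachine-class].
#' @return `machineStates` and `machineAlphabet` return character
#'   vectors; `transitionTable` returns the rule data.frame.
#' @name machine-accessors
NULL

#' @rdname machine-accessors
#' @export
setGeneric("machineStates", function(x) standardGeneric("machineStates"))
#' @rdname machine-accessors
setMethod("machineStates", "TuringMachine", function(x) x@states)

#' @rdname machine-accessors
#' @export
setGeneric("machineAlphabet", function(x) standardGeneric("machineAlphabet"))
#' @rdname machine-accessors
setMethod("machineAlphabet", "TuringMachine", function(x) x@alphabet)

#' @rdname machine-accessors
#' @export
setGeneric("transitionTable", function(x) standardGeneric("transitionTable"))
#' @rdname machine-accessors
setMethod("transitionTable", "TuringMachine", function(x) x@table)

#' Accessors for execution traces
#'
#' @param x an [ExecutionTrace-class].
#' @return `traceEvents` returns the ordered list of events,
#'   `traceStatus` the final status string.
#' @name trace-accessors
NULL

#' @rdname trace-accessors
#' @export
setGeneric("traceEvents", function(x) standardGeneric("traceEvents"))
#' @rdname trace-accessors
setMethod("traceEvents", "ExecutionTrace", function(x) x@events)

#' @rdname trace-accessors
#' @export
setGeneric("traceStatus", function(x) standardGeneric("traceStatus"))
#' @rdname trace-accessors
setMethod("traceStatus", "ExecutionTrace", function(x) x@status)

#' Accessors for the virtual platform
#'
#' @param x a [PlatformState-class].
#' @param vessel a vessel id.
#' @return `vesselIds` returns all vessel ids; `vesselVolume` the total
#'   volume of one vessel in mL; `vesselContents` its contents as a named
#'   numeric vector of mL keyed by solution id.
#' @name platform-accessors
NULL

#' @rdname platform-accessors
#' @export
setGeneric("vesselIds", function(x) standardGeneric("vesselIds"))
#' @rdname platform-accessors
setMethod("vesselIds", "PlatformState", function(x) names(x@vessels))

#' @rdname platform-accessors
#' @export
setGeneric("vesselVolume", function(x, vessel) standardGeneric("vesselVolume"))
#' @rdname platform-accessors
setMethod("vesselVolume", "PlatformState", function(x, vessel) {
  .checkVessel(x, vessel)
  sum(x@vessels[[vessel]]$contents) / 1000
})

#' @rdname platform-accessors
#' @export
setGeneric("vesselContents", function(x, vessel) standardGeneric("vesselContents"))
#' @rdname platform-accessors
setMethod("vesselContents", "PlatformState", function(x, vessel) {
  .checkVessel(x, vessel)
  x@vessels[[vessel]]$contents / 1000
})
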