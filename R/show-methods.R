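setMethod("show", "TuringMachine", function(object) {
  cat(sprintf("TuringMachine: %d states (+HALT), alphabet {%s}, initial '%s'\n",
              length(object@states) - 1L,
              paste(object@alphabet, collapse = ","),
              object@initial))
  cat(sprintf("  %d transition rules\n", nrow(object@table)))
})

setMethod("show", "TMConfiguration", function(object) {
  marker <- rep(" ", length(object@tape))
  marker[object@head] <- "^"
  cat(sprintf("TMConfiguration: state %s, head %d\n  tape %s\n       %s\n",
              object@state, object@head, tapeString(object),
              paste(marker, collapse = "")))
})

setMethod("show", "PlatformState", function(object) {
  nV <- length(object@vessels)
  filled <- sum(vapply(object@vessels,
                       function(v) length(v$contents) > 0L, logical(1L)))
  cat(sprintf("PlatformState: %d vessels (%d holding liquid), %.1f mL total\n",
              nV, filled, totalVolume(object)))
  cat(sprintf("  backbone: %d nodes, %d edges; %d operations so far\n",
              length(object@nodes), nrow(object@edges), object@counter))
})

setMethod("show", "XDLDocument", function(object) {
  cat(sprintf("XDLDocument: %d reagents, %d vessels, %d blueprints, %d main steps\n",
              nrow(object@reagents), length(object@vessels),
              length(object@blueprints), length(object@main)))
  cat(sprintf("  %d step elements in total\n", .countSteps(object)))
})

setMethod("show", "ExecutionTrace", function(object) {
  types <- vapply(object@events, function(e) e$event, character(1L))
  cat(sprintf("ExecutionTrace: %d events, status '%s'\n",
              length(object@events), object@status))
  if (length(types)) {
    tab <- table(types)
    cat(sprintf("  %s\n", paste(sprintf("%s=%d", names(tab), tab),
                                collapse = ", ")))
  }
})

setMethod("show", "ColorEncoding", function(object) {
  cat(sprintf("ColorEncoding: %d symbols, %d states, tape length %d\n",
              length(object@symbolToColor), nrow(object@statePairs),
              object@tapeLength))
  cat(sprintf("  symbols: %s\n",
              paste(sprintf("%s->%s", names(object@symbolToColor),
                            object@symbolToColor), collapse = ", ")))
})

setMethod("show", "CompiledProgram", function(object) {
  cat(sprintf("CompiledProgram: %d rules over %d tape cells, cap %d\n",
              nrow(object@machine@table), object@encoding@tapeLength,
              object@cap))
  cat(sprintf("  document: %d blueprints, %d step elements\n",
              length(object@document@blueprints), .countSteps(object@document)))
})
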