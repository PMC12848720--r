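# Compilation of a transition table into nested XDL blueprints.
#
# The dialect has only booleans (no integers), so all position logic is
# unrolled over the N tape cells behind head_at_<i> guards — a
# Theta(|rules| * N) blow-up per rule, the price of the dialect's
# expressive budget.  Because step_ids are unique per document, the
# "what symbol is under the head" booleans are per position
# (read_<i>_is_<a>, measured unguarded so every variable referenced by
# a condition is always set) and rule guards expand to
#   s1_is_p1 and s2_is_p2 and ((head_at_1 and read_1_is_a) or ...).
#
# Emitted blueprint structure:
#   TuringMachine = [ReadState;
#                    Repeat("not (s1_is_h1 and s2_is_h2)", cap) {
#                      ReadTape; LookUpTable; ReadState }]
#   ReadState   = color Measures of the two state vials
#   ReadTape    = head_at_<i> and read_<i>_is_<a> Measures
#   LookUpTable = one guarded Rule_<S>_<a> invocation per rule
#   Rule_<S>_<a> = Write (empty+add at the head cell), Move (shift the
#                  orange head marker), Switch (recolor the state vials)
#
# ReadState runs once before the loop (the exit condition is checked
# before the first iteration) and at the end of each iteration, so the
# exit check always sees the post-switch state.  A rule that moves the
# head off the tape compiles to an Add on a phantom head vial
# (head_0 / head_<N+1>) that is declared in the document but absent
# from the platform, so the move fails at run time exactly like the
# finite physical rig.

.symToken <- function(a) a  # symbols are single alphanumeric characters

.ruleBlueprintId <- function(state, read) sprintf("Rule_%s_%s", state, read)

.ruleCondition <- function(encoding, state, read, N) {
  pair <- encoding@statePairs[state, ]
  disj <- paste(sprintf("(head_at_%d and read_%d_is_%s)", 1:N, 1:N,
                        .symToken(read)), collapse = " or ")
  sprintf("s1_is_%s and s2_is_%s and (%s)", pair[[1L]], pair[[2L]], disj)
}

.readStateSteps <- function(encoding) {
  vial1 <- unique(encoding@statePairs[, 1L])
  vial2 <- unique(encoding@statePairs[, 2L])
  # stable order: the platform color order, filtered
  vial1 <- .CHEM_COLORS[.CHEM_COLORS %in% vial1]
  vial2 <- .CHEM_COLORS[.CHEM_COLORS %in% vial2]
  c(
    lapply(vial1, function(col)
      .step("Measure",
            list(vessel = "state_1", quantity = "color",
                 comparison = "equal", value = col),
            step_id = sprintf("s1_is_%s", col))),
    lapply(vial2, function(col)
      .step("Measure",
            list(vessel = "state_2", quantity = "color",
                 comparison = "equal", value = col),
            step_id = sprintf("s2_is_%s", col)))
  )
}

.readTapeSteps <- function(machine, encoding) {
  N <- encoding@tapeLength
  heads <- lapply(seq_len(N), function(i)
    .step("Measure",
          list(vessel = sprintf("head_%d", i), quantity = "color",
               comparison = "equal", value = "orange"),
          step_id = sprintf("head_at_%d", i)))
  reads <- list()
  for (a in machine@alphabet) {
    col <- encoding@symbolToColor[[a]]
    for (i in seq_len(N)) {
      reads[[length(reads) + 1L]] <-
        .step("Measure",
              list(vessel = sprintf("tape_%d", i), quantity = "color",
                   comparison = "equal", value = col),
              step_id = sprintf("read_%d_is_%s", i, .symToken(a)))
    }
  }
  c(heads, reads)
}

.ruleSteps <- function(rule, encoding) {
  N <- encoding@tapeLength
  writeColor <- encoding@symbolToColor[[rule$write]]
  delta <- if (rule$move == "R") 1L else -1L
  nextPair <- encoding@statePairs[rule[["next"]], ]
  steps <- list()
  add <- function(s) steps[[length(steps) + 1L]] <<- s
  # Write: replace the contents of the tape vial under the head
  for (i in seq_len(N)) {
    guard <- sprintf("head_at_%d", i)
    add(.step("EmptyToWaste", list(vessel = sprintf("tape_%d", i)),
              condition = guard))
    if (writeColor != "white")
      add(.step("Add", list(vessel = sprintf("tape_%d", i),
                            reagent = writeColor, volume = 1),
                condition = guard))
  }
  # Move: shift the orange head marker one vial left or right; a move
  # off the tape targets a phantom vial and fails at run time
  for (i in seq_len(N)) {
    guard <- sprintf("head_at_%d", i)
    add(.step("EmptyToWaste", list(vessel = sprintf("head_%d", i)),
              condition = guard))
    add(.step("Add", list(vessel = sprintf("head_%d", i + delta),
                          reagent = "orange", volume = 1),
              condition = guard))
  }
  # Switch: recolor the two state vials to the next state's pair
  add(.step("EmptyToWaste", list(vessel = "state_1")))
  if (nextPair[[1L]] != "white")
    add(.step("Add", list(vessel = "state_1", reagent = nextPair[[1L]],
                          volume = 1)))
  add(.step("EmptyToWaste", list(vessel = "state_2")))
  if (nextPair[[2L]] != "white")
    add(.step("Add", list(vessel = "state_2", reagent = nextPair[[2L]],
                          volume = 1)))
  steps
}

#' Compile a Turing machine to a conditional-XDL program
#'
#' Emits the nested-blueprint document described above: an outer
#' `TuringMachine` blueprint whose Repeat loop keeps running while the
#' state vials do not show the HALT pair, reading the state and tape
#' vials into booleans each iteration and dispatching exactly one
#' guarded rule blueprint per iteration.  The document validates under
#' [parseXDL()]'s invariants, and compilation is deterministic: the
#' same machine and encoding always yield a byte-identical document.
#'
#' @param machine a total [TuringMachine-class] with at most 16 states
#'   and 4 symbols.
#' @param initial the starting [TMConfiguration-class].
#' @param encoding a [ColorEncoding-class], default
#'   `colorEncoding(machine, length(initial@tape))`.
#' @param cap iteration cap of the outer Repeat loop (default 10000).
#' @return a [CompiledProgram-class].
#' @examples
#' prog <- compileMachine(busyBeaverMachine(), busyBeaverConfiguration())
#' prog
#' @seealso [runCompiled()], [compiledStepCount()]
#' @export
compileMachine <- function(machine, initial, encoding = NULL,
                           cap = 10000L) {
  if (is.null(encoding))
    encoding <- colorEncoding(machine, tapeLength = length(initial@tape))
  N <- encoding@tapeLength
  haltPair <- encoding@statePairs["HALT", ]
  haltCond <- sprintf("not (s1_is_%s and s2_is_%s)",
                      haltPair[[1L]], haltPair[[2L]])

  blueprints <- list()
  blueprints[["ReadState"]] <- list(params = character(0),
                                    steps = .readStateSteps(encoding))
  blueprints[["ReadTape"]] <- list(params = character(0),
                                   steps = .readTapeSteps(machine, encoding))
  tb <- machine@table
  lut <- list()
  for (r in seq_len(nrow(tb))) {
    rule <- as.list(tb[r, ])
    id <- .ruleBlueprintId(rule$state, .symToken(rule$read))
    blueprints[[id]] <- list(params = character(0),
                             steps = .ruleSteps(rule, encoding))
    lut[[length(lut) + 1L]] <-
      .step(id, condition = .ruleCondition(encoding, rule$state, rule$read, N))
  }
  blueprints[["LookUpTable"]] <- list(params = character(0), steps = lut)
  blueprints[["TuringMachine"]] <- list(
    params = character(0),
    steps = list(
      .step("ReadState"),
      .step("Repeat", list(max_iterations = as.integer(cap)),
            condition = haltCond,
            children = list(.step("ReadTape"), .step("LookUpTable"),
                            .step("ReadState")))
    ))

  usedColors <- unique(c("orange",
                         unname(encoding@symbolToColor),
                         as.vector(encoding@statePairs)))
  usedColors <- .SOLUTION_COLORS[.SOLUTION_COLORS %in% usedColors]
  vessels <- c(sprintf("tape_%d", seq_len(N)),
               sprintf("head_%d", 0:(N + 1L)),  # 0 and N+1 are phantoms
               "state_1", "state_2")
  doc <- new("XDLDocument",
             reagents = data.frame(id = usedColors, color = usedColors,
                                   stringsAsFactors = FALSE),
             vessels = vessels,
             blueprints = blueprints,
             main = list(.step("TuringMachine")))
  validateXDLDocument(doc)
  prog <- new("CompiledProgram", document = doc, encoding = encoding,
              machine = machine, initial = initial, cap = as.integer(cap))
  prog
}

#' Predicted size of a compiled document
#'
#' Counts the step elements the compiler emits (all blueprint bodies
#' plus the main sequence), showing the Theta(|rules| x N) growth:
#' with N tape cells, A symbols, R rules, and u1/u2 the distinct colors
#' on state vials 1/2,
#' `u1 + u2` (ReadState) `+ N + N*A` (ReadTape) `+ R` (LookUpTable)
#' `+ sum over rules of (N + N*[write nonblank] + 2N + 2 +
#' [pair1 nonwhite] + [pair2 nonwhite])` (rule bodies) `+ 6`
#' (TuringMachine body and main).
#'
#' @param machine a [TuringMachine-class].
#' @param tapeLength number of tape cells.
#' @return integer step count; equals the actual count in
#'   `compileMachine(...)@document`.
#' @export
compiledStepCount <- function(machine, tapeLength = 8L) {
  enc <- colorEncoding(machine, tapeLength)
  N <- as.integer(tapeLength)
  u1 <- length(unique(enc@statePairs[, 1L]))
  u2 <- length(unique(enc@statePairs[, 2L]))
  A <- length(machine@alphabet)
  tb <- machine@table
  ruleBody <- 0L
  for (r in seq_len(nrow(tb))) {
    wNonblank <- enc@symbolToColor[[tb$write[r]]] != "white"
    pair <- enc@statePairs[tb[["next"]][r], ]
    ruleBody <- ruleBody + N + N * wNonblank + 2L * N + 2L +
      (pair[[1L]] != "white") + (pair[[2L]] != "white")
  }
  as.integer(u1 + u2 + N + N * A + nrow(tb) + ruleBody + 6L)
}

# Count step elements actually present in a document (recursively).
.countSteps <- function(doc) {
  cnt <- function(steps) {
    n <- length(steps)
    for (s in steps) if (length(s$children)) n <- n + cnt(s$children)
    n
  }
  n <- cnt(doc@main)
  for (bp in doc@blueprints) n <- n + cnt(bp$steps)
  n
}
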