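#' Run a compiled program on the virtual platform
#'
#' Loads the initial configuration onto the platform with
#' [encodeConfiguration()], executes the compiled document with
#' [executeProcedure()], and decodes the platform back into a
#' [TMConfiguration-class] after every completed loop iteration.  The
#' decoded sequence (starting configuration first) is the object
#' compared against the reference interpreter — the simulation
#' soundness check.  A decode failure mid-run flags a compiler bug and
#' propagates as an error.
#'
#' @param program a [CompiledProgram-class].
#' @param platform optional base [PlatformState-class] (defaults to
#'   [virtualPlatform()] of the encoding's tape length); it is
#'   (re)initialized from the program's initial configuration.
#' @return a list with `trace` (an [ExecutionTrace-class]), `configs`
#'   (list of decoded [TMConfiguration-class]), `status`
#'   (`"completed"`, `"cap"` or `"error"`), `halted` (did the machine
#'   reach HALT), and `platform` (final state).
#' @examples
#' prog <- compileMachine(busyBeaverMachine(), busyBeaverConfiguration())
#' run <- runCompiled(prog)
#' tapeString(run$configs[[length(run$configs)]])  # "01111110"
#' @export
runCompiled <- function(program, platform = NULL) {
  enc <- program@encoding
  platform <- encodeConfiguration(program@initial, enc, platform)
  acc <- new.env(parent = emptyenv())
  acc$configs <- vector("list", 64L)
  acc$configs[[1L]] <- decodeConfiguration(platform, enc)
  acc$n <- 1L
  res <- executeProcedure(
    program@document, platform, maxIterations = program@cap,
    onIteration = function(p, i) {
      acc$n <- acc$n + 1L
      if (acc$n > length(acc$configs))
        length(acc$configs) <- 2L * length(acc$configs)
      acc$configs[[acc$n]] <- decodeConfiguration(p, enc)
    })
  configs <- acc$configs[seq_len(acc$n)]
  final <- configs[[length(configs)]]
  list(trace = res$trace, configs = configs, status = res$status,
       halted = res$status == "completed" && final@state == "HALT",
       platform = res$platform)
}

#' Check a machine's compiled run against the reference interpreter
#'
#' Runs `machine` from `initial` both on the reference interpreter
#' ([tmTrajectory()]) and as a compiled XDL program on the virtual
#' platform ([runCompiled()]), then compares the two configuration
#' sequences element for element and the way both runs ended
#' (halted / iteration cap / off-tape failure).  This is the
#' Turing-machine simulation test: equivalence for arbitrary machines
#' is what makes the dialect Turing complete.
#'
#' @param machine a [TuringMachine-class].
#' @param initial starting [TMConfiguration-class]; default blank tape,
#'   head at the middle cell, machine's initial state.
#' @param cap bounded-run step/iteration cap (default 200).
#' @param tapeLength tape length for the default initial configuration.
#' @return a list with `equivalent` (logical), `steps`, `refStatus`,
#'   `compiledStatus`, and the two configuration sequences.
#' @examples
#' v <- verifyMachine(busyBeaverMachine(), busyBeaverConfiguration())
#' v$equivalent
#' @export
verifyMachine <- function(machine, initial = NULL, cap = 200L,
                          tapeLength = 8L) {
  if (is.null(initial))
    initial <- tmConfiguration(rep(machine@blank, tapeLength),
                               head = as.integer(ceiling(tapeLength / 2)),
                               state = machine@initial)
  ref <- tmTrajectory(machine, initial, maxSteps = cap)
  prog <- compileMachine(machine, initial, cap = cap)
  run <- runCompiled(prog)
  # error on the platform means the head marker was pushed off the row,
  # the finite-tape failure mode
  compiledClass <- switch(run$status,
    completed = if (run$halted) "halted" else "cap",
    cap = "cap",
    error = "overrun")
  sameLen <- length(ref$configs) == length(run$configs)
  sameCfg <- sameLen && all(vapply(seq_along(ref$configs), function(i) {
    a <- ref$configs[[i]]; b <- run$configs[[i]]
    identical(a@tape, b@tape) && a@head == b@head && a@state == b@state
  }, logical(1L)))
  list(equivalent = sameCfg && identical(ref$status, compiledClass),
       steps = ref$steps,
       refStatus = ref$status,
       compiledStatus = compiledClass,
       refConfigs = ref$configs,
       compiledConfigs = run$configs)
}
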