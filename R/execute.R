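# Depth-first interpreter for conditional XDL on the virtual platform.

.haltSignal <- function(reason) {
  structure(class = c("chemturing_halt", "condition"),
            list(message = reason, call = NULL, reason = reason))
}

#' Build a Measure specification
#'
#' @param step_id unique identifier under which the boolean result is
#'   stored.
#' @param vessel vessel to read.
#' @param quantity one of `"color"`, `"temperature"`, `"pH"`,
#'   `"volume"`.
#' @param comparison one of `"equal"`, `"not_equal"`, `"less_than"`,
#'   `"greater_than"`, `"between"`; `less_than`/`greater_than` are
#'   strict, `between` is inclusive on both ends, and only
#'   `equal`/`not_equal` apply to colors.
#' @param value reference value (color label or number).
#' @param value2 upper bound, only for `between`.
#' @return a validated list of class `MeasureSpec`.
#' @export
measureSpec <- function(step_id, vessel, quantity, comparison, value,
                        value2 = NULL) {
  s <- .step("Measure",
             params = c(list(vessel = vessel, quantity = quantity,
                             comparison = comparison, value = value),
                        if (!is.null(value2)) list(value2 = value2)),
             step_id = step_id)
  .validateMeasureSpec(s)
  structure(s, class = "MeasureSpec")
}

.compareReading <- function(raw, comparison, value, value2, quantity) {
  if (quantity == "color") {
    switch(comparison,
      equal = identical(raw, value),
      not_equal = !identical(raw, value),
      stop(.runtimeError(sprintf("comparison '%s' is not defined on colors",
                                 comparison))))
  } else {
    value <- as.numeric(value)
    switch(comparison,
      equal = raw == value,
      not_equal = raw != value,
      less_than = raw < value,
      greater_than = raw > value,
      between = raw >= value & raw <= as.numeric(value2),
      stop(.runtimeError(sprintf("unknown comparison '%s'", comparison))))
  }
}

#' Execute a Measure step
#'
#' Reads the sensor via [sense()], applies the comparison, stores
#' `{step_id: result}` in the variable store (overwriting any prior
#' value for that step_id) and returns the boolean.
#'
#' @param spec a [measureSpec()] (or an equivalent step list).
#' @param platform a [PlatformState-class].
#' @param store an environment used as the variable store.
#' @return the boolean result, invisibly the store is updated.
#' @examples
#' p <- transfer(virtualPlatform(), "stock_orange", "tape_1", 1)
#' store <- new.env()
#' executeMeasure(measureSpec("C", "tape_1", "color", "equal", "orange"),
#'                p, store)
#' store$C  # TRUE
#' @export
executeMeasure <- function(spec, platform, store) {
  stopifnot(is.environment(store))
  p <- spec$params
  raw <- sense(platform, p$vessel, p$quantity)$value
  result <- .compareReading(raw, p$comparison, p$value, p$value2, p$quantity)
  assign(spec$step_id, result, envir = store)
  result
}

#' Execute a parsed XDL document on the virtual platform
#'
#' Walks the main step sequence depth-first.  A step whose `condition`
#' evaluates to false is skipped (and recorded); the platform is left
#' untouched by skipped steps.  `Repeat` re-evaluates its condition
#' before every iteration (continue-while semantics, so a loop whose
#' condition starts false runs zero iterations) and a mandatory
#' iteration cap turns a runaway loop into an explicit `halt(cap)`
#' outcome.  Blueprint invocation binds formal parameters to the
#' supplied vessel/reagent ids and executes the body.  Any platform
#' error aborts the run, leaving the trace up to the failure and the
#' last consistent platform state (operations are transactional).
#'
#' @param doc a validated [XDLDocument-class].
#' @param platform the starting [PlatformState-class].
#' @param maxIterations default iteration cap for `Repeat` steps that do
#'   not set their own `max_iterations` (default 10000).
#' @param onIteration optional callback `function(platform, index)`
#'   invoked after every completed `Repeat` iteration.
#' @return a list with `trace` (an [ExecutionTrace-class]), `platform`
#'   (final state), `store` (named logical vector of measured booleans)
#'   and `status` (`"completed"`, `"cap"` or `"error"`).
#' @examples
#' doc <- parseXDL(system.file("extdata", "quench_transfer.xdl",
#'                             package = "chemturing"))
#' platform <- readPlatformConfig(system.file("extdata", "demo_platform.yaml",
#'                                            package = "chemturing"))
#' res <- executeProcedure(doc, platform)
#' res$status
#' @export
executeProcedure <- function(doc, platform, maxIterations = 10000L,
                             onIteration = NULL) {
  store <- new.env(parent = emptyenv())
  evEnv <- new.env(parent = emptyenv(), size = 4096L)
  ctx <- new.env(parent = emptyenv())
  ctx$platform <- platform
  ctx$n <- 0L
  rec <- function(ev) {
    ctx$n <- ctx$n + 1L
    assign(as.character(ctx$n), ev, envir = evEnv)
  }

  resolveParams <- function(params, bindings) {
    if (length(bindings)) {
      for (p in names(params)) {
        v <- params[[p]]
        if (is.character(v) && v %in% names(bindings))
          params[[p]] <- bindings[[v]]
      }
    }
    for (p in intersect(names(params), .NUMERIC_PARAMS))
      if (is.character(params[[p]]))
        params[[p]] <- as.numeric(params[[p]])
    params
  }

  execSteps <- function(steps, bindings) {
    for (s in steps) {
      if (!is.null(s$condition) &&
          !evaluateCondition(s$condition, store)) {
        rec(list(event = "step-skipped", name = s$name,
                 condition = s$condition_text, value = FALSE))
        next
      }
      execStep(s, bindings)
    }
  }

  execStep <- function(s, bindings) {
    params <- resolveParams(s$params, bindings)
    switch(s$name,
      Add = {
        color <- doc@reagents$color[match(params$reagent, doc@reagents$id)]
        if (is.na(color))
          stop(.platformError(sprintf("unknown reagent '%s'", params$reagent)))
        ctx$platform <- addFromStock(ctx$platform, color, params$vessel,
                                     params$volume)
        rec(list(event = "step-executed", name = "Add", params = params))
      },
      Transfer = {
        ctx$platform <- transfer(ctx$platform, params$from_vessel,
                                 params$to_vessel, params$volume)
        rec(list(event = "step-executed", name = "Transfer", params = params))
      },
      EmptyToWaste = {
        ctx$platform <- emptyToWaste(ctx$platform, params$vessel)
        rec(list(event = "step-executed", name = "EmptyToWaste", params = params))
      },
      Wait = {
        rec(list(event = "step-executed", name = "Wait", params = params))
      },
      Measure = {
        spec <- s
        spec$params <- params
        raw <- sense(ctx$platform, params$vessel, params$quantity)$value
        result <- .compareReading(raw, params$comparison, params$value,
                                  params$value2, params$quantity)
        assign(s$step_id, result, envir = store)
        rec(list(event = "measurement", step_id = s$step_id,
                 vessel = params$vessel, quantity = params$quantity,
                 raw = raw, result = result))
      },
      Repeat = {
        cap <- if (!is.null(params$max_iterations)) params$max_iterations
               else as.integer(maxIterations)
        i <- 0L
        repeat {
          if (!is.null(s$condition) &&
              !evaluateCondition(s$condition, store)) break
          if (i >= cap) {
            rec(list(event = "halt", reason = "cap",
                     message = sprintf("iteration cap %d reached", cap)))
            stop(.haltSignal("cap"))
          }
          i <- i + 1L
          execSteps(s$children, bindings)
          rec(list(event = "loop-iteration", index = i))
          if (!is.null(onIteration)) onIteration(ctx$platform, i)
        }
        rec(list(event = "step-executed", name = "Repeat",
                 params = list(iterations = i)))
      },
      { # blueprint invocation
        bp <- doc@blueprints[[s$name]]
        if (is.null(bp))
          stop(.validationError(sprintf("undefined blueprint '%s'", s$name)))
        rec(list(event = "step-executed", name = s$name, params = params))
        execSteps(bp$steps, params)
      }
    )
  }

  status <- tryCatch({
    execSteps(doc@main, list())
    rec(list(event = "halt", reason = "completed"))
    "completed"
  },
  chemturing_halt = function(c) c$reason,
  chemturing_platform = function(c) {
    rec(list(event = "halt", reason = "error", message = conditionMessage(c)))
    "error"
  })

  events <- if (ctx$n > 0L)
    unname(mget(as.character(seq_len(ctx$n)), envir = evEnv))
  else list()
  storeVals <- vapply(ls(store, sorted = TRUE), get, logical(1L), envir = store)
  list(trace = new("ExecutionTrace", events = events, status = status),
       platform = ctx$platform,
       store = storeVals,
       status = status)
}
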