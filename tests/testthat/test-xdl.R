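minimalDoc <- function() {
  parseXDL('
  <XDL>
    <Reagents><Reagent id="quencher" color="blue"/></Reagents>
    <Vessels><Vessel id="reactor_1"/><Vessel id="holding_flask"/></Vessels>
    <Procedure>
      <Measure step_id="C" vessel="reactor_1" quantity="color"
               comparison="equal" value="orange"/>
      <Add vessel="reactor_1" reagent="quencher" volume="2" condition="C"/>
      <Transfer from_vessel="reactor_1" to_vessel="holding_flask"
                volume="5" condition="not C"/>
    </Procedure>
  </XDL>')
}

demoPlatform <- function(reactorColor = "orange") {
  p <- readPlatformConfig(system.file("extdata", "demo_platform.yaml",
                                      package = "chemturing"))
  if (reactorColor != "orange") {
    p <- emptyToWaste(p, "reactor_1")
    p <- addFromStock(p, reactorColor, "reactor_1", 5)
  }
  p
}

test_that("a minimal conditional document parses", {
  doc <- minimalDoc()
  expect_s4_class(doc, "XDLDocument")
  expect_length(doc@main, 3L)
  expect_identical(doc@main[[1L]]$step_id, "C")
  expect_identical(doc@main[[3L]]$condition_text, "not C")
})

test_that("document validation rejects every contract violation", {
  tpl <- '
  <XDL>
    <Reagents><Reagent id="q" color="blue"/></Reagents>
    <Vessels><Vessel id="r"/></Vessels>
    %s
    <Procedure>%s</Procedure>
  </XDL>'
  doc <- function(proc, bp = "") parseXDL(sprintf(tpl, bp, proc))

  expect_error(doc('<Quench vessel="r" condition="D"/>'),
               "unknown step name", class = "chemturing_validation")
  expect_error(doc(paste0('<Measure step_id="C" vessel="r" quantity="color"',
                          ' comparison="equal" value="orange"/>',
                          '<Add vessel="r" reagent="q" volume="1" condition="D"/>')),
               "undefined condition variable D", class = "chemturing_validation")
  expect_error(doc('<Measure vessel="r" quantity="color" comparison="equal" value="orange"/>'),
               "Measure without step_id", class = "chemturing_validation")
  expect_error(doc(paste0('<Measure step_id="C" vessel="r" quantity="color"',
                          ' comparison="equal" value="orange"/>') |> strrep(2L)),
               "duplicate step_id", class = "chemturing_validation")
  expect_error(doc('<Add vessel="ghost" reagent="q" volume="1"/>'),
               "undeclared vessel", class = "chemturing_validation")
  expect_error(doc('<Add vessel="r" reagent="ghost" volume="1"/>'),
               "undeclared reagent", class = "chemturing_validation")
  expect_error(doc('<Measure step_id="C" vessel="r" quantity="color" comparison="between" value="orange" value2="blue"/>'),
               "not defined on colors", class = "chemturing_validation")
  expect_error(doc('<Measure step_id="C" vessel="r" quantity="temperature" comparison="between" value="9" value2="4"/>'),
               "low <= high", class = "chemturing_validation")
  expect_error(doc('<Loop/>', bp = '<Blueprint id="Loop"><Loop/></Blueprint>'),
               "recursive blueprint", class = "chemturing_validation")
  expect_error(doc('<Ghost/>'), "unknown step", class = "chemturing_validation")
})

test_that("measured color steers quench-vs-transfer branching", {
  doc <- minimalDoc()
  # color matches: quench (Add) executed, Transfer skipped
  res <- executeProcedure(doc, demoPlatform("orange"))
  kinds <- vapply(traceEvents(res$trace), function(e)
    paste(e$event, if (is.null(e$name)) "" else e$name), character(1L))
  expect_identical(kinds, c("measurement ", "step-executed Add",
                            "step-skipped Transfer", "halt "))
  expect_true(res$store[["C"]])
  # color does not match: quench skipped, Transfer executed
  res2 <- executeProcedure(doc, demoPlatform("blue"))
  kinds2 <- vapply(traceEvents(res2$trace), function(e)
    paste(e$event, if (is.null(e$name)) "" else e$name), character(1L))
  expect_identical(kinds2, c("measurement ", "step-skipped Add",
                             "step-executed Transfer", "halt "))
  expect_identical(vesselVolume(res2$platform, "holding_flask"), 5)
})

test_that("skipped steps leave the platform bit-identical", {
  doc <- parseXDL('
  <XDL>
    <Reagents><Reagent id="q" color="blue"/></Reagents>
    <Vessels><Vessel id="reactor_1"/><Vessel id="holding_flask"/></Vessels>
    <Procedure>
      <Measure step_id="C" vessel="reactor_1" quantity="color"
               comparison="equal" value="green"/>
      <Add vessel="reactor_1" reagent="q" volume="2" condition="C"/>
      <Transfer from_vessel="reactor_1" to_vessel="holding_flask"
                volume="5" condition="C"/>
      <EmptyToWaste vessel="reactor_1" condition="C"/>
    </Procedure>
  </XDL>')
  p <- demoPlatform("orange")  # C will be false; all guarded steps skip
  res <- executeProcedure(doc, p)
  expect_identical(res$platform@vessels, p@vessels)
  expect_identical(totalVolume(res$platform), totalVolume(p))
})

test_that("Measure comparisons follow the boundary conventions", {
  p <- demoPlatform()
  p <- setVesselAttribute(p, "reactor_1", temperature = 50, pH = 6.5)
  store <- new.env()
  # strictly below: 50 < 50 is false
  expect_false(executeMeasure(
    measureSpec("T", "reactor_1", "temperature", "less_than", 50), p, store))
  expect_true(executeMeasure(
    measureSpec("T2", "reactor_1", "temperature", "less_than", 50.1), p, store))
  # between is inclusive on both ends
  expect_true(executeMeasure(
    measureSpec("P", "reactor_1", "pH", "between", 6.5, 9), p, store))
  expect_false(executeMeasure(
    measureSpec("P2", "reactor_1", "pH", "between", 7, 9), p, store))
  # re-execution overwrites the stored value
  expect_true(store$T2)
  executeMeasure(measureSpec("T2", "reactor_1", "temperature",
                             "greater_than", 100), p, store)
  expect_false(store$T2)
  expect_error(measureSpec("X", "r", "color", "between", "orange", "blue"),
               class = "chemturing_validation")
})

test_that("Repeat has continue-while semantics with an explicit cap", {
  tpl <- '
  <XDL>
    <Vessels><Vessel id="tape_1"/></Vessels>
    <Procedure>
      <Measure step_id="GO" vessel="tape_1" quantity="volume" comparison="%s" value="0"/>
      <Repeat condition="GO" max_iterations="%d">
        <Wait time="1"/>
      </Repeat>
    </Procedure>
  </XDL>'
  p <- virtualPlatform()

  # condition false on entry: zero iterations, completed
  resF <- executeProcedure(parseXDL(sprintf(tpl, "less_than", 5L)), p)
  expect_identical(resF$status, "completed")
  expect_false(any(vapply(traceEvents(resF$trace),
                          function(e) e$event == "loop-iteration", logical(1L))))

  # condition stays true: the cap stops the loop and is an explicit outcome
  resT <- executeProcedure(parseXDL(sprintf(tpl, "equal", 5L)), p)
  expect_identical(resT$status, "cap")
  iters <- sum(vapply(traceEvents(resT$trace),
                      function(e) e$event == "loop-iteration", logical(1L)))
  expect_identical(iters, 5L)
  last <- traceEvents(resT$trace)[[length(traceEvents(resT$trace))]]
  expect_identical(last$event, "halt")
  expect_identical(last$reason, "cap")
})

test_that("execution is deterministic and traces round-trip as JSON lines", {
  doc <- minimalDoc()
  r1 <- executeProcedure(doc, demoPlatform())
  r2 <- executeProcedure(doc, demoPlatform())
  expect_identical(traceEvents(r1$trace), traceEvents(r2$trace))
  expect_identical(r1$platform, r2$platform)

  path <- withr::local_tempfile(fileext = ".jsonl")
  writeTrace(r1$trace, path)
  back <- readTrace(path)
  expect_equal(traceEvents(back), traceEvents(r1$trace))
  expect_identical(traceStatus(back), traceStatus(r1$trace))
})

test_that("blueprints bind parameters and forbid hidden state", {
  doc <- parseXDL('
  <XDL>
    <Reagents><Reagent id="q" color="blue"/></Reagents>
    <Vessels><Vessel id="reactor_1"/><Vessel id="holding_flask"/></Vessels>
    <Blueprint id="Fill" params="target,amount">
      <Add vessel="target" reagent="q" volume="1"/>
      <Transfer from_vessel="target" to_vessel="holding_flask" volume="amount"/>
    </Blueprint>
    <Procedure>
      <Fill target="reactor_1" amount="0.5"/>
    </Procedure>
  </XDL>')
  res <- executeProcedure(doc, demoPlatform())
  expect_identical(res$status, "completed")
  expect_identical(vesselVolume(res$platform, "holding_flask"), 0.5)
})

test_that("a compiled document survives a serialize/parse round trip", {
  prog <- compileMachine(busyBeaverMachine(), busyBeaverConfiguration())
  xml <- serializeXDL(prog@document)
  doc2 <- parseXDL(xml)
  expect_equal(doc2, prog@document)
  expect_identical(serializeXDL(doc2), xml)
})
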