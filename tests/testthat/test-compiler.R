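test_that("configurations encode onto the platform as specified", {
  bb <- busyBeaverMachine()
  enc <- colorEncoding(bb)
  expect_identical(enc@symbolToColor, c("0" = "white", "1" = "orange"))
  p <- encodeConfiguration(busyBeaverConfiguration(), enc)
  for (i in 1:8)
    expect_identical(sense(p, sprintf("tape_%d", i), "color")$value, "white")
  expect_identical(headMarkerCount(p, 8L), 1L)
  expect_identical(sense(p, "head_3", "color")$value, "orange")
  pair <- enc@statePairs["A", ]
  expect_identical(sense(p, "state_1", "color")$value, unname(pair[[1L]]))
  expect_identical(sense(p, "state_2", "color")$value, unname(pair[[2L]]))
})

test_that("decode inverts encode over the full symbol/state space", {
  m <- generateMachine(15, 4, seed = 99)  # 15 states + HALT, 4 symbols
  enc <- colorEncoding(m)
  expect_identical(nrow(enc@statePairs), 16L)
  set.seed(31)
  p0 <- virtualPlatform()
  for (i in 1:25) {
    cfg <- tmConfiguration(sample(machineAlphabet(m), 8, replace = TRUE),
                           head = sample(1:8, 1),
                           state = sample(machineStates(m), 1))
    p <- encodeConfiguration(cfg, enc, p0)
    back <- decodeConfiguration(p, enc)
    expect_identical(back@tape, cfg@tape)
    expect_identical(back@head, cfg@head)
    expect_identical(back@state, cfg@state)
  }
  # every state pair decodes, including HALT (always the last code)
  for (s in machineStates(m)) {
    p <- encodeConfiguration(tmConfiguration(rep("0", 8), 1, s), enc, p0)
    expect_identical(decodeConfiguration(p, enc)@state, s)
  }
})

test_that("decoding rejects corrupted platform states", {
  enc <- colorEncoding(busyBeaverMachine())
  p <- encodeConfiguration(busyBeaverConfiguration(), enc)
  # two head markers
  p2 <- addFromStock(p, "orange", "head_5", 1)
  expect_error(decodeConfiguration(p2, enc), "exactly one orange",
               class = "chemturing_runtime")
  # no head marker
  p3 <- emptyToWaste(p, "head_3")
  expect_error(decodeConfiguration(p3, enc), "exactly one orange")
  # unrecognized state pair (green is not used by a 4-state encoding's vial 1)
  p4 <- addFromStock(p, "green", "state_1", 1)
  expect_error(decodeConfiguration(p4, enc), "state-vial pair")
})

test_that("compilation is deterministic and sized by the counting formula", {
  bb <- busyBeaverMachine()
  c0 <- busyBeaverConfiguration()
  x1 <- serializeXDL(compileMachine(bb, c0)@document)
  x2 <- serializeXDL(compileMachine(bb, c0)@document)
  expect_identical(x1, x2)

  for (m in list(bb, binaryAdderMachine(), generateMachine(3, 3, seed = 4))) {
    prog <- compileMachine(m, tmConfiguration(rep("0", 8), 4, m@initial))
    expect_identical(chemturing:::.countSteps(prog@document),
                     compiledStepCount(m, 8L))
  }
  # Theta(|rules| * N): doubling N roughly doubles the rule-body count
  n8 <- compiledStepCount(bb, 8L)
  n16 <- compiledStepCount(bb, 16L)
  expect_gt(n16, 1.7 * n8)
})

test_that("a single-rule machine compiles, runs one iteration, and stops", {
  m <- turingMachine(rbind(
    data.frame(state = "A", read = "0", write = "0", move = "R",
               "next" = "HALT", check.names = FALSE),
    data.frame(state = "A", read = "1", write = "1", move = "R",
               "next" = "HALT", check.names = FALSE)), initial = "A")
  prog <- compileMachine(m, tmConfiguration(rep("0", 8), 3, "A"))
  run <- runCompiled(prog)
  expect_true(run$halted)
  expect_length(run$configs, 2L)  # initial + one iteration
  expect_identical(run$configs[[2L]]@state, "HALT")
  expect_identical(run$configs[[2L]]@head, 4L)
})

test_that("an already-halted start runs zero iterations", {
  m <- busyBeaverMachine()
  prog <- compileMachine(m, tmConfiguration(rep("0", 8), 3, "HALT"))
  run <- runCompiled(prog)
  expect_identical(run$status, "completed")
  expect_length(run$configs, 1L)
})

test_that("the compiled Busy Beaver reproduces the reference run exactly", {
  v <- verifyMachine(busyBeaverMachine(), busyBeaverConfiguration())
  expect_true(v$equivalent)
  expect_identical(v$refStatus, "halted")
  expect_identical(v$steps, 14L)
  final <- v$compiledConfigs[[length(v$compiledConfigs)]]
  expect_identical(tapeString(final), "01111110")
})

test_that("a compiled run keeps one head marker, drains stocks monotonically", {
  bb <- busyBeaverMachine()
  c0 <- busyBeaverConfiguration()
  prog <- compileMachine(bb, c0)
  platform <- encodeConfiguration(c0, prog@encoding)
  tot <- totalVolume(platform)
  stockIds <- unname(platform@stocks)
  prev <- vapply(stockIds, function(s) vesselVolume(platform, s), numeric(1L))
  prevWaste <- vesselVolume(platform, "waste")
  res <- executeProcedure(prog@document, platform, maxIterations = prog@cap,
    onIteration = function(p, i) {
      expect_identical(headMarkerCount(p, 8L), 1L)
      cur <- vapply(stockIds, function(s) vesselVolume(p, s), numeric(1L))
      expect_true(all(cur <= prev))
      w <- vesselVolume(p, "waste")
      expect_true(w >= prevWaste)
      prev <<- cur
      prevWaste <<- w
    })
  expect_identical(res$status, "completed")
  expect_identical(totalVolume(res$platform), tot)
  # the whole run draws well under 50 mL from any one stock
  consumed <- 1000 - vapply(stockIds, function(s)
    vesselVolume(res$platform, s), numeric(1L))
  expect_true(all(consumed <= 50))
})

test_that("moving off the tape fails like the finite physical rig", {
  m <- turingMachine(rbind(
    data.frame(state = "A", read = "0", write = "0", move = "L",
               "next" = "A", check.names = FALSE),
    data.frame(state = "A", read = "1", write = "1", move = "L",
               "next" = "A", check.names = FALSE)), initial = "A")
  v <- verifyMachine(m, tmConfiguration(rep("0", 8), 2, "A"), cap = 50L)
  expect_true(v$equivalent)
  expect_identical(v$refStatus, "overrun")
  expect_identical(v$compiledStatus, "overrun")
  expect_length(v$compiledConfigs, 2L)  # initial + the one completed step
})

test_that("a never-halting machine stops at the iteration cap on both paths", {
  m <- turingMachine(rbind(
    data.frame(state = "A", read = "0", write = "1", move = "R",
               "next" = "B", check.names = FALSE),
    data.frame(state = "A", read = "1", write = "1", move = "R",
               "next" = "B", check.names = FALSE),
    data.frame(state = "B", read = "0", write = "0", move = "L",
               "next" = "A", check.names = FALSE),
    data.frame(state = "B", read = "1", write = "0", move = "L",
               "next" = "A", check.names = FALSE)), initial = "A")
  v <- verifyMachine(m, tmConfiguration(rep("0", 8), 4, "A"), cap = 20L)
  expect_true(v$equivalent)
  expect_identical(v$refStatus, "cap")
  expect_length(v$refConfigs, 21L)
})
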