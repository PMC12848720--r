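test_that("tmStep applies a rule: write, move, switch state", {
  m <- turingMachine(rbind(
    data.frame(state = "A", read = "0", write = "1", move = "R",
               "next" = "B", check.names = FALSE),
    data.frame(state = "A", read = "1", write = "1", move = "R",
               "next" = "HALT", check.names = FALSE),
    data.frame(state = "B", read = "0", write = "0", move = "L",
               "next" = "A", check.names = FALSE),
    data.frame(state = "B", read = "1", write = "0", move = "L",
               "next" = "HALT", check.names = FALSE)),
    initial = "A")
  c0 <- tmConfiguration(rep("0", 8), head = 3, state = "A")
  c1 <- tmStep(m, c0)
  expect_identical(c1@tape[3], "1")
  expect_identical(c1@head, 4L)
  expect_identical(c1@state, "B")
  # purity: input untouched, locality: only the pre-step head cell changed
  expect_identical(c0@tape, rep("0", 8))
  expect_identical(which(c1@tape != c0@tape), 3L)

  expect_error(tmStep(m, tmConfiguration("0", 1, "HALT")), "halted")
  # move L at head 1 overruns the finite tape
  expect_error(tmStep(m, tmConfiguration(c("0", "0"), 1, "B")),
               class = "chemturing_overrun")
})

test_that("machine construction rejects broken tables", {
  partial <- data.frame(state = "A", read = "0", write = "1", move = "R",
                        "next" = "A", check.names = FALSE)
  expect_error(turingMachine(rbind(partial,
    data.frame(state = "A", read = "1", write = "2", move = "R",
               "next" = "A", check.names = FALSE)), initial = "A"),
    "not in alphabet|total")
  expect_error(turingMachine(
    data.frame(state = "HALT", read = "0", write = "0", move = "R",
               "next" = "HALT", check.names = FALSE), initial = "HALT"),
    "HALT")
})

test_that("tmRun agrees with an independent naive simulator", {
  set.seed(123)
  for (k in 1:200) {
    m <- generateMachine(sample(2:4, 1), sample(2:3, 1), seed = k)
    tape <- sample(machineAlphabet(m), 12, replace = TRUE)
    head <- sample(3:10, 1)
    cfg <- tmConfiguration(tape, head = head, state = "A")
    ref <- naiveTM(transitionTable(m), tape, head, "A", steps = 100L)
    got <- tryCatch(tmRun(m, cfg, maxSteps = 100L),
                    chemturing_overrun = function(e) list(overrun = TRUE))
    if (isTRUE(ref$overrun)) {
      expect_true(isTRUE(got$overrun), label = sprintf("machine %d", k))
    } else {
      expect_identical(got$config@tape, ref$tape, label = sprintf("machine %d", k))
      expect_identical(got$config@head, ref$head)
      expect_identical(got$config@state, ref$state)
    }
  }
})

test_that("bounded runs compose: run(k) then run(m) equals run(k+m)", {
  bb <- busyBeaverMachine()
  c0 <- busyBeaverConfiguration()
  a <- tmRun(bb, c0, maxSteps = 5L)
  b <- tmRun(bb, a$config, maxSteps = 9L)
  whole <- tmRun(bb, c0, maxSteps = 14L)
  expect_identical(b$config, whole$config)
  expect_identical(a$steps + b$steps, whole$steps)
})

test_that("the Busy Beaver writes six consecutive ones and halts", {
  bb <- busyBeaverMachine()
  c0 <- busyBeaverConfiguration()
  expect_true(all(c0@tape == "0"))  # initial empty tape
  res <- tmRun(bb, c0)
  expect_true(res$halted)
  expect_identical(tapeString(res$config), "01111110")
  expect_identical(countMaxConsecutive(res$config@tape, "1"), 6L)
  # a machine whose every rule halts does so in one step
  one <- turingMachine(rbind(
    data.frame(state = "A", read = "0", write = "1", move = "R",
               "next" = "HALT", check.names = FALSE),
    data.frame(state = "A", read = "1", write = "1", move = "R",
               "next" = "HALT", check.names = FALSE)), initial = "A")
  expect_identical(tmRun(one, c0)$steps, 1L)
  # a ping-pong machine never halts and stops at the cap
  pp <- turingMachine(rbind(
    data.frame(state = "A", read = "0", write = "0", move = "R",
               "next" = "B", check.names = FALSE),
    data.frame(state = "A", read = "1", write = "1", move = "R",
               "next" = "B", check.names = FALSE),
    data.frame(state = "B", read = "0", write = "0", move = "L",
               "next" = "A", check.names = FALSE),
    data.frame(state = "B", read = "1", write = "1", move = "L",
               "next" = "A", check.names = FALSE)), initial = "A")
  res <- tmRun(pp, c0, maxSteps = 50L)
  expect_false(res$halted)
  expect_identical(res$steps, 50L)
})

test_that("the binary adder is exhaustively correct on all 64 inputs", {
  add <- binaryAdderMachine()
  for (a in 0:7) for (b in 0:7) {
    res <- tmRun(add, adderConfiguration(a, b), maxSteps = 500L)
    expect_true(res$halted, label = sprintf("%d + %d halts", a, b))
    ts <- tapeString(res$config)
    expect_identical(substr(ts, 1, 4), "0000")
    expect_identical(strtoi(substr(ts, 5, 8), base = 2L), a + b,
                     label = sprintf("%d + %d", a, b))
  }
})

test_that("countMaxConsecutive matches a run-length-encoding oracle", {
  expect_identical(countMaxConsecutive(c("0","1","1","1","1","1","1","0")), 6L)
  expect_identical(countMaxConsecutive(rep("0", 8), "1"), 0L)
  set.seed(5)
  for (i in 1:50) {
    tape <- sample(c("0", "1"), 20, replace = TRUE)
    r <- rle(tape)
    want <- if (any(r$values == "1")) max(r$lengths[r$values == "1"]) else 0L
    expect_identical(countMaxConsecutive(tape, "1"), as.integer(want))
  }
})

test_that("transition tables round-trip through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  writeTransitionTable(binaryAdderMachine(), path)
  m <- readTransitionTable(path)
  expect_identical(transitionTable(m), transitionTable(binaryAdderMachine()))
  expect_identical(machineStates(m), machineStates(binaryAdderMachine()))
  # the shipped fixtures load and validate
  bb <- readTransitionTable(bbFixturePath())
  expect_identical(transitionTable(bb), transitionTable(busyBeaverMachine()))
})
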