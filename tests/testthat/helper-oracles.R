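# Independent oracles used across the suite.  These deliberately share
# no code with the package internals.

# A naive table-scanning Turing-machine simulator (the five-line dual
# implementation used to cross-check tmRun).
naiveTM <- function(table, tape, head, state, steps) {
  for (k in seq_len(steps)) {
    if (state == "HALT") break
    row <- table[table$state == state & table$read == tape[head], , drop = FALSE]
    tape[head] <- row$write[1L]
    head <- head + if (row$move[1L] == "R") 1L else -1L
    if (head < 1L || head > length(tape)) return(list(overrun = TRUE))
    state <- row[["next"]][1L]
  }
  list(tape = tape, head = head, state = state, overrun = FALSE)
}

# Evaluate a condition string by translating it to an R logical
# expression (independent of the package's recursive evaluator).
rCondOracle <- function(text, assignment) {
  rtext <- text
  rtext <- gsub("\\bnot\\b", "!", rtext, ignore.case = TRUE)
  rtext <- gsub("\\band\\b", "&", rtext, ignore.case = TRUE)
  rtext <- gsub("\\bor\\b", "|", rtext, ignore.case = TRUE)
  rtext <- gsub("\\btrue\\b", "TRUE", rtext, ignore.case = TRUE)
  rtext <- gsub("\\bfalse\\b", "FALSE", rtext, ignore.case = TRUE)
  eval(parse(text = rtext), envir = as.list(assignment))
}

# Seed-deterministic random condition text over the given variables.
randomConditionText <- function(vars, maxDepth = 3L) {
  build <- function(depth) {
    if (depth >= maxDepth || runif(1) < 0.35)
      return(sample(c(vars, "true", "false"), 1L,
                    prob = c(rep(0.3, length(vars)), 0.05, 0.05)))
    op <- sample(c("not", "and", "or", "paren"), 1L)
    switch(op,
      not = paste("not", build(depth + 1L)),
      and = paste(build(depth + 1L), "and", build(depth + 1L)),
      or = paste(build(depth + 1L), "or", build(depth + 1L)),
      paren = paste0("(", build(depth + 1L), ")"))
  }
  build(0L)
}

# Random but valid platform operation sequence applied to a platform;
# returns the final state (errors from deliberately invalid picks are
# skipped so the sequence stays valid).
randomPlatformOps <- function(platform, n) {
  ids <- vesselIds(platform)
  applied <- 0L
  while (applied < n) {
    kind <- sample(c("transfer", "empty", "stock"), 1L)
    newState <- tryCatch(switch(kind,
      transfer = transfer(platform, sample(ids, 1L), sample(ids, 1L),
                          volume = sample(c(0.1, 0.5, 1, 2), 1L)),
      empty = emptyToWaste(platform, sample(ids, 1L)),
      stock = addFromStock(platform, sample(c("orange", "blue", "green"), 1L),
                           sample(ids, 1L), volume = sample(c(0.5, 1), 1L))),
      error = function(e) NULL)
    if (!is.null(newState)) {
      platform <- newState
      applied <- applied + 1L
    }
  }
  platform
}

# Count orange markers in the head row.
headMarkerCount <- function(platform, N) {
  sum(vapply(seq_len(N), function(i)
    sense(platform, sprintf("head_%d", i), "color")$value == "orange",
    logical(1L)))
}

bbFixturePath <- function() {
  system.file("extdata", "busy_beaver.json", package = "chemturing")
}
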