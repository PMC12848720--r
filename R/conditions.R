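# Boolean condition grammar attached to steps:
#   expr    := or
#   or      := and ("or" and)*
#   and     := unary ("and" unary)*
#   unary   := "not" unary | primary
#   primary := "(" expr ")" | identifier | "true" | "false"
# Precedence NOT > AND > OR; keywords are case-insensitive; identifiers
# are the step_ids of Measure steps.

.condError <- function(msg, pos) {
  stop(structure(
    class = c("chemturing_condition_syntax", "error", "condition"),
    list(message = sprintf("condition syntax error at position %d: %s", pos, msg),
         call = NULL)
  ))
}

.condTokens <- function(text) {
  n <- nchar(text)
  toks <- list()
  i <- 1L
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("[[:space:]]", ch)) { i <- i + 1L; next }
    if (ch == "(") { toks[[length(toks) + 1L]] <- list(type = "lparen", pos = i); i <- i + 1L; next }
    if (ch == ")") { toks[[length(toks) + 1L]] <- list(type = "rparen", pos = i); i <- i + 1L; next }
    m <- regmatches(substr(text, i, n),
                    regexpr("^[A-Za-z_][A-Za-z0-9_]*", substr(text, i, n)))
    if (length(m) == 1L) {
      word <- m
      type <- switch(tolower(word),
        "not" = "not", "and" = "and", "or" = "or",
        "true" = "true", "false" = "false", "ident")
      toks[[length(toks) + 1L]] <- list(type = type, value = word, pos = i)
      i <- i + nchar(word)
      next
    }
    .condError(sprintf("unexpected character '%s'", ch), i)
  }
  toks
}

#' Parse a boolean condition expression
#'
#' Parses the condition grammar used in `condition` attributes: atoms are
#' step_id references or the literals `true`/`false`, combined with
#' `not`, `and`, `or` and parentheses, with precedence NOT > AND > OR.
#'
#' @param text a nonempty condition string, e.g. `"not HALT"` or
#'   `"A and not B or C"`.
#' @return an expression tree: nested lists with a `type` field
#'   (`"atom"`, `"lit"`, `"not"`, `"and"`, `"or"`).
#' @examples
#' parseCondition("C")
#' parseCondition("A and not B or C")
#' @seealso [evaluateCondition()], [conditionVariables()]
#' @export
parseCondition <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text)))
    .condError("empty expression", 1L)
  toks <- .condTokens(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  expect_end_pos <- function() if (pos <= length(toks)) toks[[pos]]$pos else nchar(text) + 1L

  parsePrimary <- function() {
    t <- peek()
    if (is.null(t)) .condError("unexpected end of expression", nchar(text) + 1L)
    if (t$type == "lparen") {
      advance()
      e <- parseOr()
      t2 <- peek()
      if (is.null(t2) || t2$type != "rparen")
        .condError("expected ')'", expect_end_pos())
      advance()
      return(e)
    }
    if (t$type == "ident") { advance(); return(list(type = "atom", id = t$value)) }
    if (t$type == "true")  { advance(); return(list(type = "lit", value = TRUE)) }
    if (t$type == "false") { advance(); return(list(type = "lit", value = FALSE)) }
    .condError(sprintf("unexpected '%s'",
                       if (!is.null(t$value)) t$value else t$type), t$pos)
  }
  parseUnary <- function() {
    t <- peek()
    if (!is.null(t) && t$type == "not") { advance(); return(list(type = "not", x = parseUnary())) }
    parsePrimary()
  }
  parseAnd <- function() {
    args <- list(parseUnary())
    while (!is.null(t <- peek()) && t$type == "and") {
      advance()
      args[[length(args) + 1L]] <- parseUnary()
    }
    if (length(args) == 1L) args[[1L]] else list(type = "and", args = args)
  }
  parseOr <- function() {
    args <- list(parseAnd())
    while (!is.null(t <- peek()) && t$type == "or") {
      advance()
      args[[length(args) + 1L]] <- parseAnd()
    }
    if (length(args) == 1L) args[[1L]] else list(type = "or", args = args)
  }

  e <- parseOr()
  if (pos <= length(toks))
    .condError(sprintf("unexpected trailing '%s'",
                       if (!is.null(toks[[pos]]$value)) toks[[pos]]$value
                       else toks[[pos]]$type),
               toks[[pos]]$pos)
  e
}

#' Evaluate a condition against a variable store
#'
#' Standard boolean semantics; evaluation is strict — every referenced
#' variable must have a stored value, and a read of an unset step_id is
#' an error, never a silent default.  The store is not modified.
#'
#' @param expr a parsed condition tree from [parseCondition()] (a string
#'   is accepted and parsed first).
#' @param store a named logical vector, list, or environment mapping
#'   step_id to boolean.
#' @return `TRUE` or `FALSE`.
#' @examples
#' evaluateCondition("not HALT", c(HALT = FALSE))
#' @export
evaluateCondition <- function(expr, store) {
  if (is.character(expr)) expr <- parseCondition(expr)
  isEnv <- is.environment(store)
  lookup <- function(id) {
    if (isEnv) {
      if (!exists(id, envir = store, inherits = FALSE))
        stop(.runtimeError(sprintf("unset condition variable '%s'", id)))
      get(id, envir = store, inherits = FALSE)
    } else {
      if (!id %in% names(store))
        stop(.runtimeError(sprintf("unset condition variable '%s'", id)))
      isTRUE(store[[id]])
    }
  }
  ev <- function(nd) {
    switch(nd$type,
      lit  = nd$value,
      atom = isTRUE(lookup(nd$id)),
      "not" = !ev(nd$x),
      "and" = all(vapply(nd$args, ev, logical(1L))),
      "or"  = any(vapply(nd$args, ev, logical(1L))),
      stop("invalid condition node")
    )
  }
  ev(expr)
}

#' Variables referenced by a condition
#'
#' @param expr a parsed condition tree or condition string.
#' @return character vector of distinct step_ids referenced.
#' @export
conditionVariables <- function(expr) {
  if (is.character(expr)) expr <- parseCondition(expr)
  vars <- character()
  walk <- function(nd) {
    switch(nd$type,
      atom = vars[[length(vars) + 1L]] <<- nd$id,
      "not" = walk(nd$x),
      "and" = , "or" = for (a in nd$args) walk(a),
      lit = invisible(NULL)
    )
  }
  walk(expr)
  unique(vars)
}

# Render a condition tree back to its textual form (used when a step was
# built programmatically without source text).
.deparseCondition <- function(nd, parent = "or") {
  txt <- switch(nd$type,
    lit  = if (nd$value) "true" else "false",
    atom = nd$id,
    "not" = paste0("not ", .deparseCondition(nd$x, "not")),
    "and" = paste(vapply(nd$args, .deparseCondition, character(1L), parent = "and"),
                  collapse = " and "),
    "or"  = paste(vapply(nd$args, .deparseCondition, character(1L), parent = "or"),
                  collapse = " or ")
  )
  needParen <- (nd$type == "or" && parent %in% c("and", "not")) ||
               (nd$type == "and" && parent == "not")
  if (needParen) paste0("(", txt, ")") else txt
}

.runtimeError <- function(msg) {
  structure(
    class = c("chemturing_runtime", "error", "condition"),
    list(message = msg, call = NULL)
  )
}
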