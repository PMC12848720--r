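# The conditional-XDL dialect (a deliberately small subset of XDL):
#
#   <XDL>
#     <Reagents><Reagent id="..." color="..."/>...</Reagents>
#     <Vessels><Vessel id="..."/>...</Vessels>
#     <Blueprint id="..." params="a,b">...steps...</Blueprint>*
#     <Procedure>...steps...</Procedure>
#   </XDL>
#
# Step elements: Add(vessel, reagent, volume), Transfer(from_vessel,
# to_vessel, volume), EmptyToWaste(vessel), Wait(time),
# Measure(step_id, vessel, quantity, comparison, value[, value2]),
# Repeat(condition, max_iterations){children}, and invocation of a
# blueprint by its id with bound parameters.  Any step may carry
# condition="<boolean expression>".

.KNOWN_STEPS <- c("Add", "Transfer", "EmptyToWaste", "Wait", "Measure", "Repeat")
.NUMERIC_PARAMS <- c("volume", "time", "value2")
.QUANTITIES <- c("color", "temperature", "pH", "volume")
.COMPARISONS <- c("equal", "not_equal", "less_than", "greater_than", "between")

# Shared step constructor so parsed and compiled documents are
# structurally identical (condition text is parsed eagerly, once).
.step <- function(name, params = list(), condition = NULL, step_id = NULL,
                  children = list()) {
  if (length(params) == 0L) params <- list()  # drop empty-names attribute
  list(name = name, params = params,
       condition = if (is.null(condition)) NULL else parseCondition(condition),
       condition_text = condition,
       step_id = step_id, children = children)
}

.parseStepNode <- function(node) {
  name <- xml2::xml_name(node)
  attrs <- as.list(xml2::xml_attrs(node))
  condition <- attrs[["condition"]]
  step_id <- attrs[["step_id"]]
  attrs[["condition"]] <- NULL
  attrs[["step_id"]] <- NULL
  params <- attrs
  numericParams <- .NUMERIC_PARAMS
  if (name == "Measure" && !identical(params[["quantity"]], "color"))
    numericParams <- c(numericParams, "value")
  if (name == "Repeat" && !is.null(params[["max_iterations"]]))
    params[["max_iterations"]] <- as.integer(params[["max_iterations"]])
  for (p in intersect(names(params), numericParams)) {
    num <- suppressWarnings(as.numeric(params[[p]]))
    # a non-numeric value here is a blueprint formal parameter name,
    # resolved (and coerced) at invocation time
    if (!is.na(num)) params[[p]] <- num
  }
  children <- lapply(xml2::xml_children(node), .parseStepNode)
  .step(name, params, condition = condition, step_id = step_id,
        children = children)
}

#' Parse a conditional-XDL document
#'
#' Reads the XML dialect, parses every `condition` attribute into an
#' expression tree, and validates the document: all referenced vessels,
#' reagents and blueprints must be declared, step_ids must be unique
#' across the document and mandatory on Measure steps, every condition
#' may reference only step_ids that some Measure defines, Measure specs
#' must be well-formed, and the blueprint call graph must be acyclic
#' (looping is provided solely by Repeat).
#'
#' @param x a file path or a literal XML string.
#' @return a validated [XDLDocument-class].
#' @examples
#' doc <- parseXDL(system.file("extdata", "quench_transfer.xdl",
#'                             package = "chemturing"))
#' length(doc@main)
#' @seealso [serializeXDL()], [executeProcedure()]
#' @export
parseXDL <- function(x) {
  xml <- if (length(x) == 1L && grepl("^\\s*<", x)) xml2::read_xml(x)
         else xml2::read_xml(x)
  if (xml2::xml_name(xml) != "XDL")
    stop(.validationError("root element must be <XDL>"))
  reagents <- data.frame(id = character(0), color = character(0),
                         stringsAsFactors = FALSE)
  vessels <- character(0)
  blueprints <- list()
  main <- list()
  for (child in xml2::xml_children(xml)) {
    nm <- xml2::xml_name(child)
    if (nm == "Reagents") {
      rows <- xml2::xml_find_all(child, "./Reagent")
      reagents <- data.frame(
        id = xml2::xml_attr(rows, "id"),
        color = xml2::xml_attr(rows, "color"),
        stringsAsFactors = FALSE)
    } else if (nm == "Vessels") {
      vessels <- xml2::xml_attr(xml2::xml_find_all(child, "./Vessel"), "id")
    } else if (nm == "Blueprint") {
      id <- xml2::xml_attr(child, "id")
      if (is.na(id)) stop(.validationError("Blueprint without id"))
      paramsAttr <- xml2::xml_attr(child, "params")
      params <- if (is.na(paramsAttr) || !nzchar(paramsAttr)) character(0)
                else trimws(strsplit(paramsAttr, ",")[[1L]])
      blueprints[[id]] <- list(
        params = params,
        steps = lapply(xml2::xml_children(child), .parseStepNode))
    } else if (nm == "Procedure") {
      main <- lapply(xml2::xml_children(child), .parseStepNode)
    } else {
      stop(.validationError(sprintf("unknown top-level element <%s>", nm)))
    }
  }
  doc <- new("XDLDocument", reagents = reagents, vessels = vessels,
             blueprints = blueprints, main = main)
  validateXDLDocument(doc)
  doc
}

# Depth-first walk over every step in the document (blueprint bodies
# included), calling fn(step, blueprint_formals).
.walkSteps <- function(doc, fn) {
  recurse <- function(steps, formals) {
    for (s in steps) {
      fn(s, formals)
      if (length(s$children)) recurse(s$children, formals)
    }
  }
  recurse(doc@main, character(0))
  for (bp in doc@blueprints) recurse(bp$steps, bp$params)
  invisible(NULL)
}

.validateMeasureSpec <- function(s) {
  p <- s$params
  if (is.null(s$step_id))
    stop(.validationError("Measure without step_id"))
  if (is.null(p$vessel) || is.null(p$quantity) || is.null(p$comparison) ||
      is.null(p$value))
    stop(.validationError(sprintf(
      "Measure '%s': vessel, quantity, comparison and value are mandatory",
      s$step_id)))
  if (!p$quantity %in% .QUANTITIES)
    stop(.validationError(sprintf("Measure '%s': unknown quantity '%s'",
                                  s$step_id, p$quantity)))
  if (!p$comparison %in% .COMPARISONS)
    stop(.validationError(sprintf("Measure '%s': unknown comparison '%s'",
                                  s$step_id, p$comparison)))
  if (p$quantity == "color") {
    if (!p$comparison %in% c("equal", "not_equal"))
      stop(.validationError(sprintf(
        "Measure '%s': comparison '%s' is not defined on colors",
        s$step_id, p$comparison)))
    if (!p$value %in% .CHEM_COLORS)
      stop(.validationError(sprintf("Measure '%s': unknown color label '%s'",
                                    s$step_id, p$value)))
  }
  if (p$comparison == "between") {
    if (is.null(p$value2))
      stop(.validationError(sprintf(
        "Measure '%s': between needs exactly two reference values", s$step_id)))
    if (p$value > p$value2)
      stop(.validationError(sprintf(
        "Measure '%s': between bounds must satisfy low <= high", s$step_id)))
  } else if (!is.null(p$value2)) {
    stop(.validationError(sprintf(
      "Measure '%s': value2 is only allowed with between", s$step_id)))
  }
  invisible(TRUE)
}

#' Validate an XDL document's invariants
#'
#' Called by [parseXDL()]; exported so programmatically built documents
#' can be checked too.  Errors (class `chemturing_validation`) on any
#' violation; see [parseXDL()] for the full list of invariants.
#'
#' @param doc an [XDLDocument-class].
#' @return `TRUE`, invisibly.
#' @export
validateXDLDocument <- function(doc) {
  stepIds <- character(0)
  condVars <- character(0)
  .walkSteps(doc, function(s, formals) {
    if (!s$name %in% .KNOWN_STEPS && !s$name %in% names(doc@blueprints))
      stop(.validationError(sprintf("unknown step name '%s'", s$name)))
    if (!is.null(s$step_id)) stepIds <<- c(stepIds, s$step_id)
    if (s$name == "Measure") {
      .validateMeasureSpec(s)
    }
    if (!is.null(s$condition))
      condVars <<- c(condVars, conditionVariables(s$condition))
    if (s$name %in% c("Add", "Transfer", "EmptyToWaste", "Measure")) {
      for (p in intersect(names(s$params), c("vessel", "from_vessel", "to_vessel"))) {
        v <- s$params[[p]]
        if (!v %in% doc@vessels && !v %in% formals)
          stop(.validationError(sprintf("undeclared vessel '%s'", v)))
      }
      if (!is.null(s$params$reagent) &&
          !s$params$reagent %in% doc@reagents$id &&
          !s$params$reagent %in% formals)
        stop(.validationError(sprintf("undeclared reagent '%s'", s$params$reagent)))
    }
    if (s$name == "Repeat" && !is.null(s$params$max_iterations) &&
        s$params$max_iterations < 0L)
      stop(.validationError("Repeat max_iterations must be >= 0"))
    if (length(s$children) && !s$name %in% c("Repeat"))
      stop(.validationError(sprintf(
        "step '%s' may not have children (only Repeat nests inline)", s$name)))
  })
  if (anyDuplicated(stepIds))
    stop(.validationError(sprintf(
      "duplicate step_id '%s'", stepIds[duplicated(stepIds)][1L])))
  measureIds <- character(0)
  .walkSteps(doc, function(s, formals) {
    if (s$name == "Measure") measureIds <<- c(measureIds, s$step_id)
  })
  undef <- setdiff(unique(condVars), measureIds)
  if (length(undef))
    stop(.validationError(sprintf("undefined condition variable %s",
                                  paste(undef, collapse = ", "))))
  # blueprint call graph must be acyclic (and all invocations defined)
  callees <- function(steps) {
    out <- character(0)
    for (s in steps) {
      if (!s$name %in% .KNOWN_STEPS) out <- c(out, s$name)
      if (length(s$children)) out <- c(out, callees(s$children))
    }
    unique(out)
  }
  visiting <- character(0)
  done <- character(0)
  visit <- function(id) {
    if (id %in% done) return(invisible(NULL))
    if (id %in% visiting)
      stop(.validationError(sprintf("recursive blueprint '%s'", id)))
    visiting <<- c(visiting, id)
    for (cal in callees(doc@blueprints[[id]]$steps)) {
      if (!cal %in% names(doc@blueprints))
        stop(.validationError(sprintf("undefined blueprint '%s'", cal)))
      visit(cal)
    }
    visiting <<- setdiff(visiting, id)
    done <<- c(done, id)
  }
  for (id in names(doc@blueprints)) visit(id)
  for (cal in callees(doc@main))
    if (!cal %in% names(doc@blueprints))
      stop(.validationError(sprintf("undefined blueprint '%s'", cal)))
  invisible(TRUE)
}
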