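.fmtParam <- function(v) {
  if (is.numeric(v)) format(v, scientific = FALSE, trim = TRUE) else as.character(v)
}

.stepToXML <- function(parent, s) {
  node <- xml2::xml_add_child(parent, s$name)
  for (p in names(s$params))
    xml2::xml_set_attr(node, p, .fmtParam(s$params[[p]]))
  if (!is.null(s$step_id)) xml2::xml_set_attr(node, "step_id", s$step_id)
  if (!is.null(s$condition_text))
    xml2::xml_set_attr(node, "condition", s$condition_text)
  for (ch in s$children) .stepToXML(node, ch)
  node
}

#' Serialize an XDL document back to XML
#'
#' Deterministic: the same document always yields byte-identical XML,
#' and `parseXDL(serializeXDL(doc))` reproduces `doc`.
#'
#' @param doc an [XDLDocument-class].
#' @return a single character string of XML.
#' @seealso [writeXDL()]
#' @export
serializeXDL <- function(doc) {
  root <- xml2::xml_new_root("XDL")
  if (nrow(doc@reagents)) {
    rs <- xml2::xml_add_child(root, "Reagents")
    for (i in seq_len(nrow(doc@reagents))) {
      r <- xml2::xml_add_child(rs, "Reagent")
      xml2::xml_set_attr(r, "id", doc@reagents$id[i])
      xml2::xml_set_attr(r, "color", doc@reagents$color[i])
    }
  }
  if (length(doc@vessels)) {
    vs <- xml2::xml_add_child(root, "Vessels")
    for (v in doc@vessels) {
      n <- xml2::xml_add_child(vs, "Vessel")
      xml2::xml_set_attr(n, "id", v)
    }
  }
  for (id in names(doc@blueprints)) {
    bp <- doc@blueprints[[id]]
    n <- xml2::xml_add_child(root, "Blueprint")
    xml2::xml_set_attr(n, "id", id)
    if (length(bp$params))
      xml2::xml_set_attr(n, "params", paste(bp$params, collapse = ","))
    for (s in bp$steps) .stepToXML(n, s)
  }
  proc <- xml2::xml_add_child(root, "Procedure")
  for (s in doc@main) .stepToXML(proc, s)
  as.character(root)
}

#' Write an XDL document to a file
#'
#' @param doc an [XDLDocument-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeXDL <- function(doc, path) {
  writeLines(serializeXDL(doc), path)
  invisible(path)
}
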