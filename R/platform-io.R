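# Platform configuration files (YAML or JSON):
#   vessels: [{id, capacity, temperature?, pH?,
#              contents?: [{solution, volume}]}]
#   solutions: [{id, color}]          # optional; defaults to the three colors
#   stocks: [{color, volume, id?}]    # creates/fills stock_<color> flasks
#   nodes: [pump_1, ...]
#   edges: [[a, b], ...]
# Volumes and capacities are mL; capacity "Inf" (or omitted) is unbounded.

#' Read a platform configuration file
#'
#' Loads a YAML (`.yaml`/`.yml`) or JSON platform description and builds
#' the corresponding [PlatformState-class].  Connectivity is taken from
#' the file, so restricted backbone topologies can be modeled.
#'
#' @param path path to the configuration file.
#' @return a [PlatformState-class].
#' @seealso [writePlatformConfig()], [virtualPlatform()]
#' @export
readPlatformConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  .platformFromConfig(cfg)
}

.platformFromConfig <- function(cfg) {
  solutions <- if (is.null(cfg$solutions)) {
    stats::setNames(.SOLUTION_COLORS, .SOLUTION_COLORS)
  } else {
    stats::setNames(
      vapply(cfg$solutions, function(s) s$color, character(1L)),
      vapply(cfg$solutions, function(s) s$id, character(1L)))
  }
  vessels <- list()
  for (v in cfg$vessels) {
    cap <- if (is.null(v$capacity) || identical(v$capacity, "Inf")) Inf
           else .mL2uL(as.numeric(v$capacity))
    vv <- .newVessel(cap,
                     temperature = if (is.null(v$temperature)) 20 else v$temperature,
                     pH = if (is.null(v$pH)) 7 else v$pH)
    if (!is.null(v$contents)) {
      ids <- vapply(v$contents, function(c) c$solution, character(1L))
      vols <- vapply(v$contents, function(c) .mL2uL(as.numeric(c$volume)), numeric(1L))
      vv$contents <- stats::setNames(vols, ids)
    }
    vessels[[v$id]] <- vv
  }
  stocks <- character(0)
  for (s in cfg$stocks) {
    sid <- if (is.null(s$id)) sprintf("stock_%s", s$color) else s$id
    if (is.null(vessels[[sid]])) vessels[[sid]] <- .newVessel(Inf)
    if (!s$color %in% names(solutions))
      solutions[[s$color]] <- s$color
    vessels[[sid]]$contents <- stats::setNames(.mL2uL(as.numeric(s$volume)), s$color)
    stocks[[s$color]] <- sid
  }
  if (is.null(vessels[["waste"]])) vessels[["waste"]] <- .newVessel(Inf)
  nodes <- as.character(unlist(cfg$nodes))
  edges <- if (length(cfg$edges))
    do.call(rbind, lapply(cfg$edges, function(e) c(e[[1L]], e[[2L]])))
  else matrix(character(0), ncol = 2L)
  .assemblePlatform(vessels, solutions, stocks, nodes, edges)
}

#' Write a platform configuration file
#'
#' Serializes a [PlatformState-class] back to YAML or JSON (chosen by
#' file extension) in the schema read by [readPlatformConfig()].
#'
#' @param state a [PlatformState-class].
#' @param path output path (`.yaml`, `.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
writePlatformConfig <- function(state, path) {
  stockIds <- unname(state@stocks)
  cfg <- list(
    vessels = lapply(setdiff(names(state@vessels), stockIds), function(id) {
      v <- state@vessels[[id]]
      out <- list(id = id,
                  capacity = if (is.finite(v$capacity)) v$capacity / 1000 else "Inf",
                  temperature = v$temperature, pH = v$pH)
      if (length(v$contents))
        out$contents <- lapply(names(v$contents), function(sid)
          list(solution = sid, volume = v$contents[[sid]] / 1000))
      out
    }),
    solutions = lapply(names(state@solutions), function(id)
      list(id = id, color = unname(state@solutions[[id]]))),
    stocks = lapply(names(state@stocks), function(col) {
      sid <- state@stocks[[col]]
      list(color = col, id = sid,
           volume = sum(state@vessels[[sid]]$contents) / 1000)
    }),
    nodes = as.list(state@nodes),
    edges = lapply(seq_len(nrow(state@edges)), function(i)
      as.list(state@edges[i, ]))
  )
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(cfg, path)
  else
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
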