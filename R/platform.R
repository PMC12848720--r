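# Virtual liquid-handling platform.  All volumes are whole microliters
# internally (exact decimal accounting); the user-facing unit is mL.

.platformError <- function(msg) {
  structure(
    class = c("chemturing_platform", "error", "condition"),
    list(message = msg, call = NULL)
  )
}

.validationError <- function(msg) {
  structure(
    class = c("chemturing_validation", "error", "condition"),
    list(message = msg, call = NULL)
  )
}

.mL2uL <- function(v) {
  u <- round(v * 1000)
  if (any(abs(v * 1000 - u) > 1e-6))
    stop(.validationError("volumes must be whole microliters (3 decimals of mL)"))
  u
}

.checkVessel <- function(state, id) {
  if (!is.character(id) || length(id) != 1L || !id %in% names(state@vessels))
    stop(.platformError(sprintf("unknown vessel '%s'", paste(id, collapse = ","))))
  invisible(TRUE)
}

.newVessel <- function(capacity_uL, temperature = 20, pH = 7) {
  list(capacity = capacity_uL,
       contents = stats::setNames(numeric(0), character(0)),
       temperature = temperature, pH = pH)
}

# Connected components over vessels + backbone nodes (transfer requires
# src and dst in one component).
.components <- function(vertices, edges) {
  if (nrow(edges) == 0L) {
    return(stats::setNames(seq_along(vertices), vertices))
  }
  df <- data.frame(from = edges[, 1L], to = edges[, 2L],
                   stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(df, directed = FALSE,
                                     vertices = data.frame(name = vertices))
  memb <- igraph::components(g)$membership
  stats::setNames(as.integer(memb), names(memb))
}

.assemblePlatform <- function(vessels, solutions, stocks, nodes, edges) {
  verts <- c(names(vessels), nodes)
  bad <- setdiff(unique(as.vector(edges)), verts)
  if (length(bad))
    stop(.validationError(sprintf("edge references unknown node(s): %s",
                                  paste(bad, collapse = ", "))))
  obj <- new("PlatformState",
    vessels = vessels, solutions = solutions, stocks = stocks,
    nodes = nodes, edges = edges,
    membership = .components(verts, edges), counter = 0L)
  validObject(obj)
  obj
}

#' Create the default virtual Chemputer
#'
#' Builds the digital twin used throughout: a row of `tapeLength` tape
#' vials, an equally long row of head vials, two state vials, one stock
#' flask per color (orange, blue, green), a waste container of unbounded
#' capacity, and a fully reachable liquid-handling backbone of three
#' pumps and five valves.
#'
#' @param tapeLength number of tape (and head) vials, default 8.
#' @param vialCapacity capacity of each vial in mL, default 10.
#' @param stockVolume initial volume of each stock flask in mL,
#'   default 1000 (a one-liter reservoir, ample for the longest runs
#'   considered here).
#' @param temperature initial temperature of every vessel in degrees C.
#' @param pH initial pH attribute of every vessel.
#' @return a [PlatformState-class].
#' @examples
#' p <- virtualPlatform()
#' vesselIds(p)
#' @export
virtualPlatform <- function(tapeLength = 8L, vialCapacity = 10,
                            stockVolume = 1000, temperature = 20, pH = 7) {
  tapeLength <- as.integer(tapeLength)
  stopifnot(tapeLength >= 1L, vialCapacity > 0, stockVolume > 0)
  cap <- .mL2uL(vialCapacity)
  vessels <- list()
  for (i in seq_len(tapeLength)) {
    vessels[[sprintf("tape_%d", i)]] <- .newVessel(cap, temperature, pH)
    vessels[[sprintf("head_%d", i)]] <- .newVessel(cap, temperature, pH)
  }
  vessels[["state_1"]] <- .newVessel(cap, temperature, pH)
  vessels[["state_2"]] <- .newVessel(cap, temperature, pH)
  solutions <- stats::setNames(.SOLUTION_COLORS, .SOLUTION_COLORS)
  stocks <- character(0)
  for (col in .SOLUTION_COLORS) {
    sid <- sprintf("stock_%s", col)
    v <- .newVessel(Inf, temperature, pH)
    v$contents <- stats::setNames(.mL2uL(stockVolume), col)
    vessels[[sid]] <- v
    stocks[[col]] <- sid
  }
  vessels[["waste"]] <- .newVessel(Inf, temperature, pH)

  nodes <- c(paste0("pump_", 1:3), paste0("valve_", 1:5))
  edges <- rbind(
    cbind(paste0("valve_", 1:4), paste0("valve_", 2:5)),
    cbind(paste0("pump_", 1:3), paste0("valve_", c(1L, 3L, 5L)))
  )
  # tape vials on valves 1-2, head vials on valves 3-4, the rest on valve 5
  for (i in seq_len(tapeLength)) {
    edges <- rbind(edges,
      c(sprintf("tape_%d", i), sprintf("valve_%d", 1L + (i %% 2L))),
      c(sprintf("head_%d", i), sprintf("valve_%d", 3L + (i %% 2L))))
  }
  for (id in c("state_1", "state_2", names(vessels)[startsWith(names(vessels), "stock_")],
               "waste"))
    edges <- rbind(edges, c(id, "valve_5"))
  .assemblePlatform(vessels, solutions, stocks, nodes, edges)
}

# Largest-remainder proportional split of `vol` uL out of `contents`,
# deterministic (ties broken by solution id).  Returns the moved vector.
.takeProportional <- function(contents, vol) {
  tot <- sum(contents)
  if (length(contents) == 1L)
    return(stats::setNames(vol, names(contents)))
  exact <- contents * (vol / tot)
  fl <- floor(exact)
  rem <- vol - sum(fl)
  if (rem > 0) {
    frac <- exact - fl
    ord <- order(-frac, names(contents))
    take <- ord[seq_len(rem)]
    fl[take] <- fl[take] + 1
  }
  fl[fl > 0]
}

.addContents <- function(contents, moved) {
  for (sid in names(moved)) {
    if (sid %in% names(contents)) contents[[sid]] <- contents[[sid]] + moved[[sid]]
    else contents[[sid]] <- moved[[sid]]
  }
  contents
}

#' Move liquid between two vessels
#'
#' Moves `volume` mL from `src` to `dst`, preserving the proportions of
#' the source mixture.  The operation is transactional: on any error the
#' returned state is untouched (the input state is never modified — all
#' platform operations are functional).  Total liquid across all vessels
#' is conserved exactly.
#'
#' @param state a [PlatformState-class].
#' @param src,dst vessel ids; must be distinct and connected through the
#'   backbone graph.
#' @param volume volume to move in mL (> 0); the source must hold at
#'   least this much and the destination must have the free capacity.
#' @return the updated [PlatformState-class].
#' @examples
#' p <- virtualPlatform()
#' p2 <- transfer(p, "stock_orange", "tape_1", 1)
#' vesselVolume(p2, "tape_1")
#' @export
transfer <- function(state, src, dst, volume) {
  .checkVessel(state, src)
  .checkVessel(state, dst)
  if (identical(src, dst))
    stop(.platformError("source and destination must differ"))
  if (state@membership[[src]] != state@membership[[dst]])
    stop(.platformError(sprintf("no backbone path between '%s' and '%s'", src, dst)))
  vol <- .mL2uL(volume)
  if (vol <= 0) stop(.platformError("transfer volume must be > 0"))
  sv <- state@vessels[[src]]
  dv <- state@vessels[[dst]]
  if (sum(sv$contents) < vol)
    stop(.platformError(sprintf(
      "insufficient volume in '%s': have %.3f mL, need %.3f mL",
      src, sum(sv$contents) / 1000, vol / 1000)))
  if (sum(dv$contents) + vol > dv$capacity)
    stop(.platformError(sprintf("capacity of '%s' exceeded", dst)))
  moved <- .takeProportional(sv$contents, vol)
  sv$contents <- .takeProportionalRemainder(sv$contents, moved)
  dv$contents <- .addContents(dv$contents, moved)
  state@vessels[[src]] <- sv
  state@vessels[[dst]] <- dv
  state@counter <- state@counter + 1L
  state
}

# contents minus moved, dropping zeros
.takeProportionalRemainder <- function(contents, moved) {
  for (sid in names(moved)) contents[[sid]] <- contents[[sid]] - moved[[sid]]
  contents[contents > 0]
}

#' Empty a vessel into the waste container
#'
#' Moves all contents of `vessel` to `waste`; emptying an already empty
#' vessel is a no-op.  Afterwards the vessel's color reads white.
#'
#' @param state a [PlatformState-class].
#' @param vessel a vessel id.
#' @return the updated [PlatformState-class].
#' @export
emptyToWaste <- function(state, vessel) {
  .checkVessel(state, vessel)
  if (identical(vessel, "waste")) return(state)  # waste drains into itself
  v <- state@vessels[[vessel]]
  if (length(v$contents) == 0L) return(state)
  w <- state@vessels[["waste"]]
  w$contents <- .addContents(w$contents, v$contents)
  v$contents <- stats::setNames(numeric(0), character(0))
  state@vessels[[vessel]] <- v
  state@vessels[["waste"]] <- w
  state@counter <- state@counter + 1L
  state
}

#' Add solution from a color's stock flask
#'
#' Looks up the stock flask registered for `color` and delegates to
#' [transfer()].
#'
#' @param state a [PlatformState-class].
#' @param color one of `"orange"`, `"blue"`, `"green"`.
#' @param vessel destination vessel id.
#' @param volume volume in mL.
#' @return the updated [PlatformState-class].
#' @export
addFromStock <- function(state, color, vessel, volume) {
  if (!color %in% names(state@stocks))
    stop(.platformError(sprintf("no stock flask for color '%s'", color)))
  transfer(state, state@stocks[[color]], vessel, volume)
}

#' Read a virtual sensor
#'
#' Pure and deterministic: repeated reads of an unchanged state are
#' equal, and the state is never modified.  The color camera reports the
#' dominant solution color by volume (ties broken by lexicographic color
#' label); a vessel whose total volume is below the detection threshold
#' (0.1 mL) reads `"white"`.
#'
#' @param state a [PlatformState-class].
#' @param vessel a vessel id.
#' @param quantity one of `"color"`, `"temperature"`, `"pH"`, `"volume"`.
#' @return a list with fields `vessel`, `quantity`, `value` (color label,
#'   degrees C, pH units, or mL).
#' @examples
#' p <- virtualPlatform()
#' sense(p, "tape_1", "color")$value  # "white"
#' @export
sense <- function(state, vessel, quantity) {
  .checkVessel(state, vessel)
  v <- state@vessels[[vessel]]
  value <- switch(quantity,
    color = {
      tot <- sum(v$contents)
      if (tot < .DETECTION_THRESHOLD_UL) "white"
      else {
        cols <- state@solutions[names(v$contents)]
        byColor <- tapply(v$contents, cols, sum)
        byColor <- byColor[order(-byColor, names(byColor))]
        names(byColor)[1L]
      }
    },
    temperature = v$temperature,
    pH = v$pH,
    volume = sum(v$contents) / 1000,
    stop(.platformError(sprintf("unknown quantity '%s'", quantity)))
  )
  list(vessel = vessel, quantity = quantity, value = value)
}

#' Total liquid held on the platform
#'
#' Sums all vessel contents (including stocks and waste), in mL.  This
#' quantity is invariant under every platform operation — the handle used
#' by the conservation tests.
#'
#' @param state a [PlatformState-class].
#' @return total volume in mL.
#' @export
totalVolume <- function(state) {
  sum(vapply(state@vessels, function(v) sum(v$contents), numeric(1L))) / 1000
}

#' Set a vessel attribute
#'
#' Sets the temperature or pH attribute of a vessel (the platform has no
#' thermal or reaction model; these are plain settable sensor targets).
#'
#' @param state a [PlatformState-class].
#' @param vessel a vessel id.
#' @param temperature,pH new values; `NULL` leaves the attribute alone.
#' @return the updated [PlatformState-class].
#' @export
setVesselAttribute <- function(state, vessel, temperature = NULL, pH = NULL) {
  .checkVessel(state, vessel)
  v <- state@vessels[[vessel]]
  if (!is.null(temperature)) v$temperature <- temperature
  if (!is.null(pH)) v$pH <- pH
  state@vessels[[vessel]] <- v
  state
}
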