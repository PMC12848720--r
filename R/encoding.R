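# Color coding between machine configurations and vial contents.

#' Build the default color encoding for a machine
#'
#' Symbols map to vial colors in alphabet order, blank first:
#' blank -> white (an empty vial), then orange, blue, green — so for the
#' usual alphabets 0 -> white, 1 -> orange, x -> blue, y -> green.
#' States map to ordered pairs of colors for the two state vials: states
#' are taken in declaration order (HALT last) and the state's index is
#' written base-4 over the color order (white, orange, blue, green) into
#' (vial 1, vial 2), which encodes up to 16 states.
#'
#' @param machine a [TuringMachine-class].
#' @param tapeLength number of tape cells (and head vials), default 8.
#' @return a [ColorEncoding-class].
#' @examples
#' enc <- colorEncoding(busyBeaverMachine())
#' enc@symbolToColor
#' @export
colorEncoding <- function(machine, tapeLength = 8L) {
  ab <- machine@alphabet
  if (length(ab) > 4L)
    stop(.validationError("alphabet larger than 4 is not encodable"))
  ordered <- c(machine@blank, setdiff(ab, machine@blank))
  s2c <- stats::setNames(.CHEM_COLORS[seq_along(ordered)], ordered)
  st <- machine@states
  if (length(st) > 16L)
    stop(.validationError("more than 16 states are not encodable"))
  idx <- seq_along(st) - 1L
  pairs <- cbind(.CHEM_COLORS[idx %/% 4L + 1L], .CHEM_COLORS[idx %% 4L + 1L])
  rownames(pairs) <- st
  colnames(pairs) <- c("vial1", "vial2")
  obj <- new("ColorEncoding", symbolToColor = s2c, statePairs = pairs,
             tapeLength = as.integer(tapeLength),
             headRowLength = as.integer(tapeLength))
  validObject(obj)
  obj
}

.fillVial <- function(platform, vessel, color) {
  platform <- emptyToWaste(platform, vessel)
  if (color != "white")
    platform <- addFromStock(platform, color, vessel, 1)
  platform
}

#' Encode a machine configuration onto the platform
#'
#' Writes a [TMConfiguration-class] into vial contents: tape vial `i`
#' holds 1 mL of the color of `tape[i]` (white means the vial stays
#' empty), the head row holds exactly one orange vial at the head
#' position, and the two state vials hold the state's color pair.
#' Target vials are emptied first, so any platform with the standard
#' vial layout can be (re)initialized.
#'
#' @param config a [TMConfiguration-class].
#' @param encoding a [ColorEncoding-class]; symbols and state must be in
#'   its domain.
#' @param platform optional starting [PlatformState-class]; defaults to
#'   [virtualPlatform()] of the encoding's tape length.
#' @return the loaded [PlatformState-class].
#' @seealso [decodeConfiguration()]
#' @export
encodeConfiguration <- function(config, encoding, platform = NULL) {
  if (is.null(platform))
    platform <- virtualPlatform(tapeLength = encoding@tapeLength)
  N <- encoding@tapeLength
  if (length(config@tape) != N)
    stop(.validationError(sprintf("configuration tape length %d != encoding tape length %d",
                                  length(config@tape), N)))
  bad <- setdiff(config@tape, names(encoding@symbolToColor))
  if (length(bad))
    stop(.validationError(sprintf("unencodable symbol '%s'", bad[1L])))
  if (!config@state %in% rownames(encoding@statePairs))
    stop(.validationError(sprintf("unencodable state '%s'", config@state)))
  for (i in seq_len(N)) {
    platform <- .fillVial(platform, sprintf("tape_%d", i),
                          encoding@symbolToColor[[config@tape[i]]])
    platform <- .fillVial(platform, sprintf("head_%d", i),
                          if (i == config@head) "orange" else "white")
  }
  pair <- encoding@statePairs[config@state, ]
  platform <- .fillVial(platform, "state_1", pair[[1L]])
  platform <- .fillVial(platform, "state_2", pair[[2L]])
  platform
}

#' Decode the platform back into a machine configuration
#'
#' Inverse of [encodeConfiguration()]: reads tape vial colors back to
#' symbols, requires exactly one orange head vial, and matches the two
#' state vials against the encoding's state pairs.
#'
#' @param platform a [PlatformState-class] holding a valid encoding.
#' @param encoding the [ColorEncoding-class].
#' @return a [TMConfiguration-class].
#' @export
decodeConfiguration <- function(platform, encoding) {
  N <- encoding@tapeLength
  c2s <- stats::setNames(names(encoding@symbolToColor), encoding@symbolToColor)
  tape <- character(N)
  headAt <- integer(0)
  for (i in seq_len(N)) {
    col <- sense(platform, sprintf("tape_%d", i), "color")$value
    if (!col %in% names(c2s))
      stop(.runtimeError(sprintf("unrecognized tape color '%s' in tape_%d", col, i)))
    tape[i] <- c2s[[col]]
    hcol <- sense(platform, sprintf("head_%d", i), "color")$value
    if (hcol == "orange") headAt <- c(headAt, i)
    else if (hcol != "white")
      stop(.runtimeError(sprintf("unexpected color '%s' in head_%d", hcol, i)))
  }
  if (length(headAt) != 1L)
    stop(.runtimeError(sprintf("head row must hold exactly one orange vial, found %d",
                               length(headAt))))
  pair <- c(sense(platform, "state_1", "color")$value,
            sense(platform, "state_2", "color")$value)
  codes <- paste(encoding@statePairs[, 1L], encoding@statePairs[, 2L])
  hit <- match(paste(pair[1L], pair[2L]), codes)
  if (is.na(hit))
    stop(.runtimeError(sprintf("unrecognized state-vial pair (%s, %s)",
                               pair[1L], pair[2L])))
  new("TMConfiguration", tape = tape, head = headAt,
      state = rownames(encoding@statePairs)[hit])
}
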