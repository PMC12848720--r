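#' Render a human-readable run report
#'
#' One line per iteration in the execution-summary style used for these
#' machines — state, head position and the tape as a digit string —
#' optionally followed by a resource section (stock volumes remaining
#' and waste collected) when the final platform state is supplied.
#'
#' @param configs list of decoded [TMConfiguration-class] (iteration 0
#'   first), e.g. `runCompiled(...)$configs`.
#' @param platform optional final [PlatformState-class] for the
#'   resource section.
#' @param initialStock stock volume each flask started with, in mL
#'   (default 1000, the [virtualPlatform()] default), used to report
#'   consumption.
#' @return a character vector of report lines (also printed when the
#'   result is auto-printed).
#' @examples
#' run <- runCompiled(compileMachine(busyBeaverMachine(),
#'                                   busyBeaverConfiguration()))
#' cat(runReport(run$configs, run$platform), sep = "\n")
#' @export
runReport <- function(configs, platform = NULL, initialStock = 1000) {
  lines <- c(sprintf("%4s  %-6s %4s  %s", "iter", "state", "head", "tape"))
  for (i in seq_along(configs)) {
    c <- configs[[i]]
    lines <- c(lines, sprintf("%4d  %-6s %4d  %s", i - 1L, c@state, c@head,
                              tapeString(c)))
  }
  if (!is.null(platform)) {
    lines <- c(lines, "", "resources (mL):")
    for (col in names(platform@stocks)) {
      left <- vesselVolume(platform, platform@stocks[[col]])
      lines <- c(lines, sprintf("  stock %-7s remaining %8.1f  consumed %8.1f",
                                col, left, initialStock - left))
    }
    lines <- c(lines, sprintf("  waste           collected %8.1f",
                              vesselVolume(platform, "waste")))
  }
  lines
}
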