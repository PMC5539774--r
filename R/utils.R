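#' @keywords internal
"_PACKAGE"

# Derive a per-stage seed from a root seed; keeps results within 32-bit range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647L)
}

#' Stage-tagged log message
#'
#' Lightweight logging used by every pipeline stage. Messages are emitted via
#' [message()] with a timestamp, a level and a stage tag, and are suppressed
#' unless `options(riskbn.verbose = TRUE)` is set (or `level = "warn"`).
#'
#' @param stage short stage tag, e.g. `"discretize"`.
#' @param msg message text.
#' @param level one of `"info"`, `"warn"`.
#' @return invisibly, the formatted line.
#' @export
rb_log <- function(stage, msg, level = "info") {
  line <- sprintf("[%s] %-5s %-12s %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), toupper(level),
                  stage, msg)
  if (isTRUE(getOption("riskbn.verbose", FALSE)) || level == "warn") {
    message(line)
  }
  invisible(line)
}

# Canonical subset key for memoization (order-insensitive).
subset_key <- function(subset) paste(sort(subset), collapse = "\x1f")
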