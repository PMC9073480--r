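#' @keywords internal
"_PACKAGE"

# Tokens treated as missing in expression TSVs (case-insensitive).
.NA_TOKENS <- c("", "na", "nan", "null")

#' Package log message
#'
#' Thin wrapper around [message()] used for all INFO-level progress and
#' count reporting. Silenced with `options(spongenet.quiet = TRUE)`.
#' @param ... passed to [sprintf()].
#' @return invisibly, the formatted string.
#' @keywords internal
sn_log <- function(...) {
  msg <- sprintf(...)
  if (!isTRUE(getOption("spongenet.quiet", FALSE))) {
    message("[spongenet] ", msg)
  }
  invisible(msg)
}

#' Stop with a stage-tagged error
#' @keywords internal
#' @noRd
sn_stop <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
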