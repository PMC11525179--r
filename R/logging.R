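# Minimal timestamped, level-controlled logging to stderr.

.log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

#' Package logging
#'
#' Writes a timestamped message to stderr if `level` is at or above the
#' threshold in `options(rburden.log_level = )` (default `"info"`; set to
#' `"warn"` or `"error"` to quieten, `"debug"` for more).
#'
#' @param level One of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @param ... Message parts, pasted together.
#' @return Invisibly, whether the message was emitted.
#' @export
rb_log <- function(level = "info", ...) {
  threshold <- getOption("rburden.log_level", "info")
  lv <- .log_levels[[match.arg(level, names(.log_levels))]]
  if (lv < .log_levels[[threshold]]) return(invisible(FALSE))
  message(sprintf("[%s] %s rburden: %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  toupper(level), paste0(..., collapse = "")))
  invisible(TRUE)
}
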