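#' @keywords internal
.mr <- new.env(parent = emptyenv())
.mr$log <- NULL

#' Reset the in-memory processing log
#'
#' The package keeps a session log of INFO/WARN/ERROR events raised while
#' processing a project (skipped rows, unmatched column rules, clamped
#' corrections, ...). `run_maxreport()` resets it at the start of a run and
#' writes it into the output folder at the end.
#'
#' @return Invisibly, `NULL`.
#' @export
mr_log_reset <- function() {
  .mr$log <- data.frame(time = character(), level = character(),
                        message = character(), stringsAsFactors = FALSE)
  invisible(NULL)
}

mr_log <- function(level, msg) {
  if (is.null(.mr$log)) mr_log_reset()
  .mr$log <- rbind(.mr$log, data.frame(
    time = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    level = level, message = msg, stringsAsFactors = FALSE))
  invisible(NULL)
}

mr_log_info  <- function(msg) mr_log("INFO", msg)
mr_log_warn  <- function(msg) mr_log("WARN", msg)
mr_log_error <- function(msg) mr_log("ERROR", msg)

#' Retrieve the current processing log
#'
#' @param level Optional level filter (`"INFO"`, `"WARN"` or `"ERROR"`).
#' @return A data frame with columns `time`, `level`, `message`.
#' @export
mr_log_entries <- function(level = NULL) {
  if (is.null(.mr$log)) mr_log_reset()
  out <- .mr$log
  if (!is.null(level)) out <- out[out$level %in% level, , drop = FALSE]
  out
}

mr_log_write <- function(path) {
  entries <- mr_log_entries()
  lines <- sprintf("%s\t%s\t%s", entries$time, entries$level, entries$message)
  writeLines(lines, path)
  invisible(path)
}
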