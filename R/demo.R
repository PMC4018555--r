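# Interactive text demo replacing the robot supervisor loop: typed commands
# are comprehended and executed on a simulated table; typed meanings are
# described in the requested sentence form.

#' Interactive text demo
#'
#' A read-eval-print loop over a trained model, standing in for the spoken
#' supervisor dialog. With a `comprehension_model`, each input line is a
#' command sentence; the decoded action list is printed and `put`-type
#' actions update a simulated table state (object -> location). With a
#' `production_model`, each input line is a meaning, optionally followed by
#' `|` and a form, e.g. `right(trumpet,guitar) | non_canonical`; the
#' generated description is printed. Empty lines re-prompt; decoding failures
#' are reported in-dialog and the loop continues; `quit` (or end of input)
#' ends the session.
#'
#' @param model A trained `comprehension_model` or `production_model`.
#' @param con Connection to read commands from (default [stdin()]); pass a
#'   [textConnection()] for scripted sessions.
#' @param quiet Suppress the banner/prompt (for scripted use).
#' @return Invisibly, the session transcript as a character vector.
#' @export
demo_loop <- function(model, con = stdin(), quiet = FALSE) {
  is_comp <- inherits(model, "comprehension_model")
  if (!is_comp && !inherits(model, "production_model")) {
    stop("need a trained comprehension or production model")
  }
  transcript <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    transcript <<- c(transcript, line)
    cat(line, "\n", sep = "")
  }
  if (!quiet) {
    say(if (is_comp) "action performer ready; type a command ('quit' to exit)"
        else "scene describer ready; type 'meaning | form' ('quit' to exit)")
  }
  table_state <- character(0)
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || identical(tolower(trimws(line)), "quit")) break
    line <- trimws(line)
    if (!nzchar(line)) next
    transcript <- c(transcript, paste0("> ", line))
    if (is_comp) {
      res <- tryCatch(comprehend(model, line), error = function(e) e)
      if (inherits(res, "error")) {
        say("error: %s", conditionMessage(res))
      } else if (isTRUE(res$meaning$incomplete)) {
        say("could not understand (incomplete meaning decoded)")
      } else {
        say("meaning: %s", format(res$meaning))
        for (p in res$meaning$predications) {
          if (!is.na(p$arg2)) table_state[p$arg1] <- p$arg2
        }
        if (length(table_state)) {
          say("table: %s", paste(sprintf("%s@%s", names(table_state), table_state),
                                 collapse = ", "))
        }
      }
    } else {
      parts <- strsplit(line, "|", fixed = TRUE)[[1]]
      form <- if (length(parts) > 1) trimws(parts[2]) else "canonical"
      res <- tryCatch(produce(model, trimws(parts[1]), form),
                      error = function(e) e, warning = function(w) w)
      if (inherits(res, "condition")) {
        say("error: %s", conditionMessage(res))
      } else if (res$malformed) {
        say("production failed (malformed token sequence)")
      } else {
        say("sentence: %s", res$sentence)
      }
    }
  }
  invisible(transcript)
}
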