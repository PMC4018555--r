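# Predicate-argument meaning records: pred(arg1[,arg2]) predications in
# execution order, their text syntax, and exact-match comparison.

#' Build a predication
#'
#' @param predicate Predicate word (non-empty).
#' @param arg1,arg2 Optional argument words (`NA` when absent).
#' @return A named list with entries `predicate`, `arg1`, `arg2`.
#' @export
predication <- function(predicate, arg1 = NA_character_, arg2 = NA_character_) {
  stopifnot(is.character(predicate), length(predicate) == 1, nzchar(predicate))
  arg1 <- as.character(arg1); arg2 <- as.character(arg2)
  list(predicate = predicate, arg1 = arg1, arg2 = arg2)
}

#' Construct a meaning record
#'
#' A meaning is an ordered list of at most two predications, in *execution*
#' order (which may differ from the order the predicates appear in a sentence,
#' e.g. under temporal inversion with "before").
#'
#' @param ... Predications, or a single list of predications.
#' @param incomplete Internal flag used by the decoder to mark a decoding that
#'   did not yield a well-formed meaning (e.g. arguments without a predicate).
#' @return Object of class `meaning_record`.
#' @export
meaning_record <- function(..., incomplete = FALSE) {
  preds <- list(...)
  if (length(preds) == 1 && !is.null(preds[[1]]) && is.null(preds[[1]]$predicate)) {
    preds <- preds[[1]]
  }
  if (!incomplete && (length(preds) < 1 || length(preds) > 2)) {
    stop("a well-formed meaning has 1 or 2 predications")
  }
  if (length(preds) > 2) stop("at most 2 predications")
  structure(list(predications = preds, incomplete = incomplete),
            class = "meaning_record")
}

#' Parse a meaning string
#'
#' Accepts the `pred(arg1[,arg2])[; pred(arg1[,arg2])]` syntax, e.g.
#' `"push(trumpet,left); put(guitar,right)"`. Whitespace is ignored;
#' predications are separated by `;` and listed in execution order.
#'
#' @param text Meaning string.
#' @return A [meaning_record()].
#' @export
parse_meaning <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty meaning string")
  parts <- trimws(strsplit(text, ";", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  preds <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^([a-z0-9_-]+)\\s*\\(([^)]*)\\)$", p))[[1]]
    if (length(m) == 0) stop(sprintf("unparseable predication: '%s'", p))
    args <- trimws(strsplit(m[3], ",", fixed = TRUE)[[1]])
    args <- args[nzchar(args)]
    if (length(args) > 2) stop(sprintf("more than 2 arguments in '%s'", p))
    predication(m[2],
                if (length(args) >= 1) args[1] else NA_character_,
                if (length(args) >= 2) args[2] else NA_character_)
  })
  meaning_record(preds)
}

#' Format a meaning record as text
#'
#' Inverse of [parse_meaning()].
#' @param x A `meaning_record`.
#' @param ... Unused.
#' @return A single string, `""` for an empty (failed) decoding.
#' @export
format.meaning_record <- function(x, ...) {
  if (length(x$predications) == 0) return("")
  paste(vapply(x$predications, function(p) {
    args <- if (is.na(p$arg1) && !is.na(p$arg2)) {
      c("", p$arg2)   # degenerate decode: arg2 slot filled without arg1
    } else {
      a <- c(p$arg1, p$arg2); a[!is.na(a)]
    }
    sprintf("%s(%s)", p$predicate, paste(args, collapse = ","))
  }, character(1)), collapse = "; ")
}

#' @export
print.meaning_record <- function(x, ...) {
  txt <- format(x)
  if (!nzchar(txt)) txt <- "<no predication>"
  cat(txt, if (isTRUE(x$incomplete)) " [incomplete]" else "", "\n", sep = "")
  invisible(x)
}

#' Words appearing in a meaning
#' @param x A `meaning_record`.
#' @return Character vector of all predicate and argument words, in order.
#' @export
meaning_words <- function(x) {
  out <- unlist(lapply(x$predications, function(p) c(p$predicate, p$arg1, p$arg2)))
  out[!is.na(out)]
}

#' Exact-match comparison of two meanings
#'
#' Two meanings are equal iff they have the same number of predications and,
#' position by position in execution order, identical predicate, arg1 and
#' arg2. Order matters: `push(a,b); put(c,d)` differs from
#' `put(c,d); push(a,b)`.
#'
#' @param a,b `meaning_record` objects.
#' @return Logical scalar.
#' @export
meanings_equal <- function(a, b) {
  stopifnot(inherits(a, "meaning_record"), inherits(b, "meaning_record"))
  if (length(a$predications) != length(b$predications)) return(FALSE)
  for (i in seq_along(a$predications)) {
    pa <- a$predications[[i]]; pb <- b$predications[[i]]
    same <- function(u, v) (is.na(u) && is.na(v)) || (!is.na(u) && !is.na(v) && u == v)
    if (!identical(pa$predicate, pb$predicate) ||
        !same(pa$arg1, pb$arg1) || !same(pa$arg2, pb$arg2)) {
      return(FALSE)
    }
  }
  TRUE
}
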