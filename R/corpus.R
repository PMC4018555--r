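# Sentence-meaning corpora: the pair container, native and two-column file
# dialects, closed-class extraction by exclusion, and codability filtering.

#' A sentence-meaning pair
#'
#' @param id Identifier string.
#' @param task `"AP"` (action performing / comprehension) or `"SD"`
#'   (scene description / production).
#' @param sentence Sentence string.
#' @param meaning A [meaning_record()] or meaning string
#'   (`pred(arg1[,arg2])[; ...]`, execution order).
#' @param style Category metadata: `"simple"`/`"elaborate"` for AP,
#'   `"canonical"`/`"non_canonical"` for SD.
#' @param subject Optional producer identifier.
#' @param template Optional template id (filled by the generators).
#' @param inverted Optional logical: surface order of the predicates is the
#'   reverse of execution order (temporal inversion).
#' @return Object of class `corpus_pair`.
#' @export
corpus_pair <- function(id, task = c("AP", "SD"), sentence, meaning,
                        style = NA_character_, subject = NA_character_,
                        template = NA_character_, inverted = NA) {
  task <- match.arg(task)
  if (is.character(meaning)) meaning <- parse_meaning(meaning)
  stopifnot(inherits(meaning, "meaning_record"))
  style <- as.character(style)
  if (!is.na(style)) {
    ok <- if (task == "AP") c("simple", "elaborate") else c("canonical", "non_canonical")
    if (!style %in% ok) {
      stop(sprintf("style '%s' does not match task %s (expected %s)",
                   style, task, paste(ok, collapse = "/")))
    }
  }
  structure(
    list(id = as.character(id), task = task, sentence = as.character(sentence),
         meaning = meaning, style = style,
         n_actions = length(meaning$predications),
         subject = as.character(subject), template = as.character(template),
         inverted = inverted),
    class = "corpus_pair"
  )
}

#' @export
print.corpus_pair <- function(x, ...) {
  cat(sprintf("[%s/%s%s] \"%s\"  ->  %s\n", x$id, x$task,
              if (!is.na(x$style)) paste0("/", x$style) else "",
              x$sentence, format(x$meaning)))
  invisible(x)
}

#' Tabular view of a corpus
#' @param pairs List of [corpus_pair()]s.
#' @return A data frame with one row per pair (meaning formatted as text).
#' @export
corpus_to_df <- function(pairs) {
  data.frame(
    id = vapply(pairs, function(p) p$id, character(1)),
    task = vapply(pairs, function(p) p$task, character(1)),
    sentence = vapply(pairs, function(p) p$sentence, character(1)),
    meaning = vapply(pairs, function(p) format(p$meaning), character(1)),
    style = vapply(pairs, function(p) p$style, character(1)),
    n_actions = vapply(pairs, function(p) p$n_actions, integer(1)),
    subject = vapply(pairs, function(p) p$subject, character(1)),
    template = vapply(pairs, function(p) p$template, character(1)),
    inverted = vapply(pairs, function(p) as.logical(p$inverted), logical(1)),
    stringsAsFactors = FALSE
  )
}

#' Write a corpus to disk
#'
#' Native format: UTF-8 tab-separated text with a header and one record per
#' line, fields `id task sentence meaning style n_actions subject template
#' inverted`; byte-deterministic for a given input. Inverse of
#' [read_corpus()].
#'
#' @param pairs List of [corpus_pair()]s.
#' @param path Output path.
#' @export
write_corpus <- function(pairs, path) {
  header <- c("id", "task", "sentence", "meaning", "style", "n_actions",
              "subject", "template", "inverted")
  lines <- paste(header, collapse = "\t")
  if (length(pairs)) {
    body <- vapply(pairs, function(p) {
      paste(c(p$id, p$task, p$sentence, format(p$meaning), p$style,
              p$n_actions, p$subject, p$template, as.character(p$inverted)),
            collapse = "\t")
    }, character(1))
    lines <- c(lines, body)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Read a corpus from disk
#'
#' Two dialects: `"native"` (the tab-separated format written by
#' [write_corpus()]) and `"two_column"` (`sentence<TAB>meaning`, one pair per
#' line, for importing external transcript data; ids are assigned from line
#' numbers and the task defaults to AP). Malformed lines are reported with
#' their line number; duplicate ids are an error.
#'
#' @param path Input path.
#' @param dialect `"native"` or `"two_column"`.
#' @param task Task label for the two-column dialect.
#' @return List of [corpus_pair()]s.
#' @export
read_corpus <- function(path, dialect = c("native", "two_column"), task = "AP") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("no such corpus file: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  parse_line <- function(i, fn) {
    tryCatch(fn(), error = function(e) {
      stop(sprintf("%s line %d: %s", path, i, conditionMessage(e)), call. = FALSE)
    })
  }
  pairs <- list()
  if (dialect == "native") {
    if (length(lines) == 0) stop("corpus file has no header")
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    need <- c("id", "task", "sentence", "meaning")
    if (!all(need %in% header)) {
      stop(sprintf("native corpus header must contain %s", paste(need, collapse = ", ")))
    }
    for (i in seq_along(lines)[-1]) {
      fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      rec <- stats::setNames(as.list(fields), header[seq_along(fields)])
      pairs[[length(pairs) + 1L]] <- parse_line(i, function() {
        corpus_pair(
          id = rec$id, task = rec$task, sentence = rec$sentence,
          meaning = rec$meaning,
          style = if (is.null(rec$style) || rec$style == "NA") NA_character_ else rec$style,
          subject = if (is.null(rec$subject) || rec$subject == "NA") NA_character_ else rec$subject,
          template = if (is.null(rec$template) || rec$template == "NA") NA_character_ else rec$template,
          inverted = if (is.null(rec$inverted) || rec$inverted == "NA") NA else as.logical(rec$inverted)
        )
      })
    }
  } else {
    for (i in seq_along(lines)) {
      fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(fields) != 2) {
        stop(sprintf("%s line %d: expected 'sentence<TAB>meaning'", path, i))
      }
      pairs[[length(pairs) + 1L]] <- parse_line(i, function() {
        corpus_pair(id = sprintf("l%04d", i), task = task,
                    sentence = trimws(fields[1]), meaning = trimws(fields[2]))
      })
    }
  }
  ids <- vapply(pairs, function(p) p$id, character(1))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate pair id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  pairs
}

#' Extract the closed-class lexicon by exclusion
#'
#' Every word occurring in any sentence of the corpus but never in any
#' meaning is closed-class; everything else is open-class (it carries a
#' thematic role somewhere). This is the rule used to build the lexicon for
#' transcript corpora, where function words cannot be enumerated in advance.
#'
#' @param pairs Non-empty list of [corpus_pair()]s.
#' @return An [lexicon()] with the closed-class words in sorted order.
#' @export
extract_closed_class <- function(pairs) {
  if (length(pairs) == 0) stop("empty corpus")
  sent_words <- unique(unlist(lapply(pairs, function(p) tokenize_sentence(p$sentence))))
  open_words <- unique(unlist(lapply(pairs, function(p) meaning_words(p$meaning))))
  lexicon(sort(setdiff(sent_words, open_words)))
}

#' Filter a corpus down to codable pairs
#'
#' A pair is codable when its sentence yields at most `max_sw` content words
#' and every meaning word can be bound to one of them. Ill-formed pairs
#' (e.g. meanings referring to words absent from the sentence) are dropped
#' and reported, mirroring the cleaning step that removes unprocessable
#' transcript sentences before evaluation.
#'
#' @param pairs List of [corpus_pair()]s.
#' @param lex Optional [lexicon()]; extracted by exclusion when `NULL`.
#' @param max_sw Maximum supported content words per sentence.
#' @return List with `kept` (codable pairs) and `dropped` (data frame of id
#'   and reason).
#' @export
codable_pairs <- function(pairs, lex = NULL, max_sw = 6L) {
  if (is.null(lex)) lex <- extract_closed_class(pairs)
  kept <- list()
  drop_id <- character(0)
  drop_why <- character(0)
  for (p in pairs) {
    reason <- tryCatch({
      form <- to_grammatical_form(p$sentence, lex, max_sw = max_sw)
      meaning_to_grid(p$meaning, form$fifo)
      NA_character_
    }, error = function(e) conditionMessage(e))
    if (is.na(reason)) {
      kept[[length(kept) + 1L]] <- p
    } else {
      drop_id <- c(drop_id, p$id)
      drop_why <- c(drop_why, reason)
    }
  }
  list(kept = kept,
       dropped = data.frame(id = drop_id, reason = drop_why,
                            stringsAsFactors = FALSE))
}
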