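# Closed-class lexicons and the sentence -> grammatical form preprocessing:
# open-class (semantic) words are replaced by a generic SW marker and pushed
# onto a FIFO working memory in order of occurrence.

#' Closed-class lexicon
#'
#' The ordered list of closed-class (grammatical) words the model knows, plus
#' the marker symbol used for every open-class (semantic) word. Any token not
#' in the lexicon is open-class by definition (closed-class-by-exclusion).
#'
#' @param words Character vector of lowercase closed-class words, no
#'   duplicates.
#' @param sw_symbol Marker token for semantic words (default `"SW"`; displayed
#'   as `X` in trace plots).
#' @return Object of class `esn_lexicon`.
#' @export
lexicon <- function(words, sw_symbol = "SW") {
  words <- as.character(words)
  if (anyDuplicated(words)) stop("duplicate words in lexicon")
  if (any(words != tolower(words))) stop("lexicon words must be lowercase")
  if (sw_symbol %in% words) stop("sw_symbol must not be a lexicon word")
  structure(list(words = words, sw_symbol = sw_symbol), class = "esn_lexicon")
}

#' @export
print.esn_lexicon <- function(x, ...) {
  cat(sprintf("Closed-class lexicon: %d words (+ marker '%s')\n",
              length(x$words), x$sw_symbol))
  cat(" ", paste(x$words, collapse = ", "), "\n")
  invisible(x)
}

#' Default comprehension lexicon
#'
#' The eight closed-class words of the basic action-performing task:
#' "after", "and", "before", "it", "on", "the", "then", "you".
#' @return An [lexicon()].
#' @export
ap_lexicon <- function() {
  lexicon(c("after", "and", "before", "it", "on", "the", "then", "you"))
}

#' Default production lexicon
#'
#' The six closed-class output words of the scene-description task:
#' "and", "is", "of", "the", "to" and the optional terminal "." (present as an
#' output unit but unused by the default sentence templates). With the SW
#' marker this gives the 7 output dimensions of the production model.
#' @return An [lexicon()].
#' @export
sd_lexicon <- function() {
  lexicon(c("and", "is", "of", "the", "to", "."))
}

# Lowercase, strip punctuation except a terminal ".", split on whitespace.
# The terminal dot is kept as its own token only when keep_dot is TRUE.
tokenize_sentence <- function(sentence, keep_dot = FALSE) {
  s <- tolower(trimws(sentence))
  if (!nzchar(s)) return(character(0))
  terminal_dot <- grepl("\\.\\s*$", s)
  s <- gsub("[.,;:!?()\"']", " ", s)
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  if (terminal_dot && keep_dot) toks <- c(toks, ".")
  toks
}

#' Convert a sentence to its grammatical form
#'
#' Tokenizes the sentence (lowercase, whitespace split, punctuation stripped
#' except a terminal "." when the lexicon contains one) and replaces every
#' open-class word by the SW marker, appending the replaced word to a FIFO
#' working memory. The token pattern of closed-class words and markers is the
#' construction's surface form; the FIFO holds the content words for later
#' re-binding.
#'
#' @param sentence A sentence string.
#' @param lex An [lexicon()].
#' @param max_sw Maximum number of semantic words supported by the meaning
#'   coding (default 6).
#' @return Object of class `grammatical_form`: list with `tokens` (over
#'   `words(lex)` and the marker) and `fifo` (extracted content words).
#' @export
to_grammatical_form <- function(sentence, lex, max_sw = 6L) {
  stopifnot(inherits(lex, "esn_lexicon"))
  toks <- tokenize_sentence(sentence, keep_dot = "." %in% lex$words)
  fifo <- character(0)
  out <- character(length(toks))
  for (i in seq_along(toks)) {
    if (toks[i] %in% lex$words) {
      out[i] <- toks[i]
    } else {
      out[i] <- lex$sw_symbol
      fifo <- c(fifo, toks[i])
    }
  }
  if (length(fifo) > max_sw) {
    stop(sprintf("too many semantic words: %d content words but the meaning coding supports at most %d",
                 length(fifo), max_sw))
  }
  structure(list(tokens = out, fifo = fifo), class = "grammatical_form")
}

#' @export
print.grammatical_form <- function(x, ...) {
  cat("[", paste(x$tokens, collapse = " "), "]\n", sep = "")
  if (length(x$fifo)) cat("  fifo:", paste(x$fifo, collapse = ", "), "\n")
  invisible(x)
}

#' Encode a grammatical form as reservoir input
#'
#' One-hot coding, one time step per token with no inter-word gap. Sentences
#' shorter than `max_len` are left-padded with all-zero rows so that the
#' complete meaning is always read out at the same final time step, and
#' `pause_len` all-zero rows are appended as the end-of-sentence pause.
#'
#' @param form A [to_grammatical_form()] result.
#' @param lex The matching [lexicon()].
#' @param max_len Padding reference length (`>=` token count).
#' @param pause_len Final pause length in steps (default 1).
#' @return Matrix of size `(max_len + pause_len) x (length(words) + 1)`;
#'   columns are the lexicon words followed by the SW marker.
#' @export
encode_sentence_input <- function(form, lex, max_len = length(form$tokens),
                                  pause_len = 1L) {
  stopifnot(inherits(form, "grammatical_form"), inherits(lex, "esn_lexicon"))
  ncols <- length(lex$words) + 1L
  units <- match(form$tokens, c(lex$words, lex$sw_symbol))
  if (anyNA(units)) {
    stop(sprintf("token(s) outside lexicon: %s",
                 paste(unique(form$tokens[is.na(units)]), collapse = ", ")))
  }
  n_tok <- length(form$tokens)
  if (max_len < n_tok) stop("max_len is smaller than the token count")
  T_len <- max_len + pause_len
  m <- matrix(0, T_len, ncols, dimnames = list(NULL, c(lex$words, lex$sw_symbol)))
  offset <- max_len - n_tok
  if (n_tok > 0) {
    m[cbind(offset + seq_len(n_tok), units)] <- 1
  }
  m
}
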