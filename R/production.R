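# The scene-describer (production) model: coded meaning + canonical flag ->
# constant reservoir input -> trained readout word trace -> decoded token
# sequence -> sentence with SW markers re-bound to content words.

#' Construction patterns for the scene-description task
#'
#' The four supported coded-meaning shapes, mapping each meaning slot to the
#' surface position (SW index) it occupies:
#' canonical single `SW2(SW1, SW3)`, non-canonical single `SW1(SW3, SW2)`,
#' canonical double `SW2(SW1,SW3); SW4(SW1,SW5)` and non-canonical double
#' `SW1(SW5,SW2); SW3(SW5,SW4)` (double relations share their agent).
#'
#' @param n_relations 1 or 2.
#' @param form `"canonical"` or `"non_canonical"`.
#' @return List with one element per predication, each giving the surface
#'   indices of `pred`, `arg1`, `arg2`.
#' @export
construction_pattern <- function(n_relations, form = c("canonical", "non_canonical")) {
  form <- normalize_form(form)
  if (n_relations == 1) {
    if (form == "canonical") {
      list(list(pred = 2L, arg1 = 1L, arg2 = 3L))
    } else {
      list(list(pred = 1L, arg1 = 3L, arg2 = 2L))
    }
  } else if (n_relations == 2) {
    if (form == "canonical") {
      list(list(pred = 2L, arg1 = 1L, arg2 = 3L),
           list(pred = 4L, arg1 = 1L, arg2 = 5L))
    } else {
      list(list(pred = 1L, arg1 = 5L, arg2 = 2L),
           list(pred = 3L, arg1 = 5L, arg2 = 4L))
    }
  } else {
    stop("1 or 2 relations supported")
  }
}

normalize_form <- function(form) {
  form <- gsub("-", "_", tolower(form[1]))
  if (form %in% c("noncanonical", "non_canonical")) return("non_canonical")
  if (form == "canonical") return("canonical")
  stop(sprintf("unknown sentence form '%s'", form))
}

#' Code a meaning for production input
#'
#' Selects the [construction_pattern()] for the meaning's relation count and
#' the requested form, assigns every content word its SW surface position,
#' and returns the active role grid together with the FIFO of content words
#' ordered by surface position.
#'
#' @param meaning A [meaning_record()] or meaning string; 1 or 2 relations,
#'   each with both arguments filled; double relations must share `arg1`.
#' @param form `"canonical"` or `"non_canonical"`.
#' @return List with elements `grid` ([role_grid()]) and `fifo`.
#' @export
meaning_to_coded_input <- function(meaning, form = "canonical") {
  if (is.character(meaning)) meaning <- parse_meaning(meaning)
  stopifnot(inherits(meaning, "meaning_record"))
  preds <- meaning$predications
  n <- length(preds)
  if (n < 1 || n > 2) stop("unsupported meaning shape: need 1 or 2 relations")
  for (p in preds) {
    if (is.na(p$arg1) || is.na(p$arg2)) {
      stop("unsupported meaning shape: every relation needs two arguments")
    }
  }
  if (n == 2 && preds[[1]]$arg1 != preds[[2]]$arg1) {
    stop("unsupported meaning shape: double relations must share their agent")
  }
  pat <- construction_pattern(n, form)
  n_sw <- if (n == 1) 3L else 5L
  fifo <- character(n_sw)
  grid <- role_grid()
  for (k in seq_len(n)) {
    slots <- pat[[k]]
    words <- c(preds[[k]]$predicate, preds[[k]]$arg1, preds[[k]]$arg2)
    idx <- c(slots$pred, slots$arg1, slots$arg2)
    for (j in 1:3) {
      fifo[idx[j]] <- words[j]
      grid[idx[j], j, k] <- TRUE
    }
  }
  list(grid = grid, fifo = fifo)
}

#' Encode a coded meaning as constant production input
#'
#' Each active grid cell drives its input unit with a constant activation of
#' 1 for the whole presentation; all other units stay 0. The presentation
#' length equals the teacher length, i.e. all inputs are padded to the
#' longest sentence.
#'
#' @param grid A [role_grid()].
#' @param T_len Presentation length in steps.
#' @return A `T_len x 36` input matrix.
#' @export
encode_meaning_input <- function(grid, T_len) {
  stopifnot(T_len >= 1)
  m <- matrix(0, T_len, GRID_DIM)
  active <- which(as.logical(grid))
  if (length(active)) m[, active] <- 1
  m
}

#' Teacher word trace for the production readout
#'
#' Each token is coded as a square wave of `word_len` steps at activation 1
#' on its output unit, followed by a `gap_len`-step pause; the trailing gap
#' after the last word is the final pause. The trace is zero-padded to
#' `T_max` so all teachers share the maximal sentence length.
#'
#' @param tokens Token sequence over the production lexicon plus the SW
#'   marker.
#' @param lex The production [lexicon()].
#' @param T_max Total length (default: exactly the sequence's own length).
#' @param word_len,gap_len Word and pause durations in steps (default 5/5).
#' @return A `T_max x (length(words) + 1)` word-trace matrix.
#' @export
encode_production_teacher <- function(tokens, lex = sd_lexicon(), T_max = NULL,
                                      word_len = 5L, gap_len = 5L) {
  stopifnot(inherits(lex, "esn_lexicon"))
  units <- match(tokens, c(lex$words, lex$sw_symbol))
  if (anyNA(units)) {
    stop(sprintf("token(s) outside production lexicon: %s",
                 paste(unique(tokens[is.na(units)]), collapse = ", ")))
  }
  slot <- word_len + gap_len
  T_need <- length(tokens) * slot
  if (is.null(T_max)) T_max <- T_need
  if (T_max < T_need) stop("T_max shorter than the token sequence requires")
  m <- matrix(0, T_max, length(lex$words) + 1L,
              dimnames = list(NULL, c(lex$words, lex$sw_symbol)))
  for (k in seq_along(tokens)) {
    rows <- ((k - 1L) * slot + 1L):((k - 1L) * slot + word_len)
    m[rows, units[k]] <- 1
  }
  m
}

#' Decode a word trace into a token sequence
#'
#' Scans the trace step by step: the winning word at a step is the
#' supra-threshold output of maximal value (none when all are below
#' threshold). Maximal runs of consecutive identical winners collapse to a
#' single token, and runs shorter than `min_run` steps are discarded as
#' noise.
#'
#' @param trace A `T x (n_words + 1)` output matrix (columns in production
#'   lexicon order, SW marker last).
#' @param lex The production [lexicon()].
#' @param threshold Decoding threshold (default 0.5).
#' @param min_run Minimum run length for a word to be emitted (default 2).
#' @return Character vector of tokens (possibly empty).
#' @export
decode_word_trace <- function(trace, lex = sd_lexicon(), threshold = 0.5,
                              min_run = 2L) {
  vocab <- c(lex$words, lex$sw_symbol)
  stopifnot(ncol(trace) == length(vocab))
  winner <- apply(trace, 1, function(v) {
    ok <- which(v >= threshold)
    if (length(ok) == 0) 0L else ok[which.max(v[ok])]
  })
  runs <- rle(winner)
  keep <- runs$values > 0L & runs$lengths >= min_run
  vocab[runs$values[keep]]
}

#' Train the production (scene-describer) model
#'
#' Fits an echo state network that maps coded meanings (thematic-role grids
#' plus the canonical/non-canonical choice, implicit in the grid) to word
#' sequences. Each training pair contributes a constant 36-dimensional input
#' and a square-wave word-trace teacher; the linear readout is trained over
#' all pairs at once. Defaults are the published scene-description settings:
#' 500 units, leak rate 0.75, spectral radius 2, input scaling 0.01.
#'
#' @param pairs List of [corpus_pair()] objects (task SD) whose `style` is
#'   `"canonical"` or `"non_canonical"`.
#' @param lex Production output [lexicon()] (default [sd_lexicon()]).
#' @param n_units,leak_rate,spectral_radius,input_scaling,win_dist Reservoir
#'   hyperparameters.
#' @param seed Integer seed for the random weights.
#' @param ridge Readout regularization.
#' @param threshold Word-trace decoding threshold.
#' @param word_len,gap_len Teacher geometry in steps.
#' @param min_run Decoder's minimum run length.
#' @return Object of class `production_model`.
#' @export
train_production <- function(pairs, lex = sd_lexicon(), n_units = 500,
                             leak_rate = 0.75, spectral_radius = 2,
                             input_scaling = 0.01, seed = 1L, ridge = 0,
                             threshold = 0.5, word_len = 5L, gap_len = 5L,
                             min_run = 2L, win_dist = "binary") {
  if (length(pairs) == 0) stop("empty training corpus")
  coded <- vector("list", length(pairs))
  token_sets <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    res <- tryCatch({
      cc <- meaning_to_coded_input(p$meaning, p$style)
      form <- to_grammatical_form(p$sentence, lex)
      if (!identical(form$fifo, cc$fifo)) {
        stop(sprintf("sentence content words [%s] do not match the %s pattern order [%s]",
                     paste(form$fifo, collapse = " "), p$style,
                     paste(cc$fifo, collapse = " ")))
      }
      list(coded = cc, tokens = form$tokens)
    }, error = function(e) {
      stop(sprintf("pair %s: %s", pair_label(p, i), conditionMessage(e)), call. = FALSE)
    })
    coded[[i]] <- res$coded
    token_sets[[i]] <- res$tokens
  }
  slot <- word_len + gap_len
  T_max <- max(vapply(token_sets, length, integer(1))) * slot
  config <- reservoir_config(
    n_units = n_units, leak_rate = leak_rate,
    spectral_radius = spectral_radius, input_scaling = input_scaling,
    input_dim = GRID_DIM, output_dim = length(lex$words) + 1L,
    seed = seed, ridge = ridge, threshold = threshold, win_dist = win_dist
  )
  weights <- init_reservoir(config)
  states <- lapply(coded, function(cc) {
    run_reservoir(weights, config, encode_meaning_input(cc$grid, T_max))
  })
  teachers <- lapply(token_sets, encode_production_teacher, lex = lex,
                     T_max = T_max, word_len = word_len, gap_len = gap_len)
  readout <- train_readout(states, teachers, ridge = ridge)
  structure(
    list(config = config, weights = weights, readout = readout, lexicon = lex,
         word_len = as.integer(word_len), gap_len = as.integer(gap_len),
         min_run = as.integer(min_run), T_max = as.integer(T_max),
         n_pairs = length(pairs), call = match.call()),
    class = "production_model"
  )
}

#' Produce a sentence from a meaning
#'
#' Codes the meaning under the requested form, drives the reservoir with the
#' constant coded-meaning input, decodes the readout word trace into a token
#' sequence, and substitutes the i-th SW marker with the i-th content word
#' held in the FIFO. When the decoded SW count does not match the FIFO length
#' the result is flagged as a malformed production (with a warning) and no
#' sentence is assembled.
#'
#' @param model A [train_production()] fit.
#' @param meaning A [meaning_record()] or meaning string such as
#'   `"right(trumpet,guitar)"` or `"right(violin,trumpet); left(violin,guitar)"`.
#' @param form `"canonical"` or `"non_canonical"`.
#' @return Object of class `production_result`: list with `sentence` (string,
#'   or `NA` when malformed), `tokens`, `trace` (the `T x 7` readout), `fifo`,
#'   `form` and `malformed`.
#' @export
produce <- function(model, meaning, form = "canonical") {
  stopifnot(inherits(model, "production_model"))
  form <- normalize_form(form)
  cc <- meaning_to_coded_input(meaning, form)
  u <- encode_meaning_input(cc$grid, model$T_max)
  states <- run_reservoir(model$weights, model$config, u)
  trace <- apply_readout(model$readout, states)
  colnames(trace) <- c(model$lexicon$words, model$lexicon$sw_symbol)
  tokens <- decode_word_trace(trace, model$lexicon,
                              threshold = model$config$threshold,
                              min_run = model$min_run)
  sw <- tokens == model$lexicon$sw_symbol
  malformed <- sum(sw) != length(cc$fifo)
  sentence <- NA_character_
  if (!malformed) {
    out <- tokens
    out[sw] <- cc$fifo
    sentence <- paste(out, collapse = " ")
  } else {
    warning(sprintf("malformed production: decoded %d SW markers for %d content words",
                    sum(sw), length(cc$fifo)))
  }
  structure(list(sentence = sentence, tokens = tokens, trace = trace,
                 fifo = cc$fifo, form = form, malformed = malformed),
            class = "production_result")
}

#' @export
print.production_result <- function(x, ...) {
  if (x$malformed) {
    cat(sprintf("<malformed production: tokens [%s], fifo [%s]>\n",
                paste(x$tokens, collapse = " "), paste(x$fifo, collapse = " ")))
  } else {
    cat(x$sentence, "\n")
  }
  invisible(x)
}

#' @rdname produce
#' @param object,newdata,... `predict` interface: `newdata` is a list of
#'   meanings (records or strings); returns a character vector of sentences
#'   (`NA` for malformed productions).
#' @export
predict.production_model <- function(object, newdata, form = "canonical", ...) {
  if (inherits(newdata, "meaning_record") || is.character(newdata) && length(newdata) == 1) {
    newdata <- list(newdata)
  }
  vapply(newdata, function(m) produce(object, m, form)$sentence, character(1))
}

#' @export
print.production_model <- function(x, ...) {
  cat("Production (scene-describer) echo state network\n")
  print(x$config)
  cat(sprintf("  trained on %d pairs; teacher geometry %d+%d steps/word, T_max %d\n",
              x$n_pairs, x$word_len, x$gap_len, x$T_max))
  invisible(x)
}

#' @export
coef.production_model <- function(object, ...) object$readout$w_out

#' Plot the word trace of a production result
#'
#' @param x A `production_result`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.production_result <- function(x, ...) {
  graphics::matplot(x$trace, type = "l", lty = 1,
                    xlab = "time step", ylab = "readout activity",
                    main = if (!is.na(x$sentence)) paste0("\"", x$sentence, "\"") else "malformed production",
                    ...)
  graphics::abline(h = 0.5, lty = 2)
  graphics::legend("topright", legend = colnames(x$trace), bty = "n",
                   col = seq_len(ncol(x$trace)), lty = 1, cex = 0.7)
  invisible(x)
}
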