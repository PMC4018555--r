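# The action-performer (comprehension) model: sentence -> grammatical form ->
# reservoir -> trained linear readout -> thresholded thematic-role grid ->
# reconstructed predicate-argument meaning.

# Build everything about a comprehension session that does not depend on the
# reservoir instance: forms, padding length, input and teacher matrices.
comp_prepare <- function(pairs, lex, pause_len) {
  forms <- vector("list", length(pairs))
  grids <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    forms[[i]] <- tryCatch(
      to_grammatical_form(p$sentence, lex),
      error = function(e) stop(sprintf("pair %s: %s", pair_label(p, i), conditionMessage(e)), call. = FALSE)
    )
    grids[[i]] <- tryCatch(
      meaning_to_grid(p$meaning, forms[[i]]$fifo),
      error = function(e) stop(sprintf("pair %s: %s", pair_label(p, i), conditionMessage(e)), call. = FALSE)
    )
  }
  max_len <- max(vapply(forms, function(f) length(f$tokens), integer(1)))
  T_len <- max_len + pause_len
  inputs <- lapply(forms, encode_sentence_input, lex = lex,
                   max_len = max_len, pause_len = pause_len)
  teachers <- mapply(function(g, f) {
    encode_teacher(g, T_len, onset = max_len - length(f$tokens))
  }, grids, forms, SIMPLIFY = FALSE)
  list(forms = forms, grids = grids, inputs = inputs, teachers = teachers,
       max_len = max_len, T_len = T_len)
}

pair_label <- function(p, i) {
  if (!is.null(p$id) && !is.na(p$id)) p$id else as.character(i)
}

#' Train the comprehension (action-performer) model
#'
#' Fits an echo state network that maps sentences to thematic-role
#' assignments over their content words. Every training sentence is reduced
#' to its grammatical form, encoded one-hot (left-padded to the longest
#' sentence of the session), driven through a fixed random reservoir, and the
#' linear readout is trained to reproduce the 36-cell role coding of the
#' annotated meaning, clamped from sentence onset to the final pause.
#'
#' Default hyperparameters are the published action-performing settings:
#' 100 units, leak rate 1/6, spectral radius 1, input scaling 0.75.
#'
#' @param pairs List of [corpus_pair()] objects (task AP).
#' @param lex Closed-class [lexicon()]; when `NULL` it is extracted from the
#'   corpus by exclusion (all sentence words never used in a meaning).
#' @param n_units,leak_rate,spectral_radius,input_scaling,win_dist Reservoir
#'   hyperparameters, see [reservoir_config()].
#' @param seed Integer seed for the random weights.
#' @param ridge Readout regularization (0 = pure pseudo-inverse).
#' @param threshold Decoding threshold.
#' @param pause_len End-of-sentence pause length in steps.
#' @return Object of class `comprehension_model`.
#' @examples
#' corp <- generate_ap_corpus(generator_params(n_subjects = 1, n_single = 2,
#'                                             n_double = 2, seed = 7))
#' m <- train_comprehension(corp, n_units = 80, seed = 1)
#' comprehend(m, corp[[1]]$sentence)$meaning
#' @export
train_comprehension <- function(pairs, lex = NULL, n_units = 100,
                                leak_rate = 1 / 6, spectral_radius = 1,
                                input_scaling = 0.75, seed = 1L, ridge = 0,
                                threshold = 0.5, pause_len = 1L,
                                win_dist = "binary") {
  if (length(pairs) == 0) stop("empty training corpus")
  if (is.null(lex)) lex <- extract_closed_class(pairs)
  prep <- comp_prepare(pairs, lex, pause_len)
  config <- reservoir_config(
    n_units = n_units, leak_rate = leak_rate,
    spectral_radius = spectral_radius, input_scaling = input_scaling,
    input_dim = length(lex$words) + 1L, output_dim = GRID_DIM,
    seed = seed, ridge = ridge, threshold = threshold, win_dist = win_dist
  )
  weights <- init_reservoir(config)
  states <- lapply(prep$inputs, function(u) run_reservoir(weights, config, u))
  readout <- train_readout(states, prep$teachers, ridge = ridge)
  structure(
    list(config = config, weights = weights, readout = readout, lexicon = lex,
         max_len = prep$max_len, pause_len = as.integer(pause_len),
         n_pairs = length(pairs), call = match.call()),
    class = "comprehension_model"
  )
}

#' Comprehend a sentence
#'
#' Runs a trained comprehension model on one sentence and decodes the
#' predicate-argument meaning from the readout at the final time step. The
#' full readout trajectory is returned as well: at any step it can be read as
#' the model's current estimate of the sentence meaning given the words so
#' far. A sentence longer than any training sentence is encoded unpadded at
#' its own length, with a warning.
#'
#' @param model A [train_comprehension()] fit.
#' @param sentence Sentence string.
#' @return Object of class `comprehension_result`: list with `meaning` (a
#'   [meaning_record()], possibly flagged incomplete), `outputs` (the
#'   `T x 36` readout trajectory), `form`, and `sentence`.
#' @export
comprehend <- function(model, sentence) {
  stopifnot(inherits(model, "comprehension_model"))
  form <- to_grammatical_form(sentence, model$lexicon)
  max_len <- model$max_len
  if (length(form$tokens) > max_len) {
    warning(sprintf("sentence has %d tokens, longer than any training sentence (%d); encoding unpadded",
                    length(form$tokens), max_len))
    max_len <- length(form$tokens)
  }
  u <- encode_sentence_input(form, model$lexicon, max_len, model$pause_len)
  states <- run_reservoir(model$weights, model$config, u)
  outputs <- apply_readout(model$readout, states)
  colnames(outputs) <- names(grid_to_vector(role_grid()))
  meaning <- decode_meaning(outputs[nrow(outputs), ], form$fifo,
                            threshold = model$config$threshold)
  structure(list(meaning = meaning, outputs = outputs, form = form,
                 sentence = sentence),
            class = "comprehension_result")
}

#' @export
print.comprehension_result <- function(x, ...) {
  cat("sentence:", x$sentence, "\n")
  cat("meaning: ")
  print(x$meaning)
  invisible(x)
}

#' @rdname comprehend
#' @param object,newdata,... `predict` interface: `newdata` is a character
#'   vector of sentences (or a list of corpus pairs); returns a list of
#'   decoded [meaning_record()]s.
#' @export
predict.comprehension_model <- function(object, newdata, ...) {
  sentences <- if (is.character(newdata)) {
    newdata
  } else {
    vapply(newdata, function(p) p$sentence, character(1))
  }
  lapply(sentences, function(s) comprehend(object, s)$meaning)
}

#' @export
print.comprehension_model <- function(x, ...) {
  cat("Comprehension (action-performer) echo state network\n")
  print(x$config)
  cat(sprintf("  lexicon: %d closed-class words; trained on %d pairs (max length %d + pause %d)\n",
              length(x$lexicon$words), x$n_pairs, x$max_len, x$pause_len))
  invisible(x)
}

#' @export
summary.comprehension_model <- function(object, ...) {
  cat("Comprehension model\n")
  print(object$config)
  print(object$lexicon)
  cat(sprintf("  trained on %d sentence-meaning pairs; encoded length %d (+%d pause)\n",
              object$n_pairs, object$max_len, object$pause_len))
  cat(sprintf("  readout: %d x %d (incl. bias column)\n",
              nrow(object$readout$w_out), ncol(object$readout$w_out)))
  invisible(object)
}

#' @export
coef.comprehension_model <- function(object, ...) object$readout$w_out

#' Plot the readout trajectory of a comprehension result
#'
#' Line plot of all 36 role-cell activations over time with the decoding
#' threshold marked; the cells active in the decoded grid are drawn on top in
#' color.
#' @param x A `comprehension_result`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.comprehension_result <- function(x, ...) {
  y <- x$outputs
  graphics::matplot(y, type = "l", lty = 1, col = "grey70",
                    xlab = "time step", ylab = "readout activity",
                    main = paste0("\"", x$sentence, "\""), ...)
  grid <- attr(x$meaning, "grid")
  if (!is.null(grid)) {
    on <- which(as.logical(grid))
    if (length(on)) {
      graphics::matlines(y[, on, drop = FALSE], lty = 1, lwd = 2,
                         col = seq_along(on) + 1)
      graphics::legend("topleft", legend = colnames(y)[on], bty = "n",
                       col = seq_along(on) + 1, lty = 1, lwd = 2, cex = 0.7)
    }
  }
  graphics::abline(h = x$meaning_threshold %||% 0.5, lty = 2)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a readout trajectory as delimited text
#'
#' @param x A `comprehension_result` or `production_result`.
#' @param path Output file; tab-separated, one time step per row.
#' @export
write_trajectory <- function(x, path) {
  m <- if (!is.null(x$outputs)) x$outputs else x$trace
  utils::write.table(m, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
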