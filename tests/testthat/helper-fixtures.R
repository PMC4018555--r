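# Shared fixtures: oracles and small corpora built in code.

# Independent step-by-step scalar implementation of the leaky-integrator
# update, deliberately loop-based (no matrix products), used as the oracle
# for run_reservoir.
oracle_reservoir <- function(w_in, w_res, leak, inputs) {
  n <- nrow(w_res)
  T_len <- nrow(inputs)
  states <- matrix(0, T_len, n)
  x <- numeric(n)
  for (t in seq_len(T_len)) {
    xn <- numeric(n)
    for (i in seq_len(n)) {
      s <- 0
      for (j in seq_len(n)) s <- s + w_res[i, j] * x[j]
      for (j in seq_len(ncol(w_in))) s <- s + w_in[i, j] * inputs[t, j]
      xn[i] <- (1 - leak) * x[i] + leak * tanh(s)
    }
    x <- xn
    states[t, ] <- x
  }
  states
}

# Independent normal-equations least-squares solve (full-rank case), used as
# the oracle for train_readout.
oracle_readout <- function(X, Y) {
  Xa <- cbind(X, 1)
  t(solve(crossprod(Xa), crossprod(Xa, Y)))
}

# 20-pair synthetic command corpus small enough for the exact-interpolation
# (memorization) regime of the comprehension model.
recall_ap_corpus <- function() {
  generate_ap_corpus(generator_params(n_subjects = 1, n_single = 4,
                                      n_double = 6, seed = 3))
}

# 20-pair single-relation scene corpus for the production interpolation regime.
recall_sd_corpus <- function() {
  generate_sd_corpus(n_single = 10, n_double = 0, seed = 5)
}

# One surface form, two competing role patterns at frequency 3:1: the
# "on my <loc>" phrase is an irrelevant distractor in the majority pairs but
# a true location in the minority pair.
ambiguous_mini_corpus <- function() {
  list(
    corpus_pair("amb1", "AP", "point the circle on my left", "point(circle)",
                style = "simple"),
    corpus_pair("amb2", "AP", "point the cross on my left", "point(cross)",
                style = "simple"),
    corpus_pair("amb3", "AP", "grasp the circle on my left", "grasp(circle)",
                style = "simple"),
    corpus_pair("amb4", "AP", "put the toy on my left", "put(toy,left)",
                style = "simple")
  )
}

# A random well-formed (meaning, fifo) pair for round-trip properties.
random_meaning_case <- function() {
  vocab <- c("point", "put", "grasp", "touch", "guitar", "toy", "cross",
             "circle", "left", "right", "middle")
  n_pred <- sample(1:2, 1)
  n_sw <- sample(max(1, n_pred):6, 1)
  fifo <- sample(vocab, n_sw, replace = FALSE)
  used <- 0
  preds <- list()
  for (k in seq_len(n_pred)) {
    avail <- n_sw - used
    if (avail < 1) break
    take <- sample(1:min(3, avail), 1)
    words <- fifo[used + seq_len(take)]
    used <- used + take
    preds[[k]] <- predication(words[1],
                              if (take >= 2) words[2] else NA_character_,
                              if (take >= 3) words[3] else NA_character_)
  }
  list(meaning = meaning_record(preds), fifo = fifo)
}

# A random production token sequence over the scene-description lexicon.
random_token_sequence <- function(lex = sd_lexicon()) {
  n <- sample(1:16, 1)
  sample(c(lex$words, lex$sw_symbol), n, replace = TRUE)
}
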