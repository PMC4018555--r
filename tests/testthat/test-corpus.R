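test_that("native corpus files round-trip exactly", {
  corp <- generate_ap_corpus(generator_params(n_subjects = 1, n_single = 2,
                                              n_double = 2, seed = 6))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_corpus(corp, path)
  back <- read_corpus(path)
  expect_length(back, length(corp))
  for (i in seq_along(corp)) {
    expect_identical(back[[i]]$id, corp[[i]]$id)
    expect_identical(back[[i]]$sentence, corp[[i]]$sentence)
    expect_true(meanings_equal(back[[i]]$meaning, corp[[i]]$meaning))
    expect_identical(back[[i]]$style, corp[[i]]$style)
    expect_identical(back[[i]]$inverted, corp[[i]]$inverted)
  }
  # byte-deterministic output
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_corpus(corp, path2)
  expect_identical(readBin(path, "raw", 1e6), readBin(path2, "raw", 1e6))
  # empty corpus: header-only file that reads back empty
  write_corpus(list(), path2)
  expect_length(readLines(path2), 1)
  expect_length(read_corpus(path2), 0)
})

test_that("the two-column dialect imports sentence<TAB>meaning lines", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("point the guitar\tpoint(guitar)",
               "put the toy on the left\tput(toy,left)"), path)
  pairs <- read_corpus(path, dialect = "two_column")
  expect_length(pairs, 2)
  expect_equal(pairs[[1]]$n_actions, 1)
  expect_true(meanings_equal(pairs[[2]]$meaning, parse_meaning("put(toy,left)")))
  # malformed meanings are reported with their line number
  writeLines(c("point the guitar\tpoint(guitar)", "garbled line"), path)
  expect_error(read_corpus(path, dialect = "two_column"), "line 2")
})

test_that("duplicate ids are rejected", {
  p <- corpus_pair("dup", "AP", "point the guitar", "point(guitar)")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_corpus(list(p, p), path)
  expect_error(read_corpus(path), "duplicate")
})

test_that("closed-class words are extracted by exclusion from the meanings", {
  pairs <- list(corpus_pair("a", "AP", "put the toy on the left", "put(toy,left)"))
  lex <- extract_closed_class(pairs)
  expect_setequal(lex$words, c("the", "on"))
  # sentences made only of meaning words leave an empty lexicon
  lex2 <- extract_closed_class(list(corpus_pair("b", "AP", "point guitar",
                                                "point(guitar)")))
  expect_length(lex2$words, 0)
  # the synthetic corpus exposes the expected construction markers
  lex3 <- extract_closed_class(generate_ap_corpus(generator_params()))
  expect_true(all(c("before", "after", "then", "it", "please", "twice") %in% lex3$words))
})

test_that("the default generator reproduces the 5 x 38 x 2 corpus design", {
  corp <- generate_ap_corpus(generator_params())
  expect_length(corp, 380)
  df <- corpus_to_df(corp)
  counts <- table(df$style, df$n_actions)
  expect_equal(unname(counts["simple", "1"]), 25)
  expect_equal(unname(counts["simple", "2"]), 165)
  expect_equal(unname(counts["elaborate", "1"]), 25)
  expect_equal(unname(counts["elaborate", "2"]), 165)
  expect_equal(length(unique(df$subject)), 5)
  # seeded determinism
  corp2 <- generate_ap_corpus(generator_params())
  expect_identical(corpus_to_df(corp2), df)
  expect_false(identical(
    corpus_to_df(generate_ap_corpus(generator_params(seed = 2))), df))
})

test_that("every generated pair is codable and constructions recur", {
  corp <- generate_ap_corpus(generator_params(n_subjects = 3, n_single = 4,
                                              n_double = 8, seed = 13))
  lex <- extract_closed_class(corp)
  expect_equal(nrow(codable_pairs(corp, lex)$dropped), 0)
  pats <- vapply(corp, function(p) {
    paste(to_grammatical_form(p$sentence, lex)$tokens, collapse = " ")
  }, character(1))
  expect_gte(min(table(pats)), 3)
  # one surface pattern never maps to two different role grids
  sig <- vapply(seq_along(corp), function(i) {
    f <- to_grammatical_form(corp[[i]]$sentence, lex)
    paste(which(as.logical(meaning_to_grid(corp[[i]]$meaning, f$fifo))),
          collapse = ",")
  }, character(1))
  expect_true(all(tapply(sig, pats, function(x) length(unique(x))) == 1))
})

test_that("temporal inversion annotations match the surface order of predicates", {
  corp <- generate_ap_corpus(generator_params(n_subjects = 2, n_single = 2,
                                              n_double = 10, seed = 21))
  lex <- extract_closed_class(corp)
  n_inverted <- 0
  for (p in Filter(function(p) p$n_actions == 2, corp)) {
    f <- to_grammatical_form(p$sentence, lex)
    g <- meaning_to_grid(p$meaning, f$fifo)
    sw_pred1 <- which(g[, "predicate", 1])
    sw_pred2 <- which(g[, "predicate", 2])
    if (sw_pred1 == sw_pred2) next  # repeated action ("twice"): no order
    if (isTRUE(p$inverted)) {
      n_inverted <- n_inverted + 1
      expect_gt(sw_pred1, sw_pred2)  # executed-first predicate surfaces later
    } else {
      expect_lt(sw_pred1, sw_pred2)
    }
  }
  expect_gt(n_inverted, 0)
})

test_that("ill-formed pairs are emitted on request and filtered by codability", {
  corp <- generate_ap_corpus(generator_params(n_subjects = 2, n_single = 3,
                                              n_double = 5,
                                              illformed_rate = 0.2, seed = 5))
  cp <- codable_pairs(corp)
  expect_gt(nrow(cp$dropped), 0)
  expect_lt(nrow(cp$dropped), length(corp))
  expect_length(cp$kept, length(corp) - nrow(cp$dropped))
  # the cleaned corpus trains without error
  expect_silent(invisible(comp_ok <- train_comprehension(cp$kept, n_units = 30, seed = 1)))
})

test_that("distractor phrases add a role-less content word", {
  corp <- generate_ap_corpus(generator_params(n_subjects = 2, n_single = 6,
                                              n_double = 2,
                                              distractor_rate = 1, seed = 8))
  with_d <- Filter(function(p) grepl(" on my ", p$sentence), corp)
  expect_gt(length(with_d), 0)
  lex <- extract_closed_class(corp)
  expect_true("my" %in% lex$words)
  p <- with_d[[1]]
  f <- to_grammatical_form(p$sentence, lex)
  g <- meaning_to_grid(p$meaning, f$fifo)
  # more content words than active role columns: the distractor has no role
  expect_gt(length(f$fifo), length(unique(which(unclass(g), arr.ind = TRUE)[, 1])))
})

test_that("the scene generator emits both forms of each scene in the Table-style frames", {
  corp <- generate_sd_corpus(n_single = 2, n_double = 2, seed = 3)
  expect_length(corp, 8)
  df <- corpus_to_df(corp)
  expect_equal(sum(df$style == "canonical"), 4)
  can1 <- corp[[1]]
  expect_match(can1$sentence, "^the \\w+ is to the (left|right) of the \\w+$")
  non1 <- corp[[2]]
  expect_match(non1$sentence, "^to the (left|right) of the \\w+ is the \\w+$")
  expect_true(meanings_equal(can1$meaning, non1$meaning))
  # double scenes share the focus object between relations
  dbl <- Find(function(p) p$n_actions == 2, corp)
  expect_identical(dbl$meaning$predications[[1]]$arg1,
                   dbl$meaning$predications[[2]]$arg1)
  expect_identical(corpus_to_df(generate_sd_corpus(n_single = 2, n_double = 2, seed = 3)), df)
})
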