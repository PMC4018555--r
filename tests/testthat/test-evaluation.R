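make_results <- function(fail_sets, n_pairs, ids = sprintf("p%02d", seq_len(n_pairs))) {
  do.call(rbind, lapply(seq_along(fail_sets), function(i) {
    data.frame(pair_id = ids, instance = i,
               passed = !ids %in% ids[fail_sets[[i]]],
               stringsAsFactors = FALSE)
  }))
}

test_that("instance aggregation computes mean, sd and the common-failure best", {
  # hand-counted: failure sets {1,2}, {2,3}, {2} over 10 pairs
  agg <- aggregate_instances(make_results(list(c(1, 2), c(2, 3), 2), 10))
  expect_equal(agg$per_instance$error_rate, c(0.2, 0.2, 0.1))
  expect_equal(agg$mean_error, 1 / 6, tolerance = 1e-12)
  expect_equal(agg$best_error, 0.1)
  expect_equal(agg$best_fail_ids, "p02")
  expect_equal(agg$sd_error, sd(c(0.2, 0.2, 0.1)))

  # disjoint failure sets: empty intersection, best = 0
  agg2 <- aggregate_instances(make_results(list(1:2, 3:4), 8))
  expect_equal(agg2$best_error, 0)

  # single instance: best equals the only rate, sd undefined
  agg3 <- aggregate_instances(make_results(list(c(1, 5)), 10))
  expect_equal(agg3$best_error, agg3$mean_error)
  expect_true(is.na(agg3$sd_error))

  # intersection bound holds
  expect_lte(agg$best_error, min(agg$per_instance$error_rate))

  # incomplete grids are rejected
  r <- make_results(list(1, 2), 5)
  expect_error(aggregate_instances(r[-1, ]), "incomplete")
})

test_that("the category breakdown partitions the global counts", {
  pairs <- list(
    corpus_pair("p1", "AP", "point the guitar", "point(guitar)", style = "simple"),
    corpus_pair("p2", "AP", "point the toy", "point(toy)", style = "simple"),
    corpus_pair("p3", "AP", "point the guitar then point the toy",
                "point(guitar); point(toy)", style = "elaborate"),
    corpus_pair("p4", "AP", "point the toy then point the cross",
                "point(toy); point(cross)", style = "elaborate")
  )
  results <- make_results(list(c(1, 3), c(3, 4)), 4,
                          ids = c("p1", "p2", "p3", "p4"))
  tab <- category_breakdown(results, pairs)
  expect_equal(nrow(tab), 2)
  s <- tab[tab$style == "simple", ]
  e <- tab[tab$style == "elaborate", ]
  expect_equal(s$n, 2); expect_equal(e$n, 2)
  expect_equal(s$mean_fail, 0.5)   # p1 fails once over two instances
  expect_equal(s$best_fail, 0)     # no common simple failure
  expect_equal(e$mean_fail, 1.5)   # p3 twice, p4 once
  expect_equal(e$best_fail, 1)     # p3 fails everywhere
  # cells sum to the global mean failure count
  agg <- aggregate_instances(results)
  expect_equal(sum(tab$mean_fail), agg$mean_error * 4)
  expect_equal(sum(tab$best_fail), length(agg$best_fail_ids))
  expect_error(category_breakdown(results, list(corpus_pair("p1", "AP", "x", "a(b)"))),
               "unlabeled|incomplete")
})

test_that("a 3:1 form ambiguity fails exactly the minority pair in learnability", {
  corp <- ambiguous_mini_corpus()
  rep <- learnability_test(corp, eval_config(n_units = 60, n_instances = 2,
                                             base_seed = 10))
  expect_equal(rep$mean_error, 0.25)
  expect_equal(rep$best_fail_ids, "amb4")
  # the majority construction wins: the minority location role is averaged out
  m <- train_comprehension(corp, n_units = 60, seed = 11)
  res <- comprehend(m, "put the toy on my left")
  expect_true(meanings_equal(res$meaning, parse_meaning("put(toy)")))
})

test_that("learnability on a clean codable corpus is error-free", {
  corp <- recall_ap_corpus()
  rep <- learnability_test(corp, eval_config(n_units = 300, n_instances = 2,
                                             base_seed = 0))
  expect_equal(rep$mean_error, 0)
  expect_equal(rep$best_error, 0)
  expect_equal(nrow(rep$results), 2 * length(corp))
  # full determinism of a report given (corpus, config)
  rep2 <- learnability_test(corp, eval_config(n_units = 300, n_instances = 2,
                                              base_seed = 0))
  expect_identical(rep2$results, rep$results)
})

test_that("the leave-one-out fast path matches naive per-fold readout retraining", {
  corp <- generate_ap_corpus(generator_params(n_subjects = 2, n_single = 2,
                                              n_double = 3, seed = 17))
  cfg <- eval_config(n_units = 40, n_instances = 1, base_seed = 4)
  rep <- leave_one_out(corp, cfg)

  lex <- extract_closed_class(corp)
  rc <- reservoir_config(40, cfg$leak_rate, cfg$spectral_radius,
                         cfg$input_scaling, length(lex$words) + 1, 36,
                         seed = cfg$base_seed + 1)
  weights <- init_reservoir(rc)
  forms <- lapply(corp, function(p) to_grammatical_form(p$sentence, lex))
  max_len <- max(vapply(forms, function(f) length(f$tokens), integer(1)))
  naive_pass <- vapply(seq_along(corp), function(j) {
    inputs <- lapply(forms, encode_sentence_input, lex = lex,
                     max_len = max_len, pause_len = cfg$pause_len)
    teachers <- lapply(seq_along(corp), function(i) {
      encode_teacher(meaning_to_grid(corp[[i]]$meaning, forms[[i]]$fifo),
                     max_len + cfg$pause_len,
                     onset = max_len - length(forms[[i]]$tokens))
    })
    states <- lapply(inputs, function(u) run_reservoir(weights, rc, u))
    ro <- train_readout(states[-j], teachers[-j])
    y <- apply_readout(ro, states[[j]])
    dec <- decode_meaning(y[nrow(y), ], forms[[j]]$fifo)
    !dec$incomplete && meanings_equal(dec, corp[[j]]$meaning)
  }, logical(1))
  expect_identical(rep$results$passed, naive_pass)
})

test_that("evaluation reports serialize to JSON", {
  corp <- ambiguous_mini_corpus()
  rep <- learnability_test(corp, eval_config(n_units = 30, n_instances = 1))
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$protocol, "learnability")
  expect_equal(back$n_pairs, 4)
  expect_equal(back$mean_error, rep$mean_error)
})
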