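# Evaluation protocols for the comprehension model: learnability (train =
# test), leave-one-out generalization, multi-instance aggregation with the
# common-failure "best" statistic, and per-category breakdowns.

#' Evaluation configuration
#'
#' Reservoir hyperparameters and the instance scheme used by the evaluation
#' protocols. Instance `i` uses seed `base_seed + i`, so a report is fully
#' determined by (corpus, config).
#'
#' @param n_units Reservoir size (the protocols typically scale this up from
#'   the comprehension default of 100).
#' @param n_instances Number of model instances (different random weight
#'   seeds) to aggregate over.
#' @param base_seed Base seed; instance `i` uses `base_seed + i`.
#' @param leak_rate,spectral_radius,input_scaling,win_dist Reservoir
#'   hyperparameters (comprehension defaults).
#' @param ridge,threshold,pause_len Readout regularization, decoding
#'   threshold and end-of-sentence pause.
#' @return Object of class `eval_config`.
#' @export
eval_config <- function(n_units = 100L, n_instances = 1L, base_seed = 0L,
                        leak_rate = 1 / 6, spectral_radius = 1,
                        input_scaling = 0.75, ridge = 0, threshold = 0.5,
                        pause_len = 1L, win_dist = "binary") {
  stopifnot(n_instances >= 1)
  structure(
    list(n_units = as.integer(n_units), n_instances = as.integer(n_instances),
         base_seed = as.integer(base_seed), leak_rate = leak_rate,
         spectral_radius = spectral_radius, input_scaling = input_scaling,
         ridge = ridge, threshold = threshold, pause_len = as.integer(pause_len),
         win_dist = win_dist),
    class = "eval_config"
  )
}

eval_reservoir_config <- function(cfg, input_dim, seed) {
  reservoir_config(
    n_units = cfg$n_units, leak_rate = cfg$leak_rate,
    spectral_radius = cfg$spectral_radius, input_scaling = cfg$input_scaling,
    input_dim = input_dim, output_dim = GRID_DIM, seed = seed,
    ridge = cfg$ridge, threshold = cfg$threshold, win_dist = cfg$win_dist
  )
}

decode_passes <- function(y_final, pair, fifo, threshold) {
  decoded <- decode_meaning(y_final, fifo, threshold = threshold)
  !isTRUE(decoded$incomplete) && meanings_equal(decoded, pair$meaning)
}

#' Learnability test (train and test on the same corpus)
#'
#' Trains the comprehension model on the full corpus and tests it on the very
#' same sentences, for each of `n_instances` reservoir instances. A sentence
#' that cannot even be memorized is an outlier (or part of an ambiguous
#' construction set) in its corpus; the learnability error is the reference
#' floor for the generalization error. Corpora must be codable (filter with
#' [codable_pairs()] first).
#'
#' @param pairs List of AP [corpus_pair()]s.
#' @param config An [eval_config()].
#' @param lex Optional [lexicon()]; extracted by exclusion when `NULL`.
#' @return An `esn_eval` report; see [aggregate_instances()].
#' @export
learnability_test <- function(pairs, config = eval_config(), lex = NULL) {
  if (is.null(lex)) lex <- extract_closed_class(pairs)
  prep <- comp_prepare(pairs, lex, config$pause_len)
  results <- list()
  for (i in seq_len(config$n_instances)) {
    rc <- eval_reservoir_config(cfg = config, input_dim = length(lex$words) + 1L,
                                seed = config$base_seed + i)
    weights <- init_reservoir(rc)
    states <- lapply(prep$inputs, function(u) run_reservoir(weights, rc, u))
    readout <- train_readout(states, prep$teachers, ridge = config$ridge)
    passed <- vapply(seq_along(pairs), function(j) {
      y <- apply_readout(readout, states[[j]])
      decode_passes(y[nrow(y), ], pairs[[j]], prep$forms[[j]]$fifo,
                    config$threshold)
    }, logical(1))
    results[[i]] <- data.frame(
      pair_id = vapply(pairs, function(p) p$id, character(1)),
      instance = i, passed = passed, stringsAsFactors = FALSE
    )
  }
  build_eval_report("learnability", do.call(rbind, results), pairs, config)
}

#' Leave-one-out generalization test
#'
#' For every instance and every pair, trains the readout on all other pairs
#' and tests the held-out sentence; the padding reference length is computed
#' over the full session (training plus held-out sentence), matching how a
#' trained system is queried with one new sentence. Reservoir states are
#' computed once per instance (they do not depend on the training subset);
#' each fold retrains the readout with the held-out pair's rows removed,
#' using a downdated normal-equations solve with a pseudo-inverse fallback.
#' Fold results are independent of execution order.
#'
#' @inheritParams learnability_test
#' @return An `esn_eval` report.
#' @export
leave_one_out <- function(pairs, config = eval_config(), lex = NULL) {
  if (length(pairs) < 2) stop("leave-one-out needs at least 2 pairs")
  if (is.null(lex)) lex <- extract_closed_class(pairs)
  prep <- comp_prepare(pairs, lex, config$pause_len)
  n_pairs <- length(pairs)
  results <- list()
  for (i in seq_len(config$n_instances)) {
    rc <- eval_reservoir_config(cfg = config, input_dim = length(lex$words) + 1L,
                                seed = config$base_seed + i)
    weights <- init_reservoir(rc)
    states <- lapply(prep$inputs, function(u) run_reservoir(weights, rc, u))
    aug <- lapply(states, function(s) cbind(unclass(s), 1))
    G <- Reduce(`+`, lapply(aug, crossprod))
    C <- Reduce(`+`, mapply(crossprod, aug, prep$teachers, SIMPLIFY = FALSE))
    if (config$ridge > 0) diag(G) <- diag(G) + config$ridge
    passed <- logical(n_pairs)
    for (j in seq_len(n_pairs)) {
      Gm <- G - crossprod(aug[[j]])
      Cm <- C - crossprod(aug[[j]], prep$teachers[[j]])
      coef <- tryCatch(chol2inv(chol(Gm)) %*% Cm, error = function(e) NULL)
      if (is.null(coef)) {
        # rank-deficient fold: fall back to the minimum-norm solution
        ro <- train_readout(states[-j], prep$teachers[-j], ridge = config$ridge)
        coef <- t(ro$w_out)
      }
      y_final <- drop(aug[[j]][nrow(aug[[j]]), , drop = FALSE] %*% coef)
      passed[j] <- decode_passes(y_final, pairs[[j]], prep$forms[[j]]$fifo,
                                 config$threshold)
    }
    results[[i]] <- data.frame(
      pair_id = vapply(pairs, function(p) p$id, character(1)),
      instance = i, passed = passed, stringsAsFactors = FALSE
    )
  }
  build_eval_report("leave_one_out", do.call(rbind, results), pairs, config)
}

#' Aggregate per-sentence results across model instances
#'
#' Computes the per-instance error rate, their mean and sample standard
#' deviation, and the "best" (common-failure) error: the fraction of pairs
#' that fail in *every* instance, i.e. the error of an oracle combination of
#' all instances. By construction best <= min(per-instance rates).
#'
#' @param results Data frame with columns `pair_id`, `instance`, `passed`
#'   covering the complete (pair x instance) grid.
#' @return List with `per_instance` (data frame), `mean_error`, `sd_error`
#'   (`NA` for a single instance), `best_error` and `best_fail_ids`.
#' @export
aggregate_instances <- function(results) {
  stopifnot(all(c("pair_id", "instance", "passed") %in% names(results)))
  tab <- table(results$pair_id, results$instance)
  if (any(tab != 1)) stop("incomplete result grid: need one record per (pair, instance)")
  n_pairs <- length(unique(results$pair_id))
  per_instance <- do.call(rbind, lapply(split(results, results$instance), function(d) {
    data.frame(instance = d$instance[1], n_fail = sum(!d$passed),
               error_rate = mean(!d$passed))
  }))
  fail_by_pair <- tapply(!results$passed, results$pair_id, all)
  best_ids <- names(fail_by_pair)[fail_by_pair]
  best_error <- length(best_ids) / n_pairs
  stopifnot(best_error <= min(per_instance$error_rate) + 1e-12)
  list(
    per_instance = per_instance,
    mean_error = mean(per_instance$error_rate),
    sd_error = if (nrow(per_instance) > 1) stats::sd(per_instance$error_rate) else NA_real_,
    best_error = best_error,
    best_fail_ids = best_ids
  )
}

#' Per-category error breakdown
#'
#' Splits results by the pairs' style and action-count metadata, reporting
#' per cell the mean failure count/rate across instances, the common-failure
#' ("best") count/rate, and the single best instance's count. Cells sum to
#' the global counts.
#'
#' @param results Result grid as in [aggregate_instances()].
#' @param pairs The evaluated pairs (supply style and `n_actions`).
#' @return Data frame with one row per (style, n_actions) cell.
#' @export
category_breakdown <- function(results, pairs) {
  meta <- data.frame(
    pair_id = vapply(pairs, function(p) p$id, character(1)),
    style = vapply(pairs, function(p) p$style, character(1)),
    n_actions = vapply(pairs, function(p) p$n_actions, integer(1)),
    stringsAsFactors = FALSE
  )
  if (anyNA(meta$style)) stop("unlabeled pair(s): style metadata required")
  d <- merge(results, meta, by = "pair_id")
  n_inst <- length(unique(d$instance))
  cells <- unique(meta[c("style", "n_actions")])
  cells <- cells[order(cells$style, cells$n_actions), ]
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(k) {
    sub <- d[d$style == cells$style[k] & d$n_actions == cells$n_actions[k], ]
    n_cell <- length(unique(sub$pair_id))
    fails_by_inst <- tapply(!sub$passed, sub$instance, sum)
    common <- tapply(!sub$passed, sub$pair_id, all)
    data.frame(
      style = cells$style[k], n_actions = cells$n_actions[k], n = n_cell,
      mean_fail = mean(fails_by_inst), mean_rate = mean(fails_by_inst) / n_cell,
      best_fail = sum(common), best_rate = sum(common) / n_cell,
      best_instance_fail = min(fails_by_inst),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

build_eval_report <- function(protocol, results, pairs, config) {
  agg <- aggregate_instances(results)
  category <- if (!anyNA(vapply(pairs, function(p) p$style, character(1)))) {
    category_breakdown(results, pairs)
  }
  structure(
    c(list(protocol = protocol, n_pairs = length(pairs),
           n_instances = config$n_instances, config = config,
           results = results, category = category),
      agg),
    class = "esn_eval"
  )
}

#' @export
print.esn_eval <- function(x, ...) {
  pct <- function(r) sprintf("%.1f%%", 100 * r)
  cat(sprintf("%s test: %d pairs, %d instance(s), %d units\n",
              switch(x$protocol, learnability = "Learnability",
                     leave_one_out = "Leave-one-out generalization", x$protocol),
              x$n_pairs, x$n_instances, x$config$n_units))
  cat(sprintf("  mean error %s%s   best (common failures) %s (%d pairs)\n",
              pct(x$mean_error),
              if (!is.na(x$sd_error)) sprintf(" (sd %s)", pct(x$sd_error)) else "",
              pct(x$best_error), length(x$best_fail_ids)))
  if (!is.null(x$category)) {
    cat("  per category (n, mean fail, best fail):\n")
    for (k in seq_len(nrow(x$category))) {
      r <- x$category[k, ]
      cat(sprintf("    %-13s x %d action(s): %3d   %5.1f (%s)   %3d (%s)\n",
                  r$style, r$n_actions, r$n, r$mean_fail, pct(r$mean_rate),
                  r$best_fail, pct(r$best_rate)))
    }
  }
  invisible(x)
}

#' Write an evaluation report as machine-readable JSON
#'
#' @param x An `esn_eval` report.
#' @param path Output path.
#' @export
write_eval_report <- function(x, path) {
  stopifnot(inherits(x, "esn_eval"))
  out <- list(
    protocol = x$protocol, n_pairs = x$n_pairs, n_instances = x$n_instances,
    n_units = x$config$n_units,
    mean_error = x$mean_error, sd_error = x$sd_error,
    best_error = x$best_error, best_fail_ids = x$best_fail_ids,
    per_instance = x$per_instance, category = x$category
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
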