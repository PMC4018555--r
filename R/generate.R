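# Seeded generators of synthetic sentence-meaning corpora emulating the
# naive-subject command corpus (action performing) and the spatial-relation
# scene descriptions (scene description task).

LOC_VERBS <- c("put", "push", "move")   # verbs taking an object and a location

#' Generator parameters for the action-performing corpus
#'
#' Defaults reproduce the naive-subject study design: 5 subjects each
#' commanding the same 38 filmed behaviors (5 single actions, 33 double
#' actions) once in a simple and once in a more elaborate style, i.e.
#' 5 x 38 x 2 = 380 sentence-meaning pairs.
#'
#' @param n_subjects Number of simulated subjects.
#' @param n_single,n_double Number of single-/double-action behaviors.
#' @param verbs,objects,locations Vocabulary. Verbs among
#'   `c("put", "push", "move")` take a location argument; the others are
#'   object-only.
#' @param distractor_rate Probability that a single-action command carries an
#'   irrelevant "on my <location>" phrase (a content word with no role);
#'   0 by default, i.e. no built-in ambiguity.
#' @param illformed_rate Probability that a pair is replaced by an ill-formed
#'   one (its meaning uses an out-of-vocabulary predicate absent from the
#'   sentence), emulating unprocessable transcript pairs.
#' @param seed Integer seed; the same parameters always generate the same
#'   corpus.
#' @return Object of class `generator_params`.
#' @export
generator_params <- function(n_subjects = 5L, n_single = 5L, n_double = 33L,
                             verbs = c("point", "put", "push", "grasp", "touch", "move"),
                             objects = c("guitar", "violin", "trumpet", "drums",
                                         "toy", "circle", "cross", "triangle"),
                             locations = c("left", "right", "middle"),
                             distractor_rate = 0, illformed_rate = 0,
                             seed = 1L) {
  stopifnot(n_subjects >= 1, n_single >= 0, n_double >= 0,
            n_single + n_double >= 1,
            length(objects) >= 2, length(locations) >= 1,
            distractor_rate >= 0, distractor_rate <= 1,
            illformed_rate >= 0, illformed_rate <= 1)
  structure(
    list(n_subjects = as.integer(n_subjects), n_single = as.integer(n_single),
         n_double = as.integer(n_double), verbs = verbs, objects = objects,
         locations = locations, distractor_rate = distractor_rate,
         illformed_rate = illformed_rate, seed = as.integer(seed)),
    class = "generator_params"
  )
}

# ---- action phrases ---------------------------------------------------------

new_action <- function(verb, obj, loc = NA_character_) {
  list(verb = verb, obj = obj, loc = loc)
}

action_meaning <- function(a) {
  predication(a$verb, a$obj, if (is.na(a$loc)) NA_character_ else a$loc)
}

vp_bare <- function(a) {
  if (is.na(a$loc)) paste(a$verb, "the", a$obj)
  else paste(a$verb, "the", a$obj, "on the", a$loc)
}

vp_it <- function(a) {
  if (is.na(a$loc)) paste(a$verb, "it")
  else paste(a$verb, "it on the", a$loc)
}

# ---- frozen template inventory ---------------------------------------------

ap_template <- function(id, style, kind, dtype, inverted, build, applies = NULL) {
  list(id = id, style = style, kind = kind, dtype = dtype,
       inverted = inverted, build = build,
       applies = if (is.null(applies)) function(a1, a2) TRUE else applies)
}

#' The action-performing template inventory
#'
#' The frozen set of sentence templates the synthetic subjects draw from.
#' Single-action templates cover plain, fronted-location and politeness
#' variants; double-action templates cover "and (then)" chaining, anaphoric
#' "it" for a shared object, "twice"/"two times" for a repeated action, and
#' the temporal constructions with "before"/"after". Sentence-initial
#' "before" and verb-medial "after" invert execution order relative to
#' surface order (`inverted = TRUE`); sentence-initial "after" and
#' verb-medial "before" preserve it.
#'
#' @return List of template records (id, style, kind, dtype, inverted, and a
#'   realization function).
#' @export
ap_templates <- function() {
  no_loc1 <- function(a1, a2) is.na(a1$loc)
  has_loc1 <- function(a1, a2) !is.na(a1$loc)
  list(
    # -- single action, simple style
    ap_template("ss_bare", "simple", "single", "any", FALSE,
                function(a1, a2) vp_bare(a1)),
    ap_template("ss_to", "simple", "single", "any", FALSE,
                function(a1, a2) paste(a1$verb, "to the", a1$obj), no_loc1),
    ap_template("ss_front", "simple", "single", "any", FALSE,
                function(a1, a2) paste("on the", a1$loc, a1$verb, "the", a1$obj),
                has_loc1),
    # -- single action, elaborate style
    ap_template("se_please", "elaborate", "single", "any", FALSE,
                function(a1, a2) paste("please", vp_bare(a1))),
    ap_template("se_could", "elaborate", "single", "any", FALSE,
                function(a1, a2) paste("could you", vp_bare(a1), "please")),
    ap_template("se_you", "elaborate", "single", "any", FALSE,
                function(a1, a2) paste("you", vp_bare(a1))),
    ap_template("se_want", "elaborate", "single", "any", FALSE,
                function(a1, a2) paste("i want you to", vp_bare(a1))),
    # -- double action, simple style
    ap_template("ds_and", "simple", "double", "indep", FALSE,
                function(a1, a2) paste(vp_bare(a1), "and", vp_bare(a2))),
    ap_template("ds_then", "simple", "double", "indep", FALSE,
                function(a1, a2) paste(vp_bare(a1), "then", vp_bare(a2))),
    ap_template("ds_andthen", "simple", "double", "indep", FALSE,
                function(a1, a2) paste(vp_bare(a1), "and then", vp_bare(a2))),
    ap_template("dr_twice", "simple", "double", "repeat", FALSE,
                function(a1, a2) paste(vp_bare(a1), "twice")),
    ap_template("dr_twotimes", "simple", "double", "repeat", FALSE,
                function(a1, a2) paste(vp_bare(a1), "two times")),
    ap_template("da_andthen_it", "simple", "double", "shared", FALSE,
                function(a1, a2) paste(vp_bare(a1), "and then", vp_it(a2))),
    ap_template("da_then_it", "simple", "double", "shared", FALSE,
                function(a1, a2) paste(vp_bare(a1), "then", vp_it(a2))),
    # -- double action, elaborate style; a1/a2 are surface-order arguments
    ap_template("de_before_please", "elaborate", "double", "indep", TRUE,
                function(a1, a2) paste("before you", vp_bare(a1), "please", vp_bare(a2))),
    ap_template("de_before", "elaborate", "double", "indep", TRUE,
                function(a1, a2) paste("before you", vp_bare(a1), vp_bare(a2))),
    ap_template("de_after", "elaborate", "double", "indep", FALSE,
                function(a1, a2) paste("after you", vp_bare(a1), vp_bare(a2))),
    ap_template("de_mid_before", "elaborate", "double", "indep", FALSE,
                function(a1, a2) paste(vp_bare(a1), "before you", vp_bare(a2))),
    ap_template("de_mid_after", "elaborate", "double", "indep", TRUE,
                function(a1, a2) paste(vp_bare(a1), "after you", vp_bare(a2))),
    ap_template("de_please_andthen", "elaborate", "double", "indep", FALSE,
                function(a1, a2) paste("please", vp_bare(a1), "and then", vp_bare(a2))),
    ap_template("der_please_twice", "elaborate", "double", "repeat", FALSE,
                function(a1, a2) paste("please", vp_bare(a1), "twice")),
    ap_template("der_could_twotimes", "elaborate", "double", "repeat", FALSE,
                function(a1, a2) paste("could you", vp_bare(a1), "two times")),
    ap_template("des_mid_before_it", "elaborate", "double", "shared", FALSE,
                function(a1, a2) paste(vp_bare(a1), "before you", vp_it(a2))),
    ap_template("des_please_it", "elaborate", "double", "shared", FALSE,
                function(a1, a2) paste("please", vp_bare(a1), "and then", vp_it(a2)))
  )
}

ILLFORMED_INVENTORY <- list(
  list(sentence = "make a u turn", meaning = "uturn(robot)"),
  list(sentence = "do it again", meaning = "redo(action)"),
  list(sentence = "touch both of them", meaning = "touch(objects)")
)

sample_action <- function(params, with_loc = NULL) {
  verbs <- params$verbs
  loc_v <- intersect(verbs, LOC_VERBS)
  obj_v <- setdiff(verbs, LOC_VERBS)
  if (is.null(with_loc)) {
    with_loc <- length(loc_v) > 0 && (length(obj_v) == 0 || stats::runif(1) < 0.5)
  }
  if (with_loc) {
    if (length(loc_v) == 0) stop("no location-taking verbs in vocabulary")
    new_action(sample(loc_v, 1), sample(params$objects, 1),
               sample(params$locations, 1))
  } else {
    if (length(obj_v) == 0) stop("no object-only verbs in vocabulary")
    new_action(sample(obj_v, 1), sample(params$objects, 1))
  }
}

action_sig <- function(a) paste(a$verb, a$obj, a$loc, sep = "|")

#' Generate a synthetic action-performing corpus
#'
#' Samples the behavior inventory once (shared by all subjects, as if all had
#' watched the same movie), then emits, for every subject and behavior, one
#' simple-style and one elaborate-style command drawn from the frozen
#' [ap_templates()] inventory (templates cycle deterministically across
#' subjects and behaviors, so every construction recurs). Double-action
#' behaviors include repeated actions (realized with "twice"/"two times") and
#' shared-object actions (realized with anaphoric "it"); temporal templates
#' annotate their meanings in execution order, inverting the surface order
#' where the construction demands it. Seeded and fully reproducible.
#'
#' @param params A [generator_params()].
#' @return List of [corpus_pair()]s of length
#'   `n_subjects * (n_single + n_double) * 2`.
#' @export
generate_ap_corpus <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  templates <- ap_templates()
  with_seed(params$seed, {
    # ---- behavior inventory (shared across subjects) ----
    singles <- lapply(seq_len(params$n_single), function(i) {
      # alternate shapes so both object-only and location constructions occur
      sample_action(params, with_loc = (i %% 2 == 0))
    })
    n_rep <- if (params$n_double >= 8) max(1L, round(0.1 * params$n_double)) else 0L
    n_shared <- if (params$n_double >= 5) max(1L, round(0.2 * params$n_double)) else 0L
    n_indep <- params$n_double - n_rep - n_shared
    doubles <- list()
    seen <- character(0)
    add_double <- function(dtype) {
      for (try in 1:200) {
        cand <- switch(dtype,
          repeat_ = { a <- sample_action(params); list(a, a, dtype = "repeat") },
          shared = {
            a <- sample_action(params)
            b <- sample_action(params)
            b$obj <- a$obj
            if (action_sig(a) == action_sig(b)) next
            list(a, b, dtype = "shared")
          },
          indep = {
            # word-disjoint actions: a shared verb/object/location between the
            # two actions would make FIFO binding surface-inconsistent under
            # the inverted (before/after) constructions, i.e. an ambiguity;
            # word sharing is covered by the repeat/shared constructions
            a <- sample_action(params)
            b <- sample_action(params)
            if (a$verb == b$verb || a$obj == b$obj ||
                (!is.na(a$loc) && !is.na(b$loc) && a$loc == b$loc)) next
            list(a, b, dtype = "indep")
          }
        )
        sig <- paste(action_sig(cand[[1]]), action_sig(cand[[2]]), cand$dtype)
        if (!sig %in% seen) {
          seen <<- c(seen, sig)
          return(cand)
        }
      }
      stop("vocabulary too small to sample distinct double actions")
    }
    for (i in seq_len(n_rep)) doubles[[length(doubles) + 1L]] <- add_double("repeat_")
    for (i in seq_len(n_shared)) doubles[[length(doubles) + 1L]] <- add_double("shared")
    for (i in seq_len(n_indep)) doubles[[length(doubles) + 1L]] <- add_double("indep")

    behaviors <- c(lapply(singles, function(a) list(a, dtype = "single")), doubles)

    # ---- plan template assignment ----
    # Within each stratum of (style, behavior type, argument shapes) the
    # applicable templates are identical, and a template plus the shapes
    # fully determines the surface pattern. Assigning templates in balanced
    # contiguous blocks — using at most floor(stratum size / 3) of the
    # applicable templates — guarantees that every emitted construction
    # recurs at least 3 times in corpora with >= 3 pairs per stratum.
    shape_of <- function(a) if (is.na(a$loc)) "N" else "L"
    units <- list()
    for (b in seq_along(behaviors)) {
      beh <- behaviors[[b]]
      for (u in seq_len(params$n_subjects)) {
        for (style in c("simple", "elaborate")) {
          key <- if (identical(beh$dtype, "single")) {
            paste(style, "single", shape_of(beh[[1]]))
          } else {
            paste(style, beh$dtype, shape_of(beh[[1]]), shape_of(beh[[2]]))
          }
          units[[length(units) + 1L]] <- list(b = b, u = u, style = style, key = key)
        }
      }
    }
    keys <- vapply(units, function(x) x$key, character(1))
    choice <- integer(length(units))
    for (key in unique(keys)) {
      members <- which(keys == key)
      beh0 <- behaviors[[units[[members[1]]]$b]]
      style0 <- units[[members[1]]]$style
      cand_ids <- which(vapply(templates, function(tp) {
        if (identical(beh0$dtype, "single")) {
          tp$style == style0 && tp$kind == "single" && tp$applies(beh0[[1]], NULL)
        } else {
          tp$style == style0 && tp$kind == "double" &&
            tp$dtype == (if (beh0$dtype == "indep") "indep" else beh0$dtype)
        }
      }, logical(1)))
      if (length(cand_ids) == 0) stop("no applicable template (inventory bug)")
      k <- max(1L, min(length(cand_ids), length(members) %/% 3L))
      for (pos in seq_along(members)) {
        choice[members[pos]] <- cand_ids[((pos - 1L) * k) %/% length(members) + 1L]
      }
    }

    # ---- emit pairs ----
    pairs <- vector("list", length(units))
    for (counter in seq_along(units)) {
      un <- units[[counter]]
      beh <- behaviors[[un$b]]
      is_single <- identical(beh$dtype, "single")
      style <- un$style
      id <- sprintf("ap%04d", counter)
      if (params$illformed_rate > 0 && stats::runif(1) < params$illformed_rate) {
        bad <- ILLFORMED_INVENTORY[[sample(length(ILLFORMED_INVENTORY), 1)]]
        pairs[[counter]] <- corpus_pair(id, "AP", bad$sentence, bad$meaning,
                                        style = style,
                                        subject = paste0("s", un$u),
                                        template = "illformed",
                                        inverted = FALSE)
        next
      }
      tp <- templates[[choice[counter]]]
      a1 <- beh[[1]]
      a2 <- if (is_single) NULL else beh[[2]]
      # surface order: inverted templates realize the later action first
      sentence <- if (!is_single && tp$inverted) tp$build(a2, a1) else tp$build(a1, a2)
      meaning <- meaning_record(lapply(if (is_single) list(a1) else list(a1, a2),
                                       action_meaning))
      if (is_single && params$distractor_rate > 0 && is.na(a1$loc) &&
          tp$id %in% c("ss_bare", "se_please", "se_you") &&
          stats::runif(1) < params$distractor_rate) {
        sentence <- paste(sentence, "on my", sample(params$locations, 1))
      }
      pairs[[counter]] <- corpus_pair(id, "AP", sentence, meaning,
                                      style = style,
                                      subject = paste0("s", un$u),
                                      template = tp$id,
                                      inverted = tp$inverted)
    }
    pairs
  })
}

# ---- scene-description corpus ----------------------------------------------

sd_realize <- function(meaning, form) {
  preds <- meaning$predications
  if (length(preds) == 1) {
    p <- preds[[1]]
    if (form == "canonical") {
      paste("the", p$arg1, "is to the", p$predicate, "of the", p$arg2)
    } else {
      paste("to the", p$predicate, "of the", p$arg2, "is the", p$arg1)
    }
  } else {
    p1 <- preds[[1]]; p2 <- preds[[2]]
    if (form == "canonical") {
      paste("the", p1$arg1, "is to the", p1$predicate, "of the", p1$arg2,
            "and to the", p2$predicate, "of the", p2$arg2)
    } else {
      paste("to the", p1$predicate, "of the", p1$arg2,
            "and to the", p2$predicate, "of the", p2$arg2,
            "is the", p1$arg1)
    }
  }
}

#' Generate a synthetic scene-description corpus
#'
#' Emits spatial-relation scenes over the object vocabulary, each described
#' in both the canonical and the non-canonical form. Single scenes are one
#' relation `rel(focus, other)` with `rel` in `relations`; double scenes are
#' two relations sharing the focus object, as in "the violin is to the right
#' of the guitar and to the left of the trumpet". Seeded and reproducible.
#'
#' @param objects Object vocabulary (at least 3 distinct objects).
#' @param relations Relation vocabulary (default `left`/`right`).
#' @param n_single,n_double Number of distinct single-/double-relation
#'   scenes; each scene yields two pairs (one per form).
#' @param seed Integer seed.
#' @return List of [corpus_pair()]s of length `2 * (n_single + n_double)`.
#' @export
generate_sd_corpus <- function(objects = c("guitar", "violin", "trumpet", "drums", "toy"),
                               relations = c("left", "right"),
                               n_single = 6L, n_double = 6L, seed = 1L) {
  stopifnot(length(objects) >= 3, length(relations) >= 1,
            n_single + n_double >= 1)
  with_seed(seed, {
    scenes <- list()
    seen <- character(0)
    draw <- function(double) {
      for (try in 1:500) {
        if (!double) {
          ab <- sample(objects, 2)
          m <- meaning_record(predication(sample(relations, 1), ab[1], ab[2]))
        } else {
          abc <- sample(objects, 3)
          m <- meaning_record(
            predication(sample(relations, 1), abc[1], abc[2]),
            predication(sample(relations, 1), abc[1], abc[3])
          )
        }
        sig <- format(m)
        if (!sig %in% seen) {
          seen <<- c(seen, sig)
          return(m)
        }
      }
      stop("vocabulary too small to sample distinct scenes")
    }
    for (i in seq_len(n_single)) scenes[[length(scenes) + 1L]] <- draw(FALSE)
    for (i in seq_len(n_double)) scenes[[length(scenes) + 1L]] <- draw(TRUE)
    pairs <- list()
    counter <- 0L
    for (m in scenes) {
      for (form in c("canonical", "non_canonical")) {
        counter <- counter + 1L
        pairs[[counter]] <- corpus_pair(sprintf("sd%04d", counter), "SD",
                                        sd_realize(m, form), m, style = form,
                                        template = if (length(m$predications) == 1)
                                          paste0("single_", form) else paste0("double_", form),
                                        inverted = FALSE)
      }
    }
    pairs
  })
}
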