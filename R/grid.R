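# The 6 SW x 3 roles x 2 actions meaning code shared by both models:
# comprehension reads it out, production receives it as input.

N_SW <- 6L
N_ROLE <- 3L   # predicate, role2 (agent/object), role3 (location/object)
N_ACT <- 2L
GRID_DIM <- N_SW * N_ROLE * N_ACT  # 36

ROLE_NAMES <- c("predicate", "role2", "role3")

#' Empty thematic-role grid
#'
#' A logical 6 x 3 x 2 array indexed by (SW position, role, action). Role 2
#' displays as "agent" in both tasks; role 3 as "location" (action performing)
#' or "object" (scene description). Flattened column order is SW-fastest,
#' then role, then action, giving the 36 readout/input dimensions.
#'
#' @return Logical array of class `role_grid`.
#' @export
role_grid <- function() {
  structure(
    array(FALSE, dim = c(N_SW, N_ROLE, N_ACT),
          dimnames = list(paste0("sw", 1:N_SW), ROLE_NAMES,
                          paste0("action", 1:N_ACT))),
    class = "role_grid"
  )
}

# column index of cell (sw, role, action) in the flattened 36-vector
grid_index <- function(sw, role, action) {
  sw + N_SW * (role - 1L) + N_SW * N_ROLE * (action - 1L)
}

#' Flatten a role grid to the 36-dimensional coding vector
#' @param grid A `role_grid`.
#' @return Named numeric vector of length 36 (0/1).
#' @export
grid_to_vector <- function(grid) {
  v <- as.numeric(grid)
  names(v) <- as.vector(outer(
    outer(paste0("sw", 1:N_SW), ROLE_NAMES, paste, sep = ":"),
    paste0("a", 1:N_ACT), paste, sep = ":"
  ))
  v
}

#' @export
print.role_grid <- function(x, ...) {
  on <- which(unclass(x), arr.ind = TRUE)
  if (nrow(on) == 0) {
    cat("<empty role grid>\n")
  } else {
    for (i in seq_len(nrow(on))) {
      cat(sprintf("  sw%d %s action%d\n", on[i, 1],
                  ROLE_NAMES[on[i, 2]], on[i, 3]))
    }
  }
  invisible(x)
}

#' Code a meaning as a thematic-role grid
#'
#' Activates, for predication *k* and each filled slot (predicate, arg1,
#' arg2), the cell (FIFO index of the word, slot role, *k*). A word that fills
#' slots in more than one predication (anaphora, repetition markers like
#' "twice") gets several active cells. Repeated content words bind
#' left-to-right: each binding consumes the first FIFO occurrence not yet used
#' by any predication, and falls back to re-using the first occurrence when
#' all are consumed.
#'
#' @param meaning A [meaning_record()].
#' @param fifo Character vector of content words in order of occurrence.
#' @return A [role_grid()].
#' @export
meaning_to_grid <- function(meaning, fifo) {
  stopifnot(inherits(meaning, "meaning_record"))
  if (length(meaning$predications) > N_ACT) stop("at most 2 predications")
  grid <- role_grid()
  consumed <- logical(length(fifo))
  bind <- function(word) {
    idx <- which(fifo == word)
    if (length(idx) == 0) {
      stop(sprintf("meaning word '%s' does not occur among the sentence content words", word))
    }
    free <- idx[!consumed[idx]]
    if (length(free) > 0) {
      consumed[free[1]] <<- TRUE
      free[1]
    } else {
      idx[1]  # anaphoric / repeated reference
    }
  }
  for (k in seq_along(meaning$predications)) {
    p <- meaning$predications[[k]]
    grid[bind(p$predicate), 1L, k] <- TRUE
    if (!is.na(p$arg1)) grid[bind(p$arg1), 2L, k] <- TRUE
    if (!is.na(p$arg2)) grid[bind(p$arg2), 3L, k] <- TRUE
  }
  grid
}

#' Teacher signal for the comprehension readout
#'
#' The meaning is assumed visible while the sentence unfolds: every active
#' grid cell is clamped to 1 from the first word of the sentence (row
#' `onset + 1`) through the last time step (final pause included); inactive
#' cells and all pre-onset padding rows are 0. Clamping from sentence onset is
#' what yields predictive readout activity during parsing.
#'
#' @param grid A [role_grid()].
#' @param T_len Total number of time steps.
#' @param onset Number of leading (left-padding) rows left at zero.
#' @return A `T_len x 36` teacher matrix.
#' @export
encode_teacher <- function(grid, T_len, onset = 0L) {
  stopifnot(T_len >= 1, onset >= 0, onset <= T_len)
  m <- matrix(0, T_len, GRID_DIM)
  active <- which(as.logical(grid))
  if (length(active) > 0 && onset < T_len) {
    m[(onset + 1L):T_len, active] <- 1
  }
  m
}

#' Decode readout activity into a meaning
#'
#' Applies the final-time-step decision rule: activations are thresholded,
#' then for each (SW, action) the surviving role with maximal activation is
#' kept (ties broken toward the lowest role index: predicate < role2 < role3).
#' Action *k* is emitted iff a predicate cell survives for it; its arg1/arg2
#' are the surviving role2/role3 words in SW order, retrieved from the FIFO.
#' Surviving argument cells for an action with no surviving predicate — or no
#' surviving predication at all — yield an *incomplete* meaning (flagged, not
#' an error); evaluation counts such decodings as failures.
#'
#' @param outputs Numeric vector of 36 readout activations (final time step),
#'   or a readout trajectory matrix whose last row is used.
#' @param fifo Content words of the sentence, in order.
#' @param threshold Decoding threshold (default 0.5).
#' @return A [meaning_record()], possibly flagged `incomplete`, with the
#'   decoded `role_grid` attached as attribute `"grid"`.
#' @export
decode_meaning <- function(outputs, fifo, threshold = 0.5) {
  if (is.matrix(outputs)) outputs <- outputs[nrow(outputs), ]
  stopifnot(length(outputs) == GRID_DIM)
  if (length(fifo) == 0) stop("empty FIFO: nothing to decode")
  grid <- role_grid()
  for (k in 1:N_ACT) {
    for (sw in 1:N_SW) {
      vals <- outputs[grid_index(sw, 1:N_ROLE, k)]
      cand <- which(vals >= threshold)
      if (length(cand) > 0) {
        grid[sw, cand[which.max(vals[cand])], k] <- TRUE
      }
    }
  }
  preds <- list()
  incomplete <- FALSE
  n_fifo <- length(fifo)
  for (k in 1:N_ACT) {
    # cells for SW positions beyond the FIFO have no word to bind; ignore them
    sw_pred <- which(grid[, 1L, k]); sw_pred <- sw_pred[sw_pred <= n_fifo]
    sw_a1 <- which(grid[, 2L, k]); sw_a1 <- sw_a1[sw_a1 <= n_fifo]
    sw_a2 <- which(grid[, 3L, k]); sw_a2 <- sw_a2[sw_a2 <= n_fifo]
    if (length(sw_pred) == 0) {
      if (length(sw_a1) + length(sw_a2) > 0) incomplete <- TRUE
      next
    }
    preds[[length(preds) + 1L]] <- predication(
      fifo[sw_pred[1]],
      if (length(sw_a1)) fifo[sw_a1[1]] else NA_character_,
      if (length(sw_a2)) fifo[sw_a2[1]] else NA_character_
    )
  }
  if (length(preds) == 0) incomplete <- TRUE
  out <- meaning_record(preds, incomplete = incomplete)
  attr(out, "grid") <- grid
  out
}
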