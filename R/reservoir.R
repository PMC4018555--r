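# Leaky echo state network core: weight generation, state simulation,
# and offline readout training by pseudo-inverse regression.

#' Reservoir configuration
#'
#' Collects the hyperparameters of a leaky echo state network: the reservoir
#' size, the leak rate \eqn{\alpha} of the leaky-integrator update, the target
#' spectral radius of the recurrent matrix, the input scaling applied to the
#' input weights, and the input/output dimensions. `1/leak_rate` can be read
#' as the time constant of the state dynamics.
#'
#' @param n_units Number of internal (reservoir) units, at least 1.
#' @param leak_rate Leak rate \eqn{\alpha} in (0, 1].
#' @param spectral_radius Target largest absolute eigenvalue of the recurrent
#'   weight matrix (> 0); the randomly drawn matrix is rescaled to this value.
#' @param input_scaling Magnitude applied to the input weights.
#' @param input_dim,output_dim Input and readout dimensions.
#' @param seed Integer seed used when drawing the weight matrices.
#' @param ridge Non-negative regularization scalar for readout training;
#'   0 (the default) selects the pure pseudo-inverse solution.
#' @param threshold Decoding threshold in (0, 1) applied to readout activity.
#' @param win_dist Input weight distribution: `"binary"` draws each entry as
#'   +/- `input_scaling` with equal probability; `"uniform"` draws uniformly
#'   from (-`input_scaling`, `input_scaling`). Input connections are fully
#'   dense in both cases.
#'
#' @return An object of class `reservoir_config`.
#' @seealso [init_reservoir()], [run_reservoir()], [train_readout()]
#' @export
reservoir_config <- function(n_units, leak_rate, spectral_radius, input_scaling,
                             input_dim, output_dim, seed = 1L, ridge = 0,
                             threshold = 0.5, win_dist = c("binary", "uniform")) {
  win_dist <- match.arg(win_dist)
  stopifnot(
    is.numeric(n_units), length(n_units) == 1, n_units >= 1,
    is.numeric(leak_rate), length(leak_rate) == 1, leak_rate > 0, leak_rate <= 1,
    is.numeric(spectral_radius), length(spectral_radius) == 1, spectral_radius > 0,
    is.numeric(input_scaling), length(input_scaling) == 1, input_scaling >= 0,
    is.numeric(input_dim), input_dim >= 1, is.numeric(output_dim), output_dim >= 1,
    is.numeric(ridge), length(ridge) == 1, ridge >= 0,
    is.numeric(threshold), length(threshold) == 1, threshold > 0, threshold < 1
  )
  structure(
    list(
      n_units = as.integer(n_units), leak_rate = leak_rate,
      spectral_radius = spectral_radius, input_scaling = input_scaling,
      input_dim = as.integer(input_dim), output_dim = as.integer(output_dim),
      seed = as.integer(seed), ridge = ridge, threshold = threshold,
      win_dist = win_dist
    ),
    class = "reservoir_config"
  )
}

#' @export
print.reservoir_config <- function(x, ...) {
  cat("Reservoir configuration\n")
  cat(sprintf("  units: %d   leak rate: %.4g   spectral radius: %.4g\n",
              x$n_units, x$leak_rate, x$spectral_radius))
  cat(sprintf("  input scaling: %.4g (%s)   dims: %d -> %d   seed: %d\n",
              x$input_scaling, x$win_dist, x$input_dim, x$output_dim, x$seed))
  invisible(x)
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

spectral_radius_of <- function(w) {
  max(Mod(eigen(w, only.values = TRUE)$values))
}

#' Generate reservoir weight matrices
#'
#' Draws the fixed random weights of the network. Recurrent weights are drawn
#' from a standard normal distribution and rescaled so that their spectral
#' radius equals `config$spectral_radius`. Input weights are fully dense,
#' either +/- `input_scaling` with equal probability (`win_dist = "binary"`)
#' or uniform in (-`input_scaling`, `input_scaling`). Generation is
#' deterministic given `config$seed`. In the degenerate case where the drawn
#' recurrent matrix has a numerically zero spectral radius, the matrix is
#' resampled with an incremented seed (with a warning).
#'
#' @param config A [reservoir_config()].
#' @return An object of class `reservoir_weights`: a list with dense matrices
#'   `w_in` (`n_units` x `input_dim`) and `w_res` (`n_units` x `n_units`).
#' @export
init_reservoir <- function(config) {
  stopifnot(inherits(config, "reservoir_config"))
  n <- config$n_units
  seed <- config$seed
  w_res <- NULL
  repeat {
    w_res <- with_seed(seed, {
      w <- matrix(stats::rnorm(n * n), n, n)
      sr0 <- spectral_radius_of(w)
      if (sr0 < .Machine$double.eps) NULL else w * (config$spectral_radius / sr0)
    })
    if (!is.null(w_res)) break
    warning(sprintf("degenerate recurrent sample (zero spectral radius); resampling with seed %d", seed + 1L))
    seed <- seed + 1L
  }
  w_in <- with_seed(seed + 1000003L, {
    k <- n * config$input_dim
    v <- switch(config$win_dist,
      binary  = sample(c(-1, 1), k, replace = TRUE),
      uniform = stats::runif(k, -1, 1)
    )
    matrix(v * config$input_scaling, n, config$input_dim)
  })
  structure(list(w_in = w_in, w_res = w_res), class = "reservoir_weights")
}

#' @export
print.reservoir_weights <- function(x, ...) {
  cat(sprintf("Reservoir weights: w_res %d x %d (spectral radius %.6g), w_in %d x %d\n",
              nrow(x$w_res), ncol(x$w_res), spectral_radius_of(x$w_res),
              nrow(x$w_in), ncol(x$w_in)))
  invisible(x)
}

#' Simulate the reservoir over an input sequence
#'
#' Runs the leaky-integrator state update
#' \deqn{x(t+1) = (1-\alpha)\,x(t) + \alpha \tanh(W_{res}\,x(t) + W_{in}\,u(t+1))}
#' from the all-zero initial state, producing one state per input row.
#'
#' @param weights A `reservoir_weights` object.
#' @param config The matching [reservoir_config()] (supplies the leak rate).
#' @param inputs Numeric matrix `T x input_dim`, one input vector per step.
#' @return A `T x n_units` state matrix of class `state_trajectory`. All
#'   activations lie strictly inside (-1, 1).
#' @export
run_reservoir <- function(weights, config, inputs) {
  stopifnot(inherits(weights, "reservoir_weights"))
  inputs <- as.matrix(inputs)
  if (ncol(inputs) != ncol(weights$w_in)) {
    stop(sprintf("input has %d columns but the reservoir expects %d",
                 ncol(inputs), ncol(weights$w_in)))
  }
  n <- nrow(weights$w_res)
  T_len <- nrow(inputs)
  a <- config$leak_rate
  # feed-forward drive for all steps in one BLAS call
  drive <- inputs %*% t(weights$w_in)
  states <- matrix(0, T_len, n)
  x <- numeric(n)
  for (t in seq_len(T_len)) {
    x <- (1 - a) * x + a * tanh(drop(weights$w_res %*% x) + drive[t, ])
    states[t, ] <- x
  }
  class(states) <- c("state_trajectory", class(states))
  states
}

# Minimum-norm least-squares solve via the singular value decomposition.
pinv_solve <- function(A, B) {
  s <- svd(A)
  tol <- max(dim(A)) * .Machine$double.eps * max(s$d, 0)
  pos <- s$d > tol
  if (!any(pos)) {
    return(matrix(0, ncol(A), ncol(B)))
  }
  s$v[, pos, drop = FALSE] %*% ((t(s$u[, pos, drop = FALSE]) %*% B) / s$d[pos])
}

#' Train the linear readout
#'
#' Concatenates all time steps of all training sequences, augments every state
#' row with a constant-1 bias entry, and returns the least-squares mapping from
#' augmented states to teacher rows: the Moore-Penrose pseudo-inverse
#' (minimum-norm) solution when `ridge = 0`, or the ridge-regularized
#' normal-equations solution otherwise. Pure linear algebra; deterministic
#' given its inputs, and invariant under uniform replication of the
#' (state, teacher) pairs.
#'
#' @param states A state matrix or a list of state matrices.
#' @param teachers A teacher matrix or a list of teacher matrices; each must
#'   have the same number of rows as the corresponding state matrix.
#' @param ridge Non-negative regularization scalar (default 0).
#' @return An object of class `readout_weights`: matrix `w_out` of dimension
#'   `output_dim x (n_units + 1)`, last column the bias.
#' @export
train_readout <- function(states, teachers, ridge = 0) {
  if (is.matrix(states)) states <- list(states)
  if (is.matrix(teachers)) teachers <- list(teachers)
  if (length(states) == 0) stop("empty training set")
  if (length(states) != length(teachers)) {
    stop("states and teachers must be paired lists of equal length")
  }
  for (i in seq_along(states)) {
    if (nrow(states[[i]]) != nrow(teachers[[i]])) {
      stop(sprintf("sequence %d: %d state rows but %d teacher rows",
                   i, nrow(states[[i]]), nrow(teachers[[i]])))
    }
  }
  X <- do.call(rbind, lapply(states, unclass))
  Y <- do.call(rbind, teachers)
  Xa <- cbind(X, 1)
  coef <- if (ridge > 0) {
    M <- crossprod(Xa)
    diag(M) <- diag(M) + ridge
    solve(M, crossprod(Xa, Y))
  } else {
    pinv_solve(Xa, Y)
  }
  dimnames(coef) <- NULL
  structure(list(w_out = t(coef)), class = "readout_weights")
}

#' Apply a trained readout to a state trajectory
#'
#' Computes the linear readout `y(t) = W_out [x(t); 1]` at every time step.
#' No squashing is applied, so the trajectory can be inspected at any step as
#' the model's running estimate given the inputs so far.
#'
#' @param readout A `readout_weights` object.
#' @param states A state matrix (`T x n_units`).
#' @return A `T x output_dim` matrix of readout activations.
#' @export
apply_readout <- function(readout, states) {
  stopifnot(inherits(readout, "readout_weights"))
  states <- unclass(states)
  if (ncol(states) + 1L != ncol(readout$w_out)) {
    stop(sprintf("trajectory has %d units but the readout expects %d",
                 ncol(states), ncol(readout$w_out) - 1L))
  }
  cbind(states, 1) %*% t(readout$w_out)
}
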