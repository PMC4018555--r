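test_that("recurrent weights are rescaled exactly to the requested spectral radius", {
  for (case in list(c(100, 1), c(50, 0.5), c(30, 2.5))) {
    cfg <- reservoir_config(case[1], 1 / 6, case[2], 0.75, 9, 36, seed = 42)
    w <- init_reservoir(cfg)
    sr <- max(Mod(eigen(w$w_res, only.values = TRUE)$values))
    expect_equal(sr, case[2], tolerance = 1e-6)
  }
  # 1x1 reservoir: spectral radius is just the absolute entry
  w1 <- init_reservoir(reservoir_config(1, 1, 2, 1, 2, 1, seed = 7))
  expect_equal(abs(w1$w_res[1, 1]), 2)
})

test_that("weight generation is deterministic in the seed and respects the input distribution", {
  cfg <- reservoir_config(40, 0.5, 1, 0.75, 9, 36, seed = 11)
  w1 <- init_reservoir(cfg)
  w2 <- init_reservoir(cfg)
  expect_identical(w1, w2)
  w3 <- init_reservoir(reservoir_config(40, 0.5, 1, 0.75, 9, 36, seed = 12))
  expect_false(identical(w1$w_res, w3$w_res))
  # binary: every input weight has magnitude input_scaling, both signs occur
  expect_true(all(abs(abs(w1$w_in) - 0.75) < 1e-15))
  expect_true(any(w1$w_in > 0) && any(w1$w_in < 0))
  # uniform alternative stays inside (-scale, scale)
  wu <- init_reservoir(reservoir_config(40, 0.5, 1, 0.3, 9, 36, seed = 11,
                                        win_dist = "uniform"))
  expect_true(all(abs(wu$w_in) <= 0.3))
  expect_gt(length(unique(abs(wu$w_in))), 10)
})

test_that("config validation rejects out-of-range hyperparameters", {
  expect_error(reservoir_config(0, 0.5, 1, 1, 2, 2))
  expect_error(reservoir_config(10, 0, 1, 1, 2, 2))
  expect_error(reservoir_config(10, 1.5, 1, 1, 2, 2))
  expect_error(reservoir_config(10, 0.5, 0, 1, 2, 2))
  expect_error(reservoir_config(10, 0.5, 1, 1, 2, 2, threshold = 1))
})

test_that("state update follows the leaky-integrator equation", {
  cfg <- reservoir_config(5, 0.3, 0.9, 0.5, 3, 2, seed = 5)
  w <- init_reservoir(cfg)
  u <- matrix(rnorm(21), 7, 3)
  states <- run_reservoir(w, cfg, u)
  expect_equal(dim(states), c(7, 5))
  expect_equal(unclass(states), oracle_reservoir(w$w_in, w$w_res, 0.3, u),
               tolerance = 1e-12)
  # zero input from zero initial state is a fixed point
  z <- run_reservoir(w, cfg, matrix(0, 4, 3))
  expect_true(all(z == 0))
  # with leak 1, a single step is tanh(W_in u)
  cfg1 <- reservoir_config(5, 1, 0.9, 0.5, 3, 2, seed = 5)
  u1 <- matrix(rnorm(3), 1, 3)
  expect_equal(drop(unclass(run_reservoir(w, cfg1, u1))),
               drop(tanh(w$w_in %*% t(u1))))
  expect_error(run_reservoir(w, cfg, matrix(0, 2, 4)), "columns")
})

test_that("without recurrence the state converges geometrically at rate (1 - leak)", {
  a <- 1 / 6
  cfg <- reservoir_config(4, a, 1, 0.75, 2, 2, seed = 3)
  w <- init_reservoir(cfg)
  w$w_res[] <- 0
  u <- matrix(rep(c(0.4, -0.2), each = 30), 30, 2)
  states <- run_reservoir(w, cfg, u)
  target <- drop(tanh(w$w_in %*% u[1, ]))
  gap <- apply(states, 1, function(x) sqrt(sum((x - target)^2)))
  ratios <- gap[-1] / gap[-length(gap)]
  expect_equal(ratios, rep(1 - a, length(ratios)), tolerance = 1e-9)
})

test_that("activations stay strictly inside (-1, 1) for large inputs", {
  cfg <- reservoir_config(30, 0.9, 2, 5, 4, 2, seed = 2)
  w <- init_reservoir(cfg)
  set.seed(1)
  states <- run_reservoir(w, cfg, matrix(rnorm(200, sd = 50), 50, 4))
  expect_true(all(abs(states) < 1))
})

test_that("readout training solves least squares and has the documented invariances", {
  set.seed(10)
  X <- matrix(rnorm(40 * 12), 40, 12)
  Y <- matrix(rnorm(40 * 3), 40, 3)
  ro <- train_readout(X, Y)
  expect_equal(ro$w_out, oracle_readout(X, Y), tolerance = 1e-8)
  # zero teacher -> zero weights (minimum norm)
  expect_true(all(train_readout(X, matrix(0, 40, 3))$w_out == 0))
  # duplicating every pair leaves the solution unchanged
  ro2 <- train_readout(list(X, X), list(Y, Y))
  expect_equal(ro2$w_out, ro$w_out, tolerance = 1e-10)
  # seed-independent: pure linear algebra
  set.seed(999)
  expect_identical(train_readout(X, Y)$w_out, ro$w_out)
  expect_error(train_readout(list(), list()), "empty")
  expect_error(train_readout(X, Y[1:10, ]), "rows")
})

test_that("in the interpolation regime training reproduces the teacher exactly", {
  set.seed(4)
  X <- matrix(rnorm(25 * 30), 25, 30)  # more units than time steps
  Y <- matrix(rnorm(25 * 4), 25, 4)
  ro <- train_readout(X, Y)
  expect_lt(max(abs(apply_readout(ro, X) - Y)), 1e-8)
})

test_that("ridge regularization shrinks the solution toward zero", {
  set.seed(6)
  X <- matrix(rnorm(60 * 10), 60, 10)
  Y <- matrix(rnorm(60 * 2), 60, 2)
  w0 <- train_readout(X, Y, ridge = 0)$w_out
  w9 <- train_readout(X, Y, ridge = 1e3)$w_out
  expect_lt(sum(w9^2), sum(w0^2))
})

test_that("apply_readout is linear with a bias column", {
  ro <- structure(list(w_out = cbind(matrix(0, 3, 5), c(1, -2, 0.5))),
                  class = "readout_weights")
  y <- apply_readout(ro, matrix(0, 4, 5))
  expect_equal(y, matrix(rep(c(1, -2, 0.5), each = 4), 4, 3))
  expect_error(apply_readout(ro, matrix(0, 4, 7)), "units")
})
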