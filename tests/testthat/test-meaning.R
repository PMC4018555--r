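test_that("meaning strings parse and format as an exact inverse pair", {
  for (txt in c("put(toy,left)", "point(guitar)",
                "push(trumpet,left); put(guitar,right)")) {
    expect_equal(format(parse_meaning(txt)), txt)
  }
  m <- parse_meaning(" push( trumpet , left ) ;  put(guitar,right) ")
  expect_equal(format(m), "push(trumpet,left); put(guitar,right)")
  expect_error(parse_meaning(""), "empty")
  expect_error(parse_meaning("put(a,b,c)"), "arguments")
  expect_error(parse_meaning("just words"), "unparseable")
})

test_that("meaning equality is positional and order-sensitive", {
  a <- parse_meaning("push(trumpet,left); put(guitar,right)")
  b <- parse_meaning("put(guitar,right); push(trumpet,left)")
  expect_true(meanings_equal(a, a))
  expect_false(meanings_equal(a, b))  # execution order matters
  expect_false(meanings_equal(parse_meaning("put(toy,left)"),
                              parse_meaning("put(toy,right)")))
  expect_false(meanings_equal(parse_meaning("point(guitar)"),
                              parse_meaning("point(guitar); point(guitar)")))
})

test_that("meanings map onto the role grid cell by cell", {
  # double action with surface/execution inversion
  fifo <- c("put", "right", "guitar", "push", "trumpet", "left")
  g <- meaning_to_grid(parse_meaning("push(trumpet,left); put(guitar,right)"), fifo)
  on <- which(unclass(g), arr.ind = TRUE)
  expect_equal(nrow(on), 6)
  expect_true(g[4, "predicate", 1] && g[5, "role2", 1] && g[6, "role3", 1])
  expect_true(g[1, "predicate", 2] && g[3, "role2", 2] && g[2, "role3", 2])

  # single action without location: only predicate and role2 cells
  g1 <- meaning_to_grid(parse_meaning("point(guitar)"), c("point", "guitar"))
  expect_equal(sum(g1), 2)
  expect_true(g1[1, "predicate", 1] && g1[2, "role2", 1])

  expect_error(meaning_to_grid(parse_meaning("point(guitar)"), c("point", "toy")),
               "guitar")
})

test_that("repeated and anaphoric words bind left-to-right with re-use", {
  # "point the cross twice": one surface occurrence, two predications
  g <- meaning_to_grid(parse_meaning("point(cross); point(cross)"),
                       c("point", "cross"))
  expect_true(g[1, "predicate", 1] && g[2, "role2", 1])
  expect_true(g[1, "predicate", 2] && g[2, "role2", 2])
  # two distinct occurrences consume distinct slots
  g2 <- meaning_to_grid(parse_meaning("grasp(circle); grasp(cross)"),
                        c("grasp", "circle", "grasp", "cross"))
  expect_true(g2[1, "predicate", 1] && g2[3, "predicate", 2])
  # anaphora: shared object re-uses the first occurrence in action 2
  g3 <- meaning_to_grid(parse_meaning("grasp(circle); point(circle)"),
                        c("grasp", "circle", "point"))
  expect_true(g3[2, "role2", 1] && g3[2, "role2", 2] && g3[3, "predicate", 2])
})

test_that("the teacher clamps active cells to 1 from onset to the end", {
  g <- meaning_to_grid(parse_meaning("put(toy,left)"), c("put", "toy", "left"))
  m <- encode_teacher(g, 10)
  expect_equal(sum(colSums(m) == 10), 3)
  expect_equal(sum(m), 30)
  # with an onset, padding rows stay zero
  m2 <- encode_teacher(g, 10, onset = 4)
  expect_true(all(m2[1:4, ] == 0))
  expect_equal(sum(m2), 18)
  expect_true(all(encode_teacher(role_grid(), 5) == 0))
})

test_that("decoding thresholds then takes the per-SW maximal role", {
  fifo <- c("put", "trumpet", "left")
  y <- numeric(36)
  gi <- function(sw, role, act) sw + 6 * (role - 1) + 18 * (act - 1)
  y[gi(1, 1, 1)] <- 0.9; y[gi(2, 2, 1)] <- 0.7; y[gi(3, 3, 1)] <- 0.8
  y[gi(4, 1, 1)] <- 0.2  # below threshold, and beyond the fifo anyway
  dec <- decode_meaning(y, fifo)
  expect_false(dec$incomplete)
  expect_equal(format(dec), "put(trumpet,left)")

  # all sub-threshold: empty meaning, flagged incomplete
  dec2 <- decode_meaning(numeric(36), fifo)
  expect_true(dec2$incomplete)
  expect_length(dec2$predications, 0)

  # per-SW max: role2 at 0.7 beats predicate at 0.6 for the same SW
  y3 <- numeric(36)
  y3[gi(1, 1, 1)] <- 0.9
  y3[gi(2, 1, 1)] <- 0.6; y3[gi(2, 2, 1)] <- 0.7
  dec3 <- decode_meaning(y3, fifo)
  expect_equal(format(dec3), "put(trumpet)")

  # arguments surviving without a predicate: incomplete signal
  y4 <- numeric(36)
  y4[gi(2, 2, 1)] <- 0.8
  expect_true(decode_meaning(y4, fifo)$incomplete)

  # ties break toward the lowest role index
  y5 <- numeric(36)
  y5[gi(1, 1, 1)] <- 0.8; y5[gi(1, 2, 1)] <- 0.8
  expect_true(attr(decode_meaning(y5, fifo), "grid")[1, "predicate", 1])
})

test_that("grid coding and decoding are mutually inverse on random meanings", {
  set.seed(123)
  for (i in 1:200) {
    cs <- random_meaning_case()
    g <- meaning_to_grid(cs$meaning, cs$fifo)
    dec <- decode_meaning(grid_to_vector(g), cs$fifo)
    expect_false(dec$incomplete)
    expect_true(meanings_equal(dec, cs$meaning))
  }
})
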