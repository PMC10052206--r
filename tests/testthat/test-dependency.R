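# Generalized-correlation detection: mutual information on the rank image,
# its invariances, and the surrogate decision rule.

test_that("an identity relation carries the full log2(b) bits of information", {
  d <- pair_dependency(1:100, 1:100, rng_seed = 1)
  expect_equal(d$mi, log2(10), tolerance = 1e-9)
  expect_true(d$structured)
  expect_equal(d$h_i, log2(10), tolerance = 1e-9)
  expect_equal(d$h_ij, log2(10), tolerance = 1e-9)
})

test_that("mutual information vanishes exactly for a product-form image", {
  # a full factorial grid has counts m_ij = (n/b^2) everywhere: independence
  x <- rep(1:10, each = 10)
  y <- rep(1:10, times = 10)
  ent <- qctrends:::mi_from_bins(as.integer(x), as.integer(y), 10L)
  expect_identical(ent$mi, ent$hx + ent$hy - ent$hxy)
  expect_equal(ent$mi, 0, tolerance = 1e-12)
})

test_that("mutual information is non-negative on arbitrary inputs", {
  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(60); y <- rnorm(60)
    d <- pair_dependency(x, y, rng_seed = i)
    expect_gte(d$mi, -1e-12)
  }
})

test_that("the verdict is bit-identical under strictly monotone transforms", {
  set.seed(11)
  x <- rnorm(100); y <- x + rnorm(100, sd = 0.6)
  ref <- pair_dependency(x, y, rng_seed = 5)
  for (f in list(function(v) exp(v), function(v) v^3,
                 function(v) -1 / (1 + exp(-v)) * -1,
                 function(v) 1000 * v - 7)) {
    alt <- pair_dependency(f(x), y, rng_seed = 5)
    expect_identical(alt$mi, ref$mi)
    expect_identical(alt$p_value, ref$p_value)
    expect_identical(alt$structured, ref$structured)
  }
})

test_that("the test is symmetric in its two arguments", {
  set.seed(21)
  for (i in 1:10) {
    x <- rnorm(80); y <- 0.5 * x + rnorm(80)
    a <- pair_dependency(x, y, rng_seed = i, window_index = 3, pair_index = 7)
    b <- pair_dependency(y, x, rng_seed = i, window_index = 3, pair_index = 7)
    expect_identical(a$mi, b$mi)
    expect_identical(a$p_value, b$p_value)
    expect_identical(a$structured, b$structured)
  }
})

test_that("the surrogate stream is deterministic and leaves R's RNG alone", {
  set.seed(99)
  x <- rnorm(100); y <- rnorm(100)
  state_before <- .Random.seed
  a <- pair_dependency(x, y, rng_seed = 2)
  expect_identical(.Random.seed, state_before)
  b <- pair_dependency(x, y, rng_seed = 2)
  expect_identical(a$p_value, b$p_value)
})

test_that("a constant variable is never structured and carries no entropy", {
  d <- pair_dependency(rep(5, 50), rnorm(50), rng_seed = 1)
  expect_false(d$structured)
  expect_equal(d$h_i, 0)
  expect_equal(d$mi, 0)
  expect_equal(d$p_value, 1)
})

test_that("undersized or mismatched inputs are rejected", {
  expect_error(pair_dependency(1:3, 1:3), "insufficient samples")
  expect_error(pair_dependency(1:10, 1:9), "equal length")
  expect_error(pair_dependency(1:10, 1:10, alpha = 0), "alpha")
  x <- c(1:3, rep(NA, 10)); y <- c(NA, NA, NA, 1:10)
  expect_error(pair_dependency(x, y), "insufficient samples")
})

test_that("two independent noise columns give an identity structure matrix", {
  set.seed(7)
  data <- cbind(a = rnorm(100), b = rnorm(100))
  mp <- build_matrices(data, alpha = 0.01, seed = 1)
  expect_identical(unname(mp$S), diag(2))
})

test_that("only the truly dependent pair of three columns is linked", {
  set.seed(8)
  x <- rnorm(100)
  data <- cbind(x = x, y = x, z = rnorm(100))
  mp <- build_matrices(data, alpha = 0.01, seed = 1)
  expect_equal(mp$S["x", "y"], 1)
  expect_equal(mp$S["x", "z"], 0)
  expect_equal(mp$S["y", "z"], 0)
  expect_equal(sum(mp$S) - 3, 2)  # exactly one off-diagonal pair
})

test_that("two identical columns give the all-ones structure matrix", {
  x <- sin(1:100)
  mp <- build_matrices(cbind(u = x, v = x), seed = 1)
  expect_identical(unname(mp$S), matrix(1, 2, 2))
  expect_equal(mp$E["u", "v"], mp$Emin["u", "v"], tolerance = 1e-12)
})

test_that("the entropy matrix has marginals on the diagonal and joints on links", {
  set.seed(9)
  x <- rnorm(100); y <- x + rnorm(100, sd = 0.2); z <- rnorm(100)
  mp <- build_matrices(cbind(x = x, y = y, z = z), seed = 1)
  expect_equal(unname(diag(mp$E)), rep(log2(10), 3), tolerance = 1e-9)
  expect_true(mp$S["x", "y"] == 1)
  d <- pair_dependency(x, y, rng_seed = 1, window_index = 0, pair_index = 1)
  expect_equal(mp$E["x", "y"], d$h_ij)
  expect_equal(mp$E["x", "z"], 0)
})

test_that("the gap policy forces starved pairs unstructured instead of aborting", {
  mask <- matrix(FALSE, 100, 3, dimnames = NULL)
  mask[1:60, 2] <- TRUE                     # variable 2 has only 40% rows
  gp <- gap_policy(mask, min_valid_fraction = 0.5)
  expect_equal(gp$n_valid[1, 2], 40L)
  expect_true(gp$forced[1, 2] && gp$forced[2, 3])
  expect_false(gp$forced[1, 3])

  set.seed(12)
  x <- rnorm(100)
  data <- cbind(a = x, b = x, c = x)
  data[1:60, 2] <- NA
  mp <- build_matrices(data, min_valid_fraction = 0.5, seed = 1)
  expect_equal(mp$S["a", "b"], 0)
  expect_equal(mp$S["a", "c"], 1)
  expect_true("a-b" %in% mp$forced_pairs)
})

test_that("variables with almost no valid rows are dropped for the window", {
  set.seed(13)
  x <- rnorm(50)
  data <- cbind(a = x, b = c(x[1:2], rep(NA, 48)))
  mp <- build_matrices(data, min_valid_fraction = 0, seed = 1)
  expect_true("b" %in% mp$dropped)
  expect_equal(mp$E["b", "b"], 0)
  expect_equal(mp$S["a", "b"], 0)
})
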