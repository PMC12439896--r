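test_that("a fresh memory is all zeros and a where-query returns 64 zeros", {
  mem <- episodicMemory(c("crab", "shrimp"), nWhen = 3, width = 8,
                        height = 8)
  expect_identical(sum(memValues(mem) != 0), 0L)
  v <- queryMemory(mem, what = 1, when = 2)
  expect_length(v, 64L)
  expect_true(all(v == 0))
  expect_identical(names(v)[1], "0,0")
})

test_that("construction validates its inputs", {
  expect_error(episodicMemory(c("a", "a"), 3, 8, 8))
  expect_error(episodicMemory("a", 3, 8, 8, alpha = 0), "alpha")
  expect_error(episodicMemory("a", 3, 8, 8, alpha = 1.5), "alpha")
})

test_that("a bound query reads back exactly what deltaUpdate wrote", {
  mem <- episodicMemory(c("crab", "shrimp"), 3, 8, 8, alpha = 0.10)
  i <- cellIndex(7, 7, 8)
  mem <- deltaUpdate(mem, "shrimp", 3, i, r = 4)
  expect_identical(
    queryMemory(mem, "shrimp", 3, i, reduction = "sum"), 0.4)
  # the worked single update: 0 + 0.10 * (4 - 0) = 0.4
  expect_equal(unname(memValues(mem)["shrimp", 3, i]), 0.4, tolerance = 1e-15)
  expect_identical(sum(memValues(mem) != 0), 1L)
})

test_that("query agrees with a brute-force gather on random tensors", {
  set.seed(11)
  for (rep in 1:100) {
    mem <- episodicMemory(c("a", "b", "c"), 4, 4, 4)
    mem@values[] <- rnorm(length(mem@values))
    v <- memValues(mem)
    what <- if (runif(1) < 0.5) sample(3, 1) else NULL
    when <- if (runif(1) < 0.5) sample(4, 1) else NULL
    where <- if (runif(1) < 0.5) sample(16, sample(5, 1)) else NULL
    red <- sample(c("max", "sum", "mean"), 1)
    expect_equal(queryMemory(mem, what, when, where, reduction = red),
                 bruteQuery(v, what, when, where, red), tolerance = 1e-12)
  }
})

test_that("reduction = none gathers the full unbound dimension in order", {
  set.seed(12)
  mem <- episodicMemory(c("a", "b"), 5, 3, 3)
  mem@values[] <- rnorm(length(mem@values))
  v <- memValues(mem)
  got <- queryMemory(mem, what = 2, when = 4)
  expect_equal(unname(got), bruteQuery(v, what = 2, when = 4))
  # exactly one unbound dimension is required
  expect_error(queryMemory(mem, what = 1), "unbound")
  expect_error(queryMemory(mem, what = 1, when = 1, where = 3), "unbound")
})

test_that("query never mutates the memory", {
  set.seed(13)
  mem <- episodicMemory(c("a", "b"), 3, 4, 4)
  mem@values[] <- rnorm(length(mem@values))
  before <- memValues(mem)
  invisible(queryMemory(mem, what = 1, when = 2, reduction = "max"))
  invisible(queryMemory(mem, when = 1, where = 1:5, reduction = "mean"))
  expect_identical(memValues(mem), before)
})

test_that("query errors name the offending dimension and reject empty sets", {
  mem <- episodicMemory(c("a", "b"), 3, 4, 4)
  expect_error(queryMemory(mem, what = 5, when = 1), "'what'")
  expect_error(queryMemory(mem, what = 1, when = 9), "'when'")
  expect_error(queryMemory(mem, what = 1, when = 1, where = 99), "'where'")
  expect_error(queryMemory(mem, what = "krill", when = 1), "krill")
  expect_error(queryMemory(mem, what = 1, when = 1, where = integer(0)),
               "empty cell set")
})

test_that("an entry equal to the reward is a delta-rule fixed point", {
  mem <- episodicMemory("a", 1, 2, 2, alpha = 0.3)
  mem <- deltaUpdate(mem, 1, 1, 1, r = 2)   # 0.6
  for (k in 1:5) mem <- deltaUpdate(mem, 1, 1, 1, r = 0.6)
  expect_equal(unname(memValues(mem)[1, 1, 1]), 0.6, tolerance = 1e-15)
})

test_that("repeated updates follow the closed form r(1-(1-a)^k) monotonically", {
  for (alpha in c(0.1, 0.37)) {
    r <- 4
    mem <- episodicMemory("a", 1, 2, 2, alpha = alpha)
    prev <- 0
    for (k in 1:60) {
      mem <- deltaUpdate(mem, 1, 1, 1, r = r)
      v <- unname(memValues(mem)[1, 1, 1])
      expect_equal(v, r * (1 - (1 - alpha)^k), tolerance = 1e-12)
      expect_equal(v, iterateDelta(0, alpha, r, k), tolerance = 1e-12)
      expect_gt(v, prev)   # monotone approach from below
      prev <- v
    }
    expect_lt(abs(unname(memValues(mem)[1, 1, 1]) - r), r)  # never overshoots
  }
})

test_that("deltaUpdate touches exactly one entry and validates input", {
  set.seed(14)
  mem <- episodicMemory(c("a", "b"), 3, 4, 4)
  mem@values[] <- rnorm(length(mem@values))
  before <- memValues(mem)
  mem2 <- deltaUpdate(mem, 2, 3, 7, r = 1)
  diff <- memValues(mem2) != before
  expect_identical(sum(diff), 1L)
  expect_true(diff[2, 3, 7])
  expect_error(deltaUpdate(mem, 9, 1, 1, 1), "'what'")
  expect_error(deltaUpdate(mem, 1, 1, 1, Inf), "finite")
})

test_that("softmax matches direct evaluation and its invariances", {
  p <- softmaxProbabilities(c(1, 0), beta = 1)
  expect_equal(unname(p), c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-15)
  expect_equal(unname(p), c(0.7310585786300049, 0.2689414213699951),
               tolerance = 1e-12)

  # equal values and beta = 0 both give the uniform distribution
  expect_equal(unname(softmaxProbabilities(rep(2.5, 7), beta = 3)),
               rep(1 / 7, 7), tolerance = 1e-15)
  expect_equal(unname(softmaxProbabilities(c(-3, 0, 10), beta = 0)),
               rep(1 / 3, 3), tolerance = 1e-15)

  set.seed(15)
  for (rep in 1:20) {
    v <- rnorm(5, sd = 3)
    b <- runif(1, 0, 4)
    p <- softmaxProbabilities(v, b)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0))
    # shift invariance
    expect_equal(softmaxProbabilities(v + 17.3, b), p, tolerance = 1e-12)
    # strictly increasing in its own value
    v2 <- v; v2[3] <- v2[3] + 1
    if (b > 0) expect_gt(softmaxProbabilities(v2, b)[3], p[3])
  }
  # max-shift keeps huge values finite
  expect_equal(sum(softmaxProbabilities(c(1e6, 1e6 - 1), 1)), 1,
               tolerance = 1e-12)
  expect_error(softmaxProbabilities(numeric(0), 1), "non-empty")
})

test_that("selectAction samples the given distribution reproducibly", {
  expect_identical(selectAction(c(1, 0, 0)), 1L)
  set.seed(16)
  draws <- replicate(10000, selectAction(c(0.5, 0.5)))
  freq <- mean(draws == 1)
  expect_lt(abs(freq - 0.5), 3 * sqrt(0.25 / 10000))
  set.seed(17); a <- replicate(50, selectAction(c(0.2, 0.3, 0.5)))
  set.seed(17); b <- replicate(50, selectAction(c(0.2, 0.3, 0.5)))
  expect_identical(a, b)
  expect_error(selectAction(c(0.5, 0.4)), "sum to 1")
  expect_error(selectAction(c(-0.5, 1.5)), "non-negative")
})
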