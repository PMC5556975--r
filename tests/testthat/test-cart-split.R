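# Split search: least-squares improvement, admissibility fractions,
# tie-breaking, and equivalence with exhaustive enumeration.

test_that("pure and undersized nodes are not split", {
  d <- data.frame(y = rep(5, 20), x = rnorm(20))
  expect_null(best_split(d, "y", "x"))

  # 10% of a root sample of 75 is 7.5 -> nodes of fewer than 8 cases stay
  d <- data.frame(y = c(rnorm(7)), x = c(1:7))
  expect_null(best_split(d, "y", "x", tree_controls(), n_root = 75))
  d8 <- data.frame(y = rnorm(8), x = 1:8)
  expect_false(is.null(best_split(d8, "y", "x", tree_controls(), n_root = 75)))
})

test_that("a perfect binary separator attains improvement = parent SSE", {
  d <- data.frame(y = c(rep(0, 10), rep(10, 10)), x = rep(0:1, each = 10))
  rule <- best_split(d, "y", "x")
  expect_equal(rule$predictor, "x")
  expect_equal(rule$threshold, 0.5)
  expect_equal(rule$improvement, 500)   # 20 * var = 20 * 25
  ora <- oracle_best_split(d, "y", "x")
  expect_equal(rule$improvement, ora$improvement)
})

test_that("thresholds are midpoints of consecutive distinct values", {
  d <- data.frame(y = c(1, 1, 8, 9), x = c(1, 2, 6, 10))
  rule <- best_split(d, "y", "x")
  expect_equal(rule$threshold, 4)
})

test_that("ties prefer the earlier predictor and the smaller threshold", {
  d <- data.frame(y = c(0, 0, 10, 10), a = c(1, 1, 2, 2), b = c(5, 5, 9, 9))
  rule <- best_split(d, "y", c("b", "a"))
  expect_equal(rule$predictor, "b")
  rule2 <- best_split(d, "y", c("a", "b"))
  expect_equal(rule2$predictor, "a")

  # equal-improvement thresholds within one predictor: smallest wins
  d3 <- data.frame(y = c(0, 5, 10), x = c(1, 2, 3))
  # both cuts give improvement 37.5; the 1.5 midpoint must be chosen
  rule3 <- best_split(d3, "y", "x")
  expect_equal(rule3$threshold, 1.5)
})

test_that("unknown predictors error; all-missing predictors are skipped", {
  d <- data.frame(y = rnorm(20), x = rnorm(20), z = NA_real_)
  expect_error(best_split(d, "y", "nope"), class = "proshift_config_error")
  rule <- best_split(d, "y", c("z", "x"))
  expect_equal(rule$predictor, "x")
})

test_that("categorical splits match the exhaustive subset search", {
  for (seed in 1:25) {
    set.seed(seed)
    k <- sample(3:5, 1)
    d <- data.frame(y = rnorm(30),
                    g = sample(letters[1:k], 30, replace = TRUE))
    rule <- best_split(d, "y", "g")
    ora <- oracle_best_split(d, "y", "g")
    if (is.null(ora)) {
      expect_null(rule)
    } else {
      expect_equal(rule$improvement, ora$improvement, tolerance = 1e-9)
    }
  }
})

test_that("best_split equals exhaustive enumeration on random tables", {
  n_root_choices <- c(10, 25, 50)
  for (case in 1:120) {
    n <- sample(n_root_choices, 1)
    d <- random_table(n, sample(1:4, 1), seed = 1000 + case)
    ctl <- tree_controls(min_parent_fraction = 0.1, min_child_fraction = 0.05)
    rule <- best_split(d, "y", setdiff(names(d), "y"), ctl)
    ora <- oracle_best_split(d, "y", setdiff(names(d), "y"),
                             min_child = ceiling(0.05 * n),
                             min_parent = ceiling(0.1 * n))
    if (is.null(ora)) {
      expect_null(rule)
    } else {
      expect_equal(rule$improvement, ora$improvement, tolerance = 1e-8,
                   label = sprintf("case %d improvement", case))
    }
  }
})

test_that("first split agrees with an independent recursive-partitioning fit", {
  skip_if_not_installed("rpart")
  for (seed in c(2, 8, 33)) {
    set.seed(seed)
    n <- 60
    d <- data.frame(y = rnorm(n), a = rnorm(n), b = rnorm(n), c = rnorm(n))
    d$y <- d$y + 2 * (d$b > 0.3)
    ours <- best_split(d, "y", c("a", "b", "c"))
    ref <- rpart::rpart(y ~ ., d, method = "anova",
                        control = rpart::rpart.control(
                          minsplit = ceiling(0.1 * n),
                          minbucket = ceiling(0.05 * n),
                          maxdepth = 1, cp = 0, xval = 0))
    expect_equal(ours$predictor, rownames(ref$splits)[1])
    expect_equal(ours$threshold, unname(ref$splits[1, "index"]),
                 tolerance = 1e-10)
  }
})
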