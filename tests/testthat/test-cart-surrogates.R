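# Surrogate splits: predictive association, agreement, ordering, discards.

test_that("an exact copy of the primary splitter is a perfect surrogate", {
  d <- data.frame(y = c(rep(0, 10), rep(10, 10)),
                  a = rep(0:1, each = 10), b = rep(0:1, each = 10))
  primary <- best_split(d, "y", c("a", "b"))
  expect_equal(primary$predictor, "a")
  surr <- find_surrogates(d, "y", primary, c("a", "b"))
  expect_length(surr, 1)
  expect_equal(surr[[1]]$rule$predictor, "b")
  expect_equal(surr[[1]]$association, 1)
  expect_equal(surr[[1]]$agreement, 1)
  # the duplicate achieves the same SSE reduction in its own right
  expect_equal(surr[[1]]$rule$improvement, primary$improvement)
})

test_that("agreement 9/10 with a balanced primary gives association 0.8", {
  # B equals A on 9 of 10 cases; primary on A splits 5/5, so
  # lambda = (0.5 - 0.1) / 0.5 = 0.8
  a <- rep(0:1, each = 5)
  b <- a; b[1] <- 1
  d <- data.frame(y = c(0, 0, 0, 0, 0, 9, 9, 9, 9, 9), a = a, b = b)
  primary <- best_split(d, "y", c("a", "b"))
  surr <- find_surrogates(d, "y", primary, c("a", "b"))
  expect_equal(surr[[1]]$agreement, 0.9)
  expect_equal(surr[[1]]$association, 0.8)
})

test_that("uninformative surrogates are discarded (lambda <= 0)", {
  set.seed(4)
  a <- rep(0:1, each = 25)
  d <- data.frame(y = c(rnorm(25, 0), rnorm(25, 10)), a = a,
                  noise = sample(rep(0:1, 25)))
  primary <- best_split(d, "y", c("a", "noise"))
  surr <- find_surrogates(d, "y", primary, c("a", "noise"))
  for (s in surr) expect_gt(s$association, 0)
  # a constant candidate can never be retained
  d$flat <- 1
  surr2 <- find_surrogates(d, "y", primary, c("a", "noise", "flat"))
  expect_false("flat" %in% vapply(surr2, function(s) s$rule$predictor, ""))
})

test_that("surrogates are ordered by non-increasing association and truncated", {
  set.seed(9)
  a <- rep(0:1, each = 20)
  mk_copy <- function(err) {
    b <- a; idx <- sample.int(40, err); b[idx] <- 1 - b[idx]; b
  }
  d <- data.frame(y = c(rnorm(20, 0, .1), rnorm(20, 10, .1)), a = a,
                  b1 = mk_copy(2), b2 = mk_copy(6), b3 = mk_copy(10))
  primary <- best_split(d, "y", c("a", "b1", "b2", "b3"))
  surr <- find_surrogates(d, "y", primary, c("a", "b1", "b2", "b3"))
  assoc <- vapply(surr, function(s) s$association, numeric(1))
  expect_true(all(diff(assoc) <= 1e-12))
  ctl <- tree_controls(max_surrogates = 1)
  surr1 <- find_surrogates(d, "y", primary, c("a", "b1", "b2", "b3"), ctl)
  expect_length(surr1, 1)
  expect_equal(surr1[[1]]$association, max(assoc))
})

test_that("a reversed-orientation surrogate is found and routes correctly", {
  # b is a mirrored copy of a: high b corresponds to the primary's left side
  a <- rep(0:1, each = 10)
  b <- 1 - a
  d <- data.frame(y = c(rep(0, 10), rep(10, 10)), a = a, b = b)
  primary <- best_split(d, "y", c("a", "b"))
  surr <- find_surrogates(d, "y", primary, c("a", "b"))
  expect_equal(surr[[1]]$association, 1)
  # routing a case missing `a` through the mirrored surrogate
  fit <- grow_tree(d, "y", c("a", "b"), cv = FALSE)
  missing_a <- data.frame(a = NA_real_, b = 1)   # b = 1 -> a = 0 side
  expect_equal(predict(fit, missing_a), 0)
})
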