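# Tree growth: stopping, node accounting, routing of incomplete cases,
# breadth-first ids, determinism, risk monotonicity.

test_that("degenerate inputs behave: empty table errors, constant outcome is a stump", {
  expect_error(grow_tree(data.frame(), "y", "x"), class = "proshift_input_error")
  d <- data.frame(y = rep(3, 30), x = rnorm(30))
  fit <- grow_tree(d, "y", "x", cv = FALSE)
  expect_length(fit$nodes, 1)
  expect_equal(fit$risk_resubstitution, 0)
  expect_equal(fit$root_variance, 0)
})

test_that("a perfect separator yields a depth-1 tree with zero risk", {
  d <- data.frame(y = c(rep(0, 10), rep(10, 10)), x = rep(0:1, each = 10))
  fit <- grow_tree(d, "y", "x", cv = FALSE)
  expect_length(fit$nodes, 3)
  expect_equal(fit$risk_resubstitution, 0)
  expect_equal(sort(vapply(fit$nodes[2:3], `[[`, numeric(1), "mean")), c(0, 10))
  # population variance at the root: mean 5, deviations 5 -> 25
  expect_equal(fit$root_variance, 25)
})

test_that("node ids are breadth-first and every non-root node has one parent", {
  set.seed(11)
  d <- data.frame(y = rnorm(120), a = rnorm(120), b = rnorm(120),
                  g = sample(c("u", "v", "w"), 120, replace = TRUE))
  fit <- grow_tree(d, "y", c("a", "b", "g"), cv = FALSE)
  nodes <- tidy(fit)
  expect_equal(nodes$node_id, seq_len(nrow(nodes)) - 1L)
  expect_true(all(diff(nodes$depth) >= 0))          # BFS: depth non-decreasing
  internal <- nodes[!nodes$terminal, ]
  kids <- c(internal$child_left, internal$child_right)
  expect_equal(sort(kids), setdiff(nodes$node_id, 0L))  # each child once
  # parent links agree with the child links
  for (i in seq_len(nrow(internal))) {
    expect_equal(nodes$parent[nodes$node_id == internal$child_left[i]],
                 internal$node_id[i])
  }
})

test_that("children sizes sum to the parent and terminals partition the root", {
  for (seed in c(3, 17, 42)) {
    d <- random_table(80, 3, seed)
    fit <- grow_tree(d, "y", setdiff(names(d), "y"), cv = FALSE)
    nodes <- tidy(fit)
    for (i in which(!nodes$terminal)) {
      expect_equal(nodes$n[i],
                   nodes$n[nodes$node_id == nodes$child_left[i]] +
                     nodes$n[nodes$node_id == nodes$child_right[i]])
    }
    expect_equal(sum(nodes$n[nodes$terminal]), fit$n_root)
    # every case reaches exactly one terminal
    pred <- predict(fit, d)
    expect_length(pred, nrow(d))
    expect_false(anyNA(pred))
    # realized splits never increase impurity
    for (i in which(!nodes$terminal)) {
      expect_gte(nodes$sse[i] + 1e-8,
                 nodes$sse[nodes$node_id == nodes$child_left[i]] +
                   nodes$sse[nodes$node_id == nodes$child_right[i]])
    }
  }
})

test_that("resubstitution risk never increases with additional depth", {
  d <- random_table(150, 3, seed = 7)
  risks <- vapply(0:5, function(dep) {
    grow_tree(d, "y", setdiff(names(d), "y"),
              tree_controls(max_depth = dep), cv = FALSE)$risk_resubstitution
  }, numeric(1))
  expect_true(all(diff(risks) <= 1e-10))
  expect_equal(risks[1], grow_tree(d, "y", "x1", tree_controls(max_depth = 0),
                                   cv = FALSE)$root_variance)
})

test_that("cases missing the primary are routed by surrogates, else majority", {
  d <- data.frame(y = c(rep(0, 12), rep(10, 8)),
                  a = c(rep(0, 12), rep(1, 8)),
                  b = c(rep(0, 12), rep(1, 8)))
  fit <- grow_tree(d, "y", c("a", "b"), cv = FALSE)
  # perfect surrogate: same terminal as if the primary were observed
  expect_equal(predict(fit, data.frame(a = NA, b = 0)), 0)
  expect_equal(predict(fit, data.frame(a = NA, b = 1)), 10)
  # all predictors missing: larger child (left, 12 cases) wins
  expect_equal(predict(fit, data.frame(a = NA, b = NA)), 0)
})

test_that("rows with a missing dependent are dropped with a warning", {
  d <- data.frame(y = c(rnorm(30), NA, NA), x = rnorm(32))
  expect_warning(fit <- grow_tree(d, "y", "x", cv = FALSE),
                 "dropping 2 row")
  expect_equal(fit$n_root, 30)
})

test_that("growth and cross-validation are deterministic given the seed", {
  d <- random_table(90, 3, seed = 21)
  ctl <- tree_controls(seed = 99)
  f1 <- grow_tree(d, "y", setdiff(names(d), "y"), ctl)
  f2 <- grow_tree(d, "y", setdiff(names(d), "y"), ctl)
  expect_identical(f1, f2)
  f3 <- grow_tree(d, "y", setdiff(names(d), "y"), tree_controls(seed = 100))
  expect_identical(tidy(f3), tidy(f1))      # structure ignores the fold seed
})

test_that("the root split can be anchored on a designated predictor", {
  co <- simulate_trial(generator_config(seed = 5), keep_items = FALSE)
  p <- co$participants
  preds <- c("dh_week8", paste0(dheq_subscales, "_change"))
  fit <- grow_tree(p, "total_change", preds, root_split = "dh_week8",
                   cv = FALSE)
  expect_equal(fit$nodes[[1]]$split$predictor, "dh_week8")
  # DH+ participants (left categories sorted by mean change) land together
  nodes <- tidy(fit)
  expect_equal(sort(nodes$n[nodes$node_id %in% 1:2]),
               sort(as.vector(table(p$dh_week8))))
})
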