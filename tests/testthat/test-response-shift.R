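# Clinical status rule, recalibration labels, node summaries, model fit,
# reprioritization.

test_that("clinical status needs two non-adjacent sensitive teeth", {
  mk <- function(pos, tac, sch) {
    data.frame(position = pos, tactile_g = tac, schiff = sch)
  }
  # nothing sensitive
  expect_equal(as.character(classify_clinical_status(
    mk(c(14, 25), c(40, 35), c(1, 0)))$dh_status), "DH-")
  # two sensitive but adjacent (same quadrant, consecutive): still negative
  expect_equal(as.character(classify_clinical_status(
    mk(c(14, 15), c(15, 10), c(2, 3)))$dh_status), "DH-")
  # different quadrants at the thresholds (20 g, Schiff 2): positive
  expect_equal(as.character(classify_clinical_status(
    mk(c(14, 25), c(20, 15), c(2, 2)))$dh_status), "DH+")
  # three teeth in a run: the outer pair is non-adjacent
  expect_equal(as.character(classify_clinical_status(
    mk(c(13, 14, 15), c(10, 10, 10), c(3, 3, 3)))$dh_status), "DH+")
  # one sensitive + one borderline (tactile ok, Schiff 1): negative
  expect_equal(as.character(classify_clinical_status(
    mk(c(14, 25), c(15, 15), c(2, 1)))$dh_status), "DH-")
})

test_that("brute force over all position pairs agrees with the adjacency rule", {
  pool <- c(11:16, 21:26, 31:36, 41:46)
  set.seed(8)
  for (rep in 1:50) {
    pos <- sample(pool, 2)
    teeth <- data.frame(position = pos, tactile_g = c(10, 10), schiff = c(2, 2))
    st <- classify_clinical_status(teeth)$dh_status
    adjacent <- (pos[1] %/% 10 == pos[2] %/% 10) &&
      abs(pos[1] %% 10 - pos[2] %% 10) == 1
    expect_equal(as.character(st), if (adjacent) "DH-" else "DH+")
  }
})

test_that("invalid per-tooth evidence is rejected", {
  bad <- data.frame(position = 14, tactile_g = 10, schiff = 4)
  expect_error(classify_clinical_status(bad), class = "proshift_input_error")
  bad2 <- data.frame(position = 14, tactile_g = 0, schiff = 2)
  expect_error(classify_clinical_status(bad2), class = "proshift_input_error")
})

test_that("recalibration labels follow the status/change discordance table", {
  d <- tibble::tibble(
    dh_week8 = c("DH+", "DH-", "DH+", "DH-", "DH+", "DH-"),
    total_change = c(-42, 17.6, 0, 0, 30, -30)
  )
  lab <- classify_recalibration(d)
  expect_equal(as.character(lab$rs_direction),
               c("downward", "upward", "none", "none", "none", "none"))
  expect_equal(as.character(lab$rs_consistency),
               c("shifted", "shifted", "consistent_worse",
                 "consistent_improved", "consistent_worse",
                 "consistent_improved"))
  # -42 exceeds the MID of 22; +17.6 does not
  expect_equal(lab$rs_important, c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE))
})

test_that("every status/change combination maps to exactly one label", {
  grid <- expand.grid(status = c("DH+", "DH-"),
                      change = c(-40, -22, -5, 0, 5, 22, 40),
                      stringsAsFactors = FALSE)
  lab <- classify_recalibration(grid, status = "status", change = "change")
  expect_false(anyNA(lab$rs_direction))
  expect_false(anyNA(lab$rs_consistency))
  # direction implies the defining conditions
  expect_true(all(lab$status == "DH+" & lab$change < 0 |
                    lab$rs_direction != "downward"))
  expect_true(all(lab$status == "DH-" & lab$change > 0 |
                    lab$rs_direction != "upward"))
})

test_that("raising the MID never increases the count of important labels", {
  set.seed(3)
  d <- tibble::tibble(dh_week8 = sample(c("DH+", "DH-"), 200, TRUE),
                      total_change = rnorm(200, -10, 30))
  counts <- vapply(c(5, 10, 22, 30, 50), function(m) {
    sum(classify_recalibration(d, mid = m)$rs_important)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("explained variance reproduces the printed model-fit arithmetic", {
  fit <- explained_variance(214.268, 1018.822)
  expect_equal(round(fit$error_variance, 2), 0.21)
  expect_equal(round(fit$explained_variance, 2), 0.79)
  expect_equal(explained_variance(0, 5)$explained_variance, 1)
  expect_equal(explained_variance(5, 5)$explained_variance, 0)
  expect_error(explained_variance(1, 0), class = "proshift_input_error")
  # affine rescaling of the outcome leaves the proportions unchanged
  expect_equal(explained_variance(214.268 * 4, 1018.822 * 4)$explained_variance,
               explained_variance(214.268, 1018.822)$explained_variance)
})

test_that("node summaries cover the sample and aggregate the labels", {
  d <- toy_cohort(n = 60, seed = 2)
  fit <- grow_tree(d, "total_change", c("dh_week8", "coping_change"),
                   cv = FALSE)
  ns <- node_rs_summary(fit, d)
  expect_equal(ns$n[ns$node_id == 0], 60)
  expect_equal(ns$pct_of_sample[ns$node_id == 0], 100)
  expect_equal(sum(ns$n[ns$terminal]), 60)
  # terminal shares sum to the whole sample
  expect_equal(sum(ns$pct_of_sample[ns$terminal]), 100)
  # the toy's DH+ members all improved by ~30: a pure downward node exists
  down_nodes <- ns[ns$terminal & ns$pct_downward == 100, ]
  expect_gt(sum(down_nodes$n), 0)
  expect_error(node_rs_summary(fit, d[, setdiff(names(d), "dh_week8")]),
               class = "proshift_input_error")
})

test_that("a root-only tree summarises as a single all-sample row", {
  d <- toy_cohort(n = 30)
  fit <- grow_tree(d, "total_change", "social_change",
                   tree_controls(max_depth = 0), cv = FALSE)
  ns <- node_rs_summary(fit, d)
  expect_equal(nrow(ns), 1)
  expect_equal(ns$pct_of_sample, 100)
})

test_that("reprioritization flags exactly the predictors whose rank moved", {
  imp1 <- tibble::tibble(predictor = c("social", "coping", "identity"),
                         raw_importance = c(30, 20, 10),
                         scaled_importance = c(100, 66.7, 33.3),
                         rank = c(1L, 2L, 3L))
  expect_equal(sum(reprioritization_report(imp1, imp1)$flagged), 0)
  imp2 <- imp1
  imp2$rank <- c(2L, 1L, 3L)
  imp2$scaled_importance <- c(80, 100, 33.3)
  rep2 <- reprioritization_report(imp1, imp2)
  expect_equal(rep2$flagged[rep2$predictor %in% c("social", "coping")],
               c(TRUE, TRUE))
  expect_false(rep2$flagged[rep2$predictor == "identity"])
  expect_equal(rep2$rank_delta[rep2$predictor == "social"], -1L)
  expect_error(reprioritization_report(imp1, imp1[1:2, ]),
               class = "proshift_input_error")
})

test_that("permuted importance orders are flagged exhaustively and exactly", {
  preds <- paste0("p", 1:5)
  base <- tibble::tibble(predictor = preds,
                         raw_importance = c(50, 40, 30, 20, 10),
                         scaled_importance = c(100, 80, 60, 40, 20),
                         rank = 1:5)
  perms <- list(c(1, 2, 3, 4, 5), c(2, 1, 3, 4, 5), c(5, 4, 3, 2, 1),
                c(1, 3, 2, 5, 4), c(3, 1, 2, 4, 5))
  for (pm in perms) {
    moved <- base
    moved$rank <- as.integer(pm)
    rep <- reprioritization_report(base, moved)
    # brute-force expectation: flag iff the permutation moves the rank
    expect_equal(rep$flagged[match(preds, rep$predictor)],
                 base$rank != pm)
    expect_equal(rep$rank_delta[match(preds, rep$predictor)],
                 as.integer(base$rank - pm))
  }
})
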