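# Synthetic cohort generator: determinism, instrument constraints, feasibility
# checks, truth firewall, consistency with the clinical classifier, and
# calibration against its own configured targets.

test_that("a fixed seed reproduces the cohort bit-identically", {
  c1 <- simulate_trial(generator_config(seed = 123))
  c2 <- simulate_trial(generator_config(seed = 123))
  expect_identical(c1$participants, c2$participants)
  expect_identical(c1$teeth, c2$teeth)
  expect_identical(c1$truth, c2$truth)
  c3 <- simulate_trial(generator_config(seed = 124))
  expect_false(identical(c1$participants, c3$participants))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(500)
  before <- rnorm(1)
  set.seed(500)
  invisible(simulate_trial(generator_config(n_participants = 10, seed = 9)))
  expect_identical(rnorm(1), before)
})

test_that("item scores, subscale totals and instrument totals are consistent", {
  co <- simulate_trial(generator_config(seed = 31))
  p <- co$participants
  expect_true(all(co$items$score >= 1 & co$items$score <= 7))
  rng <- dheq_range()
  for (tp in c("screening", "week8")) {
    tot <- p[[paste0("total_", tp)]]
    expect_true(all(tot >= rng["min"] & tot <= rng["max"]))
    sub_sum <- Reduce(`+`, lapply(dheq_subscales, function(s) {
      p[[paste0(s, "_", tp)]]
    }))
    expect_equal(sub_sum, tot)
    # items sum back to their subscale totals
    item_sums <- co$items |>
      dplyr::filter(timepoint == tp) |>
      dplyr::group_by(id, subscale) |>
      dplyr::summarise(s = sum(score), .groups = "drop")
    for (s in dheq_subscales) {
      expect_equal(item_sums$s[item_sums$subscale == s][order(
        item_sums$id[item_sums$subscale == s])],
        p[[paste0(s, "_", tp)]])
    }
  }
  expect_equal(p$total_change, p$total_week8 - p$total_screening)
})

test_that("emitted per-tooth evidence reproduces the assigned clinical status", {
  co <- simulate_trial(generator_config(n_participants = 150, seed = 77))
  st <- classify_clinical_status(co$teeth)
  expect_equal(as.character(st$dh_status[order(st$id)]),
               as.character(co$participants$dh_week8))
})

test_that("truth columns live outside the analysis table", {
  co <- simulate_trial(generator_config(seed = 5))
  expect_false(any(grepl("true|persist|latent|intended",
                         names(co$participants))))
  expect_true(all(c("true_class", "true_shift") %in% names(co$truth)))
  # observed change is the intended latent + shift, rounded to the grid and
  # clipped to the instrument range
  intended <- co$truth$latent_change + co$truth$true_shift
  expected <- pmin(pmax(round(co$participants$total_screening + intended),
                        34), 238) - co$participants$total_screening
  expect_equal(co$participants$total_change, expected)
})

test_that("infeasible class probabilities are rejected with the binding constraint", {
  expect_error(generator_config(p_downward = 0.6, p_dh_persist = 0.493),
               "p_dh_persist", class = "proshift_config_error")
  expect_error(generator_config(p_upward = 0.6, p_dh_persist = 0.493),
               class = "proshift_config_error")
  expect_error(generator_config(p_downward = 0.7, p_upward = 0.4),
               class = "proshift_config_error")
})

test_that("with no injected shifts no participant carries a shift", {
  co <- simulate_trial(generator_config(p_downward = 0, p_upward = 0,
                                        seed = 55))
  expect_true(all(co$truth$true_class == "none"))
  expect_true(all(co$truth$true_shift == 0))
})

test_that("completer subsampling matches the configured counts", {
  co <- simulate_trial(generator_config(seed = 20))
  p <- co$participants
  expect_equal(sum(!is.na(p$then_total)), 43)
  expect_equal(sum(!is.na(p$ideal_total_screening)), 31)
  expect_equal(sum(!is.na(p$ideal_total_week8)), 31)
})

test_that("marginal summaries cover arms and pooled rows in the table layout", {
  co <- simulate_trial(generator_config(seed = 3))
  marg <- summarize_marginals(co)
  expect_setequal(unique(marg$arm), c("A", "B", "C", "pooled"))
  expect_setequal(unique(marg$block),
                  c("demographics", "baseline", "change", "status"))
  pooled_total <- marg[marg$arm == "pooled" & marg$measure == "total_screening", ]
  expect_equal(pooled_total$mean, mean(co$participants$total_screening))
  dh_rows <- marg[marg$arm == "pooled" & marg$block == "status", ]
  expect_equal(sum(dh_rows$mean), 100)
  # single participant: SDs undefined, reported as NA
  one <- summarize_marginals(co$participants[1, ])
  expect_true(all(is.na(one$sd[one$block %in% c("baseline", "change")])))
})

test_that("generator moments track the configured targets over replicates", {
  reps <- vapply(1:40, function(s) {
    p <- simulate_trial(generator_config(seed = 7000 + s),
                        keep_items = FALSE)$participants
    c(mean(p$total_screening), mean(p$total_change),
      mean(p$dh_week8 == "DH+"))
  }, numeric(3))
  m <- rowMeans(reps)
  se <- apply(reps, 1, stats::sd) / sqrt(ncol(reps))
  expect_lt(abs(m[1] - 129.9), 3 * se[1] + 0.5)
  expect_lt(abs(m[2] + 14.1), 3 * se[2] + 0.5)
  expect_lt(abs(m[3] - 0.493), 3 * se[3] + 0.01)
})
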