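## Seeded generator of DHEQ-like two-timepoint cohorts. Baseline subscale
## totals follow a one-factor (single latent severity) model calibrated to the
## trial-table marginals; week-8 change is a four-class mixture (persistent
## DH with/without downward recalibration, resolved DH with/without upward
## recalibration) whose class means are solved so the observed total-change
## mean matches the configured target; per-tooth clinical evidence is built to
## be consistent with the DH+ rule; hidden truth columns are kept in a
## separate element so analysis code can never see them.

## Relative subscale magnitudes and SDs behind the default calibration
## (pooled active-treatment baseline rows of the source trial's sample table).
.baseline_subscale_means <- c(restrictions = 18.1, coping = 50.3,
                              social = 17.2, emotional = 32.4,
                              identity = 13.9)
.baseline_subscale_sds <- c(restrictions = 5.5, coping = 14.3, social = 6.4,
                            emotional = 6.6, identity = 7.0)

#' Configuration of the synthetic DHEQ trial generator
#'
#' Defaults reproduce the study conditions of an 8-week dentine
#' hypersensitivity trial's active arms: n = 75, baseline total 129.9
#' (SD 36.5), 8-week change -14.1, 49.3% clinically persistent DH at week 8,
#' 36% downward and 14.7% upward recalibrators, 43 then-test and 31 ideals
#' completers, 34 seven-point items across five correlated subscales.
#'
#' @param n_participants Cohort size. Default 75.
#' @param baseline_total_mean,baseline_total_sd Target moments of the
#'   baseline DHEQ total. Defaults 129.9 and 36.5.
#' @param change_total_mean Target mean of the week-8 minus screening total
#'   change. Default -14.1.
#' @param change_total_sd Scale of individual change variability; the
#'   class-conditional change SDs are proportional to it. Default 31.9.
#' @param p_dh_persist Probability of clinically persistent DH at week 8.
#'   Default 0.493.
#' @param p_downward,p_upward Cohort fractions of downward and upward
#'   recalibrators. Downward recalibration can only occur among persisters
#'   and upward only among resolvers, so `p_downward <= p_dh_persist` and
#'   `p_upward <= 1 - p_dh_persist` are required. Defaults 0.36 and 0.147.
#' @param downward_shift_mean Mean shift (score points) added to downward
#'   recalibrators' status-consistent change. Default -35, which places their
#'   average observed change beyond the MID of 22.
#' @param upward_shift_mean Mean shift added to upward recalibrators.
#'   Default +40 (observed mean about +17 given the resolver baseline).
#' @param persist_change_mean Mean status-consistent change among persisters
#'   who do not recalibrate. Default +9.
#' @param subscale_weights_t1 Positive weights shaping how strongly each
#'   subscale loads on the latent severity factor at baseline (screening-time
#'   correlation structure). Default emphasises the social subscale.
#' @param subscale_weights_t2 Positive weights allocating the total change
#'   across subscales (follow-up-time structure). Default emphasises coping.
#'   Reprioritization is injected by `t1 != t2`.
#' @param subscale_correlation Baseline one-factor strength in `[0, 1)`.
#'   Default 0.6.
#' @param items_per_subscale Item counts (must sum to 34). Default
#'   5/14/5/6/4 for restrictions/coping/social/emotional/identity, chosen to
#'   match the subscale mean magnitudes.
#' @param then_completers,ideals_completers Numbers of participants with
#'   then-test and ideals data. Defaults 43 and 31.
#' @param then_shift_mean,then_shift_sd Moments of the then-minus-pre
#'   difference among completers. Defaults -15.9 and 32.3.
#' @param ideals_shift_mean,ideals_shift_sd Moments of the ideal-followup
#'   minus ideal-baseline total difference. Defaults -6.19 and 20.26.
#' @param ideals_emotional_shift_mean,ideals_emotional_shift_sd Moments of
#'   the emotional-subscale ideals difference (the contrast the ideals design
#'   flags). Defaults -2.16 and 5.15.
#' @param arm_probs Allocation probabilities of the three active arms.
#' @param seed Integer seed; the cohort is bit-identical across calls with
#'   the same seed.
#'
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_participants = 75L,
                             baseline_total_mean = 129.9,
                             baseline_total_sd = 36.5,
                             change_total_mean = -14.1,
                             change_total_sd = 31.9,
                             p_dh_persist = 0.493,
                             p_downward = 0.36,
                             p_upward = 0.147,
                             downward_shift_mean = -35,
                             upward_shift_mean = 40,
                             persist_change_mean = 9,
                             subscale_weights_t1 = c(restrictions = 1,
                                                     coping = 1.2,
                                                     social = 2,
                                                     emotional = 1.4,
                                                     identity = 0.8),
                             subscale_weights_t2 = c(restrictions = 0.8,
                                                     coping = 2,
                                                     social = 0.9,
                                                     emotional = 1.5,
                                                     identity = 0.6),
                             subscale_correlation = 0.6,
                             items_per_subscale = c(restrictions = 5L,
                                                    coping = 14L,
                                                    social = 5L,
                                                    emotional = 6L,
                                                    identity = 4L),
                             then_completers = 43L,
                             ideals_completers = 31L,
                             then_shift_mean = -15.9,
                             then_shift_sd = 32.3,
                             ideals_shift_mean = -6.19,
                             ideals_shift_sd = 20.26,
                             ideals_emotional_shift_mean = -2.16,
                             ideals_emotional_shift_sd = 5.15,
                             arm_probs = c(A = 32, B = 26, C = 17) / 75,
                             seed = NULL) {
  if (p_downward < 0 || p_upward < 0 || p_downward + p_upward > 1) {
    abort("need p_downward >= 0, p_upward >= 0, p_downward + p_upward <= 1",
          class = "proshift_config_error")
  }
  if (p_downward > p_dh_persist) {
    abort(paste("infeasible class probabilities: p_downward exceeds",
                "p_dh_persist, but downward recalibration occurs only among",
                "participants with persistent DH"),
          class = "proshift_config_error")
  }
  if (p_upward > 1 - p_dh_persist) {
    abort(paste("infeasible class probabilities: p_upward exceeds",
                "1 - p_dh_persist, but upward recalibration occurs only",
                "among participants whose DH resolved"),
          class = "proshift_config_error")
  }
  stopifnot(length(items_per_subscale) == 5L,
            all(items_per_subscale >= 1L),
            length(subscale_weights_t1) == 5L,
            length(subscale_weights_t2) == 5L,
            all(subscale_weights_t1 > 0), all(subscale_weights_t2 > 0),
            subscale_correlation >= 0, subscale_correlation < 1,
            n_participants >= 1L)
  structure(
    list(n_participants = as.integer(n_participants),
         baseline_total_mean = baseline_total_mean,
         baseline_total_sd = baseline_total_sd,
         change_total_mean = change_total_mean,
         change_total_sd = change_total_sd,
         p_dh_persist = p_dh_persist, p_downward = p_downward,
         p_upward = p_upward,
         downward_shift_mean = downward_shift_mean,
         upward_shift_mean = upward_shift_mean,
         persist_change_mean = persist_change_mean,
         subscale_weights_t1 = subscale_weights_t1,
         subscale_weights_t2 = subscale_weights_t2,
         subscale_correlation = subscale_correlation,
         items_per_subscale = as.integer(items_per_subscale),
         then_completers = as.integer(then_completers),
         ideals_completers = as.integer(ideals_completers),
         then_shift_mean = then_shift_mean, then_shift_sd = then_shift_sd,
         ideals_shift_mean = ideals_shift_mean,
         ideals_shift_sd = ideals_shift_sd,
         ideals_emotional_shift_mean = ideals_emotional_shift_mean,
         ideals_emotional_shift_sd = ideals_emotional_shift_sd,
         arm_probs = arm_probs, seed = seed),
    class = "generator_config"
  )
}

## Class-conditional change-noise SDs, proportional to the configured total
## change scale. The proportions were fixed once so that (a) class-consistent
## change directions dominate (truth recovery) and (b) the observed change SD
## stays in a realistic band; see the methods vignette.
change_noise_sds <- function(config) {
  s <- config$change_total_sd
  list(pn = 0.70 * s, down_latent = 0.38 * s, down_shift = 0.64 * s,
       rn = 0.63 * s, up_latent = 0.25 * s, up_shift = 0.46 * s)
}

## Mean of a normal rounded to the integer grid lo..hi and clipped there.
expected_grid_mean <- function(mu, sd, lo, hi) {
  g <- lo:hi
  upper <- stats::pnorm((g + 0.5 - mu) / sd)
  upper[length(g)] <- 1
  sum(g * (upper - c(0, upper[-length(g)])))
}

## Location mu such that the rounded-and-clipped normal has the target mean
## (compensates the floor/ceiling bias of the item grid).
calibrate_location <- function(target, sd, lo, hi) {
  if (sd <= 0 || target <= lo || target >= hi) return(target)
  stats::uniroot(function(m) expected_grid_mean(m, sd, lo, hi) - target,
                 lower = lo - 3 * sd, upper = hi + 3 * sd)$root
}

## E[clip(X, lo, hi) - X] for X ~ N(mu, sd): the mean lift induced by
## clipping at the instrument floor minus the drop at the ceiling.
clip_lift <- function(mu, sd, lo, hi) {
  zl <- (lo - mu) / sd
  zh <- (hi - mu) / sd
  ((lo - mu) * stats::pnorm(zl) + sd * stats::dnorm(zl)) -
    ((mu - hi) * stats::pnorm(-zh) + sd * stats::dnorm(zh))
}

## Solve the resolver-class location so the observed mixture mean equals the
## target, correcting for the expected instrument-range clipping of the
## week-8 total (a fixed-point iteration; the lift is a weak function of the
## solution and converges in a few steps).
resolver_change_mean <- function(config, baseline_mean = NULL,
                                 baseline_sd = NULL) {
  p_d <- config$p_downward; p_u <- config$p_upward
  p_pn <- config$p_dh_persist - p_d
  p_rn <- (1 - config$p_dh_persist) - p_u
  m_pn <- config$persist_change_mean
  d_sh <- config$downward_shift_mean; u_sh <- config$upward_shift_mean
  if (p_rn + p_u <= 0) return(0)
  solve_mr <- function(target) {
    (target - p_pn * m_pn - p_d * (m_pn + d_sh) - p_u * u_sh) / (p_rn + p_u)
  }
  m_r <- solve_mr(config$change_total_mean)
  if (is.null(baseline_mean) || is.null(baseline_sd) ||
      is.na(baseline_sd) || baseline_sd <= 0) {
    return(m_r)
  }
  sds <- change_noise_sds(config)
  class_sd <- c(sds$pn,
                sqrt(sds$down_latent^2 + sds$down_shift^2),
                sds$rn,
                sqrt(sds$up_latent^2 + sds$up_shift^2))
  p <- c(p_pn, p_d, p_rn, p_u)
  rng <- dheq_range(sum(config$items_per_subscale))
  for (it in 1:4) {
    class_m <- c(m_pn, m_pn + d_sh, m_r, m_r + u_sh)
    lifts <- clip_lift(baseline_mean + class_m,
                       sqrt(baseline_sd^2 + class_sd^2),
                       rng[["min"]], rng[["max"]])
    m_r <- solve_mr(config$change_total_mean - sum(p * lifts))
  }
  m_r
}

#' Simulate a DHEQ-like two-timepoint trial cohort
#'
#' Draws a latent severity per participant, builds correlated integer
#' subscale totals at screening on the 34-item 1-7 grid, assigns week-8
#' clinical persistence and recalibration classes, adds the corresponding
#' shifts to a status-consistent latent change, allocates the change across
#' subscales, and emits per-tooth clinical evidence consistent with the DH+
#' rule plus then-test and ideals columns for the configured completer
#' subsamples.
#'
#' @param config A [generator_config()].
#' @param keep_items Also emit the per-item scores (a deterministic
#'   disaggregation of each subscale total onto its items)? Default `TRUE`;
#'   switch off for large cohorts.
#' @return An object of class `synthetic_cohort`: a list with `participants`
#'   (the analysis table; never contains truth columns), `teeth` (long
#'   per-tooth evidence: `id`, `position`, `tactile_g`, `schiff`), `truth`
#'   (hidden labels: `id`, `persist`, `true_class`, `true_shift`,
#'   `latent_change`, `intended_change`), `items` (optional long item table)
#'   and `config`.
#' @export
#' @examples
#' cohort <- simulate_trial(generator_config(n_participants = 40, seed = 1))
#' head(cohort$participants)
simulate_trial <- function(config = generator_config(), keep_items = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  with_local_seed(config$seed, simulate_trial_impl(config, keep_items))
}

simulate_trial_impl <- function(config, keep_items) {
  n <- config$n_participants
  n_items <- config$items_per_subscale
  names(n_items) <- dheq_subscales

  ## --- baseline subscale totals (one latent severity factor) -------------
  w_base <- .baseline_subscale_means / sum(.baseline_subscale_means)
  m_k <- w_base * config$baseline_total_mean
  sd_k <- .baseline_subscale_sds * config$baseline_total_sd / 36.5
  w1 <- config$subscale_weights_t1 / mean(config$subscale_weights_t1)
  rho_k <- pmin(pmax(config$subscale_correlation * w1, 0.02), 0.95)
  l_k <- sd_k * sqrt(rho_k)
  u_k <- sd_k * sqrt(1 - rho_k)
  ## compensate the floor/ceiling bias of the item grid per subscale
  for (k in seq_len(5L)) {
    m_k[k] <- calibrate_location(m_k[k], sd_k[k], n_items[k], 7L * n_items[k])
  }
  z <- rnorm(n)
  s1_cont <- matrix(0, n, 5L)
  for (k in seq_len(5L)) {
    s1_cont[, k] <- m_k[k] + l_k[k] * z + u_k[k] * rnorm(n)
  }
  s1 <- clip_round(s1_cont, n_items)

  ## --- week-8 classes and total change -----------------------------------
  sds <- change_noise_sds(config)
  persist <- rbinom(n, 1L, config$p_dh_persist) == 1L
  true_class <- rep("none", n)
  pr_down <- if (config$p_dh_persist > 0) {
    config$p_downward / config$p_dh_persist
  } else 0
  pr_up <- if (config$p_dh_persist < 1) {
    config$p_upward / (1 - config$p_dh_persist)
  } else 0
  true_class[persist][runif(sum(persist)) < pr_down] <- "downward"
  true_class[!persist][runif(sum(!persist)) < pr_up] <- "upward"

  total1_pre <- rowSums(s1)
  m_pn <- config$persist_change_mean
  m_r <- resolver_change_mean(config, baseline_mean = mean(total1_pre),
                              baseline_sd = if (n > 1L) {
                                stats::sd(total1_pre)
                              } else NA_real_)
  latent <- numeric(n); shift <- numeric(n)
  cl <- paste0(ifelse(persist, "P", "R"), ".", true_class)
  idx <- cl == "P.none"
  latent[idx] <- rnorm(sum(idx), m_pn, sds$pn)
  idx <- cl == "P.downward"
  latent[idx] <- rnorm(sum(idx), m_pn, sds$down_latent)
  shift[idx] <- rnorm(sum(idx), config$downward_shift_mean, sds$down_shift)
  idx <- cl == "R.none"
  latent[idx] <- rnorm(sum(idx), m_r, sds$rn)
  idx <- cl == "R.upward"
  latent[idx] <- rnorm(sum(idx), m_r, sds$up_latent)
  shift[idx] <- rnorm(sum(idx), config$upward_shift_mean, sds$up_shift)
  change_intended <- latent + shift

  ## --- allocate change over subscales, rebuild week-8 totals --------------
  ## The change is controlled at the total level (clipping there is only the
  ## instrument range, far from the operating region, so the configured mean
  ## is preserved); subscale scores absorb it in proportion to the follow-up
  ## weights, with unit redistribution keeping every subscale on its item
  ## grid while the subscale totals still sum to the instrument total.
  total1 <- rowSums(s1)
  rng <- dheq_range(sum(n_items))
  total2 <- pmin(pmax(round(total1 + change_intended), rng["min"]),
                 rng["max"])
  v <- config$subscale_weights_t2 / sum(config$subscale_weights_t2)
  eta <- matrix(rnorm(n * 5L, sd = 4), n, 5L)
  eta <- eta - rowMeans(eta)             # allocation noise sums to zero
  delta <- outer(change_intended, unname(v)) + eta
  s2 <- clip_round(s1 + delta, n_items)
  s2 <- redistribute_to_total(s2, total2, n_items)

  ## --- per-tooth clinical evidence ---------------------------------------
  teeth <- simulate_teeth(persist)

  ## --- then-test / ideals completer columns ------------------------------
  rng <- dheq_range(sum(n_items))
  then_total <- rep(NA_real_, n)
  take <- sample.int(n, min(config$then_completers, n))
  then_total[take] <- pmin(pmax(total1[take] +
    round(rnorm(length(take), config$then_shift_mean, config$then_shift_sd)),
    rng["min"]), rng["max"])

  ideal_base <- rep(NA_real_, n); ideal_wk8 <- rep(NA_real_, n)
  ideal_emo_base <- rep(NA_real_, n); ideal_emo_wk8 <- rep(NA_real_, n)
  take <- sample.int(n, min(config$ideals_completers, n))
  ideal_base[take] <- pmin(pmax(round(rnorm(length(take), 60, 15)),
                                rng["min"]), rng["max"])
  ideal_wk8[take] <- pmin(pmax(ideal_base[take] +
    round(rnorm(length(take), config$ideals_shift_mean,
                config$ideals_shift_sd)), rng["min"]), rng["max"])
  emo_rng <- c(n_items[["emotional"]], 7L * n_items[["emotional"]])
  ideal_emo_base[take] <- pmin(pmax(round(rnorm(length(take), 12, 4)),
                                    emo_rng[1L]), emo_rng[2L])
  ideal_emo_wk8[take] <- pmin(pmax(ideal_emo_base[take] +
    round(rnorm(length(take), config$ideals_emotional_shift_mean,
                config$ideals_emotional_shift_sd)),
    emo_rng[1L]), emo_rng[2L])

  ## --- assemble ------------------------------------------------------------
  participants <- tibble(
    id = seq_len(n),
    arm = sample(names(config$arm_probs), n, replace = TRUE,
                 prob = config$arm_probs),
    age = round(pmin(pmax(rnorm(n, 37.6, 9.8), 18), 75)),
    female = rbinom(n, 1L, 0.81) == 1L
  )
  for (k in seq_len(5L)) {
    participants[[paste0(dheq_subscales[k], "_screening")]] <- s1[, k]
  }
  participants$total_screening <- total1
  for (k in seq_len(5L)) {
    participants[[paste0(dheq_subscales[k], "_week8")]] <- s2[, k]
  }
  participants$total_week8 <- total2
  for (k in seq_len(5L)) {
    participants[[paste0(dheq_subscales[k], "_change")]] <- s2[, k] - s1[, k]
  }
  participants$total_change <- total2 - total1
  participants$dh_week8 <- factor(ifelse(persist, "DH+", "DH-"),
                                  levels = dh_levels)
  participants$then_total <- then_total
  participants$ideal_total_screening <- ideal_base
  participants$ideal_total_week8 <- ideal_wk8
  participants$ideal_emotional_screening <- ideal_emo_base
  participants$ideal_emotional_week8 <- ideal_emo_wk8

  truth <- tibble(
    id = seq_len(n), persist = persist,
    true_class = factor(true_class, levels = c("downward", "upward", "none")),
    true_shift = shift, latent_change = latent,
    intended_change = change_intended
  )

  items <- NULL
  if (keep_items) {
    items <- bind_rows(
      disaggregate_items(s1, n_items, "screening"),
      disaggregate_items(s2, n_items, "week8")
    )
  }

  structure(list(participants = participants, teeth = teeth, truth = truth,
                 items = items, config = config),
            class = "synthetic_cohort")
}

## Move single points between subscales until they sum to the target total,
## always adjusting the subscale with the most room, so every subscale stays
## within [n_items, 7 * n_items] and the sum is exact.
redistribute_to_total <- function(s2, target, n_items) {
  lo <- n_items; hi <- 7L * n_items
  for (i in seq_len(nrow(s2))) {
    d <- target[i] - sum(s2[i, ])
    while (d != 0) {
      if (d > 0) {
        k <- which.max(hi - s2[i, ])
        if (hi[k] - s2[i, k] <= 0) break
        s2[i, k] <- s2[i, k] + 1; d <- d - 1
      } else {
        k <- which.max(s2[i, ] - lo)
        if (s2[i, k] - lo[k] <= 0) break
        s2[i, k] <- s2[i, k] - 1; d <- d + 1
      }
    }
  }
  s2
}

## Round to the item grid and clip each subscale total into its achievable
## range [n_items, 7 * n_items].
clip_round <- function(s_cont, n_items) {
  s <- round(s_cont)
  for (k in seq_along(n_items)) {
    s[, k] <- pmin(pmax(s[, k], n_items[k]), 7L * n_items[k])
  }
  s
}

## Deterministic disaggregation of integer subscale totals onto items:
## every item gets floor(total / n_items), the remainder is spread one point
## each over the leading items. Scores stay in 1..7 and sum exactly.
disaggregate_items <- function(s, n_items, timepoint) {
  n <- nrow(s)
  out <- vector("list", length(n_items))
  for (k in seq_along(n_items)) {
    nk <- n_items[k]
    q <- s[, k] %/% nk; r <- s[, k] %% nk
    scores <- matrix(q, n, nk) + outer(r, seq_len(nk), `>=`)
    out[[k]] <- tibble(
      id = rep(seq_len(n), times = nk),
      timepoint = timepoint,
      subscale = names(n_items)[k],
      item = rep(seq_len(nk), each = n),
      score = as.vector(scores)
    )
  }
  bind_rows(out)
}

## Per-tooth evidence consistent with the classification rule: persisters get
## at least two non-adjacent sensitive teeth; resolvers get zero, one, or an
## adjacent-only pair of sensitive teeth (still DH-). Six assessed teeth per
## participant, FDI positions.
simulate_teeth <- function(persist) {
  pool <- c(11:16, 21:26, 31:36, 41:46)
  n <- length(persist)
  n_teeth <- 6L
  pos <- matrix(0L, n_teeth, n)
  tac <- matrix(0, n_teeth, n)
  sch <- matrix(0L, n_teeth, n)
  for (i in seq_len(n)) {
    p <- sample(pool, n_teeth)
    sens <- logical(n_teeth)
    if (persist[i]) {
      pair <- first_nonadjacent_pair(p)
      sens[pair] <- TRUE
      extra <- rbinom(1L, n_teeth - 2L, 0.2)
      if (extra > 0) {
        sens[sample(which(!sens), extra)] <- TRUE
      }
    } else {
      u <- runif(1)
      if (u < 0.35) {
        sens[sample.int(n_teeth, 1L)] <- TRUE
      } else if (u < 0.5) {
        pair <- first_adjacent_pair(p)
        if (!is.null(pair)) sens[pair] <- TRUE
        else sens[sample.int(n_teeth, 1L)] <- TRUE
      }
    }
    tac[sens, i] <- runif(sum(sens), 5, 20)
    sch[sens, i] <- sample(2:3, sum(sens), replace = TRUE)
    ns <- !sens
    borderline <- ns & runif(n_teeth) < 0.2
    tac[borderline, i] <- runif(sum(borderline), 10, 20)
    sch[borderline, i] <- sample(0:1, sum(borderline), replace = TRUE)
    rest <- ns & !borderline
    tac[rest, i] <- runif(sum(rest), 21, 65)
    sch[rest, i] <- sample(0:2, sum(rest), replace = TRUE,
                           prob = c(0.5, 0.3, 0.2))
    pos[, i] <- p
  }
  tibble(id = rep(seq_len(n), each = n_teeth),
         position = as.vector(pos),
         tactile_g = round(as.vector(tac), 1),
         schiff = as.vector(sch))
}

first_nonadjacent_pair <- function(p) {
  quad <- p %/% 10L; num <- p %% 10L
  for (i in seq_along(p)[-1L]) {
    for (j in seq_len(i - 1L)) {
      if (quad[i] != quad[j] || abs(num[i] - num[j]) > 1L) return(c(j, i))
    }
  }
  c(1L, 2L)   # unreachable for six distinct teeth
}

first_adjacent_pair <- function(p) {
  quad <- p %/% 10L; num <- p %% 10L
  for (i in seq_along(p)[-1L]) {
    for (j in seq_len(i - 1L)) {
      if (quad[i] == quad[j] && abs(num[i] - num[j]) == 1L) return(c(j, i))
    }
  }
  NULL
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic DHEQ cohort: %d participants (seed %s)\n",
              nrow(x$participants),
              if (is.null(x$config$seed)) "unset" else x$config$seed))
  cat(sprintf("  baseline total %.1f (SD %.1f); change %.1f (SD %.1f); DH+ %.1f%%\n",
              mean(x$participants$total_screening),
              stats::sd(x$participants$total_screening),
              mean(x$participants$total_change),
              stats::sd(x$participants$total_change),
              100 * mean(x$participants$dh_week8 == "DH+")))
  invisible(x)
}

#' Marginal summary of a cohort in the trial-table layout
#'
#' Means and SDs of the subscale and total scores at screening and for the
#' 8-week change, per arm and pooled, plus the week-8 clinical status split
#' and demographics.
#'
#' @param cohort A `synthetic_cohort` or a participants data frame in the
#'   generator's column layout.
#' @return A tibble: `block` (baseline / change / status / demographics),
#'   `measure`, `arm` (including `"pooled"`), `n`, `mean` (a percentage for
#'   status and the female row) and `sd` (`NA` where undefined).
#' @export
summarize_marginals <- function(cohort) {
  p <- if (inherits(cohort, "synthetic_cohort")) cohort$participants
       else as_tibble(cohort)
  if (!nrow(p)) abort("empty cohort", class = "proshift_input_error")
  score_cols <- c(paste0(dheq_subscales, "_screening"), "total_screening",
                  paste0(dheq_subscales, "_change"), "total_change")
  score_cols <- intersect(score_cols, names(p))
  arms <- if ("arm" %in% names(p)) p$arm else rep("A", nrow(p))
  per_arm <- function(sub, label) {
    long <- tidyr::pivot_longer(sub[score_cols], dplyr::everything(),
                                names_to = "measure", values_to = "value")
    scores <- long %>%
      group_by(.data$measure) %>%
      summarise(n = sum(!is.na(.data$value)),
                mean = mean(.data$value, na.rm = TRUE),
                sd = if (sum(!is.na(.data$value)) > 1L) {
                  stats::sd(.data$value, na.rm = TRUE)
                } else NA_real_,
                .groups = "drop") %>%
      mutate(block = ifelse(grepl("_change$|^total_change$", .data$measure),
                            "change", "baseline"))
    extra <- tibble(
      measure = c("dh_positive", "dh_negative", "age", "female"),
      n = nrow(sub),
      mean = c(
        if ("dh_week8" %in% names(sub)) {
          c(100 * mean(sub$dh_week8 == "DH+"), 100 * mean(sub$dh_week8 == "DH-"))
        } else c(NA_real_, NA_real_),
        if ("age" %in% names(sub)) mean(sub$age) else NA_real_,
        if ("female" %in% names(sub)) 100 * mean(sub$female) else NA_real_
      ),
      sd = c(NA_real_, NA_real_,
             if ("age" %in% names(sub) && nrow(sub) > 1L) stats::sd(sub$age)
             else NA_real_, NA_real_),
      block = c("status", "status", "demographics", "demographics")
    )
    bind_rows(scores, extra) %>% mutate(arm = label)
  }
  out <- bind_rows(
    purrr::map(sort(unique(arms)), function(a) per_arm(p[arms == a, ], a)),
    per_arm(p, "pooled")
  )
  out %>% select("block", "measure", "arm", "n", "mean", "sd") %>%
    arrange(match(.data$block, c("demographics", "baseline", "change",
                                 "status")),
            match(.data$measure, c(score_cols, "dh_positive", "dh_negative",
                                   "age", "female")),
            .data$arm)
}
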