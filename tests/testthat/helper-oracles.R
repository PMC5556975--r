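# Independent oracles and fixture builders, written without reference to the
# package internals they check.

# Brute-force best split: enumerate every (predictor, threshold) midpoint and,
# for categoricals, every proper subset of levels. Returns the maximal
# improvement and the argmax set (there may be ties).
oracle_best_split <- function(data, dependent, predictors,
                              min_child = 1L, min_parent = 1L) {
  y <- data[[dependent]]
  sse <- function(v) if (length(v)) sum((v - mean(v))^2) else 0
  n <- length(y)
  if (n < min_parent || sse(y) < 1e-12) return(NULL)
  best <- list(improvement = 0, splits = list())
  consider <- function(go_left, x_obs, y_obs, desc) {
    nl <- sum(go_left); nr <- sum(!go_left)
    if (nl < min_child || nr < min_child) return()
    imp <- sse(y_obs) - sse(y_obs[go_left]) - sse(y_obs[!go_left])
    if (imp > best$improvement + 1e-9) {
      best$improvement <<- imp
      best$splits <<- list(desc)
    } else if (abs(imp - best$improvement) <= 1e-9 && imp > 0) {
      best$splits <<- c(best$splits, list(desc))
    }
  }
  for (p in predictors) {
    x <- data[[p]]
    obs <- !is.na(x)
    x_obs <- x[obs]; y_obs <- y[obs]
    if (!length(x_obs)) next
    if (is.numeric(x_obs)) {
      ux <- sort(unique(x_obs))
      if (length(ux) < 2) next
      thr <- (ux[-1] + ux[-length(ux)]) / 2
      for (t in thr) {
        consider(x_obs <= t, x_obs, y_obs, list(predictor = p, threshold = t))
      }
    } else {
      lev <- unique(as.character(x_obs))
      if (length(lev) < 2) next
      for (mask in 1:(2^length(lev) - 2)) {
        left <- lev[bitwAnd(mask, 2^(seq_along(lev) - 1)) > 0]
        consider(as.character(x_obs) %in% left, x_obs, y_obs,
                 list(predictor = p, left = left))
      }
    }
  }
  if (best$improvement <= 0) return(NULL)
  best
}

# Textbook one-sample t.
oracle_t <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  s <- sqrt(sum((x - m)^2) / (n - 1))
  t <- m / (s / sqrt(n))
  list(n = n, mean = m, sd = s, t = t,
       p = 2 * stats::pt(-abs(t), df = n - 1))
}

# A vector of length n with exactly the requested mean and sample SD:
# symmetric pair construction around the mean.
vector_with_moments <- function(n, mean, sd) {
  half <- (n - 1) %/% 2
  d <- sd * sqrt((n - 1) / (2 * half))
  x <- c(rep(mean - d, half), rep(mean + d, half), rep(mean, n - 2 * half))
  stopifnot(length(x) == n, abs(mean(x) - mean) < 1e-12,
            abs(stats::sd(x) - sd) < 1e-9)
  x
}

# Random small tables for the split-oracle comparisons: numeric and
# categorical predictors, with optional missingness and duplicated values to
# exercise ties.
random_table <- function(n, n_pred, seed) {
  set.seed(seed)
  out <- data.frame(y = round(stats::rnorm(n), 1))
  for (j in seq_len(n_pred)) {
    kind <- sample(c("num", "int", "cat"), 1)
    x <- switch(kind,
      num = round(stats::rnorm(n), 1),
      int = sample.int(4L, n, replace = TRUE),
      cat = sample(letters[1:sample(2:4, 1)], n, replace = TRUE)
    )
    if (stats::runif(1) < 0.3) x[sample.int(n, max(1, n %/% 10))] <- NA
    out[[paste0("x", j)]] <- x
  }
  out
}

# Small two-timepoint cohort with a controllable structure, for pipeline and
# response-shift tests without the full generator.
toy_cohort <- function(n = 40, seed = 1) {
  set.seed(seed)
  status <- factor(rep(c("DH+", "DH-"), length.out = n),
                   levels = c("DH-", "DH+"))
  change <- ifelse(status == "DH+", stats::rnorm(n, -30, 5),
                   stats::rnorm(n, 10, 5))
  tibble::tibble(
    id = seq_len(n),
    dh_week8 = status,
    total_change = change,
    coping_change = change * 0.5 + stats::rnorm(n, 0, 2),
    social_change = stats::rnorm(n, 0, 3)
  )
}
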