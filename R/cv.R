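#' Cross-validated risk of a regression tree specification
#'
#' Splits the sample into `controls$cv_folds` roughly equal parts by seeded
#' random shuffling (optionally balanced across outcome quantiles), grows a
#' tree on each training complement and scores the held-out part by squared
#' prediction error. The risk is the mean squared error over all cases; its
#' standard error is the standard error of the per-case squared errors.
#' Repeated calls with the same seed are identical.
#'
#' @inheritParams grow_tree
#' @return A tibble with columns `risk_cv`, `risk_cv_se`, `n`, `folds`.
#' @export
cv_risk <- function(data, dependent, predictors, controls = tree_controls(),
                    root_split = NULL) {
  n <- nrow(data)
  k <- controls$cv_folds
  if (k > n) {
    abort("cv_folds exceeds the number of cases", class = "proshift_input_error")
  }
  folds <- cv_fold_assignment(data[[dependent]], k, controls$seed,
                              controls$stratify_folds)
  sq_err <- numeric(n)
  for (f in seq_len(k)) {
    test <- folds == f
    fit <- grow_tree(data[!test, , drop = FALSE], dependent, predictors,
                     controls, root_split = root_split, cv = FALSE)
    pred <- predict(fit, data[test, , drop = FALSE])
    sq_err[test] <- (data[[dependent]][test] - pred)^2
  }
  tibble(risk_cv = mean(sq_err),
         risk_cv_se = stats::sd(sq_err) / sqrt(n),
         n = n, folds = k)
}

## Seeded fold labels 1..k, sizes as equal as possible. With stratification,
## cases are blocked by outcome order and folds rotated within blocks so each
## fold sees a similar outcome distribution.
cv_fold_assignment <- function(y, k, seed, stratify = FALSE) {
  n <- length(y)
  with_local_seed(seed, {
    if (stratify) {
      folds <- integer(n)
      ord <- order(y, sample.int(n))       # random tie order
      folds[ord] <- as.vector(vapply(seq_len(ceiling(n / k)),
                                     function(i) sample.int(k),
                                     integer(k)))[seq_len(n)]
      folds
    } else {
      sample(rep_len(seq_len(k), n))
    }
  })
}
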