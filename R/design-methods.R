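## Design-based recalibration statistics: the then-test ('Then' - 'Pre'
## retrospective re-rating) and the ideals approach ('Ideal follow-up' -
## 'Ideal baseline'), each summarised by a one-sample t-test of the paired
## difference scores against zero. Complete-case per contrast: participants
## missing either side are dropped, so the two contrasts may use different
## subsamples (e.g. 43 then-test and 31 ideals completers out of 75).

#' Paired difference scores
#'
#' Computes `a - b` per participant, dropping pairs with either side missing.
#'
#' @param data Data frame, one row per participant.
#' @param a,b Names of the two score columns (`a` minus `b`; e.g. then-score
#'   minus pre-score).
#' @param id Optional participant-id column name, carried through.
#' @return A tibble with columns `id` (when supplied) and `diff`; the number
#'   of retained pairs is `nrow()` of the result.
#' @export
difference_scores <- function(data, a, b, id = NULL) {
  missing_cols <- setdiff(c(a, b, id), names(data))
  if (length(missing_cols)) {
    abort(paste0("unknown column(s): ", paste(missing_cols, collapse = ", ")),
          class = "proshift_config_error")
  }
  keep <- !is.na(data[[a]]) & !is.na(data[[b]])
  if (!any(keep)) {
    abort("no complete pairs to difference", class = "proshift_input_error")
  }
  out <- tibble(diff = data[[a]][keep] - data[[b]][keep])
  if (!is.null(id)) out <- tibble(id = data[[id]][keep], diff = out$diff)
  out
}

#' One-sample recalibration test on difference scores
#'
#' Tests the mean of per-participant difference scores against zero with a
#' one-sample t-test (sample SD, n-1 denominator; two-tailed p from the t
#' distribution with n-1 df). A negative mean on the then-test contrast is
#' read as lowered internal standards (downward recalibration); a negative
#' mean on the ideals contrast as raised expectations (upward recalibration).
#'
#' @param diffs Numeric vector of difference scores, or a data frame from
#'   [difference_scores()] (its `diff` column is used).
#' @param contrast One of `"then_test"`, `"ideals"`, `"total_change"`; sets
#'   the interpretation string only.
#' @param scope Label for the score level tested, e.g. `"total"` or a
#'   subscale name.
#' @return A one-row tibble: `contrast`, `scope`, `n`, `mean_diff`,
#'   `sd_diff`, `t`, `p_two_tailed`, `interpretation`.
#' @export
#' @examples
#' recalibration_test(c(-20, -8, -15, 3), contrast = "then_test")
recalibration_test <- function(diffs,
                               contrast = c("then_test", "ideals",
                                            "total_change"),
                               scope = "total") {
  contrast <- match.arg(contrast)
  if (is.data.frame(diffs)) diffs <- diffs$diff
  diffs <- diffs[!is.na(diffs)]
  n <- length(diffs)
  if (n < 2L) abort("need at least two difference scores",
                    class = "proshift_input_error")
  s <- stats::sd(diffs)
  if (s == 0) {
    abort("difference scores are constant; the t statistic is undefined",
          class = "proshift_input_error")
  }
  tt <- stats::t.test(diffs, mu = 0)
  m <- mean(diffs)
  interpretation <- switch(
    contrast,
    then_test = if (m < 0) "downward recalibration (lowered internal standards)"
                else "upward recalibration (raised internal standards)",
    ideals = if (m < 0) "upward recalibration (raised ideals/expectations)"
             else "downward recalibration (lowered ideals/expectations)",
    total_change = if (m < 0) "improved quality of life (lower impact scores)"
                   else "worse quality of life (higher impact scores)"
  )
  tibble(contrast = contrast, scope = scope, n = n,
         mean_diff = m, sd_diff = s,
         t = unname(tt$statistic), p_two_tailed = unname(tt$p.value),
         interpretation = interpretation)
}

#' Then-test recalibration contrast
#'
#' Differences the retrospective baseline re-rating ('then') against the
#' original baseline rating ('pre'), complete-case, and applies
#' [recalibration_test()].
#'
#' @inheritParams difference_scores
#' @param then,pre Column names of the then-score and the pre-score.
#' @param scope Score level label.
#' @return See [recalibration_test()].
#' @export
then_test <- function(data, then, pre, scope = "total") {
  recalibration_test(difference_scores(data, then, pre),
                     contrast = "then_test", scope = scope)
}

#' Ideals recalibration contrast
#'
#' Differences the ideal rating at follow-up against the ideal rating at
#' baseline, complete-case, and applies [recalibration_test()].
#'
#' @inheritParams difference_scores
#' @param ideal_followup,ideal_baseline Column names of the two ideal scores.
#' @param scope Score level label.
#' @return See [recalibration_test()].
#' @export
ideals_test <- function(data, ideal_followup, ideal_baseline,
                        scope = "total") {
  recalibration_test(difference_scores(data, ideal_followup, ideal_baseline),
                     contrast = "ideals", scope = scope)
}
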